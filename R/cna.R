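# Arm-level copy-number aberration calling from het-SNP B-allele frequencies
# and normalized read depth.
#
# A segment is scored by two observables: the mean folded BAF deviation
# |BAF - 0.5| over its heterozygous germline SNPs, and its mean coverage
# divided by the genome-wide baseline. Deviated BAF with raised coverage is
# an amplification, with lowered coverage a deletion, and with unchanged
# coverage a copy-neutral LOH. Thresholds operationalize "raised/lowered"
# as fixed ratio cutoffs and are exposed in default_thresholds().

#' Normalize per-bin coverage by a baseline
#'
#' @param depths numeric vector of mean depths per bin.
#' @param baseline positive scalar; defaults to the mean of `depths`, so the
#'   mean ratio is 1 by construction.
#' @return numeric vector of coverage ratios (depth / baseline).
#' @export
#' @examples
#' normalize_coverage(c(100, 150, 50))
normalize_coverage <- function(depths, baseline = mean(depths)) {
  if (length(depths) == 0L) stop_ct("empty bin list")
  if (!is.finite(baseline) || baseline <= 0) stop_ct("baseline must be > 0")
  depths / baseline
}

#' Mean folded B-allele-frequency deviation of a segment
#'
#' Per SNP, BAF = alt/(ref+alt) folded as |BAF - 0.5|; the segment value is
#' the mean of folded values. Segments with fewer than `min_snps` usable
#' SNPs are UNCALLABLE (baf_dev = NA), not an error.
#'
#' @param ref_count,alt_count integer vectors of het-SNP read counts.
#' @param min_snps minimum usable SNPs (default 10).
#' @param min_depth SNPs with total depth below this are dropped (default 10).
#' @return list with `baf_dev` (NA when uncallable) and `n_snps` used.
#' @export
#' @examples
#' segment_baf_dev(rep(25, 20), rep(75, 20))$baf_dev  # 0.25
segment_baf_dev <- function(ref_count, alt_count, min_snps = 10L, min_depth = 10L) {
  stopifnot(length(ref_count) == length(alt_count))
  tot <- ref_count + alt_count
  keep <- !is.na(tot) & tot >= min_depth
  n <- sum(keep)
  if (n < min_snps) return(list(baf_dev = NA_real_, n_snps = n))
  baf <- alt_count[keep] / tot[keep]
  list(baf_dev = mean(abs(baf - 0.5)), n_snps = n)
}

#' Classify a segment from BAF deviation and coverage ratio
#'
#' Deterministic total rule over the (baf_dev, cov_ratio) plane:
#' deviated BAF with raised coverage is AMP, with lowered coverage DEL,
#' with unchanged coverage CN_LOH; undeviated BAF is NEUTRAL. Vectorized.
#'
#' @param baf_dev folded BAF deviation in [0, 0.5]; NA gives UNCALLABLE.
#' @param cov_ratio normalized coverage ratio (> 0).
#' @param thresholds list with baf_dev_min, cov_gain_min, cov_loss_max
#'   (see [default_thresholds()]).
#' @return character vector of states (AMP, DEL, CN_LOH, NEUTRAL, UNCALLABLE).
#' @export
#' @examples
#' classify_segment(0.15, 1.4)   # AMP
#' classify_segment(0.20, 1.0)   # CN_LOH
classify_segment <- function(baf_dev, cov_ratio, thresholds = default_thresholds()) {
  n <- max(length(baf_dev), length(cov_ratio))
  baf_dev <- rep_len(baf_dev, n); cov_ratio <- rep_len(cov_ratio, n)
  out <- rep("UNCALLABLE", n)
  ok <- !is.na(baf_dev) & !is.na(cov_ratio)
  dev <- ok & baf_dev >= thresholds$baf_dev_min
  out[ok & !dev] <- "NEUTRAL"
  out[dev & cov_ratio >= thresholds$cov_gain_min] <- "AMP"
  out[dev & cov_ratio <= thresholds$cov_loss_max] <- "DEL"
  out[dev & cov_ratio > thresholds$cov_loss_max & cov_ratio < thresholds$cov_gain_min] <- "CN_LOH"
  out
}

#' Packaged GRCh37 chromosome-arm boundary table
#'
#' Arm boundaries (0-based half-open) for chr1-22 and chrX at whole-Mb
#' resolution, sufficient for arm-level aggregation.
#'
#' @return data.frame with columns chrom, arm, start, end.
#' @export
arm_boundaries <- function() {
  path <- system.file("extdata", "arm_boundaries_grch37.tsv", package = "clonetrace")
  df <- read_canonical_tsv(path)
  data.frame(chrom = df$chrom, arm = df$arm,
             start = as.numeric(df$start), end = as.numeric(df$end),
             stringsAsFactors = FALSE)
}

#' Aggregate segment calls to chromosome arms
#'
#' An arm takes a non-NEUTRAL state when at least `arm_frac` (default 80%)
#' of its callable length (length covered by called segments) shares that
#' state; otherwise it is NEUTRAL. Arms with no callable overlap are
#' UNCALLABLE.
#'
#' @param segments data.frame with chrom, start, end, state (0-based
#'   half-open, non-overlapping).
#' @param arms arm boundary table (default: packaged GRCh37 arms).
#' @param thresholds see [default_thresholds()]; uses `arm_frac`.
#' @return data.frame with columns chrom, arm, state, callable_bp, frac.
#' @export
arm_calls <- function(segments, arms = arm_boundaries(),
                      thresholds = default_thresholds()) {
  check_no_overlap(segments)
  seg_gr <- GenomicRanges::GRanges(segments$chrom,
    IRanges::IRanges(start = segments$start + 1, end = segments$end))
  arm_gr <- GenomicRanges::GRanges(arms$chrom,
    IRanges::IRanges(start = arms$start + 1, end = arms$end))
  # differing chromosome sets between query and subject are expected here
  hits <- suppressWarnings(GenomicRanges::findOverlaps(arm_gr, seg_gr))
  out <- data.frame(chrom = arms$chrom, arm = arms$arm,
                    state = "UNCALLABLE", callable_bp = 0, frac = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(arms))) {
    js <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    js <- js[segments$state[js] %in% CNA_STATES]
    if (!length(js)) next
    ov <- pmin(segments$end[js], arms$end[i]) - pmax(segments$start[js], arms$start[i])
    callable <- sum(ov)
    by_state <- tapply(ov, segments$state[js], sum)
    top <- names(by_state)[which.max(by_state)]
    frac <- as.numeric(by_state[top]) / callable
    out$callable_bp[i] <- callable
    out$frac[i] <- frac
    out$state[i] <- if (top != "NEUTRAL" && frac >= thresholds$arm_frac) top else "NEUTRAL"
  }
  out
}

#' Call arm-level copy number from raw het-SNP and depth data
#'
#' Convenience wrapper: computes per-arm folded BAF deviation from het SNPs,
#' per-arm normalized coverage from bin depths (baseline = genome-wide mean),
#' classifies each arm with [classify_segment()].
#'
#' @param snps data.frame with chrom, pos (1-based), ref_count, alt_count.
#' @param bins data.frame with chrom, start, end (0-based half-open), depth.
#' @param arms arm boundary table.
#' @param thresholds see [default_thresholds()].
#' @return data.frame: chrom, arm, start, end, state, baf_dev, cov_ratio, n_snps.
#' @export
call_arms_from_snps <- function(snps, bins, arms = arm_boundaries(),
                                thresholds = default_thresholds()) {
  ratios <- normalize_coverage(bins$depth)
  out <- arms
  out$state <- "UNCALLABLE"; out$baf_dev <- NA_real_
  out$cov_ratio <- NA_real_; out$n_snps <- 0L
  for (i in seq_len(nrow(arms))) {
    in_arm <- snps$chrom == arms$chrom[i] &
      snps$pos > arms$start[i] & snps$pos <= arms$end[i]
    bd <- segment_baf_dev(snps$ref_count[in_arm], snps$alt_count[in_arm],
                          min_snps = thresholds$min_snps,
                          min_depth = thresholds$min_depth)
    bin_in <- bins$chrom == arms$chrom[i] &
      bins$start >= arms$start[i] & bins$end <= arms$end[i]
    cr <- if (any(bin_in)) mean(ratios[bin_in]) else NA_real_
    out$baf_dev[i] <- bd$baf_dev
    out$n_snps[i] <- bd$n_snps
    out$cov_ratio[i] <- cr
    out$state[i] <- classify_segment(bd$baf_dev, cr, thresholds)
  }
  out
}
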