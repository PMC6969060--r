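# Copy-number- and purity-aware correction of somatic allele frequencies.
#
# The read-count correction assumes the copy-number event always affects the
# mutated allele to the largest extent (duplication lands on the mutated
# chromosome, deletion removes the reference chromosome, CN-LOH duplicates
# the mutated homolog), so each state has a closed-form count adjustment:
#
#   duplication   Ref' = Ref          Alt' = Alt/2
#   deletion      Ref' = Ref + Alt    Alt' = Alt
#   male X        Ref' = Ref*2 + Alt  Alt' = Alt   (hemizygous, LOH-like)
#   CN-LOH        Ref' = Ref + Alt/2  Alt' = Alt/2
#
# Adjusted counts may be fractional (Alt/2 on odd counts); they are kept
# exact — halves are dyadic rationals and representable without drift —
# and only the final frequency matters. The corrected VAF is then divided
# by the histology-estimated tumor content and capped at 1.

#' Adjust ref/alt read counts for the copy-number state
#'
#' Applies the closed-form count corrections above. On chromosome X of a
#' male patient the X rule replaces any copy-number rule (the composition
#' is not defined); such variants additionally get an AMBIGUOUS flag in
#' [correct_sample()] when their segment is non-neutral. X variants with
#' unknown sex cannot be corrected and are EXCLUDED upstream.
#'
#' @param ref,alt nonnegative read counts (ref + alt > 0).
#' @param cna_state one of NEUTRAL, AMP, DEL, CN_LOH.
#' @param chrom chromosome name; "X" (optionally "chrX") triggers the X rule.
#' @param sex "MALE", "FEMALE" or "UNKNOWN".
#' @return list with `ref_adj`, `alt_adj` (possibly fractional).
#' @export
#' @examples
#' adjust_counts(50, 50, "AMP")     # ref 50, alt 25
#' adjust_counts(30, 70, "DEL")     # ref 100, alt 70
#' adjust_counts(40, 60, "CN_LOH")  # ref 70, alt 30
adjust_counts <- function(ref, alt, cna_state, chrom = "1", sex = "FEMALE") {
  if (is.na(ref) || is.na(alt) || ref < 0 || alt < 0 || ref + alt <= 0)
    stop_ct("invalid counts (ref=%s, alt=%s)", ref, alt)
  if (!cna_state %in% CNA_STATES)
    stop_ct("unknown cna_state '%s'", cna_state)
  if (is_chrX(chrom)) {
    if (identical(sex, "MALE"))
      return(list(ref_adj = ref * 2 + alt, alt_adj = alt))
    if (!identical(sex, "FEMALE"))
      stop_ct("sex must be known to correct a chromosome X variant")
  }
  switch(cna_state,
    NEUTRAL = list(ref_adj = ref, alt_adj = alt),
    AMP     = list(ref_adj = ref, alt_adj = alt / 2),
    DEL     = list(ref_adj = ref + alt, alt_adj = alt),
    CN_LOH  = list(ref_adj = ref + alt / 2, alt_adj = alt / 2)
  )
}

is_chrX <- function(chrom) toupper(sub("^chr", "", chrom)) == "X"

is_autosome <- function(chrom) grepl("^[0-9]+$", sub("^chr", "", chrom))

#' Scale a CNA-adjusted VAF by tumor content
#'
#' corrected_vaf = min(adjusted VAF / tumor_content, 1). Values that hit
#' the cap are flagged CAPPED by [correct_sample()].
#'
#' @param ref_adj,alt_adj adjusted counts from [adjust_counts()].
#' @param tumor_content purity in (0, 1].
#' @return corrected VAF in [0, 1].
#' @export
#' @examples
#' purity_correct(80, 20, 0.5)  # 0.4
purity_correct <- function(ref_adj, alt_adj, tumor_content) {
  if (is.na(tumor_content) || tumor_content <= 0 || tumor_content > 1)
    stop_ct("tumor_content must be in (0, 1]")
  min((alt_adj / (ref_adj + alt_adj)) / tumor_content, 1.0)
}

#' Correct all variants of one sample for CNA context and tumor content
#'
#' Each variant takes the copy-number state of the segment containing it
#' (NEUTRAL when no segment covers it), gets its counts adjusted with
#' [adjust_counts()] and its frequency scaled with [purity_correct()].
#' Variants on chromosome X with unknown sex, and variants on non-autosomes
#' other than X (Y, MT), are excluded and listed in the exclusion report.
#'
#' @param variants data.frame from [read_variants()].
#' @param segments data.frame from [read_segments()] (non-overlapping);
#'   NULL means no CNA data, all NEUTRAL.
#' @param tumor_content purity in (0, 1].
#' @param sex patient sex ("MALE", "FEMALE", "UNKNOWN").
#' @return list with `corrected` — data.frame (variant_id, chrom, pos,
#'   ref_count, alt_count, raw_vaf, cna_state, ref_adj, alt_adj,
#'   corrected_vaf, cellular_proportion, flags) — and `excluded`
#'   (variant_id, reason).
#' @export
correct_sample <- function(variants, segments = NULL, tumor_content = 1.0,
                           sex = "UNKNOWN") {
  n <- nrow(variants)
  state <- rep("NEUTRAL", n)
  if (!is.null(segments) && nrow(segments)) {
    check_no_overlap(segments)
    var_gr <- GenomicRanges::GRanges(variants$chrom,
      IRanges::IRanges(start = variants$pos, width = 1L))
    seg_gr <- GenomicRanges::GRanges(segments$chrom,
      IRanges::IRanges(start = segments$start + 1, end = segments$end))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(var_gr, seg_gr, select = "first"))
    hit_state <- segments$state[hits]
    state[!is.na(hits)] <- hit_state[!is.na(hits)]
  }
  on_x <- is_chrX(variants$chrom)
  excl <- rep(NA_character_, n)
  excl[!is_autosome(variants$chrom) & !on_x] <- "NON_AUTOSOME"
  excl[on_x & sex == "UNKNOWN"] <- "X_SEX_UNKNOWN"
  keep <- is.na(excl)

  out <- variants[keep, c("variant_id", "chrom", "pos", "ref_count", "alt_count")]
  st <- state[keep]
  k <- nrow(out)
  ref_adj <- alt_adj <- cvaf <- numeric(k)
  flags <- character(k)
  for (i in seq_len(k)) {
    adj <- adjust_counts(out$ref_count[i], out$alt_count[i], st[i],
                         chrom = out$chrom[i], sex = sex)
    ref_adj[i] <- adj$ref_adj; alt_adj[i] <- adj$alt_adj
    cvaf[i] <- purity_correct(adj$ref_adj, adj$alt_adj, tumor_content)
    fl <- character(0)
    if ((adj$alt_adj / (adj$ref_adj + adj$alt_adj)) / tumor_content > 1) fl <- c(fl, "CAPPED")
    if (is_chrX(out$chrom[i]) && sex == "MALE" && st[i] != "NEUTRAL") fl <- c(fl, "AMBIGUOUS")
    flags[i] <- paste(fl, collapse = ",")
  }
  out$raw_vaf <- out$alt_count / (out$ref_count + out$alt_count)
  out$cna_state <- st
  out$ref_adj <- ref_adj
  out$alt_adj <- alt_adj
  out$corrected_vaf <- cvaf
  # cellular proportion under the heterozygous single-copy model; for male X
  # the hemizygous rule already rescales counts, the same doubling applies
  out$cellular_proportion <- pmin(2 * cvaf, 1)
  out$flags <- flags
  rownames(out) <- NULL
  excluded <- data.frame(variant_id = variants$variant_id[!keep],
                         reason = excl[!keep], stringsAsFactors = FALSE)
  list(corrected = out, excluded = excluded)
}
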