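# 96-context substitution profiles and signature exposure refitting.
#
# Profiles follow the conventional pyrimidine frame: substitutions with a
# purine reference base are reverse-complemented, so every event falls in one
# of 6 substitution classes x 16 flanking contexts = 96 bins.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Canonical 96 trinucleotide substitution context labels
#'
#' Labels like "A[C>A]A", ordered by substitution class (C>A, C>G, C>T,
#' T>A, T>C, T>G), then 5' base, then 3' base — the conventional ordering
#' of signature matrices.
#'
#' @return character vector of length 96.
#' @export
#' @examples
#' head(context_labels())
context_labels <- function() {
  unlist(lapply(SUB_CLASSES, function(s)
    unlist(lapply(BASES, function(p)
      paste0(p, "[", s, "]", BASES)))))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1), USE.NAMES = FALSE))
}

#' Count substitutions into the 96 trinucleotide context bins
#'
#' Each substitution is a single-base change with its 3-mer context; the
#' context's middle base must equal the reference base. Purine-reference
#' events (G>*, A>*) are folded to the pyrimidine strand by reverse
#' complementation. Invalid records (middle base mismatch, non-SNV, bad
#' characters) are counted and reported, never silently dropped.
#'
#' @param ref_base,alt_base,context character vectors of equal length:
#'   single reference and alternate bases and the 3-mer context.
#' @param sample_id optional label stored on the result.
#' @return list with `counts` (named integer vector of length 96 in
#'   canonical order), `total`, `n_invalid`, `invalid_idx`, `sample_id`.
#' @export
#' @examples
#' count_contexts("C", "T", "ACG")$counts[["A[C>T]G"]]
#' count_contexts("G", "A", "CGT")$counts[["A[C>T]G"]]  # strand-folded
count_contexts <- function(ref_base, alt_base, context, sample_id = NA_character_) {
  ref_base <- toupper(as.character(ref_base))
  alt_base <- toupper(as.character(alt_base))
  context <- toupper(as.character(context))
  n <- length(ref_base)
  stopifnot(length(alt_base) == n, length(context) == n)
  labs <- context_labels()
  counts <- setNames(integer(96L), labs)
  invalid <- logical(n)
  if (n) {
    ok <- !is.na(ref_base) & !is.na(alt_base) & !is.na(context) &
      nchar(ref_base) == 1L & nchar(alt_base) == 1L & nchar(context) == 3L &
      ref_base %in% BASES & alt_base %in% BASES & ref_base != alt_base &
      grepl("^[ACGT]{3}$", context) & substr(context, 2L, 2L) == ref_base
    invalid <- !ok
    if (any(ok)) {
      r <- ref_base[ok]; a <- alt_base[ok]; ctx <- context[ok]
      pur <- r %in% c("A", "G")
      r[pur] <- chartr("ACGT", "TGCA", r[pur])
      a[pur] <- chartr("ACGT", "TGCA", a[pur])
      ctx[pur] <- revcomp(ctx[pur])
      lab <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
      tab <- table(factor(lab, levels = labs))
      counts <- setNames(as.integer(tab), labs)
    }
  }
  list(counts = counts, total = sum(counts), n_invalid = sum(invalid),
       invalid_idx = which(invalid), sample_id = sample_id)
}

#' Build a context profile from a variant table
#'
#' Convenience wrapper over [count_contexts()] for the variant data.frame
#' produced by [read_variants()]; variants without a context are invalid.
#'
#' @param variants data.frame with ref_allele, alt_allele, context columns.
#' @param sample_id optional label.
#' @return see [count_contexts()].
#' @export
profile_from_variants <- function(variants, sample_id = NA_character_) {
  count_contexts(variants$ref_allele, variants$alt_allele, variants$context,
                 sample_id = sample_id)
}

#' Refit signature exposures by iterated nonnegative least squares
#'
#' Fits the normalized 96-context profile as a nonnegative combination of
#' reference signature columns (Lawson-Hanson NNLS). Signatures whose
#' fitted weight falls below `min_weight` are removed and the fit repeated
#' on the survivors until the retained set is stable, mirroring the usual
#' refitting practice of discarding trace contributions. Exposures are
#' scaled to sum to at most 1.
#'
#' @param profile result of [count_contexts()], or a length-96 count vector.
#' @param reference 96 x S signature matrix (see [read_signature_matrix()]).
#' @param min_weight exposures below this are zeroed and the fit repeated
#'   (default 0.06).
#' @param min_mutations profiles with fewer mutations are flagged LOW_COUNT.
#' @return list with `exposures` (named, length S), `residual`
#'   (1 - sum(exposures)), `reconstruction_cosine`, `flags`, `sample_id`.
#' @export
refit_exposures <- function(profile, reference, min_weight = 0.06,
                            min_mutations = 20L) {
  if (is.list(profile)) {
    counts <- profile$counts
    sample_id <- profile$sample_id %||% NA_character_
  } else {
    counts <- profile
    sample_id <- NA_character_
  }
  if (length(counts) != 96L) stop_ct("profile must have exactly 96 context bins")
  validate_signature_matrix(reference)
  total <- sum(counts)
  if (total == 0) stop_ct("cannot refit an empty profile (total = 0)")
  flags <- character(0)
  if (total < min_mutations) flags <- c(flags, "LOW_COUNT")
  y <- as.numeric(counts) / total

  signames <- colnames(reference) %||% paste0("S", seq_len(ncol(reference)))
  active <- seq_len(ncol(reference))
  w <- NULL
  repeat {
    fit <- pracma::lsqnonneg(reference[, active, drop = FALSE], y)
    w <- fit$x
    keep <- w >= min_weight
    if (all(keep) || !any(keep)) break
    active <- active[keep]
  }
  exposures <- setNames(numeric(ncol(reference)), signames)
  if (any(w >= min_weight)) exposures[active[w >= min_weight]] <- w[w >= min_weight]
  recon <- as.numeric(reference %*% exposures)
  cosine <- if (sum(recon^2) == 0) 0 else
    sum(recon * y) / sqrt(sum(recon^2) * sum(y^2))
  s <- sum(exposures)
  if (s > 1) exposures <- exposures / s
  list(exposures = exposures, residual = 1 - sum(exposures),
       reconstruction_cosine = cosine, flags = flags, sample_id = sample_id,
       total = total)
}
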