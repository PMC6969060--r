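# Readers/writers for the external file formats. Everything downstream works
# on validated data.frames; raw files are touched only here.
#
# Canonical TSV dialect: tab-separated, single '#'-prefixed header line,
# UTF-8, '.' for missing values. Chosen so write(read(x)) is byte-stable and
# read(write(r)) is record-identical in tests.

MISSING_TOKEN <- "."

read_canonical_tsv <- function(path) {
  if (!file.exists(path)) stop_ct("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop_ct("empty file (no header): %s", path)
  if (!startsWith(lines[[1]], "#")) stop_ct("missing '#'-prefixed header line: %s", path)
  header <- strsplit(sub("^#", "", lines[[1]]), "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(header)), header),
                        stringsAsFactors = FALSE)
    attr(df, "source_lines") <- integer(0)
    return(df)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop_ct("line %d of %s has %d fields, expected %d", bad + 1L, path, nf[bad], length(header))
  }
  m <- do.call(rbind, fields)
  m[m == MISSING_TOKEN] <- NA
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  attr(df, "source_lines") <- seq_along(body) + 1L
  df
}

write_canonical_tsv <- function(df, path) {
  m <- as.matrix(format_canonical(df))
  m[is.na(m)] <- MISSING_TOKEN
  lines <- c(paste0("#", paste(colnames(m), collapse = "\t")),
             apply(m, 1L, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

format_canonical <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      out <- vapply(col, function(x) {
        if (is.na(x)) NA_character_
        else if (x == round(x) && abs(x) < 1e15) sprintf("%.0f", x)
        else format(x, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1))
      out
    } else if (is.logical(col)) {
      ifelse(is.na(col), NA_character_, ifelse(col, "true", "false"))
    } else {
      as.character(col)
    }
  }), stringsAsFactors = FALSE)
}

need_cols <- function(df, cols, path, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_ct("%s %s is missing required column(s): %s", what, path, paste(miss, collapse = ", "))
}

as_count <- function(x, col, path, lines) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v < 0 | v != round(v))
  if (length(bad))
    stop_ct("invalid %s at line %d of %s: '%s' (nonnegative integer required)",
            col, lines[bad[1]], path, x[bad[1]])
  as.integer(round(v))
}

parse_logical <- function(x, col, path, lines) {
  lo <- tolower(as.character(x))
  v <- ifelse(lo %in% c("true", "t", "1", "yes"), TRUE,
              ifelse(lo %in% c("false", "f", "0", "no"), FALSE, NA))
  bad <- which(is.na(v))
  if (length(bad))
    stop_ct("invalid boolean in %s at line %d of %s: '%s'", col, lines[bad[1]], path, x[bad[1]])
  as.logical(v)
}

check_enum <- function(x, levels, col, path, lines) {
  v <- toupper(as.character(x))
  bad <- which(!v %in% levels)
  if (length(bad))
    stop_ct("invalid %s '%s' at line %d of %s (allowed: %s)",
            col, x[bad[1]], lines[bad[1]], path, paste(levels, collapse = ", "))
  v
}

#' Read somatic variant calls
#'
#' Reads per-sample somatic variants with ref/alt read counts from the
#' canonical TSV dialect or from a VCF with AD-style per-sample depths.
#' Every record is validated against the variant invariants (nonnegative
#' counts, alt != ref, pos >= 1) and the input order is preserved.
#'
#' @param path file path.
#' @param format "tsv" (canonical dialect: columns chrom, pos, ref_allele,
#'   alt_allele, ref_count, alt_count, and optionally context, annotation)
#'   or "vcf" (AD FORMAT field; optional INFO keys CONTEXT and CLASS).
#' @param sample for VCF input, the sample column to read (default: first).
#' @return data.frame with columns variant_id, chrom, pos, ref_allele,
#'   alt_allele, ref_count, alt_count, context, annotation.
#' @export
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeLines(c("#chrom\tpos\tref_allele\talt_allele\tref_count\talt_count",
#'              "chr1\t100\tA\tT\t60\t40"), p)
#' read_variants(p)
read_variants <- function(path, format = c("tsv", "vcf"), sample = NULL) {
  format <- match.arg(format)
  if (format == "vcf") return(read_variants_vcf(path, sample))
  df <- read_canonical_tsv(path)
  lines <- attr(df, "source_lines")
  need_cols(df, c("chrom", "pos", "ref_allele", "alt_allele", "ref_count", "alt_count"),
            path, "variant table")
  n <- nrow(df)
  out <- data.frame(
    variant_id = character(n), chrom = as.character(df$chrom),
    pos = suppressWarnings(as.integer(df$pos)),
    ref_allele = as.character(df$ref_allele), alt_allele = as.character(df$alt_allele),
    ref_count = if (n) as_count(df$ref_count, "ref_count", path, lines) else integer(0),
    alt_count = if (n) as_count(df$alt_count, "alt_count", path, lines) else integer(0),
    context = if ("context" %in% names(df)) as.character(df$context) else rep(NA_character_, n),
    annotation = if ("annotation" %in% names(df))
      check_enum(ifelse(is.na(df$annotation), "UNKNOWN", df$annotation),
                 ANNOTATION_CLASSES, "annotation", path, lines)
      else rep("UNKNOWN", n),
    stringsAsFactors = FALSE
  )
  if (n) {
    if (anyNA(out$pos) || any(out$pos < 1L))
      stop_ct("invalid pos at line %d of %s", lines[which(is.na(out$pos) | out$pos < 1L)[1]], path)
    same <- which(out$ref_allele == out$alt_allele)
    if (length(same))
      stop_ct("alt_allele equals ref_allele at line %d of %s", lines[same[1]], path)
  }
  out$variant_id <- variant_id(out)
  dup <- which(duplicated(out$variant_id))
  if (length(dup))
    stop_ct("duplicate variant_id '%s' at line %d of %s", out$variant_id[dup[1]], lines[dup[1]], path)
  out
}

variant_id <- function(v) {
  if (!nrow(v)) return(character(0))
  paste0(v$chrom, ":", v$pos, ":", v$ref_allele, ">", v$alt_allele)
}

read_variants_vcf <- function(path, sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) stop_ct("VCF %s has no AD FORMAT field", path)
  if (is.null(sample)) sample <- colnames(ad)[1]
  if (!sample %in% colnames(ad))
    stop_ct("sample '%s' not found in VCF %s", sample, path)
  parts <- strsplit(ad[, sample], ",", fixed = TRUE)
  ref_count <- vapply(parts, function(p) suppressWarnings(as.integer(p[1])), integer(1))
  alt_count <- vapply(parts, function(p) suppressWarnings(as.integer(p[2])), integer(1))
  if (anyNA(ref_count) || anyNA(alt_count))
    stop_ct("VCF %s: AD field for sample %s is not 'ref,alt' at record %d",
            path, sample, which(is.na(ref_count) | is.na(alt_count))[1])
  context <- vcfR::extract.info(vcf, element = "CONTEXT")
  klass <- vcfR::extract.info(vcf, element = "CLASS")
  out <- data.frame(
    variant_id = character(nrow(fix)), chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT,
    ref_count = ref_count, alt_count = alt_count,
    context = if (is.null(context)) NA_character_ else as.character(context),
    annotation = if (is.null(klass)) "UNKNOWN" else toupper(as.character(klass)),
    stringsAsFactors = FALSE
  )
  out$annotation[!out$annotation %in% ANNOTATION_CLASSES] <- "UNKNOWN"
  out$variant_id <- variant_id(out)
  out
}

#' Write somatic variant calls in the canonical TSV dialect
#'
#' @param variants data.frame as returned by [read_variants()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variants <- function(variants, path) {
  cols <- c("chrom", "pos", "ref_allele", "alt_allele", "ref_count", "alt_count",
            "context", "annotation")
  write_canonical_tsv(variants[, cols], path)
}

#' Read copy-number segments
#'
#' BED-like table (chrom, start, end, state and optionally arm, baf_dev,
#' cov_ratio, n_snps). Intervals are 0-based half-open; segments on the same
#' chromosome must not overlap.
#'
#' @param path file path.
#' @return data.frame with columns chrom, start, end, arm, state, baf_dev,
#'   cov_ratio, n_snps.
#' @export
read_segments <- function(path) {
  df <- read_canonical_tsv(path)
  lines <- attr(df, "source_lines")
  need_cols(df, c("chrom", "start", "end", "state"), path, "segment table")
  n <- nrow(df)
  out <- data.frame(
    chrom = as.character(df$chrom),
    start = suppressWarnings(as.numeric(df$start)),
    end = suppressWarnings(as.numeric(df$end)),
    arm = if ("arm" %in% names(df)) as.character(df$arm) else rep(NA_character_, n),
    state = if (n) check_enum(df$state, CNA_STATES, "state", path, lines) else character(0),
    baf_dev = if ("baf_dev" %in% names(df)) suppressWarnings(as.numeric(df$baf_dev)) else rep(NA_real_, n),
    cov_ratio = if ("cov_ratio" %in% names(df)) suppressWarnings(as.numeric(df$cov_ratio)) else rep(NA_real_, n),
    n_snps = if ("n_snps" %in% names(df)) suppressWarnings(as.integer(df$n_snps)) else rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  if (n) {
    bad <- which(is.na(out$start) | is.na(out$end) | out$end <= out$start)
    if (length(bad))
      stop_ct("segment with end <= start at line %d of %s", lines[bad[1]], path)
    check_no_overlap(out, path, lines)
  }
  out
}

check_no_overlap <- function(seg, path = "<segments>", lines = seq_len(nrow(seg)) + 1L) {
  for (ch in unique(seg$chrom)) {
    idx <- which(seg$chrom == ch)
    o <- idx[order(seg$start[idx])]
    if (length(o) > 1L) {
      ov <- which(seg$start[o][-1] < seg$end[o][-length(o)])
      if (length(ov))
        stop_ct("overlapping segments on %s (line %d of %s)", ch, lines[o[ov[1] + 1L]], path)
    }
  }
  invisible(TRUE)
}

#' Write copy-number segments in the canonical TSV dialect
#' @param segments data.frame as returned by [read_segments()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_segments <- function(segments, path) {
  cols <- c("chrom", "start", "end", "arm", "state", "baf_dev", "cov_ratio", "n_snps")
  write_canonical_tsv(segments[, intersect(cols, names(segments))], path)
}

#' Read the sample sheet
#'
#' One row per sequenced lesion: sample_id, patient_id, lesion_type
#' (PRIMARY / METASTASIS / RECURRENCE), site, resection_index (order of
#' resection within the patient, contiguous from 1), interval_therapy
#' (systemic therapy administered since the previous resection),
#' tumor_content (histology-estimated purity in (0,1]) and sex.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read_canonical_tsv(path)
  lines <- attr(df, "source_lines")
  req <- c("sample_id", "patient_id", "lesion_type", "site", "resection_index",
           "interval_therapy", "tumor_content", "sex")
  need_cols(df, req, path, "sample sheet")
  n <- nrow(df)
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    patient_id = as.character(df$patient_id),
    lesion_type = if (n) check_enum(df$lesion_type, LESION_TYPES, "lesion_type", path, lines) else character(0),
    site = as.character(df$site),
    resection_index = suppressWarnings(as.integer(df$resection_index)),
    interval_therapy = if (n) parse_logical(df$interval_therapy, "interval_therapy", path, lines) else logical(0),
    tumor_content = suppressWarnings(as.numeric(df$tumor_content)),
    sex = if (n) check_enum(df$sex, SEX_LEVELS, "sex", path, lines) else character(0),
    stringsAsFactors = FALSE
  )
  if (n) {
    dup <- which(duplicated(out$sample_id))
    if (length(dup)) stop_ct("duplicate sample_id '%s' in %s", out$sample_id[dup[1]], path)
    bad <- which(is.na(out$tumor_content) | out$tumor_content <= 0 | out$tumor_content > 1)
    if (length(bad))
      stop_ct("tumor_content outside (0,1] at line %d of %s", lines[bad[1]], path)
    for (p in unique(out$patient_id)) {
      ri <- sort(out$resection_index[out$patient_id == p])
      if (anyDuplicated(ri))
        stop_ct("duplicate resection_index for patient %s in %s", p, path)
      if (!identical(as.integer(ri), seq_along(ri)))
        stop_ct("resection_index for patient %s must be contiguous from 1 in %s", p, path)
    }
  }
  out
}

#' Write a sample sheet in the canonical TSV dialect
#' @param sheet data.frame as returned by [read_sample_sheet()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  cols <- c("sample_id", "patient_id", "lesion_type", "site", "resection_index",
            "interval_therapy", "tumor_content", "sex")
  write_canonical_tsv(sheet[, cols], path)
}

#' Read a reference signature matrix
#'
#' TSV with a `context` column of the 96 trinucleotide substitution labels
#' (e.g. "A[C>A]A") and one column per reference signature. Rows are
#' reordered to the canonical context order; each signature column must be
#' nonnegative and sum to 1 (tolerance 1e-6).
#'
#' @param path file path.
#' @return numeric matrix, 96 rows (rownames = context labels) by S signatures.
#' @export
read_signature_matrix <- function(path) {
  df <- read_canonical_tsv(path)
  need_cols(df, "context", path, "signature matrix")
  labs <- context_labels()
  if (nrow(df) != 96L)
    stop_ct("signature matrix %s has %d rows; exactly 96 required", path, nrow(df))
  if (!setequal(df$context, labs))
    stop_ct("signature matrix %s context labels do not match the canonical 96", path)
  sigcols <- setdiff(names(df), "context")
  if (length(sigcols) < 1L) stop_ct("signature matrix %s has no signature columns", path)
  m <- as.matrix(vapply(df[sigcols], function(x) suppressWarnings(as.numeric(x)),
                        numeric(nrow(df))))
  rownames(m) <- df$context
  m <- m[labs, , drop = FALSE]
  validate_signature_matrix(m)
  m
}

validate_signature_matrix <- function(m) {
  if (nrow(m) != 96L) stop_ct("signature matrix must have exactly 96 rows")
  if (anyNA(m) || any(m < 0)) stop_ct("signature matrix entries must be nonnegative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    stop_ct("signature column(s) do not sum to 1: %s",
            paste(colnames(m)[abs(cs - 1) > 1e-6], collapse = ", "))
  invisible(m)
}

#' Write a signature matrix in the canonical TSV dialect
#' @param m 96 x S matrix with context rownames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_signature_matrix <- function(m, path) {
  validate_signature_matrix(m)
  df <- data.frame(context = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_canonical_tsv(df, path)
}
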