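# shared fixture builders; everything is generated in code, no stored data

make_variants <- function(n = 50L, seed = 1L, chrom = "1") {
  set.seed(seed)
  pos <- sort(sample.int(2e8, n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  depth <- rpois(n, 100) + 1L
  alt_n <- rbinom(n, depth, 0.3)
  df <- data.frame(
    chrom = chrom, pos = pos, ref_allele = ref, alt_allele = unname(alt),
    ref_count = as.integer(depth - alt_n), alt_count = as.integer(alt_n),
    context = paste0(sample(bases, n, TRUE), ref, sample(bases, n, TRUE)),
    annotation = sample(c("SILENT", "NONSILENT"), n, TRUE),
    stringsAsFactors = FALSE
  )
  df$variant_id <- paste0(df$chrom, ":", df$pos, ":", df$ref_allele, ">", df$alt_allele)
  df[, c("variant_id", "chrom", "pos", "ref_allele", "alt_allele",
         "ref_count", "alt_count", "context", "annotation")]
}

make_segments <- function(n = 20L, seed = 2L) {
  set.seed(seed)
  starts <- sort(sample.int(2e8, n)) * 10
  data.frame(chrom = "1", start = starts, end = starts + 5e5,
             arm = NA_character_,
             state = sample(c("AMP", "DEL", "CN_LOH", "NEUTRAL"), n, TRUE),
             baf_dev = round(runif(n, 0, 0.5), 4), cov_ratio = round(runif(n, 0.5, 2), 4),
             n_snps = sample(10:100, n, TRUE), stringsAsFactors = FALSE)
}

write_tsv_lines <- function(lines) {
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  p
}

# tiny corrected-variant frame for clustering inputs
corrected_frame <- function(ids, vaf) {
  data.frame(variant_id = ids, corrected_vaf = vaf, stringsAsFactors = FALSE)
}
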