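# Clone fates between lesions, driver persistence, hypermutation flagging
# and the per-patient evolutionary report.

#' Classify the fate of each clone cluster between two lesions
#'
#' A cluster present in both lesions is MAINTAINED, present only in the
#' earlier lesion LOST, only in the later lesion EMERGENT. Proportions are
#' reported on the cellular-proportion scale (twice the corrected-VAF
#' center, capped at 1) and delta = proportion_b - proportion_a.
#'
#' @param clusters data.frame from [extract_clusters()]`$clusters` (a
#'   two-lesion fit: center_a, center_b, present_a, present_b).
#' @return data.frame: cluster_id, fate, proportion_a, proportion_b, delta,
#'   n_members, weight.
#' @export
#' @examples
#' cl <- data.frame(cluster_id = 1:3,
#'                  center_a = c(0.40, 0.22, 0.02), center_b = c(0.41, 0.01, 0.18),
#'                  weight = rep(1/3, 3), n_members = c(10L, 10L, 10L),
#'                  present_a = c(TRUE, TRUE, FALSE), present_b = c(TRUE, FALSE, TRUE))
#' classify_fates(cl)$fate
classify_fates <- function(clusters) {
  stopifnot(all(c("center_a", "center_b", "present_a", "present_b") %in% names(clusters)))
  fate <- ifelse(clusters$present_a & clusters$present_b, "MAINTAINED",
          ifelse(clusters$present_a, "LOST", "EMERGENT"))
  pa <- pmin(2 * clusters$center_a, 1)
  pb <- pmin(2 * clusters$center_b, 1)
  data.frame(cluster_id = clusters$cluster_id, fate = fate,
             proportion_a = pa, proportion_b = pb, delta = pb - pa,
             n_members = clusters$n_members, weight = clusters$weight,
             stringsAsFactors = FALSE)
}

#' Packaged default driver gene list
#'
#' The six clinically-relevant colorectal-cancer genes followed by the
#' targeted ultra-deep assay: APC, TP53, KRAS, NRAS, PIK3CA, BRAF.
#'
#' @return character vector of gene symbols.
#' @export
driver_genes <- function() {
  path <- system.file("extdata", "driver_genes.tsv", package = "clonetrace")
  read_canonical_tsv(path)$gene
}

#' Driver mutation presence across lesions
#'
#' A gene is present in a lesion when it carries at least one non-silent
#' variant with alt_count >= `min_alt` and raw VAF >= `min_vaf` (the floor
#' reflects ultra-deep targeted sensitivity; both config-exposed).
#'
#' @param variants_per_lesion named list of variant data.frames (must carry
#'   a `gene` column); names are lesion sample ids.
#' @param genes gene list (default [driver_genes()]).
#' @param min_alt,min_vaf presence floor.
#' @return logical matrix genes x lesions.
#' @export
driver_persistence <- function(variants_per_lesion, genes = driver_genes(),
                               min_alt = 3L, min_vaf = 0.02) {
  m <- matrix(FALSE, length(genes), length(variants_per_lesion),
              dimnames = list(genes, names(variants_per_lesion)))
  for (les in names(variants_per_lesion)) {
    v <- variants_per_lesion[[les]]
    if (is.null(v$gene)) next
    vaf <- v$alt_count / (v$ref_count + v$alt_count)
    ok <- !is.na(v$gene) & v$annotation == "NONSILENT" &
      v$alt_count >= min_alt & vaf >= min_vaf
    m[, les] <- genes %in% v$gene[ok]
  }
  m
}

#' Flag a hypermutated sample
#'
#' TRUE when the sample's somatic exonic mutation count reaches the
#' threshold (default 1000, inclusive).
#'
#' @param variants variant data.frame (or an integer count).
#' @param threshold mutation-count threshold.
#' @return logical.
#' @export
#' @examples
#' flag_hypermutation(1285)  # TRUE
#' flag_hypermutation(116)   # FALSE
flag_hypermutation <- function(variants, threshold = 1000L) {
  n <- if (is.numeric(variants)) variants[1] else nrow(variants)
  n >= threshold
}

jaccard <- function(a, b) {
  if (!length(union(a, b))) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}

#' Assemble the per-patient evolutionary report
#'
#' Collects lesion metadata in resection order, per-pair clone fates with
#' the interval-therapy flag, the driver persistence matrix, hypermutation
#' flags and signature exposures into one machine-readable structure.
#' Missing pairs are noted, not fatal. Therapy effects are reported as
#' annotations on the quantitative fates; no causal inference is attempted.
#'
#' @param sheet sample-sheet rows for one patient ([read_sample_sheet()]).
#' @param pair_results named list ("<sample_a>|<sample_b>") of lists with
#'   elements `fates` ([classify_fates()]) and optionally `model`.
#' @param driver_matrix logical matrix from [driver_persistence()], or NULL.
#' @param burdens named integer vector of exonic mutation counts per sample.
#' @param exposures named list of [refit_exposures()] results, or NULL.
#' @param hypermutation_threshold see [flag_hypermutation()].
#' @return object of class `ct_patient_report` (a named list, JSON-ready).
#' @export
assemble_report <- function(sheet, pair_results = list(), driver_matrix = NULL,
                            burdens = NULL, exposures = NULL,
                            hypermutation_threshold = 1000L) {
  stopifnot(length(unique(sheet$patient_id)) == 1L)
  sheet <- sheet[order(sheet$resection_index), ]
  lesions <- lapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet[i, ]
    list(sample_id = s$sample_id, lesion_type = s$lesion_type, site = s$site,
         resection_index = s$resection_index,
         interval_therapy = s$interval_therapy,
         tumor_content = s$tumor_content,
         burden = if (!is.null(burdens)) unname(burdens[s$sample_id]) else NULL,
         hypermutated = if (!is.null(burdens))
           flag_hypermutation(unname(burdens[s$sample_id]), hypermutation_threshold)
           else NULL)
  })
  expected_pairs <- character(0)
  if (nrow(sheet) > 1L) {
    prim <- sheet$sample_id[sheet$lesion_type == "PRIMARY"]
    others <- setdiff(sheet$sample_id, prim[1])
    if (length(prim))
      expected_pairs <- paste0(prim[1], "|", others)
    mets <- sheet$sample_id[sheet$lesion_type != "PRIMARY"]
    if (length(mets) > 1L)
      expected_pairs <- union(expected_pairs,
                              paste0(mets[-length(mets)], "|", mets[-1]))
  }
  pairs <- lapply(names(pair_results), function(key) {
    pr <- pair_results[[key]]
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    fates <- pr$fates
    ther <- sheet$interval_therapy[sheet$sample_id == ab[2]]
    list(sample_a = ab[1], sample_b = ab[2],
         interval_therapy = if (length(ther)) ther else NA,
         n_maintained = sum(fates$fate == "MAINTAINED"),
         n_lost = sum(fates$fate == "LOST"),
         n_emergent = sum(fates$fate == "EMERGENT"),
         fates = fates)
  })
  names(pairs) <- names(pair_results)
  missing_pairs <- setdiff(expected_pairs, names(pair_results))
  report <- list(
    patient_id = sheet$patient_id[1],
    lesions = lesions,
    pairs = pairs,
    missing_pairs = missing_pairs,
    driver_matrix = if (!is.null(driver_matrix)) {
      dm <- as.data.frame(driver_matrix)
      dm <- cbind(gene = rownames(driver_matrix), dm)
      rownames(dm) <- NULL
      dm
    },
    driver_similarity = if (!is.null(driver_matrix) && ncol(driver_matrix) > 1L) {
      combs <- utils::combn(colnames(driver_matrix), 2L)
      data.frame(sample_a = combs[1, ], sample_b = combs[2, ],
                 jaccard = apply(combs, 2L, function(p)
                   jaccard(rownames(driver_matrix)[driver_matrix[, p[1]]],
                           rownames(driver_matrix)[driver_matrix[, p[2]]])),
                 stringsAsFactors = FALSE)
    },
    signature_exposures = if (!is.null(exposures))
      lapply(exposures, function(e)
        list(exposures = as.list(e$exposures), residual = e$residual,
             reconstruction_cosine = e$reconstruction_cosine,
             flags = e$flags))
  )
  class(report) <- c("ct_patient_report", "list")
  report
}

#' Write a patient report to JSON
#'
#' Deterministic serialization (no timestamps), so identical inputs give
#' byte-identical files.
#'
#' @param report from [assemble_report()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
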