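# End-to-end orchestration: io -> CNA -> correction -> per-pair clustering
# -> fates -> signatures -> report, plus the simulate-and-score harness.

lesion_pairs <- function(sheet) {
  sheet <- sheet[order(sheet$resection_index), ]
  prim <- sheet$sample_id[sheet$lesion_type == "PRIMARY"]
  pairs <- list()
  if (length(prim)) {
    for (s in setdiff(sheet$sample_id, prim[1]))
      pairs[[length(pairs) + 1L]] <- c(prim[1], s)
  }
  mets <- sheet$sample_id[sheet$lesion_type != "PRIMARY"]
  if (length(mets) > 1L)
    for (i in seq_len(length(mets) - 1L)) {
      pr <- c(mets[i], mets[i + 1L])
      if (!any(vapply(pairs, identical, logical(1), pr)))
        pairs[[length(pairs) + 1L]] <- pr
    }
  pairs
}

#' Run the clonal-evolution analysis for one patient (in-memory inputs)
#'
#' Stages: CNA- and purity-correction per lesion, joint 2-D EM clustering of
#' corrected VAFs for every lesion pair (primary against each later lesion,
#' plus consecutive metastases), clone-fate classification per pair,
#' optional signature refitting and driver persistence, and report assembly.
#'
#' @param variants named list of variant data.frames (one per sample_id).
#' @param sheet sample sheet rows for the patient.
#' @param segments named list of segment data.frames (NULL entries = no CNA).
#' @param reference optional 96 x S signature matrix for exposure refitting.
#' @param thresholds see [default_thresholds()].
#' @param seed integer seed for the EM restarts.
#' @return list with `report` (ct_patient_report), `corrected`, `pairs`
#'   (per-pair model / clusters / fates), `exposures`, `thresholds`, `seed`.
#' @export
run_patient_data <- function(variants, sheet, segments = NULL, reference = NULL,
                             thresholds = default_thresholds(), seed = 17L) {
  sheet <- sheet[order(sheet$resection_index), ]
  miss <- setdiff(sheet$sample_id, names(variants))
  if (length(miss)) stop_ct("no variant table for sample(s): %s", paste(miss, collapse = ", "))
  corrected <- list()
  for (sid in sheet$sample_id) {
    row <- sheet[sheet$sample_id == sid, ]
    corrected[[sid]] <- correct_sample(variants[[sid]], segments[[sid]],
                                       tumor_content = row$tumor_content,
                                       sex = row$sex)
  }
  pair_out <- list()
  for (pr in lesion_pairs(sheet)) {
    key <- paste(pr, collapse = "|")
    a <- corrected[[pr[1]]]$corrected; b <- corrected[[pr[2]]]$corrected
    if (!nrow(a) && !nrow(b)) next
    vm <- build_vaf_matrix(a, b, min_depth = thresholds$min_depth)
    model <- select_k(vm$points, k_range = seq_len(thresholds$k_max),
                      seed = seed, n_restarts = thresholds$n_restarts)
    cl <- extract_clusters(model, vm$points, vm$ids,
                           presence_min = thresholds$presence_min)
    fates <- classify_fates(cl$clusters)
    pair_out[[key]] <- list(model = model, clusters = cl$clusters,
                            assignments = cl$assignments, fates = fates,
                            dropped = vm$dropped)
  }
  exposures <- NULL
  if (!is.null(reference)) {
    exposures <- list()
    for (sid in sheet$sample_id) {
      prof <- profile_from_variants(variants[[sid]], sample_id = sid)
      exposures[[sid]] <- if (prof$total > 0)
        refit_exposures(prof, reference,
                        min_weight = thresholds$min_weight,
                        min_mutations = thresholds$min_mutations)
    }
    exposures <- Filter(Negate(is.null), exposures)
    if (!length(exposures)) exposures <- NULL
  }
  has_gene <- all(vapply(variants[sheet$sample_id], function(v)
    "gene" %in% names(v), logical(1)))
  dmat <- if (has_gene)
    driver_persistence(variants[sheet$sample_id],
                       min_alt = thresholds$driver_min_alt,
                       min_vaf = thresholds$driver_min_vaf)
  burdens <- vapply(variants[sheet$sample_id], nrow, integer(1))
  report <- assemble_report(sheet, pair_out, driver_matrix = dmat,
                            burdens = burdens, exposures = exposures,
                            hypermutation_threshold = thresholds$hypermutation_threshold)
  list(report = report, corrected = corrected, pairs = pair_out,
       exposures = exposures, thresholds = thresholds, seed = seed)
}

#' Run the pipeline from files
#'
#' Thin file-based wrapper over [run_patient_data()]. The run directory
#' receives `report.json`, `manifest.json` and per-pair/per-sample TSV
#' tables under `tables/`. Outputs carry no timestamps, so a rerun with the
#' same inputs and seed is byte-identical.
#'
#' @param config named list (or path to a YAML/JSON file holding one):
#'   `sample_sheet` (path), `variants` (named list of paths per sample_id),
#'   optional `segments` (named list of paths), optional `snps` and `bins`
#'   (named lists of paths with het-SNP counts / bin depths to derive
#'   segments from), optional `reference` (signature matrix path),
#'   `out_dir`, `seed`, optional `thresholds` (named overrides).
#' @return the [run_patient_data()] result, invisibly.
#' @export
run_patient <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  th <- do.call(default_thresholds, config$thresholds %||% list())
  seed <- as.integer(config$seed %||% 17L)
  sheet <- read_sample_sheet(config$sample_sheet)
  variants <- lapply(config$variants, read_variants)
  segments <- NULL
  if (!is.null(config$segments)) {
    segments <- lapply(config$segments, read_segments)
  } else if (!is.null(config$snps) && !is.null(config$bins)) {
    segments <- list()
    for (sid in names(config$snps)) {
      snps <- read_canonical_tsv(config$snps[[sid]])
      snps <- data.frame(chrom = snps$chrom, pos = as.numeric(snps$pos),
                         ref_count = as.integer(snps$ref_count),
                         alt_count = as.integer(snps$alt_count))
      bins <- read_canonical_tsv(config$bins[[sid]])
      bins <- data.frame(chrom = bins$chrom, start = as.numeric(bins$start),
                         end = as.numeric(bins$end), depth = as.numeric(bins$depth))
      ac <- call_arms_from_snps(snps, bins, thresholds = th)
      keep <- !ac$state %in% c("NEUTRAL", "UNCALLABLE")
      segments[[sid]] <- data.frame(chrom = ac$chrom[keep], start = ac$start[keep],
                                    end = ac$end[keep], arm = ac$arm[keep],
                                    state = ac$state[keep],
                                    baf_dev = ac$baf_dev[keep],
                                    cov_ratio = ac$cov_ratio[keep],
                                    n_snps = ac$n_snps[keep],
                                    stringsAsFactors = FALSE)
    }
  }
  reference <- if (!is.null(config$reference)) read_signature_matrix(config$reference)
  res <- run_patient_data(variants, sheet, segments = segments,
                          reference = reference, thresholds = th, seed = seed)
  if (!is.null(config$out_dir))
    write_run_artifacts(res, config$out_dir, config)
  invisible(res)
}

read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_ct("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write a completed run's report, manifest and tables to a directory
#'
#' @param res result of [run_patient_data()].
#' @param out_dir output directory (created; receives report.json,
#'   manifest.json and tables/).
#' @param config optional run configuration echoed into the manifest.
#' @return the directory, invisibly.
#' @export
write_run_artifacts <- function(res, out_dir, config = NULL) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  write_report(res$report, file.path(out_dir, "report.json"))
  manifest <- list(package = "clonetrace",
                   version = as.character(utils::packageVersion("clonetrace")),
                   seed = res$seed, thresholds = res$thresholds,
                   inputs = config[setdiff(names(config), c("thresholds", "out_dir"))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  for (sid in names(res$corrected)) {
    cc <- res$corrected[[sid]]$corrected
    write_canonical_tsv(cc, file.path(out_dir, "tables",
                                      paste0("corrected_", sid, ".tsv")))
  }
  for (key in names(res$pairs)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
    write_canonical_tsv(res$pairs[[key]]$clusters,
                        file.path(out_dir, "tables", paste0("clusters_", safe, ".tsv")))
    write_canonical_tsv(res$pairs[[key]]$fates,
                        file.path(out_dir, "tables", paste0("fates_", safe, ".tsv")))
    write_canonical_tsv(res$pairs[[key]]$assignments,
                        file.path(out_dir, "tables", paste0("scatter_", safe, ".tsv")))
  }
  invisible(out_dir)
}

# minimal-cost perfect matching of inferred to truth centers (k is small,
# so full permutation search is exact and cheap)
match_centers <- function(inferred, truth) {
  ki <- nrow(inferred); kt <- nrow(truth)
  k <- min(ki, kt)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  cand <- utils::combn(seq_len(ki), k, simplify = FALSE)
  best <- NULL; best_cost <- Inf
  for (sel in cand) for (pm in perms(sel)) {
    cost <- mean(sqrt(rowSums((inferred[pm, , drop = FALSE] -
                               truth[seq_len(k), , drop = FALSE])^2)))
    if (cost < best_cost) { best_cost <- cost; best <- pm }
  }
  list(idx = best, cost = best_cost)
}

#' Simulate a patient and score recovery against the truth
#'
#' Runs [simulate_patient()] then the full analysis, and compares the
#' result to the generative truth: cluster-center error on the corrected
#' scale, the fate confusion matrix, the CNA arm confusion matrix (when
#' raw CNA inputs are scored) and signature-exposure error.
#'
#' @param config `ct_sim_config`.
#' @param thresholds see [default_thresholds()].
#' @param seed seed for the analysis (EM restarts); the simulation uses
#'   `config$seed`.
#' @param use_truth_segments use the simulated truth segment tables for the
#'   correction (TRUE, default) or re-derive them from the simulated
#'   het-SNP / bin data via the CNA caller.
#' @return list: `run` ([run_patient_data()] result), `truth`, `metrics`
#'   (k_selected, k_truth, center_mae, max_center_error, fate_confusion,
#'   fate_diagonal, arm_accuracy, exposure_mae).
#' @export
simulate_and_run <- function(config, thresholds = default_thresholds(),
                             seed = config$seed, use_truth_segments = TRUE) {
  sim <- simulate_patient(config)
  segments <- sim$segments
  arm_accuracy <- NA_real_
  arm_confusion <- NULL
  if (!use_truth_segments) {
    segments <- list()
    truth_states <- character(0); called_states <- character(0)
    for (sid in sim$sheet$sample_id) {
      ac <- call_arms_from_snps(sim$snps[[sid]], sim$bins[[sid]],
                                thresholds = thresholds)
      truth_arm <- sim$truth$arm_state[ac$arm, sid]
      truth_states <- c(truth_states, truth_arm)
      called_states <- c(called_states, ac$state)
      keep <- !ac$state %in% c("NEUTRAL", "UNCALLABLE")
      segments[[sid]] <- data.frame(chrom = ac$chrom[keep], start = ac$start[keep],
                                    end = ac$end[keep], arm = ac$arm[keep],
                                    state = ac$state[keep], stringsAsFactors = FALSE)
    }
    arm_accuracy <- mean(called_states == truth_states)
    arm_confusion <- table(truth = truth_states, called = called_states)
  }
  run <- run_patient_data(sim$variants, sim$sheet, segments = segments,
                          reference = config$reference,
                          thresholds = thresholds, seed = seed)
  metrics <- list(arm_accuracy = arm_accuracy, arm_confusion = arm_confusion)
  if (length(run$pairs)) {
    key <- names(run$pairs)[1]
    pr <- run$pairs[[key]]
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    prop <- sim$truth$proportions[, ab, drop = FALSE]
    truth_centers <- prop / 2          # corrected-VAF scale
    active <- rowSums(prop) > 0
    truth_centers <- truth_centers[active, , drop = FALSE]
    inferred <- as.matrix(pr$clusters[, c("center_a", "center_b")])
    mm <- match_centers(inferred, truth_centers)
    errs <- sqrt(rowSums((inferred[mm$idx, , drop = FALSE] - truth_centers)^2))
    pm <- thresholds$presence_min
    truth_fate <- ifelse(truth_centers[, 1] >= pm & truth_centers[, 2] >= pm,
                         "MAINTAINED",
                  ifelse(truth_centers[, 1] >= pm, "LOST", "EMERGENT"))
    inferred_fate <- pr$fates$fate[mm$idx]
    conf <- table(truth = factor(truth_fate, FATE_LEVELS),
                  called = factor(inferred_fate, FATE_LEVELS))
    metrics$k_selected <- pr$model$k
    metrics$k_truth <- nrow(truth_centers)
    metrics$center_mae <- mean(errs)
    metrics$max_center_error <- max(errs)
    metrics$fate_confusion <- conf
    metrics$fate_diagonal <- sum(diag(conf)) == sum(conf)
  }
  if (!is.null(config$signature_mixture) && !is.null(run$exposures)) {
    mix <- config$signature_mixture
    err <- vapply(run$exposures, function(e)
      mean(abs(e$exposures[names(mix)] - mix)), numeric(1))
    metrics$exposure_mae <- mean(err)
  }
  list(run = run, truth = sim$truth, sim = sim, metrics = metrics)
}

#' Write simulated patient inputs to a directory
#'
#' Emits the exact formats the readers consume (variant, segment, het-SNP
#' and bin tables per lesion, the sample sheet, and truth JSON), so a
#' simulated patient can be re-run through the file-based pipeline.
#'
#' @param sim result of [simulate_patient()].
#' @param out_dir output directory (created).
#' @return named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
                variants = list(), segments = list(), snps = list(), bins = list())
  write_sample_sheet(sim$sheet, paths$sample_sheet)
  for (sid in sim$sheet$sample_id) {
    paths$variants[[sid]] <- file.path(out_dir, paste0("variants_", sid, ".tsv"))
    write_variants(sim$variants[[sid]], paths$variants[[sid]])
    paths$segments[[sid]] <- file.path(out_dir, paste0("segments_", sid, ".tsv"))
    write_segments(sim$segments[[sid]], paths$segments[[sid]])
    paths$snps[[sid]] <- file.path(out_dir, paste0("snps_", sid, ".tsv"))
    write_canonical_tsv(sim$snps[[sid]], paths$snps[[sid]])
    paths$bins[[sid]] <- file.path(out_dir, paste0("bins_", sid, ".tsv"))
    write_canonical_tsv(sim$bins[[sid]], paths$bins[[sid]])
  }
  jsonlite::write_json(list(clones = sim$truth$clones,
                            mutations = sim$truth$mutations),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
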