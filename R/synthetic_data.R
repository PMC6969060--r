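# Forward simulator for multi-lesion patients with known ground truth.
#
# The generative model mirrors the analysis assumptions so every stage is
# testable against truth:
#   * a set of clones with per-lesion cellular proportions (tree-consistent
#     if a parent column is supplied);
#   * arm-level CNA events per lesion; a somatic mutation falling on a CNA
#     arm is modelled as co-occurring with the CNA in its carrier cells
#     ("the aberration affects the altered allele to the largest extent"),
#     giving expected VAF
#         v = purity * phi * m / (2 + purity * phi * (C - 2))
#     with (m, C) = (1,2) NEUTRAL, (2,3) AMP, (1,1) DEL, (2,2) CN_LOH —
#     the form the count-correction rules invert exactly;
#   * germline het SNPs see the CNA as clonal in all tumor cells (they are
#     present in every cell), giving the BAF and coverage shifts the CNA
#     caller consumes;
#   * site depth ~ Poisson(assay mean), alt reads ~ Binomial(depth, v).

STATE_MULT <- list(NEUTRAL = c(m = 1, C = 2), AMP = c(m = 2, C = 3),
                   DEL = c(m = 1, C = 1), CN_LOH = c(m = 2, C = 2))

#' Expected variant allele frequency under the generative model
#'
#' @param purity tumor content in (0,1].
#' @param proportion clone cellular proportion in [0,1].
#' @param state CNA state at the locus.
#' @param male_x TRUE for a hemizygous male-X locus.
#' @return expected VAF.
#' @export
#' @examples
#' expected_vaf(1, 1, "NEUTRAL")    # 0.5
#' expected_vaf(0.5, 1, "NEUTRAL")  # 0.25
expected_vaf <- function(purity, proportion, state = "NEUTRAL", male_x = FALSE) {
  if (male_x) return(purity * proportion)
  mc <- STATE_MULT[[state]]
  if (is.null(mc)) stop_ct("unknown CNA state '%s'", state)
  purity * proportion * mc[["m"]] / (2 + purity * proportion * (mc[["C"]] - 2))
}

#' Build a simulation configuration
#'
#' @param lesions data.frame, one row per lesion in resection order:
#'   sample_id, lesion_type, site, purity (0,1], depth_mean (> 0),
#'   interval_therapy (logical).
#' @param clones data.frame: clone_id, n_mutations, optional parent, and
#'   one proportion column per sample_id.
#' @param cna data.frame (or NULL): arm (e.g. "13q"), state, sample_id —
#'   one row per (event, lesion) carrying it.
#' @param patient_id,sex patient annotations.
#' @param het_snps_per_arm,snp_depth_mean,bins_per_arm inputs generated for
#'   the CNA caller.
#' @param signature_mixture optional named weights over `reference` columns
#'   used to draw trinucleotide contexts (NULL = uniform contexts).
#' @param reference optional 96 x S signature matrix.
#' @param seed integer seed; identical config + seed give identical output.
#' @return validated `ct_sim_config` list.
#' @export
sim_config <- function(lesions, clones, cna = NULL,
                       patient_id = "SIM-001", sex = "FEMALE",
                       het_snps_per_arm = 60L, snp_depth_mean = 60,
                       bins_per_arm = 20L,
                       signature_mixture = NULL, reference = NULL,
                       seed = 17L) {
  stopifnot(is.data.frame(lesions), is.data.frame(clones))
  if (any(lesions$purity <= 0 | lesions$purity > 1))
    stop_ct("purity must be in (0, 1]")
  if (any(lesions$depth_mean <= 0)) stop_ct("depth_mean must be > 0")
  for (sid in lesions$sample_id)
    if (!sid %in% names(clones))
      stop_ct("clones table lacks a proportion column for lesion '%s'", sid)
  prop <- as.matrix(clones[, lesions$sample_id, drop = FALSE])
  if (any(prop < 0 | prop > 1)) stop_ct("clone proportions must be in [0, 1]")
  if (!is.null(clones$parent)) {
    for (i in seq_len(nrow(clones))) {
      p <- clones$parent[i]
      if (is.na(p) || !nzchar(p)) next
      j <- match(p, clones$clone_id)
      if (is.na(j)) stop_ct("clone '%s' has unknown parent '%s'", clones$clone_id[i], p)
      if (any(prop[i, ] > prop[j, ] + 1e-12))
        stop_ct("clone '%s' exceeds its parent's proportion", clones$clone_id[i])
    }
  }
  if (!is.null(cna)) {
    stopifnot(all(c("arm", "state", "sample_id") %in% names(cna)))
    if (!all(cna$state %in% setdiff(CNA_STATES, "NEUTRAL")))
      stop_ct("cna states must be AMP, DEL or CN_LOH")
    if (!all(cna$sample_id %in% lesions$sample_id))
      stop_ct("cna references unknown sample_id")
    if (!all(cna$arm %in% arm_boundaries()$arm))
      stop_ct("cna references unknown arm")
  }
  # expected VAF must stay in [0, 1] for every clone x lesion x state combo
  for (st in CNA_STATES)
    if (any(outer(seq_len(nrow(clones)), seq_len(nrow(lesions)), function(i, j)
      expected_vaf(lesions$purity[j], prop[cbind(i, j)], st)) > 1 + 1e-12))
      stop_ct("configuration implies expected VAF > 1 under state %s", st)
  structure(list(lesions = lesions, clones = clones, cna = cna,
                 patient_id = patient_id, sex = sex,
                 het_snps_per_arm = as.integer(het_snps_per_arm),
                 snp_depth_mean = snp_depth_mean,
                 bins_per_arm = as.integer(bins_per_arm),
                 signature_mixture = signature_mixture, reference = reference,
                 seed = as.integer(seed)),
            class = "ct_sim_config")
}

#' Canonical two-lesion three-clone scenario
#'
#' Primary and metastasis with a shared clone (proportion 0.8 in both), a
#' primary-private clone (0.5 / 0) and a metastasis-private clone (0 / 0.4);
#' purities 0.6 / 0.55, whole-exome depth 100x, 100 mutations per clone.
#' On the corrected-VAF scale the three cluster centers sit near
#' (0.4, 0.4), (0.25, 0) and (0, 0.2).
#'
#' @param seed integer seed.
#' @param n_mutations mutations per clone.
#' @param depth_mean sequencing depth.
#' @return `ct_sim_config`.
#' @export
fig2_config <- function(seed = 17L, n_mutations = 100L, depth_mean = 100) {
  lesions <- data.frame(
    sample_id = c("SIM-A", "SIM-B"),
    lesion_type = c("PRIMARY", "METASTASIS"),
    site = c("rectum", "liver"),
    purity = c(0.6, 0.55),
    depth_mean = depth_mean,
    interval_therapy = c(FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  clones <- data.frame(
    clone_id = c("shared", "primary_private", "met_private"),
    parent = c(NA, "shared", "shared"),
    n_mutations = n_mutations,
    `SIM-A` = c(0.8, 0.5, 0.0),
    `SIM-B` = c(0.8, 0.0, 0.4),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  sim_config(lesions, clones, seed = seed)
}

draw_context <- function(n, mixture, reference) {
  labs <- context_labels()
  probs <- if (is.null(mixture) || is.null(reference)) rep(1 / 96, 96)
           else as.numeric(reference[, names(mixture), drop = FALSE] %*% mixture)
  idx <- sample.int(96L, n, replace = TRUE, prob = probs)
  labs[idx]
}

context_to_substitution <- function(lab) {
  ref <- substr(lab, 3L, 3L)
  alt <- substr(lab, 5L, 5L)
  ctx <- paste0(substr(lab, 1L, 1L), ref, substr(lab, 7L, 7L))
  data.frame(ref_base = ref, alt_base = alt, context = ctx,
             stringsAsFactors = FALSE)
}

#' Simulate a multi-lesion patient
#'
#' Generates, per lesion, a somatic variant table (binomial read counts at
#' the lesion's depth), a CNA segment table, het-SNP and coverage-bin
#' inputs for the CNA caller, plus the sample sheet and a truth record.
#' All randomness flows from `config$seed`; identical configs reproduce
#' identical output.
#'
#' @param config `ct_sim_config` from [sim_config()].
#' @return list with `variants` (named list of data.frames), `segments`,
#'   `snps`, `bins` (idem), `sheet`, and `truth` (clone table, per-mutation
#'   table with expected VAFs, config echo).
#' @export
simulate_patient <- function(config) {
  stopifnot(inherits(config, "ct_sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  arms <- arm_boundaries()
  arms <- arms[arms$chrom != "X" | identical(config$sex, "FEMALE"), ]
  lesions <- config$lesions
  clones <- config$clones
  prop <- as.matrix(clones[, lesions$sample_id, drop = FALSE])
  rownames(prop) <- clones$clone_id

  # state of each arm in each lesion
  arm_state <- matrix("NEUTRAL", nrow(arms), nrow(lesions),
                      dimnames = list(arms$arm, lesions$sample_id))
  if (!is.null(config$cna))
    for (i in seq_len(nrow(config$cna)))
      arm_state[config$cna$arm[i], config$cna$sample_id[i]] <- config$cna$state[i]

  # place mutations: arm chosen length-weighted, position uniform in arm
  n_mut <- sum(clones$n_mutations)
  arm_idx <- sample.int(nrow(arms), n_mut, replace = TRUE,
                        prob = arms$end - arms$start)
  pos <- arms$start[arm_idx] + 1L +
    floor(runif(n_mut) * (arms$end[arm_idx] - arms$start[arm_idx] - 1))
  ctx <- draw_context(n_mut, config$signature_mixture, config$reference)
  sub <- context_to_substitution(ctx)
  clone_of <- rep(clones$clone_id, clones$n_mutations)

  truth_mut <- data.frame(
    variant_id = paste0(arms$chrom[arm_idx], ":", pos, ":",
                        sub$ref_base, ">", sub$alt_base),
    chrom = arms$chrom[arm_idx], pos = pos, arm = arms$arm[arm_idx],
    ref_allele = sub$ref_base, alt_allele = sub$alt_base, context = sub$context,
    clone_id = clone_of, stringsAsFactors = FALSE
  )
  dup <- duplicated(truth_mut$variant_id)
  truth_mut <- truth_mut[!dup, ]

  variants <- segments <- snps <- bins <- list()
  for (j in seq_len(nrow(lesions))) {
    sid <- lesions$sample_id[j]
    p <- lesions$purity[j]
    st <- arm_state[truth_mut$arm, sid]
    phi <- prop[truth_mut$clone_id, sid]
    male_x <- identical(config$sex, "MALE") & truth_mut$chrom == "X"
    ev <- vapply(seq_len(nrow(truth_mut)), function(i)
      expected_vaf(p, phi[i], st[i], male_x[i]), numeric(1))
    depth <- rpois(nrow(truth_mut), lesions$depth_mean[j])
    depth[depth == 0] <- 1L
    alt <- rbinom(nrow(truth_mut), depth, ev)
    truth_mut[[paste0("expected_vaf_", sid)]] <- ev
    truth_mut[[paste0("proportion_", sid)]] <- unname(phi)
    truth_mut[[paste0("state_", sid)]] <- unname(st)
    present <- phi > 0 & alt >= 1
    variants[[sid]] <- data.frame(
      variant_id = truth_mut$variant_id[present],
      chrom = truth_mut$chrom[present], pos = truth_mut$pos[present],
      ref_allele = truth_mut$ref_allele[present],
      alt_allele = truth_mut$alt_allele[present],
      ref_count = as.integer(depth[present] - alt[present]),
      alt_count = as.integer(alt[present]),
      context = truth_mut$context[present],
      annotation = "UNKNOWN", stringsAsFactors = FALSE
    )
    ev_arm <- arm_state[, sid]
    seg <- arms[ev_arm != "NEUTRAL", c("chrom", "arm", "start", "end")]
    seg$state <- ev_arm[ev_arm != "NEUTRAL"]
    segments[[sid]] <- data.frame(chrom = seg$chrom, start = seg$start,
                                  end = seg$end, arm = seg$arm,
                                  state = seg$state, stringsAsFactors = FALSE)

    # het SNPs and coverage bins for the CNA caller (CNA clonal in tumor)
    snp_list <- bin_list <- vector("list", nrow(arms))
    for (a in seq_len(nrow(arms))) {
      stt <- arm_state[a, sid]
      mc <- STATE_MULT[[stt]]
      C <- mc[["C"]]
      b_major <- switch(stt, NEUTRAL = 1, AMP = 2, DEL = 1, CN_LOH = 2)
      baf_major <- (p * b_major + (1 - p)) / (p * C + 2 * (1 - p))
      cov_mult <- (p * C + 2 * (1 - p)) / 2
      ns <- config$het_snps_per_arm
      spos <- sort(arms$start[a] + 1L +
                     floor(runif(ns) * (arms$end[a] - arms$start[a] - 1)))
      sdepth <- rpois(ns, config$snp_depth_mean * cov_mult)
      sdepth[sdepth == 0] <- 1L
      # the mutated/retained homolog is randomly ref or alt per SNP
      is_alt_major <- runif(ns) < 0.5
      baf <- ifelse(is_alt_major, baf_major, 1 - baf_major)
      salt <- rbinom(ns, sdepth, baf)
      snp_list[[a]] <- data.frame(chrom = arms$chrom[a], pos = spos,
                                  ref_count = as.integer(sdepth - salt),
                                  alt_count = as.integer(salt),
                                  stringsAsFactors = FALSE)
      nb <- config$bins_per_arm
      bstart <- arms$start[a] + (arms$end[a] - arms$start[a]) %/% nb * (seq_len(nb) - 1)
      bend <- c(bstart[-1], arms$end[a])
      bin_list[[a]] <- data.frame(chrom = arms$chrom[a], start = bstart,
                                  end = bend,
                                  depth = rpois(nb, config$snp_depth_mean * cov_mult),
                                  stringsAsFactors = FALSE)
    }
    snps[[sid]] <- do.call(rbind, snp_list)
    bins[[sid]] <- do.call(rbind, bin_list)
  }

  sheet <- data.frame(
    sample_id = lesions$sample_id, patient_id = config$patient_id,
    lesion_type = lesions$lesion_type, site = lesions$site,
    resection_index = seq_len(nrow(lesions)),
    interval_therapy = lesions$interval_therapy,
    tumor_content = lesions$purity, sex = config$sex,
    stringsAsFactors = FALSE
  )
  list(variants = variants, segments = segments, snps = snps, bins = bins,
       sheet = sheet,
       truth = list(clones = clones, proportions = prop, mutations = truth_mut,
                    arm_state = arm_state, config = config))
}

#' Draw substitutions from a mixture of reference signatures
#'
#' @param n number of substitutions.
#' @param mixture named nonnegative weights over columns of `reference`,
#'   summing to 1.
#' @param reference 96 x S signature matrix.
#' @param seed integer seed.
#' @return data.frame ref_base, alt_base, context (n rows), with the truth
#'   mixture attached as attribute "mixture".
#' @export
simulate_signature_mutations <- function(n, mixture, reference, seed = 17L) {
  if (!length(mixture)) stop_ct("empty signature mixture")
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-9)
    stop_ct("mixture weights must be nonnegative and sum to 1")
  validate_signature_matrix(reference)
  if (is.null(names(mixture))) names(mixture) <- colnames(reference)[seq_along(mixture)]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  labs <- draw_context(n, mixture, reference)
  out <- if (n > 0) context_to_substitution(labs) else
    data.frame(ref_base = character(0), alt_base = character(0),
               context = character(0), stringsAsFactors = FALSE)
  attr(out, "mixture") <- mixture
  out
}

#' Generate a synthetic reference signature matrix
#'
#' Random sparse signatures for testing the refitting machinery; with
#' `disjoint = TRUE` the signatures have non-overlapping context support,
#' making exposures identifiable by construction. This is a synthetic
#' stand-in — real analyses should supply a published reference matrix.
#'
#' @param n_sig number of signatures.
#' @param seed integer seed.
#' @param disjoint give each signature a disjoint block of contexts.
#' @return 96 x n_sig matrix, columns "SYN1"... each summing to 1.
#' @export
synthetic_signatures <- function(n_sig = 2L, seed = 17L, disjoint = TRUE) {
  stopifnot(n_sig >= 1L, n_sig <= 96L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  m <- matrix(0, 96L, n_sig, dimnames = list(context_labels(), paste0("SYN", seq_len(n_sig))))
  if (disjoint) {
    blocks <- split(seq_len(96L), cut(seq_len(96L), n_sig, labels = FALSE))
    for (s in seq_len(n_sig)) {
      w <- runif(length(blocks[[s]]))
      m[blocks[[s]], s] <- w / sum(w)
    }
  } else {
    for (s in seq_len(n_sig)) {
      w <- runif(96L)^3
      m[, s] <- w / sum(w)
    }
  }
  m
}
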