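test_that("expected VAF closed forms are correct", {
  expect_equal(expected_vaf(1, 1, "NEUTRAL"), 0.5)
  expect_equal(expected_vaf(0.5, 1, "NEUTRAL"), 0.25)
  expect_equal(expected_vaf(1, 1, "AMP"), 2 / 3)
  expect_equal(expected_vaf(1, 1, "DEL"), 1)
  expect_equal(expected_vaf(1, 1, "CN_LOH"), 1)
  expect_equal(expected_vaf(0.6, 0.5, "NEUTRAL"), 0.15)
  expect_equal(expected_vaf(0.8, 0.5, "X", male_x = TRUE), 0.4)
})

test_that("observed mean VAF matches the closed form at ultra depth", {
  lesions <- data.frame(sample_id = "S1", lesion_type = "PRIMARY", site = "colon",
                        purity = 1.0, depth_mean = 25000, interval_therapy = FALSE)
  clones <- data.frame(clone_id = "c1", n_mutations = 60L, S1 = 1.0)
  cfg <- sim_config(lesions, clones, seed = 2L)
  sim <- simulate_patient(cfg)
  v <- sim$variants$S1
  vaf <- v$alt_count / (v$ref_count + v$alt_count)
  expect_lt(abs(mean(vaf) - 0.5), 0.01)
})

test_that("simulation is deterministic given config and seed", {
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_simulation(simulate_patient(fig2_config(seed = 5L)), d1)
  p2 <- write_simulation(simulate_patient(fig2_config(seed = 5L)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the data
  d3 <- tempfile()
  write_simulation(simulate_patient(fig2_config(seed = 6L)), d3)
  expect_false(identical(readLines(file.path(d1, "variants_SIM-A.tsv")),
                         readLines(file.path(d3, "variants_SIM-A.tsv"))))
})

test_that("serialized truth reproduces the sampling expectation exactly", {
  lesions <- data.frame(sample_id = "S1", lesion_type = "PRIMARY", site = "colon",
                        purity = 0.7, depth_mean = 100, interval_therapy = FALSE)
  clones <- data.frame(clone_id = c("a", "b"), n_mutations = 40L, S1 = c(1, 0.3))
  cna <- data.frame(arm = c("13q", "17p"), state = c("AMP", "CN_LOH"), sample_id = "S1")
  sim <- simulate_patient(sim_config(lesions, clones, cna = cna, seed = 3L))
  tm <- sim$truth$mutations
  recomputed <- mapply(function(prop, st) expected_vaf(0.7, prop, st),
                       tm$proportion_S1, tm$state_S1)
  expect_equal(unname(recomputed), tm$expected_vaf_S1)
})

test_that("correction exactly inverts the generator on noiseless counts", {
  # algebraic identity: for rational (purity, proportion) and each CNA
  # state, counts built from the closed-form expected VAF correct back to
  # exactly proportion / 2 on the corrected-VAF scale
  depth <- 840  # divisible enough that all counts are exact dyadic rationals
  for (purity in c(1, 0.5, 0.6, 0.75)) {
    for (phi in c(1, 0.8, 0.5, 0.25)) {
      for (st in c("NEUTRAL", "AMP", "DEL", "CN_LOH")) {
        v <- expected_vaf(purity, phi, st)
        alt <- v * depth
        ref <- depth - alt
        adj <- adjust_counts(ref, alt, st)
        cv <- purity_correct(adj$ref_adj, adj$alt_adj, purity)
        expect_equal(cv, phi / 2, tolerance = 1e-12,
                     label = sprintf("state %s purity %g phi %g", st, purity, phi))
      }
    }
  }
})

test_that("clone proportions must respect the tree and the VAF bound", {
  lesions <- data.frame(sample_id = "S1", lesion_type = "PRIMARY", site = "colon",
                        purity = 0.7, depth_mean = 100, interval_therapy = FALSE)
  bad_tree <- data.frame(clone_id = c("root", "child"), parent = c(NA, "root"),
                         n_mutations = 10L, S1 = c(0.4, 0.6))
  expect_error(sim_config(lesions, bad_tree), "parent")
  bad_prop <- data.frame(clone_id = "c", n_mutations = 10L, S1 = 1.2)
  expect_error(sim_config(lesions, bad_prop), "proportions")
  expect_error(sim_config(transform(lesions, purity = 0), bad_prop), "purity")
})

test_that("signature mutation drawing respects support and edge cases", {
  ref <- synthetic_signatures(2L, seed = 4L)
  subs <- simulate_signature_mutations(200, c(SYN1 = 1), ref, seed = 6L)
  prof <- count_contexts(subs$ref_base, subs$alt_base, subs$context)
  support <- names(which(ref[, "SYN1"] > 0))
  expect_true(all(names(which(prof$counts > 0)) %in% support))
  expect_equal(nrow(simulate_signature_mutations(0, c(SYN1 = 1), ref)), 0L)
  expect_error(simulate_signature_mutations(10, numeric(0), ref), "empty")
  expect_error(simulate_signature_mutations(10, c(SYN1 = 0.5, SYN2 = 0.2), ref),
               "sum to 1")
})
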