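test_that("count adjustment matches the closed-form rules", {
  expect_equal(adjust_counts(50, 50, "AMP"), list(ref_adj = 50, alt_adj = 25))
  a <- adjust_counts(30, 70, "DEL")
  expect_equal(a, list(ref_adj = 100, alt_adj = 70))
  expect_equal(a$alt_adj / (a$ref_adj + a$alt_adj), 70 / 170)
  expect_equal(adjust_counts(10, 80, "NEUTRAL", chrom = "X", sex = "MALE"),
               list(ref_adj = 100, alt_adj = 80))
  b <- adjust_counts(40, 60, "CN_LOH")
  expect_equal(b, list(ref_adj = 70, alt_adj = 30))
  expect_equal(b$alt_adj / (b$ref_adj + b$alt_adj), 0.30)
  expect_equal(adjust_counts(60, 40, "NEUTRAL"), list(ref_adj = 60, alt_adj = 40))
  expect_error(adjust_counts(0, 0, "NEUTRAL"), "invalid counts")
  expect_error(adjust_counts(10, 10, "NEUTRAL", chrom = "X", sex = "UNKNOWN"),
               "sex")
})

test_that("the male-X rule overrides the CNA rule on X", {
  # X rule replaces (never composes with) the CNA state
  expect_equal(adjust_counts(10, 80, "AMP", chrom = "chrX", sex = "MALE"),
               list(ref_adj = 100, alt_adj = 80))
  # female X follows the autosomal rules
  expect_equal(adjust_counts(50, 50, "AMP", chrom = "X", sex = "FEMALE"),
               list(ref_adj = 50, alt_adj = 25))
})

test_that("purity scaling divides by tumor content and caps at 1", {
  expect_equal(purity_correct(80, 20, 0.5), 0.4)
  expect_equal(purity_correct(80, 20, 1.0), 0.2)
  expect_equal(purity_correct(20, 80, 0.5), 1.0)
  expect_error(purity_correct(80, 20, 0), "tumor_content")
})

test_that("corrected VAF is invariant to count scaling", {
  for (st in c("NEUTRAL", "AMP", "DEL", "CN_LOH")) {
    for (mult in c(2L, 7L, 31L)) {
      a1 <- adjust_counts(13, 9, st)
      a2 <- adjust_counts(13 * mult, 9 * mult, st)
      expect_equal(a1$alt_adj / (a1$ref_adj + a1$alt_adj),
                   a2$alt_adj / (a2$ref_adj + a2$alt_adj))
    }
  }
})

test_that("correct_sample assigns segment states and handles exclusions", {
  v <- data.frame(
    variant_id = c("1:100:A>T", "1:5000:C>G", "2:100:G>A", "X:100:A>C", "Y:100:G>T"),
    chrom = c("1", "1", "2", "X", "Y"), pos = c(100L, 5000L, 100L, 100L, 100L),
    ref_allele = c("A", "C", "G", "A", "G"), alt_allele = c("T", "G", "A", "C", "T"),
    ref_count = c(50L, 50L, 60L, 10L, 10L), alt_count = c(50L, 50L, 40L, 80L, 10L),
    context = NA_character_, annotation = "UNKNOWN", stringsAsFactors = FALSE)
  seg <- data.frame(chrom = "1", start = 0, end = 1000, state = "AMP",
                    stringsAsFactors = FALSE)
  res <- correct_sample(v, seg, tumor_content = 1.0, sex = "MALE")
  cc <- res$corrected
  expect_equal(cc$cna_state[cc$variant_id == "1:100:A>T"], "AMP")
  expect_equal(cc$corrected_vaf[cc$variant_id == "1:100:A>T"], 25 / 75)
  # beyond the segment: NEUTRAL identity
  expect_equal(cc$cna_state[cc$variant_id == "1:5000:C>G"], "NEUTRAL")
  expect_equal(cc$corrected_vaf[cc$variant_id == "1:5000:C>G"], 0.5)
  # male X rule applied
  expect_equal(cc$corrected_vaf[cc$variant_id == "X:100:A>C"], 80 / 180)
  # Y excluded
  expect_false("Y:100:G>T" %in% cc$variant_id)
  expect_equal(res$excluded$reason, "NON_AUTOSOME")

  # unknown sex: X excluded rather than corrected
  res2 <- correct_sample(v, seg, tumor_content = 1.0, sex = "UNKNOWN")
  expect_setequal(res2$excluded$reason, c("X_SEX_UNKNOWN", "NON_AUTOSOME"))
})

test_that("capped variants are flagged and NEUTRAL/full purity is identity", {
  v <- make_variants(10L, seed = 3L)
  res <- correct_sample(v, NULL, tumor_content = 1.0, sex = "FEMALE")
  expect_equal(res$corrected$corrected_vaf, res$corrected$raw_vaf)
  res2 <- correct_sample(v, NULL, tumor_content = 0.2, sex = "FEMALE")
  capped <- res2$corrected$corrected_vaf == 1
  expect_true(all(grepl("CAPPED", res2$corrected$flags[capped])))
  expect_false(any(grepl("CAPPED", res2$corrected$flags[!capped])))
})

test_that("corrected VAFs track truth on a deep-coverage simulated sample", {
  lesions <- data.frame(sample_id = "S1", lesion_type = "PRIMARY", site = "colon",
                        purity = 0.6, depth_mean = 1000, interval_therapy = FALSE)
  clones <- data.frame(clone_id = c("a", "b"), n_mutations = 100L,
                       S1 = c(1.0, 0.4))
  cna <- data.frame(arm = c("13q", "5q", "17p"), state = c("AMP", "DEL", "CN_LOH"),
                    sample_id = "S1")
  cfg <- sim_config(lesions, clones, cna = cna, seed = 8L)
  sim <- simulate_patient(cfg)
  res <- correct_sample(sim$variants$S1, sim$segments$S1,
                        tumor_content = 0.6, sex = "FEMALE")
  cc <- res$corrected
  tm <- sim$truth$mutations
  truth_prop <- tm$proportion_S1[match(cc$variant_id, tm$variant_id)]
  expect_lt(mean(abs(cc$corrected_vaf - truth_prop / 2)), 0.03)
})
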