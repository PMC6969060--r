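fixture_clusters <- function() {
  data.frame(cluster_id = 1:3,
             center_a = c(0.40, 0.22, 0.02), center_b = c(0.41, 0.01, 0.18),
             weight = rep(1 / 3, 3), n_members = c(10L, 10L, 10L),
             present_a = c(TRUE, TRUE, FALSE), present_b = c(TRUE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

test_that("clone fates follow presence in each lesion", {
  f <- classify_fates(fixture_clusters())
  expect_equal(f$fate, c("MAINTAINED", "LOST", "EMERGENT"))
  # proportions are on the cellular-proportion (2x VAF) scale
  expect_equal(f$proportion_a[1], 0.80)
  expect_equal(f$delta[1], 0.02)
  expect_equal(f$delta[2], 2 * (0.01 - 0.22))
})

test_that("fate classification is permutation-invariant and conservative", {
  cl <- fixture_clusters()
  f1 <- classify_fates(cl)
  shuf <- cl[c(3, 1, 2), ]
  f2 <- classify_fates(shuf)
  expect_equal(f2$fate[match(f1$cluster_id, f2$cluster_id)], f1$fate)
  # conservation: every cluster gets exactly one fate
  expect_equal(sum(f1$fate == "MAINTAINED") + sum(f1$fate == "LOST") +
               sum(f1$fate == "EMERGENT"), nrow(cl))
})

test_that("driver persistence applies the count and VAF floors", {
  mk <- function(gene, alt, depth = 100L, ann = "NONSILENT") {
    data.frame(variant_id = paste0("12:25398284:G>", alt),
               chrom = "12", pos = 25398284L, ref_allele = "G", alt_allele = "T",
               ref_count = as.integer(depth - alt), alt_count = as.integer(alt),
               context = NA_character_, annotation = ann, gene = gene,
               stringsAsFactors = FALSE)
  }
  lesions <- list(primary = mk("KRAS", 30L), met = mk("KRAS", 28L))
  m <- driver_persistence(lesions)
  expect_true(all(m["KRAS", ]))
  expect_false(any(m["BRAF", ]))
  # alt_count 2 is below the floor
  low <- driver_persistence(list(primary = mk("KRAS", 2L)))
  expect_false(low["KRAS", "primary"])
  # silent variants never count
  sil <- driver_persistence(list(primary = mk("KRAS", 30L, ann = "SILENT")))
  expect_false(sil["KRAS", "primary"])
})

test_that("hypermutation flagging is an inclusive threshold", {
  expect_true(flag_hypermutation(1285))
  expect_false(flag_hypermutation(116))
  expect_true(flag_hypermutation(1000))
  expect_false(flag_hypermutation(999))
})

test_that("the patient report assembles pairs, therapy flags and gaps", {
  hdr <- "#sample_id\tpatient_id\tlesion_type\tsite\tresection_index\tinterval_therapy\ttumor_content\tsex"
  sheet <- read_sample_sheet(write_tsv_lines(c(hdr,
    "P\tPT1\tPRIMARY\trectum\t1\tfalse\t0.6\tFEMALE",
    "M\tPT1\tMETASTASIS\tliver\t2\tfalse\t0.5\tFEMALE")))
  shared <- data.frame(cluster_id = 1L, center_a = 0.4, center_b = 0.4,
                       weight = 1, n_members = 50L,
                       present_a = TRUE, present_b = TRUE)
  rep1 <- assemble_report(sheet,
                          pair_results = list("P|M" = list(fates = classify_fates(shared))),
                          burdens = c(P = 120L, M = 150L))
  expect_equal(rep1$pairs[["P|M"]]$n_maintained, 1L)
  expect_false(rep1$pairs[["P|M"]]$interval_therapy)
  expect_equal(length(rep1$missing_pairs), 0L)
  expect_false(rep1$lesions[[1]]$hypermutated)

  # missing pair is reported, not fatal
  rep2 <- assemble_report(sheet, pair_results = list())
  expect_equal(rep2$missing_pairs, "P|M")

  # single-sample patient: burden only, no pairs
  solo <- sheet[1, ]
  rep3 <- assemble_report(solo, burdens = c(P = 1285L))
  expect_equal(length(rep3$pairs), 0L)
  expect_true(rep3$lesions[[1]]$hypermutated)
})

test_that("a five-lesion patient mirrors shared-liver / divergent-lung drivers", {
  # primary + 2 liver + 2 lung; liver lesions share all drivers, each lung
  # lesion carries one exclusive driver
  mk <- function(genes) {
    n <- length(genes)
    data.frame(variant_id = paste0("g", seq_len(n)), chrom = "1",
               pos = seq_len(n) * 1000L, ref_allele = "A", alt_allele = "T",
               ref_count = 70L, alt_count = 30L, context = NA_character_,
               annotation = "NONSILENT", gene = genes, stringsAsFactors = FALSE)
  }
  lesions <- list(
    primary = mk(c("APC", "TP53", "KRAS")),
    liver1 = mk(c("APC", "TP53", "KRAS")),
    liver2 = mk(c("APC", "TP53", "KRAS")),
    lung1 = mk(c("TP53", "KRAS", "APC")),
    lung2 = mk(c("TP53", "KRAS", "BRAF")))
  m <- driver_persistence(lesions)
  hdr <- "#sample_id\tpatient_id\tlesion_type\tsite\tresection_index\tinterval_therapy\ttumor_content\tsex"
  sheet <- read_sample_sheet(write_tsv_lines(c(hdr,
    "primary\tPT\tPRIMARY\trectum\t1\tfalse\t0.6\tFEMALE",
    "liver1\tPT\tMETASTASIS\tliver\t2\ttrue\t0.5\tFEMALE",
    "lung1\tPT\tMETASTASIS\tlung\t3\ttrue\t0.5\tFEMALE",
    "lung2\tPT\tMETASTASIS\tlung\t4\tfalse\t0.5\tFEMALE",
    "liver2\tPT\tMETASTASIS\tliver\t5\ttrue\t0.4\tFEMALE")))
  rep <- assemble_report(sheet, driver_matrix = m)
  sim <- rep$driver_similarity
  liver_pair <- sim$jaccard[sim$sample_a == "liver1" & sim$sample_b == "liver2"]
  expect_equal(liver_pair, 1.0)
  lung_vs_liver <- sim$jaccard[(sim$sample_a == "liver1" & sim$sample_b == "lung2") |
                               (sim$sample_a == "lung2" & sim$sample_b == "liver1")]
  expect_lt(lung_vs_liver, 1.0)
})
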