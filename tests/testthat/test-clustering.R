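test_that("the lesion-pair join applies the absence-means-zero rule", {
  a <- corrected_frame(c("v1", "v2"), c(0.4, 0.3))
  b <- corrected_frame("v1", 0.35)
  vm <- build_vaf_matrix(a, b)
  expect_equal(unname(vm$points["v1", ]), c(0.4, 0.35))
  expect_equal(unname(vm$points["v2", ]), c(0.3, 0.0))
  expect_equal(vm$ids, sort(vm$ids))

  # uncovered site in the other lesion is dropped with a report
  vm2 <- build_vaf_matrix(a, b, depth_b = c(v1 = 100, v2 = 3))
  expect_equal(vm2$dropped$variant_id, "v2")
  expect_equal(nrow(vm2$points), 1L)

  expect_error(build_vaf_matrix(corrected_frame(character(0), numeric(0)),
                                corrected_frame(character(0), numeric(0))),
               "no variants")
})

test_that("EM handles degenerate and well-separated inputs", {
  m <- fit_em(rep(0.4, 30), k = 3, seed = 1)
  expect_equal(m$k, 1L)
  expect_equal(unname(m$means[1, 1]), 0.4)
  expect_equal(unname(m$variances[1, 1]), 1e-5)
  expect_true("DEGENERATE" %in% m$flags)

  expect_error(fit_em(rnorm(5), k = 10, seed = 1), "exceeds")

  set.seed(21)
  x <- c(rnorm(100, 0.10, 0.01), rnorm(100, 0.45, 0.01))
  m2 <- fit_em(x, k = 2, seed = 5)
  mu <- sort(m2$means[, 1])
  expect_lt(abs(mu[1] - 0.10), 0.02)
  expect_lt(abs(mu[2] - 0.45), 0.02)
})

test_that("the EM log-likelihood trace is non-decreasing", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    d <- sample(1:2, 1)
    pts <- matrix(runif(n * d), ncol = d)
    m <- fit_em(pts, k = sample(1:4, 1), seed = i)
    expect_true(all(diff(m$loglik_trace) >= -1e-8))
  }
})

test_that("BIC selects the planted number of components", {
  set.seed(3)
  one <- rnorm(150, 0.3, 0.02)
  expect_equal(select_k(one, seed = 2)$k, 1L)

  hits <- 0L
  for (s in 1:3) {
    set.seed(100 + s)
    x <- c(rnorm(100, 0.10, 0.02), rnorm(100, 0.30, 0.02), rnorm(100, 0.50, 0.02))
    if (select_k(x, seed = s)$k == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 2L)

  # unresolvably close components collapse to one
  set.seed(5)
  close2 <- c(rnorm(100, 0.300, 0.02), rnorm(100, 0.305, 0.02))
  expect_equal(select_k(close2, seed = 9)$k, 1L)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(13)
  x <- c(rnorm(150, 0.15, 0.02), rnorm(150, 0.40, 0.03))
  ours <- fit_em(x, k = 2, seed = 4)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$means[, 1]), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.01)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-3)
})

test_that("cluster extraction sorts centers, breaks ties low and flags presence", {
  pts <- matrix(c(0.1, 0.1, 0.3, 0.3), ncol = 1)
  model <- structure(list(k = 2L, d = 1L,
                          means = matrix(c(0.3, 0.1), 2, 1),
                          variances = matrix(0.01, 2, 1),
                          weights = c(0.5, 0.5), loglik = 0,
                          loglik_trace = 0, n_iter = 1L, converged = TRUE,
                          seed = 1L, flags = character(0), n = 4L),
                     class = "ct_mixture")
  # centers re-sorted ascending; equidistant point goes to the lower id
  res <- extract_clusters(model, matrix(0.2, 1, 1), ids = "mid")
  expect_equal(res$clusters$center_a, c(0.1, 0.3))
  expect_equal(res$assignments$cluster_id, 1L)

  cl <- data.frame(center_a = c(0.38, 0.27), center_b = c(0.41, 0.01))
  m2 <- structure(list(k = 2L, d = 2L,
                       means = as.matrix(cl), variances = matrix(0.01, 2, 2),
                       weights = c(0.5, 0.5), loglik = 0, loglik_trace = 0,
                       n_iter = 1L, converged = TRUE, seed = 1L,
                       flags = character(0), n = 2L), class = "ct_mixture")
  res2 <- extract_clusters(m2, as.matrix(cl), ids = c("a", "b"))
  expect_equal(res2$clusters$present_a, c(TRUE, TRUE))
  expect_equal(res2$clusters$present_b, c(FALSE, TRUE))
})

test_that("well-separated fits are label-stable across seeds", {
  set.seed(6)
  x <- cbind(c(rnorm(80, 0.1, 0.01), rnorm(80, 0.4, 0.01)),
             c(rnorm(80, 0.4, 0.01), rnorm(80, 0.1, 0.01)))
  centers <- lapply(1:4, function(s) {
    m <- fit_em(x, k = 2, seed = s)
    res <- extract_clusters(m, x)
    round(as.matrix(res$clusters[, c("center_a", "center_b")]), 3)
  })
  for (i in 2:4) expect_equal(centers[[i]], centers[[1]], tolerance = 0.01)
})
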