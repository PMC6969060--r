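# Expectation-maximization Gaussian mixture clustering of corrected VAFs.
#
# The mixture is fit from scratch: diagonal-covariance Gaussians in 1 or 2
# dimensions (one axis per lesion), k-means++ seeding, log-space E step,
# a variance floor against collapse on point masses (private mutations sit
# exactly at 0 in the lesion they are absent from), and BIC over restarts
# for the number of components. mclust is deliberately not used here; it
# serves as an independent cross-check in the test suite only.

#' Join two lesions' corrected variants into a clustering matrix
#'
#' Variants are joined on variant_id. A variant absent from one lesion gets
#' coordinate 0 there (absence = VAF 0), provided the site is covered in
#' that lesion; when per-site depths are supplied, sites below `min_depth`
#' in the lesion missing the variant are dropped and reported. Rows are
#' sorted by variant_id for determinism.
#'
#' @param lesion_a,lesion_b corrected data.frames from [correct_sample()]
#'   (columns variant_id, corrected_vaf).
#' @param depth_a,depth_b optional named numeric vectors: per-site total
#'   depth keyed by variant_id, used for the coverage check. NULL = assume
#'   covered.
#' @param min_depth coverage floor for the absence-means-zero rule.
#' @return list with `points` (n x 2 matrix, columns lesion_a / lesion_b),
#'   `ids`, and `dropped` (data.frame variant_id, reason).
#' @export
build_vaf_matrix <- function(lesion_a, lesion_b, depth_a = NULL, depth_b = NULL,
                             min_depth = 10L) {
  ids <- sort(union(lesion_a$variant_id, lesion_b$variant_id))
  if (!length(ids)) stop_ct("no variants to cluster")
  va <- setNames(lesion_a$corrected_vaf, lesion_a$variant_id)
  vb <- setNames(lesion_b$corrected_vaf, lesion_b$variant_id)
  x <- unname(va[ids]); y <- unname(vb[ids])
  covered <- function(id, depth) {
    if (is.null(depth)) rep(TRUE, length(id))
    else !is.na(depth[id]) & depth[id] >= min_depth
  }
  drop <- (is.na(x) & !covered(ids, depth_a)) | (is.na(y) & !covered(ids, depth_b))
  dropped <- data.frame(variant_id = ids[drop],
                        reason = rep("UNCOVERED", sum(drop)),
                        stringsAsFactors = FALSE)
  ids <- ids[!drop]
  if (!length(ids)) stop_ct("no variants to cluster")
  x <- x[!drop]; y <- y[!drop]
  x[is.na(x)] <- 0; y[is.na(y)] <- 0
  pts <- cbind(lesion_a = x, lesion_b = y)
  rownames(pts) <- ids
  list(points = pts, ids = ids, dropped = dropped)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  i <- sample.int(n, 1L)
  centers[1L, ] <- points[i, ]
  if (k > 1L) {
    d2 <- rowSums((points - matrix(centers[1L, ], n, ncol(points), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) i <- sample.int(n, 1L)
      else i <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- points[i, ]
      d2 <- pmin(d2, rowSums((points - matrix(centers[j, ], n, ncol(points), byrow = TRUE))^2))
    }
  }
  centers
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' Standard EM with k-means++ initialization from `seed`, log-space
#' responsibilities, per-component diagonal variances floored at
#' `var_floor`, and convergence when the log-likelihood improves by less
#' than `tol`. The log-likelihood trace is recorded and is non-decreasing
#' up to floating tolerance (EM monotonicity).
#'
#' @param points numeric matrix (n x d, d = 1 or 2) or vector.
#' @param k number of components (1 <= k <= n).
#' @param seed integer seed for the initialization.
#' @param max_iter,tol convergence controls.
#' @param var_floor variance floor (default 1e-5).
#' @return object of class `ct_mixture`: k, means (k x d), variances
#'   (k x d), weights, loglik, loglik_trace, n_iter, converged, seed, flags.
#' @export
fit_em <- function(points, k, seed = 17L, max_iter = 500L, tol = 1e-8,
                   var_floor = 1e-5) {
  if (is.vector(points)) points <- matrix(points, ncol = 1L)
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (k < 1L) stop_ct("k must be >= 1")
  if (k > n) stop_ct("k = %d exceeds number of points (%d)", k, n)
  flags <- character(0)
  if (n > 1L && all(apply(points, 2L, function(c) max(c) - min(c)) == 0)) {
    # all points identical: one degenerate component regardless of requested k
    k <- 1L
    flags <- "DEGENERATE"
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  means <- kmeanspp_centers(points, k)
  variances <- matrix(rep(pmax(apply(points, 2L, stats::var), var_floor), each = k),
                      k, d)
  variances[is.na(variances)] <- var_floor
  weights <- rep(1 / k, k)

  trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  logdens <- matrix(0, n, k)
  while (iter < max_iter) {
    iter <- iter + 1L
    for (j in seq_len(k)) {
      lp <- 0
      for (dd in seq_len(d))
        lp <- lp + dnorm(points[, dd], means[j, dd], sqrt(variances[j, dd]), log = TRUE)
      logdens[, j] <- log(weights[j]) + lp
    }
    m <- apply(logdens, 1L, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    new_loglik <- sum(lse)
    trace <- c(trace, new_loglik)
    if (is.finite(loglik) && new_loglik - loglik < tol) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
    resp <- exp(logdens - lse)           # n x k responsibilities
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    weights <- nk / n
    weights <- weights / sum(weights)
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * points) / nk[j]
      means[j, ] <- mu
      dev2 <- (points - matrix(mu, n, d, byrow = TRUE))^2
      variances[j, ] <- pmax(colSums(resp[, j] * dev2) / nk[j], var_floor)
    }
  }
  structure(list(k = k, d = d, means = means, variances = variances,
                 weights = weights, loglik = loglik, loglik_trace = trace,
                 n_iter = iter, converged = converged, seed = seed,
                 flags = flags, n = n),
            class = "ct_mixture")
}

#' @export
print.ct_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: k = %d, d = %d, n = %d, loglik = %.3f (%s)\n",
              x$k, x$d, x$n, x$loglik,
              if (x$converged) sprintf("converged in %d iterations", x$n_iter)
              else "not converged"))
  for (j in seq_len(x$k))
    cat(sprintf("  component %d: mean (%s)  weight %.3f\n", j,
                paste(sprintf("%.3f", x$means[j, ]), collapse = ", "),
                x$weights[j]))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits each k in `k_range` with `n_restarts` k-means++ seeds (derived from
#' `seed`), keeps the best log-likelihood per k, and returns the fit
#' minimizing BIC = -2 loglik + p log(n) with p = k(2d + 1) - 1 free
#' parameters (d means, d variances and a weight per component, minus the
#' weight sum constraint).
#'
#' @param points numeric matrix or vector.
#' @param k_range candidate component counts (default 1:6, truncated at n).
#' @param seed base seed.
#' @param n_restarts restarts per k.
#' @param ... passed to [fit_em()].
#' @return the selected `ct_mixture`, with `bic` and a `selection` table
#'   (k, loglik, bic) attached.
#' @export
select_k <- function(points, k_range = 1:6, seed = 17L, n_restarts = 5L, ...) {
  if (is.vector(points)) points <- matrix(points, ncol = 1L)
  n <- nrow(points)
  k_range <- k_range[k_range <= n]
  if (!length(k_range)) stop_ct("empty k_range")
  best <- NULL; best_bic <- Inf
  sel <- data.frame(k = integer(0), loglik = numeric(0), bic = numeric(0))
  for (k in k_range) {
    fit_k <- NULL
    for (r in seq_len(n_restarts)) {
      f <- fit_em(points, k, seed = seed + 1009L * k + r, ...)
      if (is.null(fit_k) || f$loglik > fit_k$loglik) fit_k <- f
    }
    p <- fit_k$k * (2 * fit_k$d + 1) - 1
    bic <- -2 * fit_k$loglik + p * log(n)
    sel <- rbind(sel, data.frame(k = fit_k$k, loglik = fit_k$loglik, bic = bic))
    if (bic < best_bic) { best_bic <- bic; best <- fit_k; best$bic <- bic }
  }
  best$selection <- unique(sel)
  best
}

#' Extract hard-assigned clone clusters from a fitted mixture
#'
#' Components are relabelled in lexicographic center order; points take the
#' component with maximum posterior responsibility, ties broken toward the
#' lower cluster_id. A cluster is present in a lesion when its center
#' coordinate there is at least `presence_min`.
#'
#' @param model `ct_mixture` from [fit_em()] / [select_k()].
#' @param points the matrix the model was fit to.
#' @param ids variant ids, one per row of `points`.
#' @param presence_min center coordinate floor for presence (default 0.05).
#' @return list with `clusters` (data.frame cluster_id, center_a, center_b,
#'   weight, n_members, present_a, present_b) and `assignments`
#'   (variant_id, x, y, cluster_id). For 1-d fits center_b / present_b are NA.
#' @export
extract_clusters <- function(model, points, ids = rownames(points),
                             presence_min = 0.05) {
  if (is.vector(points)) points <- matrix(points, ncol = 1L)
  n <- nrow(points); d <- model$d
  ord <- do.call(order, as.data.frame(model$means))
  means <- model$means[ord, , drop = FALSE]
  variances <- model$variances[ord, , drop = FALSE]
  weights <- model$weights[ord]
  logdens <- matrix(0, n, model$k)
  for (j in seq_len(model$k)) {
    lp <- 0
    for (dd in seq_len(d))
      lp <- lp + dnorm(points[, dd], means[j, dd], sqrt(variances[j, dd]), log = TRUE)
    logdens[, j] <- log(weights[j]) + lp
  }
  assign <- max.col(logdens, ties.method = "first")
  clusters <- data.frame(
    cluster_id = seq_len(model$k),
    center_a = means[, 1L],
    center_b = if (d > 1L) means[, 2L] else NA_real_,
    weight = weights,
    n_members = as.integer(tabulate(assign, nbins = model$k)),
    present_a = means[, 1L] >= presence_min,
    present_b = if (d > 1L) means[, 2L] >= presence_min else NA,
    stringsAsFactors = FALSE
  )
  assignments <- data.frame(
    variant_id = ids %||% as.character(seq_len(n)),
    x = points[, 1L],
    y = if (d > 1L) points[, 2L] else NA_real_,
    cluster_id = assign,
    stringsAsFactors = FALSE
  )
  list(clusters = clusters, assignments = assignments)
}
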