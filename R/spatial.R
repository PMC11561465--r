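# 3D point-pattern inference: nearest-neighbor G function with Monte-Carlo
# CSR envelopes, Moran's I with permutation nulls, Fisher pooling, and the
# distance-to-nearest-KC comparison.

#' Nearest-neighbor distances of a 3D point pattern
#'
#' @param pattern A [point_pattern()] or an `n x 3` coordinate matrix
#'   (n >= 2).
#' @return List with `distances` (per-point nearest-neighbor distance, um)
#'   and `mean`. Coincident points produce zero distances and a warning.
#' @examples
#' nn_distances(rbind(c(0, 0, 0), c(10, 0, 0)))$mean
#' @export
nn_distances <- function(pattern) {
  pts <- pattern_points(pattern)
  n <- nrow(pts)
  if (n < 2L) stopf("nearest-neighbor distances need at least 2 points")
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  if (any(nn == 0))
    warnf("%d coincident point pair(s): zero nearest-neighbor distances",
          sum(nn == 0) %/% 2)
  list(distances = unname(nn), mean = mean(nn))
}

#' Empirical G function
#'
#' `G(r)` is the cumulative distribution of nearest-neighbor distances:
#' the fraction of points whose nearest neighbor lies within `r`. No edge
#' correction is applied; envelope inference compares data and simulations
#' with the identical estimator inside the identical region, which keeps
#' the test exact without correcting the estimator itself.
#'
#' @param pattern A [point_pattern()] or coordinate matrix (n >= 2).
#' @param r_grid Increasing vector of distances (um).
#' @return Numeric vector `G(r)` over `r_grid`.
#' @examples
#' g_function(rbind(c(0, 0, 0), c(10, 0, 0)), r_grid = c(5, 10, 15))
#' @export
g_function <- function(pattern, r_grid) {
  if (is.unsorted(r_grid, strictly = FALSE)) stopf("`r_grid` must increase")
  nn <- nn_distances(pattern)$distances
  vapply(r_grid, function(r) mean(nn <= r), numeric(1))
}

#' Monte-Carlo CSR envelope test for the G function
#'
#' Simulates `n_sim` patterns of complete spatial randomness with the same
#' number of points in the same region, computes pointwise envelopes of the
#' simulated G functions, and a global Monte-Carlo p-value from the rank of
#' an integrated deviation statistic (mean absolute deviation of `G` from
#' the null mean over the r grid; `"max"` deviation available) among the
#' simulations: `p = (k + 1) / (n_sim + 1)`.
#'
#' @param pattern A [point_pattern()] with a valid region (n >= 2).
#' @param r_grid Distance grid (um); default 64 points up to the 98th
#'   percentile of the observed nearest-neighbor distances times 1.5.
#' @param n_sim Number of CSR simulations (>= 19 enforced; 999 matches the
#'   published envelope convention).
#' @param statistic `"mad"` (integrated absolute deviation, default) or
#'   `"max"`.
#' @param envelope_rank Pointwise envelopes use the `envelope_rank`-th
#'   smallest/largest simulated value (1 = min/max envelopes).
#' @param seed Integer seed or `NULL`.
#' @return Object of class `kc_envelope`: `r`, `g_obs`, `null_mean`,
#'   `lower`, `upper`, `p`, `n_sim`, `statistic`.
#' @examples
#' reg <- region_box(upper = c(500, 500, 500))
#' pat <- gen_point_pattern(reg, 50, "csr", seed = 2)
#' env <- csr_envelope(pat, n_sim = 39, seed = 3)
#' env$p
#' @export
csr_envelope <- function(pattern, r_grid = NULL, n_sim = 999,
                         statistic = c("mad", "max"), envelope_rank = 1L,
                         seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(pattern, "kc_pattern"))
  if (pattern$n < 2L) stopf("envelope test needs at least 2 points")
  if (n_sim < 19) stopf("n_sim < 19 refused: envelope resolution too coarse")
  nn_obs <- nn_distances(pattern)$distances
  if (is.null(r_grid))
    r_grid <- seq(0, 1.5 * quantile(nn_obs, 0.98), length.out = 64)
  g_obs <- vapply(r_grid, function(r) mean(nn_obs <= r), numeric(1))
  with_seed(seed, {
    sims <- matrix(0, n_sim, length(r_grid))
    for (s in seq_len(n_sim)) {
      p_s <- region_sample(pattern$region, pattern$n)
      nn_s <- nn_distances(p_s)$distances
      sims[s, ] <- vapply(r_grid, function(r) mean(nn_s <= r), numeric(1))
    }
    null_mean <- colMeans(sims)
    k <- as.integer(envelope_rank)
    lower <- apply(sims, 2, function(v) sort(v)[k])
    upper <- apply(sims, 2, function(v) sort(v, decreasing = TRUE)[k])
    dev_fun <- if (statistic == "mad") {
      function(g) mean(abs(g - null_mean))
    } else {
      function(g) max(abs(g - null_mean))
    }
    t_obs <- dev_fun(g_obs)
    t_sim <- apply(sims, 1, dev_fun)
    p <- (1 + sum(t_sim >= t_obs)) / (n_sim + 1)
    structure(list(r = r_grid, g_obs = g_obs, null_mean = null_mean,
                   lower = lower, upper = upper, p = p, n_sim = n_sim,
                   statistic = statistic, t_obs = t_obs),
              class = "kc_envelope")
  })
}

#' @export
print.kc_envelope <- function(x, ...) {
  cat(sprintf("<kc_envelope: %s statistic, %d sims, p = %.4g>\n",
              x$statistic, x$n_sim, x$p))
  invisible(x)
}

#' @export
plot.kc_envelope <- function(x, ...) {
  graphics::plot(x$r, x$g_obs, type = "l", col = "red3", lwd = 2,
                 xlab = "r (um)", ylab = "G(r)", ylim = c(0, 1), ...)
  graphics::polygon(c(x$r, rev(x$r)), c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(x$r, x$null_mean, lty = 2)
  graphics::lines(x$r, x$g_obs, col = "red3", lwd = 2)
  invisible(x)
}

#' Spatial weight matrices for marked patterns
#'
#' Row-standardized spatial weights over point locations: inverse Euclidean
#' distance with a cutoff (default; cutoff defaults to twice the mean
#' nearest-neighbor distance), k nearest neighbors, or a user matrix.
#' Points isolated under the cutoff get an all-zero row and a warning.
#'
#' @param pts `n x 3` coordinate matrix.
#' @param scheme `"idw"` or `"knn"`.
#' @param cutoff Distance cutoff (um) for `"idw"`.
#' @param k Neighbor count for `"knn"`.
#' @param row_standardize Divide each row by its sum (default `TRUE`).
#' @return `n x n` weight matrix with zero diagonal.
#' @export
moran_weights <- function(pts, scheme = c("idw", "knn"), cutoff = NULL,
                          k = 4L, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  pts <- as_xyz(pts)
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  if (scheme == "idw") {
    if (is.null(cutoff)) cutoff <- 2 * mean(apply(d, 1, min))
    w <- ifelse(d <= cutoff, 1 / d, 0)
    diag(w) <- 0
    if (any(rowSums(w) == 0))
      warnf("%d point(s) isolated under cutoff %.3g um: zero weight rows",
            sum(rowSums(w) == 0), cutoff)
  } else {
    if (k >= n) stopf("`k` must be smaller than the number of points")
    w <- matrix(0, n, n)
    for (i in seq_len(n)) w[i, order(d[i, ])[seq_len(k)]] <- 1
  }
  if (row_standardize) {
    rs <- rowSums(w)
    w[rs > 0, ] <- w[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  w
}

#' Moran's I with a permutation null
#'
#' Global spatial autocorrelation of a numeric (or 0/1-coded binary) mark
#' over 3D positions:
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W = sum_ij w_ij`. Significance comes from random permutations of
#' the marks over the positions; the two-sided p-value doubles the smaller
#' tail rank and is capped at 1. The permutation-null expectation of I is
#' `-1 / (n - 1)`.
#'
#' @param pattern A marked [point_pattern()], or an `n x 3` coordinate
#'   matrix with `marks` supplied.
#' @param marks Numeric marks (required if `pattern` carries none).
#' @param weights A weight matrix, or a scheme name passed to
#'   [moran_weights()] (`"idw"` default, `"knn"`).
#' @param n_perm Number of mark permutations (default 999).
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @param seed Integer seed or `NULL`.
#' @param ... Passed to [moran_weights()] when `weights` is a scheme name.
#' @return Object of class `kc_moran`: `i`, `p`, `null_mean`, `null_sd`,
#'   `expectation` (`-1/(n-1)`), `n`, `n_perm`, `weights_scheme`.
#' @examples
#' pts <- matrix(runif(30, 0, 100), 10, 3)
#' morans_i(pts, marks = rnorm(10), n_perm = 99, seed = 1)
#' @export
morans_i <- function(pattern, marks = NULL, weights = "idw", n_perm = 999,
                     alternative = c("two.sided", "greater", "less"),
                     seed = NULL, ...) {
  alternative <- match.arg(alternative)
  if (inherits(pattern, "kc_pattern")) {
    pts <- pattern$points
    if (is.null(marks)) marks <- pattern$marks
  } else pts <- as_xyz(pattern)
  if (is.null(marks)) stopf("`marks` are required")
  if (is.logical(marks)) marks <- as.numeric(marks)
  if (is.factor(marks)) stopf("marks must be numeric (code binary as 0/1)")
  n <- nrow(pts)
  if (n < 3L) stopf("Moran's I needs at least 3 points")
  if (length(marks) != n) stopf("marks must align 1:1 with points")
  if (anyNA(marks) || sd(marks) == 0)
    stopf("marks are constant (or NA): Moran's I is undefined")
  scheme <- if (is.matrix(weights)) "custom" else weights
  w <- if (is.matrix(weights)) weights else moran_weights(pts, weights, ...)
  s0 <- sum(w)
  if (s0 <= 0) stopf("all spatial weights are zero")
  z <- marks - mean(marks)
  denom <- sum(z^2)
  i_obs <- (n / s0) * drop(crossprod(z, w %*% z)) / denom
  with_seed(seed, {
    perm_z <- vapply(seq_len(n_perm), function(b) z[sample.int(n)],
                     numeric(n))
    i_perm <- (n / s0) * colSums(perm_z * (w %*% perm_z)) / denom
    p_hi <- (1 + sum(i_perm >= i_obs)) / (n_perm + 1)
    p_lo <- (1 + sum(i_perm <= i_obs)) / (n_perm + 1)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_hi, p_lo)),
                greater = p_hi, less = p_lo)
    structure(list(i = i_obs, p = p, null_mean = mean(i_perm),
                   null_sd = sd(i_perm), expectation = -1 / (n - 1),
                   n = n, n_perm = n_perm, weights_scheme = scheme,
                   alternative = alternative),
              class = "kc_moran")
  })
}

#' @export
print.kc_moran <- function(x, ...) {
  cat(sprintf("<kc_moran: I = %.4f (E[I] = %.4f), p = %.4g, %d perms>\n",
              x$i, x$expectation, x$p, x$n_perm))
  invisible(x)
}

#' Pool p-values across specimens
#'
#' Fisher's method: `-2 * sum(log p_i)` referred to a chi-square
#' distribution with `2k` degrees of freedom. Zero p-values are refused
#' (replace them with their Monte-Carlo lower bound `1/(n_sim+1)` first).
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param method Only `"fisher"` is implemented.
#' @return Pooled p-value.
#' @examples
#' pool_pvalues(c(0.5, 0.5))
#' @export
pool_pvalues <- function(p, method = "fisher") {
  method <- match.arg(method, "fisher")
  if (!length(p)) stopf("no p-values to pool")
  if (any(!is.finite(p)) || any(p > 1)) stopf("p-values must be in (0, 1]")
  if (any(p <= 0))
    stopf("p = 0 refused: use the Monte-Carlo lower bound 1/(n_sim+1)")
  stat <- -2 * sum(log(p))
  pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

#' Distance-to-nearest-KC test
#'
#' Tests whether query points (e.g. isolated proliferating cells: singles,
#' pairs, trios) sit farther from their nearest KC than KCs sit from each
#' other, via a one-sided Wilcoxon rank-sum comparison of query-to-nearest-
#' KC distances against KC-to-KC nearest-neighbor distances.
#'
#' @param query `m x 3` coordinate matrix (or pattern), m >= 1.
#' @param kcs `n x 3` KC centroid matrix (or pattern), n >= 2.
#' @param alternative Passed to [wilcox.test()]; default `"greater"`
#'   (queries farther).
#' @return Object of class `kc_nnkc_test`: `query_distances`,
#'   `kc_nn_distances`, `p`, `statistic`.
#' @export
distance_to_nearest_kc_test <- function(query, kcs,
                                        alternative = "greater") {
  qp <- pattern_points(query)
  kp <- pattern_points(kcs)
  if (nrow(qp) < 1L) stopf("need at least one query point")
  if (nrow(kp) < 2L) stopf("need at least two KCs")
  qd <- apply(qp, 1, function(q) sqrt(min(colSums((t(kp) - q)^2))))
  kd <- nn_distances(kp)$distances
  wt <- suppressWarnings(wilcox.test(qd, kd, alternative = alternative,
                                     exact = FALSE))
  structure(list(query_distances = qd, kc_nn_distances = kd,
                 p = wt$p.value, statistic = unname(wt$statistic),
                 alternative = alternative),
            class = "kc_nnkc_test")
}

#' @export
print.kc_nnkc_test <- function(x, ...) {
  cat(sprintf(
    "<kc_nnkc_test: median query %.1f um vs KC NN %.1f um, p = %.4g>\n",
    median(x$query_distances), median(x$kc_nn_distances), x$p))
  invisible(x)
}

pattern_points <- function(x) {
  if (inherits(x, "kc_pattern")) x$points else as_xyz(x)
}
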