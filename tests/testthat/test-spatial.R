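# 3D point-pattern statistics: G function, CSR envelopes, Moran's I,
# pooling, distance-to-nearest-KC test.

test_that("nearest-neighbor distances: hand geometry and isometry", {
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  nn <- nn_distances(two)
  expect_equal(nn$distances, c(10, 10))
  expect_equal(nn$mean, 10)
  # unit-cube corners scaled to 100 um: every NN distance is one edge
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 100
  expect_equal(nn_distances(cube)$distances, rep(100, 8))
  # invariance under rigid rotation + translation
  set.seed(5)
  pts <- matrix(runif(60, 0, 200), 20, 3)
  rot <- random_rotation()
  moved <- sweep(pts %*% rot, 2, c(50, -20, 7), "+")
  expect_equal(nn_distances(moved)$distances, nn_distances(pts)$distances)
  expect_error(nn_distances(matrix(0, 1, 3)), "at least 2")
  expect_warning(nn_distances(rbind(c(0, 0, 0), c(0, 0, 0))), "coincident")
})

test_that("G function is the NN-distance CDF", {
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(g_function(two, c(5, 10, 15)), c(0, 1, 1))
  # CSR closed form in a large box
  pat <- gen_point_pattern(region_box(upper = c(1000, 1000, 1000)), 2000,
                           "csr", seed = 21)
  r <- seq(0, 45, by = 1.5)
  g <- g_function(pat, r)
  theo <- 1 - exp(-2e-6 * 4 / 3 * pi * r^3)
  expect_lt(max(abs(g - theo)), 0.05)
  # refining the grid never reorders values (CDF monotonicity)
  g_fine <- g_function(pat, seq(0, 45, by = 0.5))
  expect_true(all(diff(g_fine) >= 0))
  expect_equal(g_fine[seq(1, 91, by = 3)], g)
  expect_error(g_function(two, c(10, 5)), "increase")
})

test_that("CSR envelope: clustered patterns are rejected at the floor", {
  reg <- region_box(upper = c(500, 500, 500))
  th <- gen_point_pattern(reg, 200, "clustered",
                          list(n_parents = 10, sigma = 8), seed = 31)
  env <- csr_envelope(th, n_sim = 999, seed = 32)
  expect_equal(env$p, 1 / 1000)  # minimum achievable with 999 sims
  expect_true(all(env$lower <= env$null_mean + 1e-12))
  expect_true(all(env$upper >= env$null_mean - 1e-12))
  expect_true(all(diff(env$g_obs) >= 0))
  expect_error(csr_envelope(th, n_sim = 10), "19")
  # a CSR pattern is not rejected wildly: p bounded away from the floor
  csr <- gen_point_pattern(reg, 100, "csr", seed = 33)
  env2 <- csr_envelope(csr, n_sim = 99, seed = 34)
  expect_gte(env2$p, 1 / 100)
  # reproducibility under fixed seed
  env3 <- csr_envelope(csr, n_sim = 99, seed = 34)
  expect_identical(env2$p, env3$p)
})

test_that("Moran's I: ring identity, equal weights, brute-force oracle", {
  # 4 points on a ring with alternating marks and adjacency weights: the
  # definition evaluates to exactly -1
  ring <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)) * 50
  w <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if ((i - j) %% 2 == 1) w[i, j] <- 1
  mi <- morans_i(ring, marks = c(1, -1, 1, -1), weights = w, n_perm = 99,
                 seed = 1)
  expect_equal(mi$i, -1)
  # all-equal weights force I = -1/(n-1) for any marks
  set.seed(2)
  for (n in c(4, 7, 10)) {
    w_eq <- matrix(1, n, n); diag(w_eq) <- 0
    x <- rnorm(n)
    mi2 <- morans_i(matrix(runif(3 * n, 0, 100), n, 3), marks = x,
                    weights = w_eq, n_perm = 99, seed = 3)
    expect_equal(mi2$i, -1 / (n - 1))
    expect_equal(mi2$i, bf_moran(w_eq, x))
  }
  # package weights vs double-loop evaluation, machine precision, n <= 10
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    pts <- matrix(runif(3 * n, 0, 100), n, 3)
    x <- rnorm(n)
    for (scheme in c("idw", "knn")) {
      w3 <- suppressWarnings(moran_weights(pts, scheme, k = 3L))
      mi3 <- morans_i(pts, marks = x, weights = w3, n_perm = 19, seed = 4)
      expect_equal(mi3$i, bf_moran(w3, x), tolerance = 1e-12)
    }
  }
  expect_error(morans_i(ring, marks = rep(1, 4), weights = w), "constant")
  expect_error(morans_i(ring[1:2, ], marks = 1:2), "3 points")
})

test_that("Moran permutation null is centred at -1/(n-1)", {
  set.seed(6)
  pts <- matrix(runif(90, 0, 300), 30, 3)
  x <- rnorm(30)
  mi <- morans_i(pts, marks = x, n_perm = 1999, seed = 7)
  expect_lt(abs(mi$null_mean - (-1 / 29)), 3 * mi$null_sd / sqrt(1999))
})

test_that("G and Moran statistics are isometry invariant", {
  set.seed(8)
  pts <- matrix(runif(75, 0, 400), 25, 3)
  x <- rnorm(25)
  rot <- random_rotation()
  moved <- sweep(pts %*% rot, 2, c(-30, 12, 100), "+")
  r <- seq(0, 150, by = 10)
  expect_equal(g_function(moved, r), g_function(pts, r))
  w_a <- moran_weights(pts, "idw")
  w_b <- moran_weights(moved, "idw")
  expect_equal(morans_i(moved, marks = x, weights = w_b, n_perm = 19,
                        seed = 9)$i,
               morans_i(pts, marks = x, weights = w_a, n_perm = 19,
                        seed = 9)$i,
               tolerance = 1e-10)
})

test_that("Fisher pooling follows the chi-square combination", {
  # frozen against pchisq(-2 * sum(log(p)), df = 2k, lower.tail = FALSE)
  expect_equal(pool_pvalues(c(0.5, 0.5)), 0.5965736, tolerance = 1e-6)
  expect_equal(pool_pvalues(1), 1)
  tiny <- rep(0.01, 4)
  expect_lt(pool_pvalues(tiny), 0.01)
  expect_error(pool_pvalues(c(0.5, 0)), "Monte-Carlo")
  expect_error(pool_pvalues(numeric(0)), "no p-values")
})

test_that("distance-to-nearest-KC test detects displaced activations", {
  reg <- region_box(upper = c(500, 500, 500))
  kcp <- gen_point_pattern(reg, 40, "csr", seed = 41)
  # queries coincident with KCs: distances 0, 'farther' alternative dead
  co <- distance_to_nearest_kc_test(kcp$points[1:10, ], kcp)
  expect_true(all(co$query_distances == 0))
  expect_gt(co$p, 0.9)
  # queries far from every KC in a region corner
  far <- matrix(runif(30, 490, 500), 10, 3) + 2000
  dt <- distance_to_nearest_kc_test(far, kcp)
  expect_lte(dt$p, 0.05)
  expect_error(distance_to_nearest_kc_test(far[0, , drop = FALSE], kcp),
               "query")
  # near-calibration: queries drawn by the same mechanism as the KCs.
  # The two distance samples are only approximately exchangeable (a query
  # sees all 40 KCs, a KC its 39 peers), so the rejection rate is allowed
  # a margin beyond the exact-null binomial band
  set.seed(43)
  rej <- mean(vapply(1:200, function(i) {
    kk <- matrix(runif(120, 0, 500), 40, 3)
    qq <- matrix(runif(30, 0, 500), 10, 3)
    distance_to_nearest_kc_test(qq, kk)$p <= 0.05
  }, logical(1)))
  expect_lt(rej, 0.12)
})
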