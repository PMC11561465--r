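# Stochastic clone model: simulator, master-equation oracle, snapshots,
# fitting machinery.

test_that("frozen clone stays frozen and is flagged", {
  p0 <- clone_params(lambda_k = 0, lambda_d = 0, gamma_k0 = 0,
                     gamma_d0 = 0, alpha_k = 0, alpha_d = 0)
  tr <- simulate_clone(p0, t_max = 50, seed = 1)
  expect_equal(unname(tr$final), c(1L, 0L, 0L))
  expect_equal(nrow(tr$events), 0L)
  expect_true(tr$frozen)
  me <- master_equation(p0, t = 5, k_max = 5, d_max = 5)
  expect_equal(me$p[2, 1], 1, tolerance = 1e-9)
  expect_true(me$reliable)
  expect_error(clone_params(alpha_k = -1), "negative")
  expect_error(simulate_clone(p0, t_max = 0), "> 0")
})

test_that("pure TAP birth follows the Yule law", {
  p <- clone_params(lambda_k = 1, lambda_d = 0, gamma_k0 = 0,
                    gamma_d0 = 0, alpha_k = 0, alpha_d = 0)
  s <- sample_kc_snapshot(p, 1e5, ages = rep(1, 1e5), min_size = 0,
                          seed = 2)
  emp <- tabulate(s$k, nbins = 60) / nrow(s)
  yule <- exp(-1) * (1 - exp(-1))^(0:59)
  tv <- 0.5 * sum(abs(emp - yule)) + 0.5 * (1 - sum(yule))
  expect_lt(tv, 0.01)
  # master-equation marginal reproduces the same closed form
  me <- master_equation(p, t = 1, k_max = 35, d_max = 1)
  expect_lt(max(abs(rowSums(me$p)[2:21] - yule[1:20])), 1e-7)
})

test_that("divergent cumulative hazard forces TAP exhaustion", {
  p <- clone_params(lambda_k = 0.4, lambda_d = 0, gamma_k0 = 0.5,
                    alpha_k = 2, gamma_d0 = 0, alpha_d = 0)
  s <- sample_kc_snapshot(p, 500, ages = rep(25, 500), min_size = 0,
                          seed = 3)
  expect_true(all(s$k == 0))
})

test_that("master equation conserves probability for small systems", {
  p <- clone_params(0.2, 0.15, 0.03, 1, 0.02, 1)
  me <- master_equation(p, t = c(1, 2, 4), k_max = 30, d_max = 30)
  for (m in me$p_list) expect_equal(sum(m), 1, tolerance = 1e-6)
})

test_that("snapshot sampling filters by the KC size definition", {
  p0 <- clone_params(lambda_k = 0, lambda_d = 0, gamma_k0 = 0,
                     gamma_d0 = 0, alpha_k = 0, alpha_d = 0)
  expect_warning(s0 <- sample_kc_snapshot(p0, 100, seed = 4), "filter")
  expect_equal(nrow(s0), 0L)
  expect_equal(attr(s0, "n_filtered"), 100L)
  s <- sample_kc_snapshot(clone_params(), 3000, seed = 5)
  expect_true(all(s$size >= 4))
  expect_equal(nrow(s) + attr(s, "n_filtered"), attr(s, "n_total"))
  # maturation crescent: median prNB fraction rises with size class
  med <- tapply(s$prnb_frac, cut(s$size, c(4, 8, 14, 22, Inf),
                                 include.lowest = TRUE), median)
  expect_true(all(diff(med) > -0.05))
  expect_gt(med[length(med)], med[1])
})

test_that("snapshot mixture over an age law matches the mixed oracle", {
  p <- clone_params(0.3, 0.25, 0.05, 2, 0.02, 2)
  age_grid <- c(1, 2.5, 4, 5.5, 7)
  me <- master_equation(p, t = age_grid, k_max = 34, d_max = 34)
  mix <- Reduce(`+`, me$p_list) / length(age_grid)
  n_per <- 2e4
  ages <- rep(age_grid, each = n_per)
  snap <- sample_kc_snapshot(p, length(ages), ages = ages, min_size = 0,
                             seed = 8)
  tab <- table(factor(pmin(snap$k, 34), levels = 0:34),
               factor(pmin(snap$d, 34), levels = 0:34))
  emp <- as.matrix(tab) / length(ages)
  expect_lt(0.5 * sum(abs(emp - mix)), 0.02)
})

test_that("stronger and later differentiation shift clones as expected", {
  # increasing gamma_k0 stochastically decreases terminal TAP counts
  base <- clone_params(gamma_k0 = 0.02)
  strong <- clone_params(gamma_k0 = 0.1)
  k_base <- sample_kc_snapshot(base, 3000, ages = rep(8, 3000),
                               min_size = 0, seed = 9)$k
  k_strong <- sample_kc_snapshot(strong, 3000, ages = rep(8, 3000),
                                 min_size = 0, seed = 9)$k
  q <- 0:20
  cdf_b <- vapply(q, function(x) mean(k_base <= x), numeric(1))
  cdf_s <- vapply(q, function(x) mean(k_strong <= x), numeric(1))
  expect_true(all(cdf_s >= cdf_b - 0.02))
  expect_gt(mean(k_base), mean(k_strong))
  # larger alpha with the cumulative hazard fixed at tau delays the first
  # differentiation: median first K -> D event time increases
  tau <- 10
  first_kd <- function(alpha) {
    g0 <- 2 * (alpha + 1) / tau^(alpha + 1)  # integral over [0, tau] = 2
    p <- clone_params(lambda_k = 0, lambda_d = 0, gamma_k0 = g0,
                      alpha_k = alpha, gamma_d0 = 0, alpha_d = 0)
    times <- vapply(1:800, function(i) {
      tr <- simulate_clone(p, t_max = tau, seed = 100 + i)
      if (nrow(tr$events)) tr$events$time[1] else tau
    }, numeric(1))
    median(times)
  }
  expect_gt(first_kd(3), first_kd(0.5))
})

test_that("fitting machinery validates inputs and reports structure", {
  expect_error(fit_clone_model(integer(0), integer(0)), "nonempty")
  obs <- sample_kc_snapshot(clone_params(), 1500, seed = 10)
  fit <- fit_clone_model(obs$k, obs$d,
                         fit_settings = list(n_sim = 1500, maxit = 40,
                                             seed = 2))
  expect_s3_class(fit, "kc_clone_fit")
  expect_true(is.finite(fit$nll))
  expect_equal(fit$n_params, 6)
  expect_named(fit$fitted, c("tap", "prnb"))
  expect_equal(sum(fit$fitted$tap$expected), 1, tolerance = 1e-6)
  fit2 <- fit_clone_model(obs$k, obs$d,
                          variant = list(gamma = "constant"),
                          fit_settings = list(n_sim = 1500, maxit = 40,
                                              seed = 2))
  expect_equal(fit2$n_params, 4)
  tab <- compare_variants(fit, fit2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$delta_aic[1], 0)
  # identical fits tie at delta AIC 0
  tab2 <- compare_variants(fit, fit)
  expect_equal(tab2$delta_aic, c(0, 0))
  expect_true(all(tab2$tied_with_best))
  # fits on different data refuse to be compared
  other <- fit_clone_model(obs$k[1:500], obs$d[1:500],
                           fit_settings = list(n_sim = 500, maxit = 5,
                                               seed = 2))
  expect_error(compare_variants(fit, other), "different observed data")
})
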