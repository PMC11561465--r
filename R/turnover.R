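# Steady-state renewal model of KC initiation and exhaustion.
#
# KCs are transient: new clusters are initiated at a constant rate r
# (fraction of the pool per day) and each lives a lifetime tau before
# exhaustion. At steady state initiation balances exhaustion; under the
# fixed-lifetime model r = 1/tau and the age distribution of the standing
# pool is uniform on [0, tau]. These closed forms drive the BrdU
# pulse-chase and tamoxifen labeling-index predictions.

#' Renewal model parameters
#'
#' @param rate KC initiation (= exhaustion) rate, fraction of the pool per
#'   day; default 0.094/day, the printed turnover rate.
#' @param lifetime KC lifetime tau in days. Under the fixed-lifetime model
#'   steady state forces `lifetime = 1/rate` (default); supplying an
#'   inconsistent pair is an error.
#' @param p_label Per-initiating-lineage labeling probability; default
#'   0.361, the printed labeling-index plateau.
#' @param pool_size Steady-state KC pool size N; default 288, the printed
#'   per-specimen mean KC count.
#' @param lifetime_model `"fixed"` (deterministic lifetime, default: the
#'   printed LI plateau at 10-14 days implies sharp saturation) or
#'   `"exponential"`.
#' @return Object of class `kc_renewal_params`.
#' @examples
#' renewal_params()$lifetime  # 1 / 0.094 = 10.64 days
#' @export
renewal_params <- function(rate = 0.094, lifetime = 1 / rate,
                           p_label = 0.361, pool_size = 288,
                           lifetime_model = c("fixed", "exponential")) {
  lifetime_model <- match.arg(lifetime_model)
  check_scalar(rate, "rate")
  if (rate <= 0) stopf("`rate` must be > 0")
  check_scalar(lifetime, "lifetime")
  if (lifetime <= 0) stopf("`lifetime` must be > 0")
  if (lifetime_model == "fixed" && abs(lifetime - 1 / rate) > 1e-8 * lifetime)
    stopf("fixed-lifetime steady state requires lifetime = 1/rate (%.4g d)",
          1 / rate)
  check_prob(p_label, "p_label")
  check_scalar(pool_size, "pool_size", lower = 1)
  structure(list(rate = rate, lifetime = lifetime, p_label = p_label,
                 pool_size = as.integer(pool_size),
                 lifetime_model = lifetime_model),
            class = "kc_renewal_params")
}

#' KC lifetime from the turnover rate
#'
#' Under steady-state turnover with fixed lifetimes, a pool turning over at
#' `rate` per day is fully replaced in `1/rate` days.
#'
#' @param rate Turnover rate per day, > 0.
#' @return Lifetime tau in days.
#' @examples
#' lifetime_from_rate(0.094)  # 10.64 days
#' @export
lifetime_from_rate <- function(rate) {
  check_scalar(rate, "rate")
  if (rate <= 0) stopf("`rate` must be > 0")
  1 / rate
}

#' Expected unlabeled-KC fraction after a saturating pulse
#'
#' A saturating pulse labels every KC alive at pulse time; a KC lacking
#' label after a chase must have been initiated during the chase. Under
#' the fixed-lifetime model the steady-state age distribution is uniform
#' on `[0, tau]`, so the unlabeled fraction is `min(chase/tau, 1)`; under
#' the exponential-lifetime model it is `1 - exp(-chase/tau)`.
#'
#' @param chase Chase duration in days, >= 0.
#' @param params A [renewal_params()] object.
#' @return Expected fraction of unlabeled (newly formed) KCs.
#' @examples
#' expected_unlabeled_fraction(4, renewal_params())  # about 0.38
#' @export
expected_unlabeled_fraction <- function(chase, params = renewal_params()) {
  stopifnot(inherits(params, "kc_renewal_params"))
  if (any(chase < 0)) stopf("`chase` must be >= 0")
  tau <- params$lifetime
  if (params$lifetime_model == "fixed") pmin(chase / tau, 1)
  else 1 - exp(-chase / tau)
}

#' Expected labeling index after tamoxifen induction
#'
#' A heritable lineage label applied at time 0 marks each KC initiated
#' afterwards with probability `p`. Under the fixed-lifetime model the
#' fraction of the standing pool initiated within the last `t` days is
#' `min(t, tau)/tau`, so `LI(t) = p * min(t, tau)/tau`: the initial slope
#' is `p * r` (the initiation rate scaled by labeling efficiency) and the
#' plateau, reached at the KC lifetime, equals `p`.
#'
#' @param t Days since induction, >= 0 (vectorized).
#' @param params A [renewal_params()] object.
#' @return Expected labeling index in `[0, p]`.
#' @examples
#' expected_li(c(4, 14, 20), renewal_params())
#' @export
expected_li <- function(t, params = renewal_params()) {
  stopifnot(inherits(params, "kc_renewal_params"))
  if (any(t < 0)) stopf("`t` must be >= 0")
  tau <- params$lifetime
  if (params$lifetime_model == "fixed")
    params$p_label * pmin(t, tau) / tau
  else params$p_label * (1 - exp(-t / tau))
}

#' Simulate steady-state KC turnover
#'
#' Stochastic population simulation of the renewal model: the pool starts
#' at steady state (`pool_size` KCs with equilibrium ages), new KCs are
#' initiated as a Poisson stream at rate `rate * pool_size` per day, and
#' each KC lives its (fixed or exponential) lifetime. Post burn-in, the
#' mean pool size fluctuates around `pool_size` and the age distribution
#' is the stationary one.
#'
#' @param params A [renewal_params()] object.
#' @param horizon Simulation length in days; must exceed `burn_in`.
#' @param burn_in Burn-in period in days, at least 3 lifetimes (enforced).
#' @param seed Integer seed or `NULL`.
#' @return Object of class `kc_turnover_sim`: `kcs` (data frame with
#'   `kc_id`, `birth`, `death` in days; the initial cohort has negative
#'   births), `events` (time-ordered initiation/exhaustion log), `params`,
#'   `horizon`, `burn_in`.
#' @examples
#' sim <- simulate_turnover(renewal_params(pool_size = 50), horizon = 60,
#'                          seed = 1)
#' nrow(population_at(sim, 40))
#' @export
simulate_turnover <- function(params = renewal_params(), horizon,
                              burn_in = 3 * params$lifetime, seed = NULL) {
  stopifnot(inherits(params, "kc_renewal_params"))
  check_scalar(horizon, "horizon", lower = 0)
  tau <- params$lifetime
  if (burn_in < 3 * tau)
    stopf("burn_in must be at least 3 lifetimes (%.4g d)", 3 * tau)
  if (horizon <= burn_in)
    stopf("horizon (%.4g d) must exceed the burn-in (%.4g d)", horizon,
          burn_in)
  n0 <- params$pool_size
  with_seed(seed, {
    if (params$lifetime_model == "fixed") {
      age0 <- runif(n0, 0, tau)
      birth0 <- -age0
      death0 <- birth0 + tau
    } else {
      birth0 <- -rexp(n0, rate = 1 / tau)
      death0 <- rexp(n0, rate = 1 / tau)  # memoryless residual lifetime
    }
    n_new <- rpois(1, params$rate * n0 * horizon)
    birth1 <- sort(runif(n_new, 0, horizon))
    death1 <- birth1 + if (params$lifetime_model == "fixed")
      tau else rexp(n_new, rate = 1 / tau)
    kcs <- data.frame(
      kc_id = sprintf("T%06d", seq_len(n0 + n_new)),
      birth = c(birth0, birth1), death = c(death0, death1),
      stringsAsFactors = FALSE)
    ev <- rbind(
      data.frame(time = kcs$birth, event = "initiation", kc_id = kcs$kc_id,
                 stringsAsFactors = FALSE),
      data.frame(time = kcs$death, event = "exhaustion", kc_id = kcs$kc_id,
                 stringsAsFactors = FALSE))
    ev <- ev[ev$time <= horizon, ]
    ev <- ev[order(ev$time), ]
    rownames(ev) <- NULL
    structure(list(kcs = kcs, events = ev, params = params,
                   horizon = horizon, burn_in = burn_in),
              class = "kc_turnover_sim")
  })
}

#' @export
print.kc_turnover_sim <- function(x, ...) {
  cat(sprintf(
    "<kc_turnover_sim: %d KCs over %.4g d (burn-in %.4g d), N = %d>\n",
    nrow(x$kcs), x$horizon, x$burn_in, x$params$pool_size))
  invisible(x)
}

#' Population snapshot of a turnover simulation
#'
#' @param sim A [simulate_turnover()] result.
#' @param t Observation time in days (`0 <= t <= horizon`).
#' @return Data frame of KCs alive at `t` with their ages (`age_days`).
#' @export
population_at <- function(sim, t) {
  stopifnot(inherits(sim, "kc_turnover_sim"))
  check_scalar(t, "t", lower = 0, upper = sim$horizon)
  alive <- sim$kcs$birth <= t & sim$kcs$death > t
  out <- sim$kcs[alive, , drop = FALSE]
  out$age_days <- t - out$birth
  rownames(out) <- NULL
  out
}

#' Simulated BrdU-negative fraction after a saturating pulse
#'
#' Marks every KC alive at each pulse time as labeled and reports the
#' fraction of the population alive `chase` days later that carries no
#' label, i.e. was initiated during the chase. Pulse times must fall after
#' the burn-in; pooling several pulse times just accumulates observations.
#'
#' @param sim A [simulate_turnover()] result.
#' @param pulse_times Vector of pulse times (days), all past the burn-in
#'   and at least `chase` days before the horizon.
#' @param chase Chase duration in days.
#' @return List: `fraction` (pooled unlabeled fraction), `n_obs` (pooled
#'   KC observations), `per_pulse` fractions.
#' @export
brdu_unlabeled_fraction <- function(sim, pulse_times, chase) {
  stopifnot(inherits(sim, "kc_turnover_sim"))
  if (chase < 0) stopf("`chase` must be >= 0")
  if (any(pulse_times < sim$burn_in))
    stopf("pulse times must fall after the burn-in")
  if (any(pulse_times + chase > sim$horizon))
    stopf("chase window exceeds the simulation horizon")
  per <- vapply(pulse_times, function(tp) {
    pop <- population_at(sim, tp + chase)
    c(sum(pop$birth > tp), nrow(pop))
  }, numeric(2))
  unlab <- sum(per[1, ]); tot <- sum(per[2, ])
  list(fraction = unlab / tot, n_obs = tot,
       per_pulse = per[1, ] / per[2, ])
}

#' Simulated labeling index under lineage labeling
#'
#' Applies a heritable lineage label at `tam_time` (each KC initiated
#' afterwards is labeled with probability `p`) and evaluates the labeled
#' fraction of the standing pool at the requested observation times.
#'
#' @param sim A [simulate_turnover()] result.
#' @param tam_time Induction time (days), past the burn-in.
#' @param times Observation times (days since start), all within horizon.
#' @param p Per-lineage labeling probability; default the simulation's
#'   `p_label`.
#' @param seed Integer seed or `NULL` (labeling draws).
#' @return Data frame with `t_days` (days since induction) and `li`.
#' @export
simulated_li <- function(sim, tam_time, times, p = sim$params$p_label,
                         seed = NULL) {
  stopifnot(inherits(sim, "kc_turnover_sim"))
  check_prob(p, "p")
  if (tam_time < sim$burn_in) stopf("`tam_time` must fall after the burn-in")
  if (any(times < tam_time) || any(times > sim$horizon))
    stopf("observation times must lie in [tam_time, horizon]")
  with_seed(seed, {
    labeled <- sim$kcs$birth > tam_time & runif(nrow(sim$kcs)) < p
    li <- vapply(times, function(t) {
      alive <- sim$kcs$birth <= t & sim$kcs$death > t
      mean(labeled[alive])
    }, numeric(1))
    data.frame(t_days = times - tam_time, li = li)
  })
}

#' Fit a hinge labeling-index curve
#'
#' Least-squares fit of the saturating labeling-index model
#' `LI(t) = s * min(t, b)`: linear rise through the origin with slope `s`
#' (initiation rate times labeling probability) up to a breakpoint `b`
#' (the KC lifetime), then a plateau `s * b`. The breakpoint is profiled
#' over a grid (0.25-day step by default); standard errors come from a
#' nonparametric bootstrap over observations.
#'
#' @param times Days since induction (>= 3 distinct values).
#' @param li Observed labeling indices in `[0, 1]`, same length.
#' @param b_grid Breakpoint grid (days); default 0.25-day steps spanning
#'   the data.
#' @param n_boot Bootstrap resamples for standard errors (default 999; 0
#'   skips the bootstrap).
#' @param seed Integer seed or `NULL`.
#' @return Object of class `kc_li_fit`: `slope`, `breakpoint`, `plateau`,
#'   `se` (named vector, `NA` if `n_boot = 0`), `plateau_identifiable`
#'   (`FALSE` when the best breakpoint is at or beyond the last
#'   observation, i.e. all points lie on the rising limb), `fitted`,
#'   `rss`.
#' @examples
#' fit <- fit_li_curve(c(0, 4, 14, 20, 28),
#'                     c(0, 0.094, 0.335, 0.361, 0.361), n_boot = 0)
#' fit$breakpoint
#' @export
fit_li_curve <- function(times, li, b_grid = NULL, n_boot = 999,
                         seed = NULL) {
  if (length(times) != length(li)) stopf("`times` and `li` lengths differ")
  keep <- complete.cases(times, li)
  times <- times[keep]; li <- li[keep]
  if (length(unique(times)) < 3L)
    stopf("need at least 3 distinct time points")
  if (any(li < 0 | li > 1)) stopf("labeling indices must lie in [0, 1]")
  if (is.null(b_grid))
    b_grid <- seq(0.25, max(times), by = 0.25)
  fit_once <- function(tt, yy) {
    best <- c(rss = Inf, slope = NA, b = NA)
    for (b in b_grid) {
      m <- pmin(tt, b)
      sm2 <- sum(m^2)
      if (sm2 == 0) next
      s <- sum(yy * m) / sm2
      rss <- sum((yy - s * m)^2)
      if (rss < best["rss"] - 1e-12) best <- c(rss = rss, slope = s, b = b)
    }
    best
  }
  est <- fit_once(times, li)
  slope <- est[["slope"]]; b <- est[["b"]]
  identifiable <- b < max(times) - 1e-9
  se <- c(slope = NA_real_, breakpoint = NA_real_, plateau = NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        ix <- sample.int(length(times), replace = TRUE)
        if (length(unique(times[ix])) < 3L) return(c(NA, NA, NA))
        e <- fit_once(times[ix], li[ix])
        c(e[["slope"]], e[["b"]], e[["slope"]] * e[["b"]])
      }, numeric(3))
    })
    se <- c(slope = sd(boots[1, ], na.rm = TRUE),
            breakpoint = sd(boots[2, ], na.rm = TRUE),
            plateau = sd(boots[3, ], na.rm = TRUE))
  }
  structure(list(slope = slope, breakpoint = b, plateau = slope * b,
                 se = se, plateau_identifiable = identifiable,
                 fitted = slope * pmin(times, b), times = times, li = li,
                 rss = est[["rss"]], b_grid = b_grid),
            class = "kc_li_fit")
}

#' @export
print.kc_li_fit <- function(x, ...) {
  cat(sprintf(
    "<kc_li_fit: slope %.4g/d, breakpoint %.4g d, plateau %.4g%s>\n",
    x$slope, x$breakpoint, x$plateau,
    if (x$plateau_identifiable) "" else " (plateau unidentifiable)"))
  invisible(x)
}

#' Astrocyte activation rate from the KC/AS ratio
#'
#' The standing KC pool integrates astrocyte activation events over one KC
#' lifetime, so the per-day activation rate per astrocyte is the KC/AS
#' ratio divided by the lifetime.
#'
#' @param kc_as_ratio KCs per astrocyte, in `[0, 1]`.
#' @param lifetime KC lifetime in days, > 0.
#' @return Activation rate per day (fraction of astrocytes).
#' @examples
#' activation_rate_from_ratio(0.019, 10.64)  # about 0.0018/day
#' @export
activation_rate_from_ratio <- function(kc_as_ratio, lifetime) {
  if (any(kc_as_ratio < 0 | kc_as_ratio > 1))
    stopf("`kc_as_ratio` must lie in [0, 1]")
  check_scalar(lifetime, "lifetime")
  if (lifetime <= 0) stopf("`lifetime` must be > 0")
  kc_as_ratio / lifetime
}
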