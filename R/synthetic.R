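# Synthetic specimens: point-pattern, composition, and labeling generators.
#
# The study's raw 3D reconstructions are unreleased, so analyses are
# exercised on synthetic specimens generated with the statistical structure
# the downstream models assume: KC centroids as spatial point processes,
# KC compositions drawn from a size law calibrated to the printed summary
# statistics, and label states implied by the steady-state renewal model.

#' Generate a 3D point pattern
#'
#' Null and fixture point processes inside an observation region:
#' `"csr"` is complete spatial randomness (the homogeneous Poisson null used
#' for envelope inference), `"clustered"` a Thomas cluster process, and
#' `"inhibited"` a hard-core process produced by dart throwing. The latter
#' two exist to give tests patterns with known departures from CSR.
#'
#' @param region A [region_box()]-style `kc_region`.
#' @param n Number of points. For `"clustered"` with `n = NULL` the count is
#'   Poisson (`n_parents x mu` expected); otherwise exactly `n` points are
#'   produced.
#' @param process `"csr"`, `"clustered"`, or `"inhibited"`.
#' @param process_params List of process parameters: `sigma` (offspring
#'   dispersion, um) and `n_parents` or `kappa` (parent intensity per um^3)
#'   plus `mu` (mean offspring per parent) for `"clustered"`; `hard_core`
#'   (minimum inter-point distance, um) for `"inhibited"`.
#' @param seed Integer seed or `NULL` (use the current RNG stream).
#' @return A [point_pattern()] object.
#' @examples
#' reg <- region_box(upper = c(1000, 1000, 1000))
#' p <- gen_point_pattern(reg, 100, "csr", seed = 1)
#' @export
gen_point_pattern <- function(region, n = NULL,
                              process = c("csr", "clustered", "inhibited"),
                              process_params = list(), seed = NULL) {
  process <- match.arg(process)
  stopifnot(inherits(region, "kc_region"))
  if (!is.null(n)) {
    check_scalar(n, "n", lower = 0)
    n <- as.integer(n)
  } else if (process != "clustered") {
    stopf("`n` is required for process `%s`", process)
  }
  with_seed(seed, {
    pts <- switch(process,
      "csr" = region_sample(region, n),
      "clustered" = thomas_points(region, n, process_params),
      "inhibited" = hardcore_points(region, n, process_params))
    point_pattern(pts, region)
  })
}

thomas_points <- function(region, n, pp) {
  sigma <- pp$sigma %||% 20
  check_scalar(sigma, "sigma", lower = 0)
  n_parents <- pp$n_parents
  if (is.null(n_parents)) {
    if (is.null(pp$kappa))
      stopf("clustered process needs `n_parents` or `kappa` (parent intensity)")
    n_parents <- max(1L, rpois(1, pp$kappa * region_volume(region)))
  }
  parents <- region_sample(region, n_parents)
  if (is.null(n)) {
    mu <- pp$mu
    if (is.null(mu)) stopf("clustered process with `n = NULL` needs `mu`")
    kids <- rpois(n_parents, mu)
    assign_to <- rep(seq_len(n_parents), kids)
  } else {
    assign_to <- sample.int(n_parents, n, replace = TRUE)
  }
  m <- length(assign_to)
  if (m == 0L) return(parents[0, , drop = FALSE])
  pts <- matrix(NA_real_, m, 3)
  for (i in seq_len(m)) {
    for (try in 1:1000) {
      cand <- parents[assign_to[i], ] + rnorm(3, sd = sigma)
      if (region_contains(region, cand)) break
      cand <- NULL
    }
    if (is.null(cand))
      stopf("could not place clustered offspring inside the region")
    pts[i, ] <- cand
  }
  pts
}

hardcore_points <- function(region, n, pp) {
  hc <- pp$hard_core
  if (is.null(hc)) stopf("inhibited process needs `hard_core` (um)")
  check_scalar(hc, "hard_core", lower = 0)
  vol_hc <- 4 / 3 * pi * hc^3
  if (n * vol_hc > region_volume(region))
    stopf(paste0("infeasible hard-core packing: n * exclusion volume ",
                 "(%.3g um^3) exceeds region volume (%.3g um^3)"),
          n * vol_hc, region_volume(region))
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  attempts <- 0L
  max_attempts <- max(10000L, 500L * n)
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- region_sample(region, 1L)
    if (placed > 0L) {
      d2 <- rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2, cand)^2)
      if (min(d2) < hc^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
  }
  if (placed < n)
    stopf("hard-core placement failed after %d attempts (%d/%d placed); %s",
          attempts, placed, n, "the packing is too dense for dart throwing")
  pts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' KC composition parameters
#'
#' Parameters of the synthetic KC composition law. Defaults reproduce the
#' printed population summaries: sizes 4-38 cells with mean 11.8 and SD 7.6,
#' about half of KCs pure (TAPs-only or prNBs-only), pmNB association rising
#' with maturity, and a dormant astrocyte clustered with ~75% of KCs.
#'
#' The marginal size distribution is an integer-rounded truncated law on
#' `size_range`, calibrated at construction so that its exact discrete mean
#' and SD match `mean_size`/`sd_size` as closely as the family allows. The
#' default family is a truncated gamma, which matches both printed moments
#' essentially exactly; a truncated normal is available but, with the mean
#' held at 11.8, cannot reach an SD of 7.6 on [4, 38] (it saturates near
#' 6.9), so it is calibrated mean-first.
#'
#' @param mean_size,sd_size Target mean and SD of KC size (cells).
#' @param size_range Integer range `c(min, max)` of KC sizes; `min >= 4`
#'   (the KC definition).
#' @param type_weights Mixture weights for `taps_only`, `mixed`,
#'   `prnbs_only` KC types; must sum to 1. The printed data say about half
#'   of KCs are pure but not how the pure half splits; the default splits
#'   it evenly.
#' @param pmnb_coef Length-3 logistic coefficients `(intercept, prNB
#'   fraction, centred size)` for the probability that a KC has associated
#'   postmitotic neuroblasts.
#' @param dormant_prob Probability that a KC includes at least one dormant
#'   (Ki67- DCX-) clonally related astrocyte.
#' @param second_dormant_prob Probability of a second dormant cell, given
#'   at least one.
#' @param size_law `"tgamma"` (default) or `"tnorm"`.
#' @return An object of class `kc_composition_params` (a list, including the
#'   calibrated discrete size distribution in `$size_dist`).
#' @examples
#' cp <- composition_params()
#' sum(cp$size_dist$prob * cp$size_dist$size)  # ~11.8
#' @export
composition_params <- function(mean_size = 11.8, sd_size = 7.6,
                               size_range = c(4, 38),
                               type_weights = c(taps_only = 0.25, mixed = 0.5,
                                                prnbs_only = 0.25),
                               pmnb_coef = c(-2.2, 3.2, 0.05),
                               dormant_prob = 0.75,
                               second_dormant_prob = 0.1,
                               size_law = c("tgamma", "tnorm")) {
  size_law <- match.arg(size_law)
  check_scalar(mean_size, "mean_size", lower = 0)
  check_scalar(sd_size, "sd_size", lower = 0)
  if (sd_size <= 0) stopf("`sd_size` must be > 0")
  size_range <- as.integer(size_range)
  if (length(size_range) != 2L || size_range[1] < 4L)
    stopf("`size_range` must be c(min, max) with min >= 4 (KC definition)")
  if (size_range[2] <= size_range[1]) stopf("empty `size_range`")
  if (length(type_weights) != 3L || any(type_weights < 0))
    stopf("`type_weights` must be 3 nonnegative weights")
  if (abs(sum(type_weights) - 1) > 1e-8)
    stopf("`type_weights` must sum to 1 (got %.6f)", sum(type_weights))
  names(type_weights) <- c("taps_only", "mixed", "prnbs_only")
  check_prob(dormant_prob, "dormant_prob")
  check_prob(second_dormant_prob, "second_dormant_prob")
  if (length(pmnb_coef) != 3L) stopf("`pmnb_coef` must have length 3")
  sd_ <- calibrate_size_law(mean_size, sd_size, size_range, size_law)
  structure(list(mean_size = mean_size, sd_size = sd_size,
                 size_range = size_range, type_weights = type_weights,
                 pmnb_coef = pmnb_coef, dormant_prob = dormant_prob,
                 second_dormant_prob = second_dormant_prob,
                 size_law = size_law, size_dist = sd_),
            class = "kc_composition_params")
}

# Exact discrete moments of an integer-rounded truncated law: cell k gets
# the parent-density mass of [k - 0.5, k + 0.5] clipped to the range.
discrete_size_probs <- function(theta, size_range, law) {
  k <- seq(size_range[1], size_range[2])
  lo <- pmax(k - 0.5, size_range[1])
  hi <- pmin(k + 0.5, size_range[2])
  p <- switch(law,
    tgamma = pgamma(hi, theta[1], theta[2]) - pgamma(lo, theta[1], theta[2]),
    tnorm = pnorm(hi, theta[1], theta[2]) - pnorm(lo, theta[1], theta[2]))
  s <- sum(p)
  if (!is.finite(s) || s <= 0) return(NULL)
  data.frame(size = k, prob = p / s)
}

calibrate_size_law <- function(mean_size, sd_size, size_range, law) {
  target <- c(mean_size, sd_size)
  moments <- function(theta) {
    d <- discrete_size_probs(theta, size_range, law)
    if (is.null(d)) return(c(NA, NA))
    m <- sum(d$size * d$prob)
    c(m, sqrt(sum((d$size - m)^2 * d$prob)))
  }
  # mean is weighted heavier: it is the quantity the family may not be able
  # to trade off against the SD (relevant for the truncated normal).
  obj <- function(th) {
    mm <- moments(exp(th))
    if (anyNA(mm)) return(1e9)
    25 * (mm[1] - target[1])^2 + (mm[2] - target[2])^2
  }
  start <- switch(law,
    tgamma = log(c((mean_size / sd_size)^2, mean_size / sd_size^2)),
    tnorm = log(c(mean_size, sd_size)))
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  theta <- exp(fit$par)
  d <- discrete_size_probs(theta, size_range, law)
  attr(d, "theta") <- theta
  attr(d, "achieved") <- moments(theta)
  d
}

#' Generate synthetic KC compositions
#'
#' Draws a table of KC records: size from the calibrated integer size law,
#' type from the mixture (pure TAPs, mixed, pure prNBs), TAP/prNB split
#' consistent with the type, pmNB association from a logistic law in prNB
#' fraction and size, and a dormant-astrocyte count.
#'
#' @param n_kc Number of KCs.
#' @param params A [composition_params()] object.
#' @param seed Integer seed or `NULL`.
#' @return Data frame with columns `kc_id`, `size`, `n_tap`, `n_prnb`,
#'   `prnb_frac`, `kc_type`, `pmnb_assoc`, `n_dormant`.
#' @examples
#' kcs <- gen_kc_composition(100, seed = 1)
#' mean(kcs$size)
#' @export
gen_kc_composition <- function(n_kc, params = composition_params(),
                               seed = NULL) {
  stopifnot(inherits(params, "kc_composition_params"))
  check_scalar(n_kc, "n_kc", lower = 0)
  n_kc <- as.integer(n_kc)
  with_seed(seed, {
    if (n_kc == 0L) return(empty_kc_table())
    size <- sample(params$size_dist$size, n_kc, replace = TRUE,
                   prob = params$size_dist$prob)
    type <- sample(names(params$type_weights), n_kc, replace = TRUE,
                   prob = params$type_weights)
    n_prnb <- integer(n_kc)
    n_prnb[type == "prnbs_only"] <- size[type == "prnbs_only"]
    mx <- which(type == "mixed")
    if (length(mx)) {
      frac <- runif(length(mx))
      n_prnb[mx] <- pmin(pmax(round(frac * size[mx]), 1L), size[mx] - 1L)
    }
    finalize_kc_table(size, n_prnb, params)
  })
}

finalize_kc_table <- function(size, n_prnb, params) {
  n_kc <- length(size)
  n_tap <- size - n_prnb
  frac <- n_prnb / size
  p_pmnb <- stats::plogis(params$pmnb_coef[1] + params$pmnb_coef[2] * frac +
                          params$pmnb_coef[3] * (size - params$mean_size))
  pmnb <- runif(n_kc) < p_pmnb
  dorm <- as.integer(runif(n_kc) < params$dormant_prob)
  dorm <- dorm + as.integer(dorm > 0 & runif(n_kc) < params$second_dormant_prob)
  data.frame(kc_id = sprintf("K%04d", seq_len(n_kc)), size = as.integer(size),
             n_tap = as.integer(n_tap), n_prnb = as.integer(n_prnb),
             prnb_frac = frac, kc_type = classify_kc(n_tap, n_prnb),
             pmnb_assoc = pmnb, n_dormant = dorm,
             stringsAsFactors = FALSE)
}

empty_kc_table <- function() {
  data.frame(kc_id = character(0), size = integer(0), n_tap = integer(0),
             n_prnb = integer(0), prnb_frac = numeric(0),
             kc_type = character(0), pmnb_assoc = logical(0),
             n_dormant = integer(0), stringsAsFactors = FALSE)
}

#' Labeling experiment designs
#'
#' Describes how a labeling experiment marks KC lineages or cells:
#' `"brdu-pulse"` is a saturating thymidine-analog pulse that labels each
#' cell of every KC alive at pulse time independently with probability
#' `p_cell`, followed by a chase; `"tam-yfp"` and `"tam-confetti"` are
#' tamoxifen-induced heritable reporters that label the founding lineage of
#' KCs initiated after induction (with probability `p_lineage` for the
#' single-color reporter, or with a color drawn from `color_probs` for the
#' multicolor one).
#'
#' @param modality `"brdu-pulse"`, `"tam-confetti"`, or `"tam-yfp"`.
#' @param p_cell Per-cell labeling probability for the pulse modality
#'   (default 0.74, the printed saturating per-cell index).
#' @param p_lineage Per-lineage labeling probability for `"tam-yfp"`
#'   (default 0.361, the printed labeling-index plateau).
#' @param color_probs Named per-lineage color probabilities for
#'   `"tam-confetti"`; defaults are the printed recombination fractions
#'   (RFP 2.4%, mCFP 1.2%, cYFP 1.7%). Must sum to at most 1; the
#'   remainder is unlabeled.
#' @param chase Days between pulse and sacrifice (pulse modality).
#' @param interval Days between tamoxifen and sacrifice (tam modalities).
#' @param recomb_stage_probs Probabilities that recombination in a labeled
#'   lineage happened at the 1-, 2-, or 3-cell stage (labeled cell fraction
#'   about 1, 1/2, 1/3), reflecting the observed partially labeled KCs.
#' @return An object of class `kc_label_design`.
#' @export
label_design <- function(modality = c("brdu-pulse", "tam-confetti", "tam-yfp"),
                         p_cell = 0.74, p_lineage = 0.361,
                         color_probs = c(rfp = 0.024, mcfp = 0.012,
                                         cyfp = 0.017),
                         chase = 4, interval = 20,
                         recomb_stage_probs = c(0.5, 0.3, 0.2)) {
  modality <- match.arg(modality)
  check_prob(p_cell, "p_cell")
  check_prob(p_lineage, "p_lineage")
  if (any(color_probs < 0) || any(color_probs > 1) || sum(color_probs) > 1)
    stopf("`color_probs` must be in [0,1] and sum to <= 1")
  if (is.null(names(color_probs)) || any(!nzchar(names(color_probs))))
    stopf("`color_probs` must be named by color")
  if (chase < 0) stopf("negative `chase` (days)")
  if (interval < 0) stopf("negative `interval` (days)")
  if (length(recomb_stage_probs) != 3L || any(recomb_stage_probs < 0))
    stopf("`recomb_stage_probs` must be 3 nonnegative probabilities")
  recomb_stage_probs <- recomb_stage_probs / sum(recomb_stage_probs)
  structure(list(modality = modality, p_cell = p_cell, p_lineage = p_lineage,
                 color_probs = color_probs, chase = chase, interval = interval,
                 recomb_stage_probs = recomb_stage_probs),
            class = "kc_label_design")
}

#' Generate a labeled KC population under steady-state turnover
#'
#' Draws KC ages from the steady-state age distribution of the renewal
#' model (uniform on `[0, tau]` for the fixed-lifetime model), advances the
#' maturation profile with age (expected prNB fraction grows linearly from
#' 0 to 1 over the lifetime), and assigns label states implied by the
#' design: KCs initiated after a pulse carry no pulse label, KCs initiated
#' after tamoxifen carry the heritable reporter with the design's lineage
#' probability.
#'
#' @param renewal A [renewal_params()] object.
#' @param design A [label_design()] object.
#' @param comp A [composition_params()] object.
#' @param n_kc Number of KCs.
#' @param seed Integer seed or `NULL`.
#' @return Data frame: the [gen_kc_composition()] columns plus `age_days`,
#'   `label` (`"none"`, `"brdu"`, `"yfp"`, or a Confetti color) and
#'   `n_labeled` (labeled member cells).
#' @examples
#' rp <- renewal_params()
#' des <- label_design("tam-yfp", interval = 20)
#' pop <- gen_labeled_population(rp, des, n_kc = 500, seed = 1)
#' mean(pop$n_labeled > 0)  # about the printed 36% plateau
#' @export
gen_labeled_population <- function(renewal, design,
                                   comp = composition_params(),
                                   n_kc = 288, seed = NULL) {
  stopifnot(inherits(renewal, "kc_renewal_params"),
            inherits(design, "kc_label_design"),
            inherits(comp, "kc_composition_params"))
  check_scalar(n_kc, "n_kc", lower = 0)
  n_kc <- as.integer(n_kc)
  with_seed(seed, {
    if (n_kc == 0L) {
      out <- empty_kc_table()
      out$age_days <- numeric(0); out$label <- character(0)
      out$n_labeled <- integer(0)
      return(out)
    }
    tau <- renewal$lifetime
    age <- if (renewal$lifetime_model == "fixed") runif(n_kc, 0, tau)
           else rexp(n_kc, rate = 1 / tau)
    size <- sample(comp$size_dist$size, n_kc, replace = TRUE,
                   prob = comp$size_dist$prob)
    # maturation advances with age: expected prNB fraction = age / tau
    n_prnb <- rbinom(n_kc, size, pmin(age / tau, 1))
    out <- finalize_kc_table(size, n_prnb, comp)
    out$age_days <- age
    lab <- assign_labels(design, age, size)
    out$label <- lab$label
    out$n_labeled <- lab$n_labeled
    out
  })
}

assign_labels <- function(design, age, size) {
  n <- length(age)
  label <- rep("none", n)
  n_labeled <- integer(n)
  if (design$modality == "brdu-pulse") {
    # a KC younger than the chase was initiated after the pulse: unlabeled
    old <- age >= design$chase
    n_labeled[old] <- rbinom(sum(old), size[old], design$p_cell)
    label[old & n_labeled > 0] <- "brdu"
    n_labeled[!old | n_labeled == 0] <- 0L
  } else {
    # heritable lineage label: only KCs initiated after TAM can carry it
    eligible <- age <= design$interval
    if (design$modality == "tam-yfp") {
      hit <- eligible & runif(n) < design$p_lineage
      label[hit] <- "yfp"
    } else {
      probs <- design$color_probs
      u <- runif(n)
      cum <- cumsum(probs)
      col_idx <- findInterval(u, c(0, cum), rightmost.closed = FALSE)
      hit <- eligible & u < sum(probs)
      label[hit] <- names(probs)[col_idx[hit]]
    }
    if (any(hit <- label != "none")) {
      stage <- sample.int(3L, sum(hit), replace = TRUE,
                          prob = design$recomb_stage_probs)
      n_labeled[hit] <- pmax(1L, rbinom(sum(hit), size[hit], 1 / stage))
    }
  }
  list(label = label, n_labeled = as.integer(n_labeled))
}

#' Specimen configuration
#'
#' Bundles everything [gen_specimen()] needs: KC count, observation region,
#' composition parameters, optional renewal/label design for labeled
#' specimens, and the geometric constants used to lay member cells out
#' around each KC centroid.
#'
#' @param n_kc Number of KCs (default 288, the printed per-specimen mean).
#' @param region Observation region; default a 1200-um box sized so the
#'   default KC count gives realistic nearest-neighbor distances.
#' @param comp A [composition_params()].
#' @param renewal Optional [renewal_params()] (needed with `design`).
#' @param design Optional [label_design()].
#' @param contact_radius Cell-contact distance (um) used both to place
#'   member cells and, downstream, to detect KCs; default 12 um, about a
#'   soma diameter.
#' @param kc_radius Maximum radius (um) of the ball holding one KC's cells.
#' @param hard_core Minimum centroid separation (um); the default
#'   `2 * kc_radius + contact_radius + 2` guarantees KCs cannot merge.
#' @param specimen_id Identifier written into the cell table.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `kc_specimen_config`.
#' @export
specimen_config <- function(n_kc = 288,
                            region = region_box(upper = c(1200, 1200, 1200)),
                            comp = composition_params(),
                            renewal = NULL, design = NULL,
                            contact_radius = 12, kc_radius = 20,
                            hard_core = 2 * kc_radius + contact_radius + 2,
                            specimen_id = "S1", seed = NULL) {
  check_scalar(n_kc, "n_kc", lower = 0)
  check_scalar(contact_radius, "contact_radius", lower = 0)
  check_scalar(kc_radius, "kc_radius", lower = 0)
  check_scalar(hard_core, "hard_core", lower = 0)
  if (!is.null(design) && is.null(renewal))
    stopf("a label `design` requires `renewal` parameters (KC ages)")
  structure(list(n_kc = as.integer(n_kc), region = region, comp = comp,
                 renewal = renewal, design = design,
                 contact_radius = contact_radius, kc_radius = kc_radius,
                 hard_core = hard_core, specimen_id = specimen_id,
                 seed = seed),
            class = "kc_specimen_config")
}

#' Generate a full synthetic specimen
#'
#' Composes the generators into one specimen bundle mirroring a
#' reconstructed tissue block: KC centroids from a hard-core point process
#' (so clusters never touch), member cells grown in a contact-connected
#' ball around each centroid (so [detect_kcs()] recovers the emitted KC
#' table exactly), plus dormant astrocytes and associated postmitotic
#' neuroblasts where the composition says so.
#'
#' @param config A [specimen_config()].
#' @return A list of class `kc_specimen`: `cells` (canonical cell table),
#'   `kcs` (KC table with centroids), `pattern` (centroid
#'   [point_pattern()]), `region`, `config`, and `meta` (seed, schema
#'   version, warnings).
#' @examples
#' sp <- gen_specimen(specimen_config(n_kc = 20, seed = 1))
#' nrow(sp$kcs)
#' @export
gen_specimen <- function(config = specimen_config()) {
  stopifnot(inherits(config, "kc_specimen_config"))
  warnings <- character(0)
  if (config$hard_core < 2 * config$kc_radius + config$contact_radius) {
    warnings <- c(warnings, paste0(
      "hard_core < 2 * kc_radius + contact_radius: ",
      "adjacent KCs may merge under detection"))
  }
  with_seed(config$seed, {
    kcs <- if (!is.null(config$design)) {
      gen_labeled_population(config$renewal, config$design, config$comp,
                             config$n_kc)
    } else {
      k <- gen_kc_composition(config$n_kc, config$comp)
      k$age_days <- NA_real_; k$label <- "none"; k$n_labeled <- 0L
      k
    }
    # erode a box region by kc_radius so cell balls stay inside
    place_region <- config$region
    if (place_region$kind == "box" &&
        all(place_region$upper - place_region$lower >
            2 * config$kc_radius + 1)) {
      place_region <- region_box(place_region$lower + config$kc_radius,
                                 place_region$upper - config$kc_radius)
    }
    pat <- gen_point_pattern(place_region, config$n_kc, "inhibited",
                             list(hard_core = config$hard_core))
    pat <- point_pattern(pat$points, config$region)
    kcs$x <- pat$points[, 1]; kcs$y <- pat$points[, 2]
    kcs$z <- pat$points[, 3]
    cells <- build_specimen_cells(kcs, config)
    list_out <- list(cells = cells, kcs = kcs, pattern = pat,
                     region = config$region, config = config,
                     meta = list(seed = config$seed,
                                 schema_version = kcdyn_schema_version(),
                                 warnings = warnings))
    class(list_out) <- "kc_specimen"
    list_out
  })
}

# Grow one KC's member cells: every new cell sits within a fraction of the
# contact radius of an already placed cell, inside a ball of kc_radius, so
# the contact graph at contact_radius is connected by construction.
grow_cluster <- function(centroid, m, contact_radius, kc_radius) {
  pts <- matrix(NA_real_, m, 3)
  pts[1, ] <- centroid
  if (m == 1L) return(pts)
  for (i in 2:m) {
    ok <- FALSE
    for (try in 1:100) {
      base <- pts[sample.int(i - 1L, 1L), ]
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      cand <- base + runif(1, 0.35, 0.6) * contact_radius * dir
      if (sum((cand - centroid)^2) <= kc_radius^2) { ok <- TRUE; break }
    }
    if (!ok)
      cand <- centroid + runif(3, -1, 1) * min(kc_radius, contact_radius) / 4
    pts[i, ] <- cand
  }
  pts
}

build_specimen_cells <- function(kcs, config) {
  rows <- vector("list", nrow(kcs))
  for (i in seq_len(nrow(kcs))) {
    kc <- kcs[i, ]
    centroid <- c(kc$x, kc$y, kc$z)
    n_pmnb <- if (isTRUE(kc$pmnb_assoc)) 1L + rpois(1, 0.5) else 0L
    m <- kc$size + kc$n_dormant + n_pmnb
    pts <- grow_cluster(centroid, m, config$contact_radius, config$kc_radius)
    ki67 <- c(rep(TRUE, kc$size), rep(FALSE, m - kc$size))
    dcx <- c(rep(FALSE, kc$n_tap), rep(TRUE, kc$n_prnb),
             rep(FALSE, kc$n_dormant), rep(TRUE, n_pmnb))
    sox9 <- c(rep("neg", kc$size), rep("high", kc$n_dormant),
              rep("neg", n_pmnb))
    brdu <- rep(FALSE, m)
    reporter <- rep("none", m)
    if (kc$n_labeled > 0) {
      lab_idx <- sample.int(kc$size, kc$n_labeled)
      if (kc$label == "brdu") brdu[lab_idx] <- TRUE
      else reporter[lab_idx] <- kc$label
    }
    rows[[i]] <- data.frame(
      specimen_id = config$specimen_id,
      cell_id = sprintf("%s_c%d", kc$kc_id, seq_len(m)),
      x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
      ki67 = ki67, dcx = dcx, sox9 = sox9, brdu = brdu,
      reporter = reporter, kc_id = kc$kc_id, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

kcdyn_schema_version <- function() "1.0"

#' @export
print.kc_specimen <- function(x, ...) {
  cat(sprintf("<kc_specimen %s: %d KCs, %d cells, %s region>\n",
              x$config$specimen_id, nrow(x$kcs), nrow(x$cells),
              x$region$kind))
  invisible(x)
}
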