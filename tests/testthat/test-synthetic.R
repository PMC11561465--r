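# Synthetic-data generators: point processes, composition law, labeling.

test_that("regions report volumes and membership correctly", {
  box <- region_box(upper = c(100, 200, 50))
  expect_equal(region_volume(box), 100 * 200 * 50)
  shell <- region_shell(center = c(0, 0, 0), r_inner = 50, r_outer = 100)
  expect_equal(region_volume(shell), 4 / 3 * pi * (100^3 - 50^3))
  expect_true(region_contains(shell, c(75, 0, 0)))
  expect_false(region_contains(shell, c(10, 0, 0)))
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, , ] <- TRUE
  vox <- region_voxels(mask, spacing = c(10, 10, 10))
  expect_equal(region_volume(vox), 32 * 1000)
  expect_true(region_contains(vox, c(5, 5, 5)))
  expect_false(region_contains(vox, c(35, 5, 5)))
  expect_error(region_box(c(0, 0, 0), c(0, 1, 1)), "positive extent")
  expect_error(region_voxels(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "empty")
})

test_that("CSR generator: empty case, seed determinism, containment", {
  box <- region_box(upper = c(1000, 1000, 1000))
  expect_equal(gen_point_pattern(box, 0, "csr", seed = 1)$n, 0L)
  a <- gen_point_pattern(box, 500, "csr", seed = 1)
  b <- gen_point_pattern(box, 500, "csr", seed = 1)
  expect_identical(a$points, b$points)
  for (reg in list(box, region_shell(c(500, 500, 500), 100, 400),
                   region_voxels(array(TRUE, c(5, 5, 5)), c(50, 50, 50)))) {
    p <- gen_point_pattern(reg, 300, "csr", seed = 2)
    expect_true(all(region_contains(reg, p$points)))
  }
})

test_that("CSR nearest-neighbor distances follow the Poisson closed form", {
  box <- region_box(upper = c(1000, 1000, 1000))
  pat <- gen_point_pattern(box, 2000, "csr", seed = 11)
  nn <- nn_distances(pat)$distances
  lambda <- 2000 / 1e9
  r <- seq(0, 50, by = 0.5)
  emp <- vapply(r, function(x) mean(nn <= x), numeric(1))
  theo <- 1 - exp(-lambda * 4 / 3 * pi * r^3)
  expect_lt(max(abs(emp - theo)), 0.05)
})

test_that("clustered and inhibited fixtures respect their definitions", {
  box <- region_box(upper = c(500, 500, 500))
  th <- gen_point_pattern(box, 200, "clustered",
                          list(n_parents = 8, sigma = 10), seed = 3)
  expect_equal(th$n, 200L)
  expect_true(all(region_contains(box, th$points)))
  # tight Thomas offspring cluster more than CSR: smaller mean NN distance
  csr <- gen_point_pattern(box, 200, "csr", seed = 3)
  expect_lt(nn_distances(th)$mean, nn_distances(csr)$mean)
  hc <- gen_point_pattern(box, 100, "inhibited", list(hard_core = 40),
                          seed = 4)
  d <- dist(hc$points)
  expect_gte(min(d), 40)
  expect_error(
    gen_point_pattern(box, 1e5, "inhibited", list(hard_core = 40)),
    "infeasible")
  expect_error(gen_point_pattern(box, 10, "inhibited"), "hard_core")
})

test_that("composition generator reproduces the printed size summaries", {
  kcs <- gen_kc_composition(10000, seed = 7)
  expect_lt(abs(mean(kcs$size) - 11.8), 0.3)
  expect_lt(abs(sd(kcs$size) - 7.6), 0.3)
  expect_true(all(kcs$size >= 4 & kcs$size <= 38))
  expect_true(all(kcs$size == kcs$n_tap + kcs$n_prnb))
  # about half of KCs are pure
  pure <- mean(kcs$kc_type %in% c("TAPs-only", "prNBs-only"))
  expect_lt(abs(pure - 0.5), 0.03)
  # dormant astrocyte in ~75% of KCs
  expect_lt(abs(mean(kcs$n_dormant > 0) - 0.75), 0.03)
  # pmNB association rises with maturity
  expect_gt(mean(kcs$pmnb_assoc[kcs$prnb_frac > 0.8]),
            mean(kcs$pmnb_assoc[kcs$prnb_frac < 0.2]))
})

test_that("forced composition types and invalid weights behave", {
  one <- gen_kc_composition(1, composition_params(
    type_weights = c(1, 0, 0)), seed = 1)
  expect_equal(one$n_prnb, 0L)
  expect_equal(one$kc_type, "TAPs-only")
  expect_error(composition_params(type_weights = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(composition_params(size_range = c(2, 38)), ">= 4")
  expect_equal(nrow(gen_kc_composition(0)), 0L)
})

test_that("label generator matches the renewal closed forms", {
  rp <- renewal_params()
  # unlabeled fraction after a chase = chase / tau (fixed-lifetime model)
  pop <- gen_labeled_population(rp, label_design("brdu-pulse", chase = 4),
                                n_kc = 10000, seed = 1)
  expect_lt(abs(mean(pop$label == "none") - 4 / rp$lifetime), 0.02)
  # saturating label with no turnover window labels everything
  pop2 <- gen_labeled_population(
    rp, label_design("brdu-pulse", p_cell = 1, chase = 0), n_kc = 300,
    seed = 1)
  expect_true(all(pop2$n_labeled == pop2$size))
  # lineage label plateau: interval >= tau gives labeled fraction ~ p
  pop3 <- gen_labeled_population(rp, label_design("tam-yfp", interval = 20),
                                 n_kc = 10000, seed = 2)
  expect_lt(abs(mean(pop3$label == "yfp") - 0.361), 0.02)
  expect_error(label_design("brdu-pulse", chase = -1), "negative")
  expect_error(label_design("tam-yfp", interval = -2), "negative")
})

test_that("labeled fraction is monotone in the tracing interval", {
  rp <- renewal_params()
  fracs <- vapply(c(0.5, 2, 5, 9, 12, 20), function(iv) {
    pop <- gen_labeled_population(rp, label_design("tam-yfp", interval = iv),
                                  n_kc = 6000, seed = 42)
    mean(pop$label == "yfp")
  }, numeric(1))
  expect_true(all(diff(fracs) > -0.02))  # nondecreasing up to MC noise
  expect_lt(fracs[1], 0.05)              # interval -> 0 gives fraction -> 0
  expect_lt(abs(fracs[6] - 0.361), 0.03) # interval >= tau saturates at p
  # maturation advances with age: young KCs are TAP-rich
  pop <- gen_labeled_population(rp, label_design("tam-yfp"), n_kc = 5000,
                                seed = 3)
  young <- pop$prnb_frac[pop$age_days < 3]
  old <- pop$prnb_frac[pop$age_days > 8]
  expect_gt(mean(old), mean(young) + 0.3)
})

test_that("specimen round-trips through detection", {
  cfg <- specimen_config(n_kc = 40, seed = 3)
  sp <- gen_specimen(cfg)
  det <- detect_kcs(sp$cells, cfg$contact_radius)
  expect_equal(nrow(det$kcs), nrow(sp$kcs))
  expect_equal(nrow(det$small_groups), 0L)
  # membership-level identity: each detected KC is exactly one emitted KC
  map <- match_detected_to_true(sp$cells, det)
  kc_map <- map[grepl("^KC", names(map))]
  expect_false(anyNA(kc_map))
  expect_equal(sort(unname(kc_map)), sort(sp$kcs$kc_id))
  for (i in seq_len(nrow(det$kcs))) {
    truth <- sp$kcs[sp$kcs$kc_id == kc_map[det$kcs$kc_id[i]], ]
    expect_equal(det$kcs$n_tap[i], truth$n_tap)
    expect_equal(det$kcs$n_prnb[i], truth$n_prnb)
    expect_equal(det$kcs$n_dormant[i], truth$n_dormant)
    expect_equal(det$kcs$pmnb_assoc[i], truth$pmnb_assoc)
  }
})

test_that("specimen generator honors the configured KC count and seed", {
  sp <- gen_specimen(specimen_config(n_kc = 288, seed = 5))
  expect_equal(nrow(sp$kcs), 288L)
  a <- gen_specimen(specimen_config(n_kc = 15, seed = 1))
  b <- gen_specimen(specimen_config(n_kc = 15, seed = 2))
  expect_false(isTRUE(all.equal(a$cells$x_um, b$cells$x_um)))
  expect_identical(names(a$cells), names(b$cells))
  # purity: same config, same seed, same output
  a2 <- gen_specimen(specimen_config(n_kc = 15, seed = 1))
  expect_identical(a$cells, a2$cells)
  # inconsistent geometry is surfaced in the bundle metadata
  sp_w <- gen_specimen(specimen_config(n_kc = 5, seed = 1, hard_core = 20))
  expect_match(sp_w$meta$warnings, "merge")
})
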