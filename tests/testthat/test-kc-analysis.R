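# KC detection, classification and per-specimen summaries.

test_that("KC definition: at least 4 proliferating cells in contact", {
  # 3 mutually touching Ki67+ cells are a trio, not a KC
  trio <- make_cells(matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0), 3, 3,
                            byrow = TRUE))
  det <- detect_kcs(trio, 12)
  expect_equal(nrow(det$kcs), 0L)
  expect_equal(det$small_groups$kind, "trio")
  # a chain of 5 cells each within radius of the next is one KC (contact
  # is transitive through the component)
  chain <- make_cells(cbind(seq(0, 40, by = 10), 0, 0))
  det2 <- detect_kcs(chain, 12)
  expect_equal(det2$kcs$size, 5L)
  expect_equal(nrow(det2$small_groups), 0L)
  # empty input is fine; non-finite coordinates are not
  det0 <- detect_kcs(make_cells(matrix(numeric(0), 0, 3)), 12)
  expect_equal(nrow(det0$kcs), 0L)
  bad <- make_cells(matrix(c(0, 0, 0, NA, 0, 0), 2, 3, byrow = TRUE))
  expect_error(detect_kcs(bad, 12), "finite")
  expect_error(detect_kcs(chain[, -which(names(chain) == "dcx")], 12),
               "dcx")
})

test_that("detection partition matches brute force and ignores row order", {
  set.seed(81)
  for (rep in 1:15) {
    n <- sample(10:60, 1)
    pts <- matrix(runif(3 * n, 0, 120), n, 3)
    r <- runif(1, 8, 25)
    cells <- make_cells(pts)
    det <- detect_kcs(cells, r)
    oracle <- bf_components(pts, r)
    got <- as.integer(factor(det$assignment,
                             levels = unique(det$assignment)))
    expect_identical(partition_sets(got), partition_sets(oracle))
    # shuffled input rows give the identical partition of the same cells
    perm <- sample.int(n)
    det2 <- detect_kcs(cells[perm, ], r)
    relab <- integer(n); relab[perm] <- seq_len(n)
    sets2 <- lapply(partition_sets(
      as.integer(factor(det2$assignment,
                        levels = unique(det2$assignment)))),
      function(s) sort(perm[s]))
    expect_identical(sets2[order(vapply(sets2, min, integer(1)))],
                     partition_sets(oracle))
  }
})

test_that("every Ki67+ cell lands in exactly one component", {
  sp <- gen_specimen(specimen_config(n_kc = 30, seed = 9))
  det <- detect_kcs(sp$cells, 12)
  ki <- as.logical(sp$cells$ki67)
  expect_true(all(!is.na(det$assignment[ki])))
  expect_true(all(is.na(det$assignment[!ki])))
  expect_equal(sum(det$kcs$size) + sum(det$small_groups$size), sum(ki))
})

test_that("maturation classification uses the stated bin edges", {
  expect_equal(classify_kc(5, 0), "TAPs-only")
  expect_equal(classify_kc(0, 7), "prNBs-only")
  expect_equal(classify_kc(3, 3), "TAPs+prNBs_Med")  # 0.5 in (1/3, 2/3]
  expect_equal(classify_kc(4, 2), "TAPs+prNBs_Low")  # 1/3 boundary -> Low
  expect_equal(classify_kc(2, 4), "TAPs+prNBs_Med")  # 2/3 boundary -> Med
  expect_equal(classify_kc(1, 5), "TAPs+prNBs_High")
  expect_error(classify_kc(2, 1), ">= 4")
  # total on valid KCs: every composition up to size 20 is classifiable
  for (sz in 4:20) {
    types <- classify_kc(sz - 0:sz, 0:sz)
    expect_true(all(nzchar(types)))
  }
})

test_that("labeling index matches hand counts and flags the empty case", {
  # 46 labeled KCs of which 18 fully labeled
  sz <- rep(6L, 60)
  nl <- c(rep(6L, 18), rep(3L, 28), rep(0L, 14))
  li <- labeling_index(data.frame(size = sz, n_labeled = nl))
  expect_equal(li$n_labeled_kcs, 46L)
  expect_equal(li$fully_labeled_frac, 18 / 46)
  expect_equal(li$li, 46 / 60)
  expect_equal(labeling_index(data.frame(size = 5, n_labeled = 0))$li, 0)
  full <- labeling_index(data.frame(size = c(4, 9), n_labeled = c(4, 9)))
  expect_equal(full$li, 1)
  expect_equal(full$fully_labeled_frac, 1)
  empty <- labeling_index(data.frame(size = integer(0),
                                     n_labeled = integer(0)))
  expect_false(empty$defined)
  expect_true(is.na(empty$li))
  expect_error(labeling_index(data.frame(size = 4, n_labeled = 5)),
               "exceed")
})

test_that("labeling index is monotone and id-independent", {
  kcs <- data.frame(size = rep(8L, 20),
                    n_labeled = c(rep(0L, 10), rep(2L, 10)))
  base <- labeling_index(kcs)$li
  kcs2 <- kcs; kcs2$n_labeled[1] <- 3L  # label cells in an unlabeled KC
  expect_gt(labeling_index(kcs2)$li, base)
  kcs3 <- kcs[sample.int(20), ]
  expect_equal(labeling_index(kcs3)$li, base)
})

test_that("clonality summary reproduces the printed worked examples", {
  # 49 labeled KCs: 42 single-color, 7 with non-recombined cells; 1048
  # cells total in labeled KCs, 25 of them colorless
  single_sizes <- rep(21L, 42)                    # 882 cells, fully recombined
  mixed_sizes <- c(24L, 24L, 24L, 24L, 24L, 23L, 23L)  # 166 cells
  none_counts <- c(4L, 4L, 4L, 4L, 3L, 3L, 3L)         # 25 colorless
  cells <- do.call(rbind, c(
    lapply(seq_len(42), function(i)
      data.frame(kc_id = sprintf("s%02d", i),
                 reporter = rep(c("rfp", "mcfp", "cyfp")[1 + i %% 3],
                                single_sizes[i]))),
    lapply(seq_len(7), function(i) {
      rep_col <- rep("rfp", mixed_sizes[i])
      rep_col[seq_len(none_counts[i])] <- "none"
      data.frame(kc_id = sprintf("m%02d", i), reporter = rep_col)
    })))
  cs <- clonality_summary(cells)
  expect_equal(cs$n_labeled, 49L)
  expect_equal(cs$n_single_color, 42L)
  expect_equal(cs$n_mixed, 7L)
  expect_equal(cs$n_cells_labeled_kcs, 1048L)
  expect_equal(cs$n_nonrecombined, 25L)
  expect_equal(round(cs$frac_nonrecombined, 2), 0.02)
  expect_gte(sum(cs$per_color), cs$n_single_color)
  none <- clonality_summary(data.frame(kc_id = "a", reporter = "none"))
  expect_equal(none$n_labeled, 0L)
  expect_equal(none$n_single_color, 0L)
})

test_that("expected same-color counts follow the multinomial mean", {
  probs <- c(rfp = 0.024, mcfp = 0.012, cyfp = 0.017)
  es <- expected_same_color(134, probs, n_sim = 199, seed = 1)
  expect_equal(unname(es$expected), c(3.216, 1.608, 2.278))
  es0 <- expected_same_color(0, probs, n_sim = 199, seed = 1)
  expect_equal(unname(es0$expected), c(0, 0, 0))
  expect_error(expected_same_color(100, probs, n_sim = 50), "99")
  expect_error(expected_same_color(100, c(a = 0.9, b = 0.3)), "sum")
  # Monte-Carlo interval brackets the analytic mean for varied configs
  for (n_kc in c(50, 134, 400)) {
    es2 <- expected_same_color(n_kc, probs, n_sim = 499, seed = n_kc)
    expect_true(all(es2$interval[1, ] <= es2$expected &
                    es2$expected <= es2$interval[2, ]))
  }
})

test_that("same-color p-values are uniform when observed comes from null", {
  probs <- c(rfp = 0.05)
  set.seed(14)
  p <- vapply(1:200, function(i) {
    obs <- rbinom(1, 134, 0.05)
    expected_same_color(134, probs, n_sim = 99, seed = 300 + i,
                        observed = c(rfp = obs))$p
  }, numeric(1))
  # two-sided rank p on a discrete statistic: check no excess rejection
  expect_lt(mean(p <= 0.05), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})
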