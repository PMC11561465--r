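# KC detection and per-specimen summaries.

#' Detect KCs in a cell table
#'
#' A KC is a group of at least 4 proliferating (Ki67+) cells in direct
#' contact. Contact is modelled as Euclidean distance at most
#' `contact_radius` (default 12 um, about a soma diameter); KCs are the
#' size >= 4 connected components of the contact graph over Ki67+ cells.
#' Smaller components are returned separately as singles, pairs, and trios.
#' Ki67- cells never participate in clustering, but each component is
#' annotated with the dormant (Ki67- DCX-) and postmitotic-neuroblast
#' (Ki67- DCX+) cells found within the contact radius of its members.
#'
#' The component partition is invariant to the row order of the input;
#' component ids are assigned in lexicographic order of the components'
#' first member coordinate.
#'
#' @param cells Cell table with columns `x_um`, `y_um`, `z_um`, `ki67`,
#'   `dcx` (and optionally `brdu`, `reporter`).
#' @param contact_radius Contact distance in um, > 0.
#' @return List with `assignment` (per input row: KC id, small-group id, or
#'   `NA` for Ki67- cells), `kcs` (one row per KC: counts by stage,
#'   classification, label summaries, centroid), and `small_groups`
#'   (components of size 1-3).
#' @examples
#' sp <- gen_specimen(specimen_config(n_kc = 10, seed = 1))
#' det <- detect_kcs(sp$cells, contact_radius = 12)
#' nrow(det$kcs)
#' @export
detect_kcs <- function(cells, contact_radius = 12) {
  check_scalar(contact_radius, "contact_radius", lower = 0)
  if (contact_radius <= 0) stopf("`contact_radius` must be > 0")
  cells <- validate_cells(cells, need = c("x_um", "y_um", "z_um",
                                          "ki67", "dcx"))
  n <- nrow(cells)
  empty_kcs <- data.frame(kc_id = character(0), size = integer(0),
                          n_tap = integer(0), n_prnb = integer(0),
                          prnb_frac = numeric(0), kc_type = character(0),
                          n_dormant = integer(0), pmnb_assoc = logical(0),
                          n_brdu = integer(0), n_reporter = integer(0),
                          colors = character(0), x = numeric(0),
                          y = numeric(0), z = numeric(0),
                          stringsAsFactors = FALSE)
  empty_small <- data.frame(group_id = character(0), size = integer(0),
                            kind = character(0), x = numeric(0),
                            y = numeric(0), z = numeric(0),
                            stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(assignment = character(0), kcs = empty_kcs,
                small_groups = empty_small))
  ki <- which(as.logical(cells$ki67))
  assignment <- rep(NA_character_, n)
  if (length(ki) == 0L)
    return(list(assignment = assignment, kcs = empty_kcs,
                small_groups = empty_small))
  pts <- as.matrix(cells[ki, c("x_um", "y_um", "z_um")])
  storage.mode(pts) <- "double"
  labels <- connected_components(pts, contact_radius)
  comps <- split(seq_along(ki), labels)
  # deterministic order: lexicographically smallest member coordinate
  rep_pt <- t(vapply(comps, function(ix) {
    p <- pts[ix, , drop = FALSE]
    p[order(p[, 1], p[, 2], p[, 3])[1], ]
  }, numeric(3)))
  comps <- comps[order(rep_pt[, 1], rep_pt[, 2], rep_pt[, 3])]
  sizes <- lengths(comps)
  is_kc <- sizes >= 4L
  quiescent <- which(!as.logical(cells$ki67))
  q_pts <- as.matrix(cells[quiescent, c("x_um", "y_um", "z_um")])
  q_dcx <- as.logical(cells$dcx)[quiescent]
  kc_rows <- list(); sg_rows <- list()
  kc_i <- 0L; sg_i <- 0L
  for (ci in seq_along(comps)) {
    ix <- comps[[ci]]                 # indices into `ki`
    rows <- ki[ix]
    p <- pts[ix, , drop = FALSE]
    cen <- colMeans(p[order(p[, 1], p[, 2], p[, 3]), , drop = FALSE])
    if (is_kc[ci]) {
      kc_i <- kc_i + 1L
      id <- sprintf("KC%04d", kc_i)
      assignment[rows] <- id
      n_prnb <- sum(as.logical(cells$dcx)[rows])
      n_tap <- length(rows) - n_prnb
      near_q <- nearby_quiescent(p, q_pts, contact_radius)
      n_dorm <- sum(near_q & !q_dcx)
      pmnb <- any(near_q & q_dcx)
      n_brdu <- if ("brdu" %in% names(cells))
        sum(as.logical(cells$brdu)[rows]) else 0L
      reps <- if ("reporter" %in% names(cells))
        cells$reporter[rows] else rep("none", length(rows))
      cols <- sort(unique(reps[reps != "none"]))
      kc_rows[[kc_i]] <- data.frame(
        kc_id = id, size = length(rows), n_tap = as.integer(n_tap),
        n_prnb = as.integer(n_prnb), prnb_frac = n_prnb / length(rows),
        kc_type = classify_kc(n_tap, n_prnb),
        n_dormant = as.integer(n_dorm), pmnb_assoc = pmnb,
        n_brdu = as.integer(n_brdu),
        n_reporter = sum(reps != "none"),
        colors = paste(cols, collapse = ","),
        x = cen[1], y = cen[2], z = cen[3], stringsAsFactors = FALSE)
    } else {
      sg_i <- sg_i + 1L
      id <- sprintf("G%04d", sg_i)
      assignment[rows] <- id
      sg_rows[[sg_i]] <- data.frame(
        group_id = id, size = length(rows),
        kind = c("single", "pair", "trio")[length(rows)],
        x = cen[1], y = cen[2], z = cen[3], stringsAsFactors = FALSE)
    }
  }
  kcs <- if (kc_i) do.call(rbind, kc_rows) else empty_kcs
  small <- if (sg_i) do.call(rbind, sg_rows) else empty_small
  rownames(kcs) <- NULL; rownames(small) <- NULL
  list(assignment = assignment, kcs = kcs, small_groups = small)
}

nearby_quiescent <- function(member_pts, q_pts, r) {
  if (nrow(q_pts) == 0L) return(logical(0))
  apply(q_pts, 1, function(q) {
    min(rowSums(sweep(member_pts, 2, q)^2)) <= r^2
  })
}

# Connected components of the geometric graph linking points within
# distance r, via a uniform grid of cell size r plus union-find.
connected_components <- function(pts, r) {
  n <- nrow(pts)
  if (n == 1L) return(1L)
  g <- floor(pts / r)
  key <- paste(g[, 1], g[, 2], g[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  r2 <- r^2
  for (bk in names(buckets)) {
    idx <- buckets[[bk]]
    gb <- g[idx[1], ]
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      k2 <- paste(gb[1] + offs[o, 1], gb[2] + offs[o, 2], gb[3] + offs[o, 3],
                  sep = ",")
      cand <- c(cand, buckets[[k2]])
    }
    for (i in idx) {
      cj <- cand[cand > i]
      if (!length(cj)) next
      d2 <- (pts[cj, 1] - pts[i, 1])^2 + (pts[cj, 2] - pts[i, 2])^2 +
            (pts[cj, 3] - pts[i, 3])^2
      for (j in cj[d2 <= r2]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Classify a KC by its maturation profile
#'
#' KCs are typed by prNB fraction: pure TAPs (`fraction 0`), pure prNBs
#' (`fraction 1`), and mixed KCs split into tertile bins `(0, 1/3]`,
#' `(1/3, 2/3]`, `(2/3, 1)` labelled Low/Med/High. The tertile cutoffs are
#' a declared convention (the underlying study does not print its bin
#' edges) and every valid KC falls in exactly one class.
#'
#' @param n_tap,n_prnb TAP and prNB member counts (vectors of equal
#'   length), or a data frame with columns `n_tap` and `n_prnb` as the
#'   first argument.
#' @return Character vector of types: `"TAPs-only"`, `"TAPs+prNBs_Low"`,
#'   `"TAPs+prNBs_Med"`, `"TAPs+prNBs_High"`, `"prNBs-only"`.
#' @examples
#' classify_kc(5, 0)
#' classify_kc(3, 3)
#' @export
classify_kc <- function(n_tap, n_prnb = NULL) {
  if (is.data.frame(n_tap)) {
    n_prnb <- n_tap$n_prnb
    n_tap <- n_tap$n_tap
  }
  if (length(n_tap) != length(n_prnb))
    stopf("`n_tap` and `n_prnb` must have equal length")
  size <- n_tap + n_prnb
  if (any(size < 4)) stopf("KC size must be >= 4 (got %d)", min(size))
  if (any(n_tap < 0 | n_prnb < 0)) stopf("negative member counts")
  frac <- n_prnb / size
  out <- character(length(frac))
  out[frac == 0] <- "TAPs-only"
  out[frac == 1] <- "prNBs-only"
  mid <- frac > 0 & frac < 1
  out[mid & frac <= 1 / 3] <- "TAPs+prNBs_Low"
  out[mid & frac > 1 / 3 & frac <= 2 / 3] <- "TAPs+prNBs_Med"
  out[mid & frac > 2 / 3] <- "TAPs+prNBs_High"
  out
}

#' KC labeling index
#'
#' The labeling index (LI) of a KC population is the fraction of KCs with
#' at least one labeled member cell. Also reported: the fraction of labeled
#' KCs that are fully labeled, and a histogram of the per-KC labeled-cell
#' fraction in fixed bins of width 0.1.
#'
#' @param kcs KC table with a size column and a labeled-cell count column.
#' @param n_labeled_col,size_col Column names (defaults `"n_labeled"`,
#'   `"size"`).
#' @return Object of class `kc_li`: `n_kc`, `li`, `n_labeled_kcs`,
#'   `fully_labeled_frac`, `hist` (named counts over `[0,0.1), ...`),
#'   `defined` (`FALSE`, with `li = NA`, when there are no KCs).
#' @examples
#' kcs <- data.frame(size = c(5, 6, 8), n_labeled = c(5, 0, 2))
#' labeling_index(kcs)$li
#' @export
labeling_index <- function(kcs, n_labeled_col = "n_labeled",
                           size_col = "size") {
  for (col in c(n_labeled_col, size_col))
    if (!col %in% names(kcs)) stopf("missing required column `%s`", col)
  nl <- kcs[[n_labeled_col]]
  sz <- kcs[[size_col]]
  if (any(nl > sz)) stopf("labeled cells exceed KC size")
  n_kc <- nrow(kcs)
  if (n_kc == 0L) {
    return(structure(list(n_kc = 0L, li = NA_real_, n_labeled_kcs = 0L,
                          fully_labeled_frac = NA_real_, hist = NULL,
                          defined = FALSE), class = "kc_li"))
  }
  labeled <- nl > 0
  frac <- nl / sz
  breaks <- seq(0, 1, by = 0.1)
  h <- table(cut(frac, breaks = breaks, include.lowest = TRUE, right = FALSE))
  # right-open bins put fraction 1.0 beyond the last break; fold it back
  h[length(h)] <- h[length(h)] + sum(frac >= 1)
  structure(list(n_kc = n_kc, li = mean(labeled),
                 n_labeled_kcs = sum(labeled),
                 fully_labeled_frac = if (any(labeled))
                   sum(nl == sz & labeled) / sum(labeled) else NA_real_,
                 hist = as.vector(h), hist_breaks = breaks, defined = TRUE),
            class = "kc_li")
}

#' @export
print.kc_li <- function(x, ...) {
  if (!x$defined) cat("<kc_li: undefined (no KCs)>\n")
  else cat(sprintf("<kc_li: LI = %.3f (%d/%d KCs), fully labeled %.3f>\n",
                   x$li, x$n_labeled_kcs, x$n_kc, x$fully_labeled_frac))
  invisible(x)
}

#' Clonality summary of reporter-labeled KCs
#'
#' Summarises multicolor (Confetti-style) reporter expression per KC. A KC
#' is labeled if any member carries a color; it is single-color if all its
#' cells carry one and the same color (no non-recombined cells); any other
#' labeled KC is mixed, including KCs whose only impurity is unlabeled
#' cells. The fraction of non-recombined cells is computed over all cells
#' of labeled KCs.
#'
#' @param cells Cell table with `kc_id` and `reporter` columns (`"none"` =
#'   non-recombined). Rows with `kc_id` `NA` are ignored.
#' @param proliferative_only If `TRUE` (default) restrict to Ki67+ cells
#'   when a `ki67` column is present (KC members proper).
#' @return Object of class `kc_clonality`: `n_labeled`, `n_single_color`,
#'   `n_mixed`, `per_color` (KC counts per color), `frac_nonrecombined`,
#'   `n_cells_labeled_kcs`.
#' @examples
#' cells <- data.frame(kc_id = rep(c("a", "b"), each = 4),
#'                     reporter = c(rep("rfp", 4), "cyfp", "cyfp", "none", "none"))
#' clonality_summary(cells)
#' @export
clonality_summary <- function(cells, proliferative_only = TRUE) {
  for (col in c("kc_id", "reporter"))
    if (!col %in% names(cells)) stopf("missing required column `%s`", col)
  keep <- !is.na(cells$kc_id)
  if (proliferative_only && "ki67" %in% names(cells))
    keep <- keep & as.logical(cells$ki67)
  cells <- cells[keep, , drop = FALSE]
  by_kc <- split(cells$reporter, cells$kc_id)
  labeled <- vapply(by_kc, function(r) any(r != "none"), logical(1))
  lab_kcs <- by_kc[labeled]
  single <- vapply(lab_kcs, function(r) {
    length(unique(r)) == 1L && r[1] != "none"
  }, logical(1))
  colors <- sort(unique(cells$reporter[cells$reporter != "none"]))
  per_color <- vapply(colors, function(cl) {
    sum(vapply(lab_kcs, function(r) cl %in% r, logical(1)))
  }, integer(1))
  cells_in_labeled <- unlist(lab_kcs, use.names = FALSE)
  n_cells <- length(cells_in_labeled)
  structure(list(n_labeled = sum(labeled),
                 n_single_color = sum(single),
                 n_mixed = sum(labeled) - sum(single),
                 per_color = per_color,
                 n_cells_labeled_kcs = n_cells,
                 n_nonrecombined = sum(cells_in_labeled == "none"),
                 frac_nonrecombined = if (n_cells)
                   sum(cells_in_labeled == "none") / n_cells else NA_real_),
            class = "kc_clonality")
}

#' @export
print.kc_clonality <- function(x, ...) {
  cat(sprintf(paste0("<kc_clonality: %d labeled KCs, %d single-color, ",
                     "%d mixed; non-recombined %.3f>\n"),
              x$n_labeled, x$n_single_color, x$n_mixed,
              x$frac_nonrecombined))
  invisible(x)
}

#' Expected same-color KC counts under clonal independence
#'
#' If every KC independently draws a reporter color with the per-lineage
#' recombination probabilities, the number of KCs per color is multinomial.
#' Returns the analytic expectation, a Monte-Carlo interval, and (when
#' observed counts are supplied) a two-sided Monte-Carlo p-value per color
#' from the rank of the observation in the null ensemble.
#'
#' @param n_kc Total number of KCs in the specimen.
#' @param color_probs Named per-lineage color probabilities, sum <= 1.
#' @param n_sim Number of multinomial null draws (>= 99; coarser ensembles
#'   are refused).
#' @param seed Integer seed or `NULL`.
#' @param observed Optional named observed per-color KC counts.
#' @return Object of class `kc_same_color`: `expected`, `interval`
#'   (2.5%/97.5% quantiles per color), `p` (or `NULL`), `n_sim`.
#' @examples
#' expected_same_color(134, c(rfp = 0.024, mcfp = 0.012, cyfp = 0.017),
#'                     n_sim = 199, seed = 1)$expected
#' @export
expected_same_color <- function(n_kc, color_probs, n_sim = 999, seed = NULL,
                                observed = NULL) {
  check_scalar(n_kc, "n_kc", lower = 0)
  if (any(color_probs < 0) || any(color_probs > 1) || sum(color_probs) > 1)
    stopf("`color_probs` must be in [0,1] with sum <= 1")
  if (n_sim < 99) stopf("n_sim < 99 refused: Monte-Carlo resolution too coarse")
  k <- length(color_probs)
  expected <- n_kc * color_probs
  with_seed(seed, {
    draws <- rmultinom(n_sim, as.integer(n_kc), c(color_probs,
                                                  1 - sum(color_probs)))
    sims <- t(draws[seq_len(k), , drop = FALSE])
    colnames(sims) <- names(color_probs)
    interval <- apply(sims, 2, quantile, probs = c(0.025, 0.975))
    p <- NULL
    if (!is.null(observed)) {
      if (length(observed) != k)
        stopf("`observed` must give one count per color")
      observed <- observed[names(color_probs)]
      p <- vapply(seq_len(k), function(j) {
        lo <- (1 + sum(sims[, j] <= observed[j])) / (n_sim + 1)
        hi <- (1 + sum(sims[, j] >= observed[j])) / (n_sim + 1)
        min(1, 2 * min(lo, hi))
      }, numeric(1))
      names(p) <- names(color_probs)
    }
    structure(list(expected = expected, interval = interval, p = p,
                   n_sim = n_sim, observed = observed),
              class = "kc_same_color")
  })
}

validate_cells <- function(cells, need) {
  if (!is.data.frame(cells)) stopf("`cells` must be a data frame")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stopf("missing required column `%s`", miss[1])
  coords <- c("x_um", "y_um", "z_um")
  for (col in intersect(coords, need)) {
    v <- cells[[col]]
    if (!is.numeric(v)) stopf("column `%s` must be numeric", col)
    if (nrow(cells) && any(!is.finite(v)))
      stopf("non-finite coordinates in column `%s` (row %d)", col,
            which(!is.finite(v))[1])
  }
  for (col in intersect(c("ki67", "dcx", "brdu"), names(cells)))
    cells[[col]] <- check_flag_col(cells[[col]], col)
  cells
}
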