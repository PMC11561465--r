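# Independent oracles and small fixture builders used across the suite.

# Brute-force connected components of the geometric contact graph:
# adjacency from the full distance matrix, components by breadth-first
# search. Deliberately naive - checks the grid/union-find implementation.
bf_components <- function(pts, r) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  adj <- as.matrix(dist(pts)) <= r
  diag(adj) <- FALSE
  lab <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(lab[v])) next
      lab[v] <- comp
      queue <- c(queue, which(adj[v, ] & is.na(lab)))
    }
  }
  lab
}

# Canonical form of a partition: sets of sorted member indices, sorted.
partition_sets <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))[
    order(vapply(split(seq_along(labels), labels), min, integer(1)))]
}

# Double-loop Moran's I straight from the definition.
bf_moran <- function(w, x) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Minimal cell table with all-Ki67+ cells at given positions.
make_cells <- function(pts, ki67 = TRUE, dcx = FALSE, specimen = "T") {
  n <- nrow(pts)
  data.frame(specimen_id = rep_len(specimen, n),
             cell_id = sprintf("c%d", seq_len(n)),
             x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
             ki67 = rep_len(ki67, n), dcx = rep_len(dcx, n),
             sox9 = rep_len("neg", n), brdu = rep_len(FALSE, n),
             reporter = rep_len("none", n),
             kc_id = rep_len(NA_character_, n), stringsAsFactors = FALSE)
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Match detected KCs back to emitted KCs through the cell membership.
match_detected_to_true <- function(cells, det) {
  memb <- split(cells$kc_id[!is.na(det$assignment)],
                det$assignment[!is.na(det$assignment)])
  vapply(memb, function(ids) {
    u <- unique(ids)
    if (length(u) == 1L) u else NA_character_
  }, character(1))
}
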