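#' Observation regions for 3D point patterns
#'
#' A `kc_region` describes the observation window (the "neurogenic area") in
#' which cells and KC centroids live. Three geometries are supported: an
#' axis-aligned box, a spherical shell (emulating a band around a roughly
#' spherical lesion border), and an arbitrary voxel label volume. All
#' coordinates and spacings are in micrometres.
#'
#' @param lower,upper Numeric length-3 vectors, box corners (um).
#' @return An object of class `kc_region` with fields `kind` and the
#'   geometry parameters; `region_volume()` gives its volume in um^3.
#' @examples
#' reg <- region_box(upper = c(1000, 1000, 1000))
#' region_volume(reg)
#' @seealso [region_sample()], [region_contains()]
#' @export
region_box <- function(lower = c(0, 0, 0), upper = c(1000, 1000, 1000)) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L ||
      !all(is.finite(c(lower, upper))))
    stopf("box corners must be finite length-3 numeric vectors")
  if (any(upper <= lower)) stopf("box must have positive extent on all axes")
  structure(list(kind = "box", lower = lower, upper = upper),
            class = "kc_region")
}

#' @rdname region_box
#' @param center Numeric length-3, shell centre (um).
#' @param r_inner,r_outer Inner/outer shell radii (um), `0 <= r_inner < r_outer`.
#' @export
region_shell <- function(center = c(0, 0, 0), r_inner = 0, r_outer = 500) {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stopf("`center` must be a finite length-3 numeric vector")
  check_scalar(r_inner, "r_inner", lower = 0)
  check_scalar(r_outer, "r_outer", lower = 0)
  if (r_outer <= r_inner) stopf("`r_outer` must exceed `r_inner`")
  structure(list(kind = "spherical-shell", center = center,
                 r_inner = r_inner, r_outer = r_outer),
            class = "kc_region")
}

#' @rdname region_box
#' @param mask 3D logical (or 0/1) array: voxels inside the region.
#' @param spacing Numeric length-3, voxel edge lengths (um), all positive.
#' @param origin Numeric length-3, coordinates of the corner of voxel
#'   `[1, 1, 1]` (um).
#' @export
region_voxels <- function(mask, spacing, origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) stopf("`mask` must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stopf("`mask` must be logical with no NA")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be positive on all axes")
  if (!any(mask)) stopf("voxel region is empty (volume must be > 0)")
  structure(list(kind = "voxel-volume", mask = mask, spacing = spacing,
                 origin = origin),
            class = "kc_region")
}

#' @rdname region_box
#' @param region A `kc_region`.
#' @export
region_volume <- function(region) {
  stopifnot(inherits(region, "kc_region"))
  switch(region$kind,
    "box" = prod(region$upper - region$lower),
    "spherical-shell" = 4 / 3 * pi * (region$r_outer^3 - region$r_inner^3),
    "voxel-volume" = sum(region$mask) * prod(region$spacing),
    stopf("unknown region kind `%s`", region$kind))
}

#' Point membership in a region
#'
#' @param region A `kc_region`.
#' @param xyz Numeric matrix with 3 columns (um), one point per row.
#' @return Logical vector, one entry per point.
#' @export
region_contains <- function(region, xyz) {
  stopifnot(inherits(region, "kc_region"))
  xyz <- as_xyz(xyz)
  if (nrow(xyz) == 0L) return(logical(0))
  switch(region$kind,
    "box" = {
      lo <- region$lower; up <- region$upper
      xyz[, 1] >= lo[1] & xyz[, 1] <= up[1] &
      xyz[, 2] >= lo[2] & xyz[, 2] <= up[2] &
      xyz[, 3] >= lo[3] & xyz[, 3] <= up[3]
    },
    "spherical-shell" = {
      d <- sqrt(rowSums(sweep(xyz, 2, region$center)^2))
      d >= region$r_inner & d <= region$r_outer
    },
    "voxel-volume" = {
      idx <- sweep(xyz, 2, region$origin)
      idx <- sweep(idx, 2, region$spacing, "/")
      ijk <- floor(idx) + 1
      dm <- dim(region$mask)
      ok <- ijk[, 1] >= 1 & ijk[, 1] <= dm[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= dm[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= dm[3]
      out <- logical(nrow(xyz))
      if (any(ok)) out[ok] <- region$mask[ijk[ok, , drop = FALSE]]
      out
    })
}

#' Uniform random points in a region
#'
#' Samples points uniformly over the region volume: directly for boxes;
#' by inverse-CDF radius plus an isotropic direction for shells; by
#' volume-weighted voxel choice plus a uniform offset for voxel volumes.
#' Uses the current RNG stream (callers manage seeds).
#'
#' @param region A `kc_region`.
#' @param n Number of points.
#' @return Numeric `n x 3` matrix (columns `x`, `y`, `z`, um).
#' @export
region_sample <- function(region, n) {
  stopifnot(inherits(region, "kc_region"))
  check_scalar(n, "n", lower = 0)
  n <- as.integer(n)
  if (n == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  pts <- switch(region$kind,
    "box" = {
      lo <- region$lower; up <- region$upper
      cbind(runif(n, lo[1], up[1]), runif(n, lo[2], up[2]),
            runif(n, lo[3], up[3]))
    },
    "spherical-shell" = {
      r <- (runif(n, region$r_inner^3, region$r_outer^3))^(1 / 3)
      z <- runif(n, -1, 1)
      phi <- runif(n, 0, 2 * pi)
      s <- sqrt(pmax(0, 1 - z^2))
      sweep(r * cbind(s * cos(phi), s * sin(phi), z), 2, region$center, "+")
    },
    "voxel-volume" = {
      inside <- which(region$mask)
      pick <- inside[sample.int(length(inside), n, replace = TRUE)]
      ijk <- arrayInd(pick, dim(region$mask))
      off <- matrix(runif(3 * n), n, 3)
      sweep((ijk - 1 + off) %*% diag(region$spacing), 2, region$origin, "+")
    })
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' @export
print.kc_region <- function(x, ...) {
  cat(sprintf("<kc_region: %s, volume %.4g um^3>\n", x$kind, region_volume(x)))
  invisible(x)
}

# Coerce point input (matrix / data.frame with x,y,z or 3 columns) to a
# numeric n x 3 matrix.
as_xyz <- function(xyz) {
  if (is.data.frame(xyz)) {
    cols <- intersect(c("x", "y", "z"), names(xyz))
    if (length(cols) == 3L) xyz <- xyz[cols]
    else {
      cols <- intersect(c("x_um", "y_um", "z_um"), names(xyz))
      if (length(cols) == 3L) xyz <- xyz[cols] else xyz <- xyz[, 1:3]
    }
    xyz <- as.matrix(xyz)
  }
  if (is.null(dim(xyz)) && length(xyz) == 3L) xyz <- matrix(xyz, 1, 3)
  xyz <- unname(as.matrix(xyz))
  if (ncol(xyz) != 3L) stopf("points must have 3 coordinates")
  storage.mode(xyz) <- "double"
  colnames(xyz) <- c("x", "y", "z")
  xyz
}
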