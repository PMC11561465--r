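#' 3D marked point patterns
#'
#' Container for a 3D point pattern inside an observation region, optionally
#' carrying one numeric or categorical mark per point (e.g. KC size, prNB
#' fraction, pmNB association).
#'
#' @param points `n x 3` numeric matrix or data frame of coordinates (um).
#' @param region A [region_box()]-style `kc_region` containing all points.
#' @param marks Optional vector of per-point marks, length `n`.
#' @return An object of class `kc_pattern`: list with `points`, `region`,
#'   `marks`, and `n`.
#' @examples
#' reg <- region_box(upper = c(100, 100, 100))
#' p <- point_pattern(matrix(runif(30, 0, 100), 10, 3), reg)
#' p$n
#' @export
point_pattern <- function(points, region, marks = NULL) {
  stopifnot(inherits(region, "kc_region"))
  points <- as_xyz(points)
  if (anyNA(points) || any(!is.finite(points)))
    stopf("point coordinates must be finite")
  if (nrow(points) > 0 && !all(region_contains(region, points)))
    stopf("all points must lie inside the region")
  if (!is.null(marks) && length(marks) != nrow(points))
    stopf("`marks` must align 1:1 with points (%d marks for %d points)",
          length(marks), nrow(points))
  structure(list(points = points, region = region, marks = marks,
                 n = nrow(points)),
            class = "kc_pattern")
}

#' @export
print.kc_pattern <- function(x, ...) {
  cat(sprintf("<kc_pattern: %d points in %s region%s>\n", x$n, x$region$kind,
              if (is.null(x$marks)) "" else ", marked"))
  invisible(x)
}
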