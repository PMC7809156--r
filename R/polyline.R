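#' Construct a polyline (ordered 3D node chain with thickness radii)
#'
#' A polyline is the continuous-curve primitive underlying every structural
#' constituent: an ordered set of 3D positions in micrometres, each carrying a
#' local thickness radius. It is stored as a tibble with columns `x`, `y`,
#' `z`, `radius` so it drops straight into dplyr/ggplot2 workflows.
#'
#' @param points Numeric matrix (n x 3) of positions in µm, or a data frame
#'   with columns `x`, `y`, `z`.
#' @param radii Per-node thickness radius in µm; recycled if scalar.
#' @return A `neuro_polyline` tibble with columns `x`, `y`, `z`, `radius`.
#' @examples
#' pl <- polyline(cbind(0:4, 0, 0), radii = 0.5)
#' polyline_length(pl)
#' @export
polyline <- function(points, radii = 0.5) {
  new_polyline(points, radii, min_points = 2L)
}

# Internal: node models tolerate single-node chains (e.g. a soma marker).
new_polyline <- function(points, radii, min_points = 2L) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  points <- matrix(as.double(points), ncol = 3L)
  n <- nrow(points)
  if (n < min_points) {
    abort(sprintf("a polyline needs at least %d points", min_points))
  }
  if (!all(is.finite(points))) abort("polyline coordinates must be finite")
  radii <- rep_len(as.double(radii), n)
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    abort("all polyline radii must be positive and finite")
  }
  if (n >= 2L) {
    seps <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                            points[-n, , drop = FALSE])^2))
    if (any(seps <= 1e-9)) {
      abort("consecutive polyline points must be distinct (separation > 1e-9 um)")
    }
  }
  out <- tibble(
    x = points[, 1L], y = points[, 2L], z = points[, 3L], radius = radii
  )
  class(out) <- c("neuro_polyline", class(out))
  out
}

polyline_points <- function(pl) {
  cbind(x = pl$x, y = pl$y, z = pl$z)
}

#' Path length of a polyline
#'
#' @param pl A polyline (or any data frame with `x`, `y`, `z`).
#' @return Total arc length in µm.
#' @export
polyline_length <- function(pl) {
  p <- polyline_points(pl)
  sum(sqrt(rowSums(diff(p)^2)))
}

# Merge nodes closer than `tol` um (numerical stability of cross products).
dedupe_polyline <- function(pl, tol = 1e-6) {
  p <- polyline_points(pl)
  keep <- c(TRUE, sqrt(rowSums(diff(p)^2)) > tol)
  pl[keep, , drop = FALSE]
}

#' Resample a polyline at uniform arc-length spacing
#'
#' Linear interpolation of positions and radii along cumulative arc length.
#' Used to place ground-truth model nodes at a fixed physical spacing and by
#' the smooth random curve generator.
#'
#' @param pl A polyline.
#' @param spacing Target node spacing in µm.
#' @return A `neuro_polyline` with approximately uniform node spacing (both
#'   endpoints always retained).
#' @export
resample_polyline <- function(pl, spacing) {
  stopifnot(spacing > 0)
  p <- polyline_points(pl)
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  total <- s[length(s)]
  n_out <- max(2L, as.integer(round(total / spacing)) + 1L)
  si <- seq(0, total, length.out = n_out)
  newp <- vapply(1:3, function(k) stats::approx(s, p[, k], xout = si)$y,
                 numeric(n_out))
  newr <- stats::approx(s, pl$radius, xout = si)$y
  polyline(newp, newr)
}
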