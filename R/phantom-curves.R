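#' Generate a parametric space curve with known differential geometry
#'
#' Produces a polyline sampled at uniform parameter steps from one of four
#' curve families. For the analytic kinds the true (constant) Frenet
#' curvature and torsion are attached as attributes, giving closed-form
#' ground truth for the geometry estimators: a helix with radius `a` and
#' pitch parameter `b` has curvature `a / (a^2 + b^2)` and torsion
#' `b / (a^2 + b^2)`; a circle of radius `a` has curvature `1 / a` and zero
#' torsion; a line has both zero.
#'
#' @param kind One of `"line"`, `"circle"`, `"helix"`, `"smooth_random"`.
#' @param params Named list of curve parameters:
#'   * line: `start` (µm, default origin), `direction`, `length` (µm).
#'   * circle: `a` (radius µm), `turns` (default 1), `center`, `phase`.
#'   * helix: `a` (radius µm), `b` (pitch parameter µm; axial rise per radian),
#'     `turns`, `center`, `handedness` (+1 right-handed, -1 left-handed).
#'   * smooth_random: `seed`, `length` (µm), `curvature_scale` (µm^-1),
#'     `start`, `smooth_window`.
#'   All kinds accept `radius` (thickness radius µm, default 0.5).
#' @param n_samples Number of sample points (>= 4).
#' @return A `neuro_polyline`; attributes `kind`, `true_curvature`,
#'   `true_torsion` (the latter two `NA` for `smooth_random`).
#' @examples
#' h <- make_parametric_curve("helix", list(a = 1, b = 0.5, turns = 3), 200)
#' attr(h, "true_curvature")  # 0.8
#' attr(h, "true_torsion")    # 0.4
#' @export
make_parametric_curve <- function(kind, params = list(), n_samples = 100L) {
  if (n_samples < 4L) abort("n_samples must be >= 4")
  thick <- params$radius %||% 0.5
  kind <- match.arg(kind, c("line", "circle", "helix", "smooth_random"))
  out <- switch(kind,
    line = {
      start <- params$start %||% c(0, 0, 0)
      dir <- unit(params$direction %||% c(1, 0, 0))
      len <- params$length %||% 10
      if (len <= 0) abort("line length must be positive")
      t <- seq(0, len, length.out = n_samples)
      pl <- polyline(outer(t, dir) + rep(start, each = n_samples), thick)
      structure(pl, true_curvature = 0, true_torsion = 0)
    },
    circle = {
      a <- params$a %||% params$radius_curve %||% 1
      if (!is.numeric(a) || a <= 0) abort("circle radius a must be positive")
      turns <- params$turns %||% 1
      phase <- params$phase %||% 0
      center <- params$center %||% c(0, 0, 0)
      # open arc: stop one step short of closure so consecutive points stay distinct
      t <- phase + seq(0, 2 * pi * turns, length.out = n_samples + 1L)[1:n_samples]
      p <- cbind(center[1L] + a * cos(t), center[2L] + a * sin(t),
                 center[3L] + 0 * t)
      structure(polyline(p, thick), true_curvature = 1 / a, true_torsion = 0)
    },
    helix = {
      a <- params$a %||% 1
      b <- params$b %||% 0.5
      if (a <= 0) abort("helix radius a must be positive")
      hand <- params$handedness %||% 1
      turns <- params$turns %||% 2
      center <- params$center %||% c(0, 0, 0)
      t <- seq(0, 2 * pi * turns, length.out = n_samples)
      p <- cbind(center[1L] + a * cos(t),
                 center[2L] + sign(hand) * a * sin(t),
                 center[3L] + b * t)
      structure(polyline(p, thick),
                true_curvature = a / (a^2 + b^2),
                true_torsion = sign(hand) * b / (a^2 + b^2))
    },
    smooth_random = smooth_random_curve(params, n_samples, thick)
  )
  attr(out, "kind") <- kind
  out
}

# Seeded random walk of the tangent, smoothed by a moving-average window and
# arc-length resampled: controllable curvature scale without handling
# self-intersections.
smooth_random_curve <- function(params, n_samples, thick) {
  seed <- params$seed %||% 1L
  len <- params$length %||% 20
  kscale <- params$curvature_scale %||% 0.5
  start <- params$start %||% c(0, 0, 0)
  win <- params$smooth_window %||% 9L
  n_raw <- max(4L * n_samples, 256L)
  step <- len / n_raw
  dirs <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    # tangent direction random walk; sd per step sets the curvature scale
    ang_sd <- kscale * step
    matrix(rnorm(3L * n_raw, sd = ang_sd), ncol = 3L)
  })
  tang <- apply(dirs, 2L, cumsum)
  tang[, 1L] <- tang[, 1L] + 1  # drift so the tangent never vanishes
  k <- rep(1 / win, win)
  tang <- vapply(1:3, function(j) as.double(
    stats::filter(tang[, j], k, sides = 2L, circular = TRUE)),
    numeric(n_raw))
  tang <- tang / sqrt(rowSums(tang^2))
  pos <- apply(tang * step, 2L, cumsum)
  p <- rbind(start, sweep(pos, 2L, start, "+"))
  pl <- polyline(p, thick)
  pl <- resample_polyline(pl, polyline_length(pl) / (n_samples - 1L))
  structure(pl, true_curvature = NA_real_, true_torsion = NA_real_)
}

#' Attach lateral spines to a parent curve
#'
#' Emulates dendritic spines: short protrusions emitted perpendicular to the
#' local parent tangent at Poisson-distributed positions along the parent,
#' with randomized azimuth. Each spine records the index of the parent node
#' it emanates from.
#'
#' @param parent Parent polyline (>= 3 points; spines attach only at interior
#'   nodes, where a tangent is defined).
#' @param density Expected spine count per µm of parent length (>= 0).
#' @param length_dist Function `n -> n` positive spine lengths (µm). Default
#'   lognormal with median 1 µm.
#' @param radius_dist Function `n -> n` positive spine thickness radii (µm).
#' @param seed Integer seed; all randomness in this call derives from it.
#' @param nodes_per_spine Sample points per spine polyline.
#' @return A list of `list(polyline, parent_index)`; empty when density or
#'   the Poisson draw is 0.
#' @export
attach_spines <- function(parent, density, length_dist = NULL,
                          radius_dist = NULL, seed = 1L,
                          nodes_per_spine = 5L) {
  if (density < 0) abort("spine density must be >= 0")
  if (nrow(parent) < 3L) abort("parent needs >= 3 points for interior tangents")
  length_dist <- length_dist %||% function(n) rlnorm(n, meanlog = 0, sdlog = 0.25)
  radius_dist <- radius_dist %||% function(n) rlnorm(n, meanlog = log(0.15), sdlog = 0.2)
  plen <- polyline_length(parent)
  p <- polyline_points(parent)
  n <- nrow(p)
  draw <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    count <- rpois(1L, density * plen)
    if (count == 0L) {
      NULL
    } else {
      # attachment nodes sampled proportional to the arc length they carry
      edge <- sqrt(rowSums(diff(p)^2))
      w <- (c(edge, 0) + c(0, edge)) / 2
      idx_pool <- 2:(n - 1L)
      list(
        count = count,
        att = sample(idx_pool, count, replace = TRUE, prob = w[idx_pool]),
        lens = length_dist(count),
        rads = radius_dist(count),
        azim = runif(count, 0, 2 * pi)
      )
    }
  })
  if (is.null(draw)) return(list())
  att <- draw$att; lens <- draw$lens; rads <- draw$rads; azim <- draw$azim
  if (any(lens <= 0) || any(rads <= 0)) {
    abort("spine length and radius distributions must have positive support")
  }
  purrr::map(seq_len(draw$count), function(i) {
    k <- att[i]
    tang <- unit(p[k + 1L, ] - p[k - 1L, ])
    b <- orthobasis(tang)
    dir <- cos(azim[i]) * b$u + sin(azim[i]) * b$w
    t <- seq(0, lens[i], length.out = nodes_per_spine)
    pts <- rep(p[k, ], each = nodes_per_spine) + outer(t, dir)
    list(polyline = polyline(pts, rads[i]), parent_index = k)
  })
}
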