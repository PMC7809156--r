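# Centerline tracing from 3D Sobel gradients and gradient vector flow.

#' 3D Sobel gradient of a volume
#'
#' Separable Sobel derivative along each axis: derivative kernel
#' `[-1, 0, 1]` on the axis, smoothing kernel `[1, 2, 1]` on the two
#' transverse axes, edge voxels handled by mirror reflection. The result is
#' scaled by 1/32 so components approximate the true intensity derivative
#' per voxel.
#'
#' @param vol A [volume()] (normalize first for threshold consistency).
#' @return A `gradient_field` list: `gx`, `gy`, `gz` (arrays, same shape as
#'   the volume; derivative along physical x, y, z).
#' @export
sobel3d <- function(vol) {
  d <- dim(vol)
  if (any(d < 3L)) abort("volume smaller than the 3x3x3 Sobel kernel")
  a <- array(as.double(vol), d)
  # axis numbering of the array is (z, y, x) = (1, 2, 3)
  gz <- ax_deriv(ax_smooth(ax_smooth(a, 2L), 3L), 1L) / 32
  gy <- ax_deriv(ax_smooth(ax_smooth(a, 1L), 3L), 2L) / 32
  gx <- ax_deriv(ax_smooth(ax_smooth(a, 1L), 2L), 3L) / 32
  structure(list(gx = gx, gy = gy, gz = gz, dim = d),
            class = "gradient_field")
}

# shift an array by +/-1 along `axis` with mirror reflection at the edges
ax_shift <- function(a, axis, by) {
  n <- dim(a)[axis]
  idx <- if (by == 1L) c(2:n, n - 1L) else c(2L, 1:(n - 1L))
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

ax_smooth <- function(a, axis) {
  ax_shift(a, axis, 1L) + 2 * a + ax_shift(a, axis, -1L)
}

ax_deriv <- function(a, axis) {
  ax_shift(a, axis, 1L) - ax_shift(a, axis, -1L)
}

#' Compute a gradient vector flow field
#'
#' Diffuses an image gradient into homogeneous regions by iterating
#' `v <- v + dt * (mu * laplacian(v) - |g|^2 (v - g))` from `v0 = g`, with
#' `dt = 1 / (6 mu + max |g|^2)`, which guarantees a monotonically
#' non-increasing energy `E = sum mu |grad v|^2 + |g|^2 |v - g|^2`. The
#' resulting field points toward bright tubular structures well beyond the
#' one-voxel support of the raw gradient and vanishes on tube centerlines,
#' which is what both seed scoring and re-centering exploit.
#'
#' @param grad A `gradient_field` from [sobel3d()].
#' @param mu Regularization weight (> 0).
#' @param n_iter Number of iterations (>= 1).
#' @return A `gvf_field` list: `vx`, `vy`, `vz`, normalized direction fields
#'   `ux`, `uy`, `uz`, `mu`, `n_iter`, `dt`, and the per-iteration `energy`
#'   trace (length `n_iter + 1`, starting at the initial energy).
#' @export
compute_gvf <- function(grad, mu = 0.2, n_iter = 80L) {
  stopifnot(inherits(grad, "gradient_field"), mu > 0, n_iter >= 1L)
  if (!all(is.finite(grad$gx)) || !all(is.finite(grad$gy)) ||
      !all(is.finite(grad$gz))) {
    abort("gradient field contains non-finite values")
  }
  d <- grad$dim
  res <- gvf_iterate_cpp(as.double(grad$gx), as.double(grad$gy),
                         as.double(grad$gz), as.integer(d), mu,
                         as.integer(n_iter))
  mag <- sqrt(res$vx^2 + res$vy^2 + res$vz^2)
  scale <- 1 / (mag + 1e-12)
  structure(list(
    vx = res$vx, vy = res$vy, vz = res$vz,
    ux = res$vx * scale, uy = res$vy * scale, uz = res$vz * scale,
    mag = mag, mu = mu, n_iter = n_iter, dt = res$dt,
    energy = as.double(res$energy), dim = d),
    class = "gvf_field")
}

#' Default tracing parameters
#'
#' Thresholds are expressed in sigma units of the raw voxel-value
#' distribution (the same convention as contouring tomograms at 3.0 sigma):
#' seeds need `background + seed_threshold * sigma`, marching stops below
#' `background + stop_threshold * sigma`.
#'
#' @param seed_threshold Seed intensity threshold (sigma units, default 3).
#' @param stop_threshold March stop threshold (sigma units, default 1.5;
#'   must not exceed `seed_threshold`).
#' @param step_voxels March step length in voxels (default 1.5).
#' @param max_nodes Maximum nodes per trace.
#' @param recenter_tol Re-centering convergence tolerance in voxels.
#' @param spine_cutoff_um Path-length cutoff below which an attached trace
#'   is classified as a spine (µm; micron-scale spines motivate 3).
#' @param half_max_fraction Radius estimation: boundary crossing at this
#'   fraction of (center - background) intensity.
#' @param ray_count Rays cast for radius estimation.
#' @param min_nodes Minimum nodes for a trace to be kept.
#' @param smooth_window Moving-average window (nodes) applied to the traced
#'   chain to suppress sub-voxel re-centering jitter; 1 disables. Odd.
#' @param gvf_mu,gvf_iter GVF regularization weight and iteration count.
#' @return A `trace_params` list.
#' @export
trace_params <- function(seed_threshold = 3, stop_threshold = 1.5,
                         step_voxels = 1.5, max_nodes = 2000L,
                         recenter_tol = 0.1, spine_cutoff_um = 3,
                         half_max_fraction = 0.5, ray_count = 12L,
                         min_nodes = 4L, smooth_window = 5L,
                         gvf_mu = 0.2, gvf_iter = 80L) {
  stopifnot(seed_threshold > 0, stop_threshold > 0,
            stop_threshold <= seed_threshold, step_voxels > 0,
            max_nodes >= 1L, recenter_tol > 0, spine_cutoff_um > 0,
            half_max_fraction > 0, half_max_fraction < 1, ray_count >= 4L,
            ray_count %% 2L == 0L, smooth_window >= 1L,
            smooth_window %% 2L == 1L)
  structure(as.list(environment()), class = "trace_params")
}

# Trilinear interpolation of `arr` at continuous 1-based (z, y, x) index
# coordinates (n x 3 matrix). Points outside are clamped to the boundary.
interp3 <- function(arr, zyx) {
  d <- dim(arr)
  zyx <- matrix(zyx, ncol = 3L)
  z <- pmin(pmax(zyx[, 1L], 1), d[1L])
  y <- pmin(pmax(zyx[, 2L], 1), d[2L])
  x <- pmin(pmax(zyx[, 3L], 1), d[3L])
  z0 <- pmin(floor(z), d[1L] - 1L); y0 <- pmin(floor(y), d[2L] - 1L)
  x0 <- pmin(floor(x), d[3L] - 1L)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  at <- function(dz, dy, dx) {
    arr[cbind(z0 + dz, y0 + dy, x0 + dx)]
  }
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(0, 0, 1)) +
                fy * ((1 - fx) * at(0, 1, 0) + fx * at(0, 1, 1))) +
    fz * ((1 - fy) * ((1 - fx) * at(1, 0, 0) + fx * at(1, 0, 1)) +
            fy * ((1 - fx) * at(1, 1, 0) + fx * at(1, 1, 1)))
}

# normalized-intensity thresholds for a normalized volume
threshold_levels <- function(vol, params) {
  bg <- attr(vol, "background")
  sig <- attr(vol, "sigma")
  if (is.null(bg) || is.null(sig)) {
    abort("volume lacks background/sigma attributes; run normalize_volume() first")
  }
  list(bg = bg, seed = bg + params$seed_threshold * sig,
       stop = bg + params$stop_threshold * sig)
}

#' Detect trace seed points
#'
#' Candidate voxels must exceed the seed intensity threshold and be local
#' maxima (3x3x3 neighbourhood) of the centerline score, the negative
#' divergence of the normalized GVF direction field: on a tube axis the
#' surrounding GVF vectors all point inward, so the score peaks there.
#' Seeds are returned sorted by intensity, brightest first.
#'
#' @param vol Normalized [volume()] (from [normalize_volume()]).
#' @param gvf A `gvf_field`.
#' @param params [trace_params()].
#' @return Tibble: `z`, `y`, `x` (1-based voxel indices), `intensity`,
#'   `score`; zero rows when nothing qualifies.
#' @export
detect_seeds <- function(vol, gvf, params = trace_params()) {
  lv <- threshold_levels(vol, params)
  d <- dim(vol)
  dvz <- (ax_shift(gvf$uz, 1L, 1L) - ax_shift(gvf$uz, 1L, -1L)) / 2
  dvy <- (ax_shift(gvf$uy, 2L, 1L) - ax_shift(gvf$uy, 2L, -1L)) / 2
  dvx <- (ax_shift(gvf$ux, 3L, 1L) - ax_shift(gvf$ux, 3L, -1L)) / 2
  score <- -(dvx + dvy + dvz)
  # separable 3-wide max filter for the local-maximum test
  mx <- score
  for (axis in 1:3) {
    mx <- pmax(mx, ax_shift(mx, axis, 1L), ax_shift(mx, axis, -1L))
  }
  cand <- which(as.vector(vol) >= lv$seed & score >= mx - 1e-12 & score > 0)
  if (length(cand) == 0L) {
    return(tibble(z = integer(), y = integer(), x = integer(),
                  intensity = double(), score = double()))
  }
  idx <- arrayInd(cand, d)
  out <- tibble(z = idx[, 1L], y = idx[, 2L], x = idx[, 3L],
                intensity = as.vector(vol)[cand],
                score = score[cand])
  out[order(-out$intensity, out$z, out$y, out$x), ]
}

# Local tangent as the least-variance eigenvector of the Sobel-gradient
# covariance around continuous index position `zyx`. The window starts at
# 5^3 and grows until it captures boundary gradients (inside thick tubes the
# interior is gradient-free) or the gradients prove isotropic.
local_tangent <- function(grad, zyx) {
  d <- dim(grad$gx)
  c0 <- round(zyx)
  for (half in c(2L, 4L, 6L, 9L, 12L)) {
    lo <- pmax(1L, c0 - half); hi <- pmin(d, c0 + half)
    gz <- grad$gz[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]]
    gy <- grad$gy[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]]
    gx <- grad$gx[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]]
    # covariance in (x, y, z) component order
    m <- cbind(as.vector(gx), as.vector(gy), as.vector(gz))
    cv <- crossprod(m)
    if (sum(diag(cv)) < 1e-12) next  # window still inside a flat region
    eg <- eigen(cv, symmetric = TRUE)
    if (eg$values[2L] >= 3 * eg$values[3L]) return(eg$vectors[, 3L])
  }
  NULL  # degenerate (isotropic) gradients: no preferred axis
}

# Cast `ray_count` evenly spaced rays in the plane orthogonal to `tangent`
# and return each ray's boundary crossing (voxel units, sub-voxel by linear
# interpolation), plus the ray directions and centre intensity.
ray_scan <- function(vol, point_um, tangent, params, max_radius_voxels = 20) {
  lv <- threshold_levels(vol, params)
  vox <- voxel_um(vol)
  zyx0 <- c(point_um[3L], point_um[2L], point_um[1L]) / vox + 1
  center <- interp3(vol, matrix(zyx0, 1L))
  thresh <- lv$bg + params$half_max_fraction * (center - lv$bg)
  b <- orthobasis(unit(tangent))
  nray <- params$ray_count
  ang <- seq(0, 2 * pi, length.out = nray + 1L)[seq_len(nray)]
  steps <- seq(0, max_radius_voxels, by = 0.25)
  dirs <- matrix(NA_real_, nray, 3L)
  crossings <- rep(NA_real_, nray)
  for (i in seq_along(ang)) {
    dir <- cos(ang[i]) * b$u + sin(ang[i]) * b$w  # unit, (x,y,z)
    dirs[i, ] <- dir
    pts <- cbind(zyx0[1L] + steps * dir[3L],
                 zyx0[2L] + steps * dir[2L],
                 zyx0[3L] + steps * dir[1L])
    prof <- interp3(vol, pts)
    below <- which(prof < thresh)
    if (length(below) > 0L && below[1L] > 1L) {
      j <- below[1L]
      frac <- (prof[j - 1L] - thresh) / (prof[j - 1L] - prof[j])
      crossings[i] <- steps[j - 1L] + frac * 0.25
    }
  }
  list(crossings = crossings, dirs = dirs, center = center, stop = lv$stop,
       vox = vox)
}

# Refine a point onto the tube axis using ray symmetry: for each pair of
# opposite rays the midpoint of their crossings estimates the centre along
# that direction; average over pairs. Returns the refined position (um).
recenter_rays <- function(vol, point_um, tangent, params, n_pass = 2L) {
  p <- point_um
  for (pass in seq_len(n_pass)) {
    rs <- ray_scan(vol, p, tangent, params)
    if (rs$center < rs$stop) return(p)
    half <- length(rs$crossings) / 2
    r1 <- rs$crossings[seq_len(half)]
    r2 <- rs$crossings[half + seq_len(half)]
    ok <- !is.na(r1) & !is.na(r2)
    if (sum(ok) < half / 2) return(p)
    dpair <- rs$dirs[seq_len(half), , drop = FALSE][ok, , drop = FALSE]
    off <- 2 * colSums(((r1[ok] - r2[ok]) / 2) * dpair) / sum(ok)
    p <- p + off * rs$vox
    if (vnorm(off) < 0.01) break
  }
  p
}

#' Estimate the local tube radius by ray casting
#'
#' Casts `ray_count` evenly spaced rays in the plane orthogonal to the local
#' tangent; each ray's crossing is the first distance at which the
#' interpolated intensity falls below
#' `background + half_max_fraction * (center - background)`, located to
#' sub-voxel precision by linear interpolation between samples. The radius
#' is the median crossing distance.
#'
#' @param vol Normalized [volume()].
#' @param point_um Position in µm, `(x, y, z)`.
#' @param tangent Unit tangent, `(x, y, z)` components.
#' @param params [trace_params()].
#' @param max_radius_voxels Ray length limit.
#' @return Radius in µm.
#' @export
estimate_radius <- function(vol, point_um, tangent, params = trace_params(),
                            max_radius_voxels = 20) {
  lv <- threshold_levels(vol, params)
  vox <- voxel_um(vol)
  zyx0 <- c(point_um[3L], point_um[2L], point_um[1L]) / vox + 1
  center <- interp3(vol, matrix(zyx0, 1L))
  if (center < lv$stop) {
    abort("radius undefined: point intensity is below the stop threshold")
  }
  thresh <- lv$bg + params$half_max_fraction * (center - lv$bg)
  b <- orthobasis(unit(tangent))
  ang <- seq(0, 2 * pi, length.out = params$ray_count + 1L)[seq_len(params$ray_count)]
  steps <- seq(0, max_radius_voxels, by = 0.25)
  crossings <- rep(NA_real_, params$ray_count)
  for (i in seq_along(ang)) {
    dir_um <- (cos(ang[i]) * b$u + sin(ang[i]) * b$w) * vox  # per 1-voxel step
    pts <- cbind(zyx0[1L] + steps * dir_um[3L] / vox,
                 zyx0[2L] + steps * dir_um[2L] / vox,
                 zyx0[3L] + steps * dir_um[1L] / vox)
    prof <- interp3(vol, pts)
    below <- which(prof < thresh)
    if (length(below) > 0L && below[1L] > 1L) {
      j <- below[1L]
      frac <- (prof[j - 1L] - thresh) / (prof[j - 1L] - prof[j])
      crossings[i] <- steps[j - 1L] + frac * 0.25
    }
  }
  ok <- !is.na(crossings)
  if (sum(ok) < params$ray_count / 2) {
    abort("radius undefined: most rays found no boundary crossing")
  }
  median(crossings[ok]) * vox
}

# single-direction march; returns a list of nodes (um positions + radii)
march <- function(vol, grad, gvf, p0_um, t0, params, visited, lv,
                  include_start = FALSE) {
  vox <- voxel_um(vol)
  d <- dim(vol)
  nodes <- list()
  p <- p0_um
  t <- t0
  last_radius <- vox
  if (include_start) {
    r0 <- tryCatch(estimate_radius(vol, p, t, params), error = function(e) NA)
    if (!is.na(r0)) last_radius <- r0
    nodes[[1L]] <- c(p, last_radius)
  }
  for (k in seq_len(params$max_nodes)) {
    p_new <- p + params$step_voxels * vox * t
    # re-center along the GVF component orthogonal to the tangent
    for (it in 1:10) {
      zyx <- c(p_new[3L], p_new[2L], p_new[1L]) / vox + 1
      u <- c(interp3(gvf$ux, matrix(zyx, 1L)),
             interp3(gvf$uy, matrix(zyx, 1L)),
             interp3(gvf$uz, matrix(zyx, 1L)))
      u_perp <- u - sum(u * t) * t
      shift_vox <- 0.3 * u_perp
      if (vnorm(shift_vox) < params$recenter_tol) break
      p_new <- p_new + shift_vox * vox
    }
    zyx <- c(p_new[3L], p_new[2L], p_new[1L]) / vox + 1
    if (any(zyx < 1.5) || any(zyx > d - 0.5)) break
    if (interp3(vol, matrix(zyx, 1L)) < lv$stop) break
    # sub-voxel refinement from ray symmetry in the orthogonal plane
    p_new <- recenter_rays(vol, p_new, t, params)
    zyx <- c(p_new[3L], p_new[2L], p_new[1L]) / vox + 1
    if (any(zyx < 1.5) || any(zyx > d - 0.5)) break
    vi <- round(zyx)
    if (visited[vi[1L], vi[2L], vi[3L]]) break
    r <- tryCatch(estimate_radius(vol, p_new, t, params),
                  error = function(e) NA)
    if (!is.na(r)) last_radius <- r
    nodes[[length(nodes) + 1L]] <- c(p_new, last_radius)
    t_new <- local_tangent(grad, zyx)
    if (!is.null(t_new)) {
      if (sum(t_new * t) < 0) t_new <- -t_new
      t <- unit(0.5 * t + 0.5 * t_new)
    }
    p <- p_new
  }
  nodes
}

#' Trace one constituent from a seed
#'
#' Bidirectional march from a seed voxel: the tangent is initialized as the
#' least-variance eigenvector of the local Sobel-gradient covariance (5^3
#' window); each step advances `step_voxels` along the tangent and then
#' re-centers by moving along the GVF direction component orthogonal to the
#' tangent (up to 10 corrections, until the proposed shift drops below
#' `recenter_tol` voxels). One node (position, ray-cast radius) is emitted
#' per step. The march stops at the stop-intensity threshold, the volume
#' boundary, `max_nodes`, or on entering the visited mask.
#'
#' @param vol Normalized [volume()].
#' @param grad A `gradient_field`.
#' @param gvf A `gvf_field`.
#' @param seed Length-3 integer voxel index `(z, y, x)` (one row of
#'   [detect_seeds()] output).
#' @param params [trace_params()].
#' @param visited Logical array of already-claimed voxels (same shape).
#' @return A [polyline()] of traced nodes (µm), or `NULL` when the seed is
#'   rejected (inside the visited mask, degenerate tangent, or fewer than
#'   `min_nodes` nodes).
#' @export
trace_constituent <- function(vol, grad, gvf, seed, params = trace_params(),
                              visited = NULL) {
  d <- dim(vol)
  if (is.null(visited)) visited <- array(FALSE, d)
  seed <- as.integer(seed)
  if (visited[seed[1L], seed[2L], seed[3L]]) return(NULL)
  lv <- threshold_levels(vol, params)
  vox <- voxel_um(vol)
  t0 <- local_tangent(grad, seed)
  if (is.null(t0)) return(NULL)  # degenerate tangent: trace abandoned
  p0 <- c(seed[3L] - 1L, seed[2L] - 1L, seed[1L] - 1L) * vox  # (x,y,z) um
  fwd <- march(vol, grad, gvf, p0, t0, params, visited, lv,
               include_start = TRUE)
  bwd <- march(vol, grad, gvf, p0, -t0, params, visited, lv)
  nodes <- c(rev(bwd), fwd)
  if (length(nodes) < params$min_nodes) return(NULL)
  m <- do.call(rbind, nodes)
  m <- smooth_chain(m, params$smooth_window)
  # drop rare duplicate positions created by aggressive re-centering
  keep <- c(TRUE, sqrt(rowSums(diff(m[, 1:3, drop = FALSE])^2)) > 1e-9)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < params$min_nodes) return(NULL)
  polyline(m[, 1:3], m[, 4L])
}

# Centered moving average of node positions and radii with a window that
# shrinks near the chain ends (endpoints keep their traced position scale).
smooth_chain <- function(m, window) {
  if (window <= 1L || nrow(m) < 3L) return(m)
  half <- (window - 1L) %/% 2L
  n <- nrow(m)
  out <- m
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    if (h == 0L) next
    out[i, ] <- colMeans(m[(i - h):(i + h), , drop = FALSE])
  }
  out
}

mark_visited <- function(visited, pl, vox) {
  d <- dim(visited)
  p_idx <- cbind(pl$z, pl$y, pl$x) / vox + 1
  r_vox <- pl$radius / vox
  for (i in seq_len(nrow(p_idx))) {
    rv <- r_vox[i] + 1
    lo <- pmax(1L, floor(p_idx[i, ] - rv))
    hi <- pmin(d, ceiling(p_idx[i, ] + rv))
    if (any(lo > hi)) next
    zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
    dist <- sqrt(outer(outer((zi - p_idx[i, 1L])^2,
                             (yi - p_idx[i, 2L])^2, "+"),
                       (xi - p_idx[i, 3L])^2, "+"))
    blk <- visited[zi, yi, xi, drop = FALSE]
    blk[dist <= rv] <- TRUE
    visited[zi, yi, xi] <- blk
  }
  visited
}

#' Trace a full structural model from a volume
#'
#' Greedy loop over detected seeds: each accepted trace claims its voxels in
#' the visited mask (dilated by the local radius) so later seeds inside
#' already-traced tubes are skipped. Traces are then classified: a trace
#' whose path length is at most `spine_cutoff_um` and whose end lies within
#' (local parent radius + 2 voxels) of a neurite node becomes a spine
#' attached at the nearest parent node; everything else is a neurite.
#'
#' @param vol A [volume()]; normalized automatically when needed.
#' @param params [trace_params()].
#' @param metadata Metadata list attached to the model (dataset, case, ...).
#' @return A [node_model()]; empty when nothing is traceable.
#' @export
trace_model <- function(vol, params = trace_params(), metadata = list()) {
  if (is.null(attr(vol, "normalized"))) {
    vol <- normalize_volume(vol)$volume
  }
  vox <- voxel_um(vol)
  grad <- sobel3d(vol)
  gvf <- compute_gvf(grad, mu = params$gvf_mu, n_iter = params$gvf_iter)
  seeds <- detect_seeds(vol, gvf, params)
  # greedy order: thickest structures first, so trunks are traced before the
  # short lateral processes that branch off them
  if (nrow(seeds) > 0L) {
    rad <- vapply(seq_len(nrow(seeds)), function(i) {
      zyx <- c(seeds$z[i], seeds$y[i], seeds$x[i])
      tg <- local_tangent(grad, zyx)
      if (is.null(tg)) return(0)
      p_um <- c(zyx[3L] - 1L, zyx[2L] - 1L, zyx[1L] - 1L) * vox
      rs <- ray_scan(vol, p_um, tg, params)
      med <- median(rs$crossings, na.rm = TRUE)
      if (is.na(med)) 0 else med
    }, numeric(1))
    seeds <- seeds[order(-rad, -seeds$intensity, seeds$z, seeds$y, seeds$x), ]
  }
  visited <- array(FALSE, dim(vol))
  traces <- list()
  for (i in seq_len(nrow(seeds))) {
    sd_i <- c(seeds$z[i], seeds$y[i], seeds$x[i])
    if (visited[sd_i[1L], sd_i[2L], sd_i[3L]]) next
    pl <- trace_constituent(vol, grad, gvf, sd_i, params, visited)
    if (is.null(pl)) next
    visited <- mark_visited(visited, pl, vox)
    traces[[length(traces) + 1L]] <- pl
  }
  if (length(traces) == 0L) {
    return(node_model(list(), metadata = c(metadata, list(
      provenance = provenance_string(params)))))
  }
  lens <- vapply(traces, polyline_length, numeric(1))
  ord <- order(-lens)
  traces <- traces[ord]; lens <- lens[ord]
  is_neurite <- lens > params$spine_cutoff_um
  # at least one neurite so short lone tubes in sparse volumes stay neurites
  if (!any(is_neurite)) is_neurite[1L] <- TRUE

  neurites <- traces[is_neurite]
  spine_cands <- traces[!is_neurite]
  spines <- list()
  for (pl in spine_cands) {
    ends <- polyline_points(pl)[c(1L, nrow(pl)), , drop = FALSE]
    best <- NULL
    for (j in seq_along(neurites)) {
      pp <- polyline_points(neurites[[j]])
      for (e in 1:2) {
        d2 <- colSums((t(pp) - ends[e, ])^2)
        nearest <- which.min(d2)
        # allowance: parent radius, the 1-voxel visited-mask dilation, one
        # march step (the first unclaimed node sits up to a step beyond the
        # mask), plus a voxel of slack
        tol <- neurites[[j]]$radius[nearest] +
          (2 + params$step_voxels) * vox
        dist <- sqrt(d2[nearest])
        if (dist <= tol && (is.null(best) || dist < best$dist)) {
          best <- list(parent = j, node = nearest, end = e, dist = dist)
        }
      }
    }
    if (is.null(best)) {
      neurites[[length(neurites) + 1L]] <- pl
    } else {
      if (best$end == 2L) pl <- pl[rev(seq_len(nrow(pl))), ]
      spines[[length(spines) + 1L]] <-
        list(pl = pl, parent = best$parent, node = best$node)
    }
  }
  cons <- purrr::imap(neurites, function(pl, j) {
    list(id = sprintf("N%03d", j), type = "neurite",
         nodes = pl, attachment = NULL)
  })
  cons <- c(cons, purrr::imap(spines, function(sp, k) {
    list(id = sprintf("S%03d", k), type = "spine",
         nodes = polyline(polyline_points(sp$pl), sp$pl$radius),
         attachment = list(parent_id = sprintf("N%03d", sp$parent),
                           parent_node = sp$node))
  }))
  node_model(cons, metadata = c(metadata, list(
    provenance = provenance_string(params))))
}

provenance_string <- function(params) {
  sprintf("tracer seed_thr=%g stop_thr=%g step=%g mu=%g iter=%d",
          params$seed_threshold, params$stop_threshold, params$step_voxels,
          params$gvf_mu, params$gvf_iter)
}
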