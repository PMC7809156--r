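#' Specify a synthetic tubular phantom volume
#'
#' A phantom emulates the contrast of Golgi-stained tissue in nanotomography:
#' bright tubular foreground on a dark background with additive Gaussian
#' noise. Curves are given as polylines with per-node thickness radii.
#'
#' @param shape Volume shape in voxels, length 3, (z, y, x) order.
#' @param voxel_size_nm Isotropic voxel size in nanometres.
#' @param curves List of curve entries: `list(polyline, type, id, parent_id,
#'   parent_index)`; `type` defaults to `"neurite"`, attachment fields are
#'   only meaningful for spines.
#' @param foreground,background Intensity levels (foreground > background),
#'   kept inside `[0, 1]` so rendered volumes are directly writable.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed for the noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), voxel_size_nm = 100,
                         curves = list(), foreground = 0.8, background = 0.1,
                         noise_sd = 0, seed = 1L) {
  if (voxel_size_nm <= 0) abort("voxel size must be positive")
  if (foreground <= background) abort("foreground must exceed background")
  if (noise_sd < 0) abort("noise sd must be >= 0")
  if (length(shape) != 3L || any(shape < 1L)) abort("shape must be 3 positive extents")
  curves <- purrr::map(curves, function(cv) {
    if (inherits(cv, "neuro_polyline")) cv <- list(polyline = cv)
    cv$type <- cv$type %||% "neurite"
    cv
  })
  extent <- (shape - 1L) * voxel_size_nm / 1000  # (z, y, x) um
  for (cv in curves) {
    p <- polyline_points(cv$polyline)
    if (any(p < -1e-9) ||
        any(p[, 1L] > extent[3L] + 1e-9) ||
        any(p[, 2L] > extent[2L] + 1e-9) ||
        any(p[, 3L] > extent[1L] + 1e-9)) {
      abort("curve extends outside the physical volume extent")
    }
  }
  structure(list(shape = as.integer(shape), voxel_size_nm = voxel_size_nm,
                 curves = curves, foreground = foreground,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Render a phantom specification into a volume plus ground truth
#'
#' Voxel values are `background + (foreground - background) * s + noise`,
#' where the soft tube indicator `s` falls linearly from 1 to 0 over one
#' voxel centred at the local tube radius (partial-volume blur, giving the
#' tracer sub-voxel information as in real tomograms). The ground-truth node
#' model contains the same curves resampled at ~2-voxel node spacing, with
#' spine attachments resolved to the nearest parent node.
#'
#' @param spec A [phantom_spec()].
#' @param node_spacing_voxels Ground-truth model node spacing (default 2).
#' @return A list: `volume` (a [volume()]) and `model` (a [node_model()]).
#' @export
render_volume <- function(spec, node_spacing_voxels = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  vox <- spec$voxel_size_nm / 1000  # um per voxel
  ind <- array(0, d)
  for (cv in spec$curves) {
    pl <- resample_polyline(cv$polyline, vox / 2)  # ~0.5 voxel point spacing
    p_idx <- cbind(pl$z, pl$y, pl$x) / vox + 1     # (z,y,x) voxel coords
    r_vox <- pl$radius / vox
    for (i in seq_len(nrow(p_idx))) {
      c0 <- p_idx[i, ]
      rv <- r_vox[i]
      lo <- pmax(1L, floor(c0 - rv - 1.5))
      hi <- pmin(d, ceiling(c0 + rv + 1.5))
      if (any(lo > hi)) next
      zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
      dz2 <- (zi - c0[1L])^2
      dy2 <- (yi - c0[2L])^2
      dx2 <- (xi - c0[3L])^2
      dist <- sqrt(outer(outer(dz2, dy2, "+"), dx2, "+"))
      s <- pmin(1, pmax(0, rv + 0.5 - dist))
      blk <- ind[zi, yi, xi, drop = FALSE]
      upd <- s > blk
      if (any(upd)) {
        blk[upd] <- s[upd]
        ind[zi, yi, xi] <- blk
      }
    }
  }
  dat <- spec$background + (spec$foreground - spec$background) * ind
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed,
                              array(rnorm(prod(d), sd = spec$noise_sd), d))
    dat <- dat + noise
  }
  dat <- pmin(1, pmax(0, dat))  # detector range; keeps volumes writable
  vol <- volume(array(dat, d), spec$voxel_size_nm)

  cons <- list()
  ids <- character(length(spec$curves))
  for (i in seq_along(spec$curves)) {
    cv <- spec$curves[[i]]
    ids[i] <- cv$id %||% sprintf("%s%02d", toupper(substr(cv$type, 1, 1)), i)
    gt <- resample_polyline(cv$polyline, node_spacing_voxels * vox)
    cons[[i]] <- list(id = ids[i], type = cv$type, nodes = gt,
                      attachment = NULL)
  }
  for (i in seq_along(spec$curves)) {
    cv <- spec$curves[[i]]
    if (identical(cv$type, "spine") && !is.null(cv$parent_id)) {
      j <- match(cv$parent_id, ids)
      if (!is.na(j)) {
        pp <- polyline_points(cons[[j]]$nodes)
        head_pt <- as.double(cons[[i]]$nodes[1L, c("x", "y", "z")])
        k <- which.min(colSums((t(pp) - head_pt)^2))
        cons[[i]]$attachment <- list(parent_id = ids[j], parent_node = k)
      }
    }
  }
  model <- node_model(cons, metadata = list(
    provenance = sprintf("phantom seed=%d noise_sd=%g", spec$seed,
                         spec$noise_sd)))
  list(volume = vol, model = model)
}
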