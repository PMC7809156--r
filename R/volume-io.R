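# Volume container and TIFF I/O.
#
# Axis order is fixed as (z, y, x): a volume is a 3D array indexed
# [z, y, x], and physical coordinates in micrometres are
# (index - 1) * voxel_size_nm / 1000 + origin, so the first voxel centre
# sits at the origin. One convention shared by tracing, models, rendering.

#' Construct a 3D volume with voxel-size metadata
#'
#' @param data 3D numeric array in (z, y, x) axis order.
#' @param voxel_size_nm Isotropic voxel size in nanometres (> 0).
#' @param origin Physical offset of the first voxel centre, µm (length 3,
#'   (z, y, x) order).
#' @return A `neuro_volume`: the array with `voxel_size_nm` and `origin`
#'   attributes.
#' @export
volume <- function(data, voxel_size_nm, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) abort("volume data must be a 3D array")
  if (!is.numeric(voxel_size_nm) || voxel_size_nm <= 0) {
    abort("voxel size must be a positive number of nanometres")
  }
  if (!all(is.finite(data))) abort("volume values must be finite")
  structure(data, voxel_size_nm = as.double(voxel_size_nm),
            origin = as.double(origin), class = "neuro_volume")
}

#' @export
print.neuro_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<neuro_volume> %d x %d x %d (z,y,x), voxel %.1f nm, range [%.4g, %.4g]\n",
              d[1L], d[2L], d[3L], attr(x, "voxel_size_nm"),
              min(x), max(x)))
  invisible(x)
}

voxel_um <- function(vol) attr(vol, "voxel_size_nm") / 1000

# index (1-based, (z,y,x)) <-> physical um; `idx` may be an n x 3 matrix
index_to_um <- function(vol, idx) {
  (idx - 1) * voxel_um(vol) + rep(attr(vol, "origin"), each = NROW(idx))
}
um_to_index <- function(vol, pos) {
  (pos - rep(attr(vol, "origin"), each = NROW(pos))) / voxel_um(vol) + 1
}

#' Read a 3D volume from TIFF
#'
#' Accepts either a multipage TIFF file or a directory of equally-sized
#' single-slice TIFF files, stacked along z in lexicographic filename order.
#'
#' @param path Multipage TIFF file or slice directory.
#' @param voxel_size_nm Isotropic voxel size in nanometres. For multipage
#'   files written by [write_volume()] this may be omitted: it is recovered
#'   from the JSON metadata sidecar written alongside the TIFF.
#' @return A [volume()].
#' @export
read_volume <- function(path, voxel_size_nm = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) abort(sprintf("no TIFF slices found in %s", path))
    slices <- purrr::map(files, function(f) {
      s <- tiff::readTIFF(f)
      if (length(dim(s)) == 3L) s <- s[, , 1L]
      s
    })
    shp <- dim(slices[[1L]])
    for (i in seq_along(slices)) {
      if (!identical(dim(slices[[i]]), shp)) {
        abort(sprintf("slice %s has shape %s; expected %s",
                      basename(files[[i]]),
                      paste(dim(slices[[i]]), collapse = "x"),
                      paste(shp, collapse = "x")))
      }
    }
    dat <- aperm(simplify2array(slices), c(3L, 1L, 2L))  # (z, y, x)
    if (is.null(voxel_size_nm)) abort("voxel_size_nm required for slice directories")
    return(volume(dat, voxel_size_nm))
  }
  if (!file.exists(path)) abort(sprintf("no such volume: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  origin <- c(0, 0, 0)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(voxel_size_nm)) voxel_size_nm <- meta$voxel_size_nm
    if (!is.null(meta$origin)) origin <- as.double(meta$origin)
  }
  if (is.null(voxel_size_nm)) {
    abort("voxel_size_nm not given and no metadata sidecar found")
  }
  pages <- purrr::map(pages, function(s) {
    if (length(dim(s)) == 3L) s[, , 1L] else s
  })
  shp <- dim(pages[[1L]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), shp)) {
      abort(sprintf("page %d has shape %s; expected %s", i,
                    paste(dim(pages[[i]]), collapse = "x"),
                    paste(shp, collapse = "x")))
    }
  }
  dat <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  volume(dat, voxel_size_nm, origin)
}

#' Write a volume as a multipage TIFF
#'
#' Values are stored as 32-bit float pages and must lie in `[0, 1]` (the
#' range float TIFF pages carry); normalize first for raw-count data. The
#' voxel size and origin are recorded in a JSON metadata sidecar
#' `<path>.meta.json`, which [read_volume()] picks up automatically.
#'
#' @param vol A [volume()] with values in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "neuro_volume"))
  d <- dim(vol)
  if (any(d == 0L) || length(vol) == 0L) abort("cannot write an empty volume")
  if (min(vol) < 0 || max(vol) > 1) {
    abort("write_volume stores float pages in [0, 1]; normalize first")
  }
  pages <- purrr::map(seq_len(d[1L]), function(z) {
    matrix(vol[z, , ], nrow = d[2L], ncol = d[3L])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(
    list(voxel_size_nm = attr(vol, "voxel_size_nm"),
         origin = attr(vol, "origin")),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Normalize a volume to [0, 1] and report raw-intensity statistics
#'
#' Affine rescale of the voxel values to `[0, 1]`. The pre-scale global mean
#' and population standard deviation are returned (and attached to the
#' volume) so thresholds expressed in sigma units of the raw voxel-value
#' distribution remain computable, following the convention of contouring
#' tomograms at multiples of the voxel-value sigma. The background level is
#' estimated as the mean of voxels below the global median, since stained
#' structures are sparse and bright.
#'
#' @param vol A [volume()]; must not be constant.
#' @return A list: `volume` (normalized, with `background`, `sigma` in
#'   normalized units as attributes), `mean` and `sd` (raw values),
#'   `background` (raw background mean).
#' @export
normalize_volume <- function(vol) {
  stopifnot(inherits(vol, "neuro_volume"))
  v <- as.double(vol)
  rng <- range(v)
  if (diff(rng) == 0) abort("cannot normalize a constant volume")
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))  # population sd
  bg <- mean(v[v < median(v)])
  if (!is.finite(bg)) bg <- rng[1L]
  scaled <- (vol - rng[1L]) / diff(rng)
  out <- volume(array(scaled, dim(vol)), attr(vol, "voxel_size_nm"),
                attr(vol, "origin"))
  attr(out, "background") <- (bg - rng[1L]) / diff(rng)
  attr(out, "sigma") <- sdv / diff(rng)
  attr(out, "normalized") <- TRUE
  list(volume = out, mean = mu, sd = sdv, background = bg)
}
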