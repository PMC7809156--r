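#' Menger curvature profile of a polyline
#'
#' Discrete curvature at each interior node as the reciprocal circumradius of
#' the circle through the node and its two neighbours (Menger curvature):
#' \deqn{\kappa_i = \frac{4 A_i}{|p_i - p_{i-1}|\,|p_{i+1} - p_i|\,|p_{i+1} - p_{i-1}|}}
#' where \eqn{A_i} is the area of the triangle spanned by the three points.
#' Exact on circles, parameter-free, and zero for collinear triples.
#'
#' @param pl A polyline or data frame with `x`, `y`, `z` in µm (>= 3 distinct
#'   nodes; nodes closer than 1e-6 µm are merged first).
#' @return Numeric vector of curvatures (µm^-1), one per interior node
#'   (length `n - 2`).
#' @examples
#' circ <- make_parametric_curve("circle", list(a = 2), 100)
#' range(curvature_profile(circ))  # all 0.5
#' @export
curvature_profile <- function(pl) {
  p <- dedupe_points(pl)
  n <- nrow(p)
  if (n < 3L) abort("curvature needs >= 3 distinct nodes")
  a <- p[1:(n - 2L), , drop = FALSE]
  b <- p[2:(n - 1L), , drop = FALSE]
  d <- p[3:n, , drop = FALSE]
  e1 <- b - a
  e2 <- d - b
  e3 <- d - a
  cr <- cbind(
    e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
    e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
    e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  )
  area2 <- sqrt(rowSums(cr^2))  # twice the triangle area
  denom <- sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)) * sqrt(rowSums(e3^2))
  2 * area2 / denom
}

#' Signed torsion profile of a polyline
#'
#' Discrete torsion from the rotation of the binormal between consecutive
#' interior nodes. With edges \eqn{e_i = p_{i+1} - p_i} and unit binormals
#' \eqn{b_i = (e_{i-1} \times e_i)/|e_{i-1} \times e_i|}, the torsion
#' attributed to edge \eqn{i} is \eqn{\tau_i = \theta_i / |e_i|} where
#' \eqn{\theta_i} is the angle between \eqn{b_i} and \eqn{b_{i+1}}, signed by
#' \eqn{(b_i \times b_{i+1}) \cdot \hat e_i}. A right-handed helix gives
#' positive torsion; planar curves give zero. Edges flanked by a degenerate
#' (collinear) triple have undefined binormals and yield `NA`, which the
#' averaging step excludes.
#'
#' @inheritParams curvature_profile
#' @return Numeric vector of signed torsions (µm^-1), length `n - 3`
#'   (possibly containing `NA` at degenerate edges).
#' @export
torsion_profile <- function(pl) {
  p <- dedupe_points(pl)
  n <- nrow(p)
  if (n < 4L) abort("torsion needs >= 4 distinct nodes")
  e <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]  # edges 1..n-1
  en <- sqrt(rowSums(e^2))
  # binormal at interior node i lives at row i-1: cross(e_{i-1}, e_i)
  m <- n - 2L
  bx <- e[1:m, 2L] * e[2:(m + 1L), 3L] - e[1:m, 3L] * e[2:(m + 1L), 2L]
  by <- e[1:m, 3L] * e[2:(m + 1L), 1L] - e[1:m, 1L] * e[2:(m + 1L), 3L]
  bz <- e[1:m, 1L] * e[2:(m + 1L), 2L] - e[1:m, 2L] * e[2:(m + 1L), 1L]
  b <- cbind(bx, by, bz)
  bnorm <- sqrt(rowSums(b^2))
  ok <- bnorm > 1e-12
  b <- b / pmax(bnorm, 1e-300)
  # consecutive binormal pairs (b_i, b_{i+1}) sit on edge i+1 (edges e_2..e_{n-2})
  b1 <- b[1:(m - 1L), , drop = FALSE]
  b2 <- b[2:m, , drop = FALSE]
  # binormals are lines, not vectors: at an in-plane inflection the discrete
  # binormal flips sign; re-orient so planar curves read zero torsion
  flip <- rowSums(b1 * b2) < 0
  b2[flip, ] <- -b2[flip, , drop = FALSE]
  dotp <- pmin(1, pmax(-1, rowSums(b1 * b2)))
  theta <- acos(dotp)
  cx <- cbind(
    b1[, 2L] * b2[, 3L] - b1[, 3L] * b2[, 2L],
    b1[, 3L] * b2[, 1L] - b1[, 1L] * b2[, 3L],
    b1[, 1L] * b2[, 2L] - b1[, 2L] * b2[, 1L]
  )
  eidx <- 2:(n - 2L)
  sgn <- sign(rowSums(cx * (e[eidx, , drop = FALSE] / en[eidx])))
  sgn[sgn == 0] <- 1
  tau <- sgn * theta / en[eidx]
  tau[!(ok[1:(m - 1L)] & ok[2:m])] <- NA_real_
  tau
}

dedupe_points <- function(pl, tol = 1e-6) {
  p <- if (is.data.frame(pl)) cbind(pl$x, pl$y, pl$z) else matrix(pl, ncol = 3L)
  if (nrow(p) < 2L) return(p)
  keep <- c(TRUE, sqrt(rowSums(diff(p)^2)) > tol)
  p[keep, , drop = FALSE]
}

#' Per-node and per-edge geometry of a polyline
#'
#' Bundles curvature, torsion, and edge arc lengths, the pieces from which
#' constituent-level averages are formed. For `n` nodes there are `n - 2`
#' curvatures, `n - 3` torsions, and `n - 1` edges.
#'
#' @inheritParams curvature_profile
#' @return A list with `curvature`, `torsion`, `edge_length` (µm).
#' @export
curve_geometry <- function(pl) {
  p <- dedupe_points(pl)
  n <- nrow(p)
  list(
    curvature = if (n >= 3L) curvature_profile(pl) else NULL,
    torsion = if (n >= 4L) torsion_profile(pl) else NULL,
    edge_length = sqrt(rowSums(diff(p)^2))
  )
}

# Arc-length weights for interior-node quantities: mean of adjacent edges.
interior_weights <- function(edge) {
  (edge[-length(edge)] + edge[-1L]) / 2
}

# Arc-length weights for all nodes (endpoints carry half their single edge).
node_weights <- function(edge) {
  (c(edge, 0) + c(0, edge)) / 2
}

#' Summarise the geometry of one structural constituent
#'
#' Computes the per-constituent scalars that drive all downstream statistics:
#' arc-length-weighted mean curvature and mean (signed) torsion,
#' arc-length-weighted mean thickness radius, path length, and for spines the
#' spine length including the segment from the parent attachment node to the
#' spine's first node. Arc-length weighting (rather than a plain node mean)
#' keeps the averages robust to uneven node spacing from tracing; set
#' `weighting = "node"` for the plain-mean sensitivity check.
#'
#' @param constituent A constituent list as stored in a [node_model()]:
#'   `list(id, type, nodes, attachment)` where `nodes` is a polyline-like
#'   tibble. A bare polyline is accepted and treated as a neurite.
#' @param parent_node Optional parent-node position (µm, length-3) used to
#'   extend the spine length by the attachment segment.
#' @param weighting `"arc"` (default) or `"node"`.
#' @return One-row tibble: `type`, `n_nodes`, `length_um`,
#'   `mean_curvature`, `mean_torsion`, `mean_radius`, `spine_length_um`
#'   (`NA` for non-spines). Statistics needing more nodes than available are
#'   `NA`, the rest are still computed.
#' @export
constituent_geometry <- function(constituent, parent_node = NULL,
                                 weighting = c("arc", "node")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(constituent)) {
    constituent <- list(id = NA_character_, type = "neurite",
                        nodes = constituent, attachment = NULL)
  }
  nodes <- dedupe_polyline(constituent$nodes)
  p <- polyline_points(nodes)
  n <- nrow(p)
  edge <- sqrt(rowSums(diff(p)^2))
  len <- sum(edge)
  wk <- if (weighting == "arc") interior_weights(edge) else NULL

  mean_k <- NA_real_
  if (n >= 3L) {
    k <- curvature_profile(nodes)
    mean_k <- if (weighting == "arc") sum(k * wk) / sum(wk) else mean(k)
  }
  mean_t <- NA_real_
  if (n >= 4L) {
    tau <- torsion_profile(nodes)
    wt <- if (weighting == "arc") edge[2:(n - 2L)] else rep(1, length(tau))
    ok <- !is.na(tau)
    if (any(ok)) {
      mean_t <- sum(tau[ok] * wt[ok]) / sum(wt[ok])
    } else if (!is.na(mean_k) && mean_k < 1e-12) {
      mean_t <- 0  # exactly straight chain: planar, so torsion is zero
    }
  }
  mean_r <- if (n >= 2L) {
    wr <- if (weighting == "arc") node_weights(edge) else rep(1, n)
    sum(nodes$radius * wr) / sum(wr)
  } else {
    nodes$radius[[1L]]
  }

  spine_len <- NA_real_
  if (identical(constituent$type, "spine")) {
    spine_len <- len
    if (!is.null(parent_node)) {
      spine_len <- spine_len + vnorm(p[1L, ] - as.double(parent_node))
    }
  }
  tibble(
    type = constituent$type %||% "neurite",
    n_nodes = n,
    length_um = len,
    mean_curvature = mean_k,
    mean_torsion = mean_t,
    mean_radius = mean_r,
    spine_length_um = spine_len
  )
}

#' Geometry table of a node model
#'
#' One row per constituent with the metadata labels (dataset, case, group,
#' area) copied from the model, in deterministic order by constituent id.
#' This is the long table that all group-level statistics consume.
#'
#' @param model A [node_model()].
#' @param weighting Passed to [constituent_geometry()].
#' @return A tibble with columns `dataset`, `case`, `group`, `area`,
#'   `constituent_id`, `type`, `n_nodes`, `length_um`, `mean_curvature`,
#'   `mean_torsion`, `mean_radius`, `spine_length_um`.
#' @export
geometry_table <- function(model, weighting = "arc") {
  stopifnot(inherits(model, "neuro_model"))
  meta <- model$metadata
  cons <- model$constituents
  if (length(cons) == 0L) {
    return(tibble(
      dataset = character(), case = character(), group = character(),
      area = character(), constituent_id = character(), type = character(),
      n_nodes = integer(), length_um = double(), mean_curvature = double(),
      mean_torsion = double(), mean_radius = double(),
      spine_length_um = double()
    ))
  }
  ord <- order(vapply(cons, function(cc) cc$id, character(1)))
  rows <- purrr::map(cons[ord], function(cc) {
    pn <- NULL
    if (!is.null(cc$attachment)) {
      par <- model_constituent(model, cc$attachment$parent_id)
      if (!is.null(par)) {
        pn <- as.double(par$nodes[cc$attachment$parent_node,
                                  c("x", "y", "z")])
      }
    }
    g <- constituent_geometry(cc, parent_node = pn, weighting = weighting)
    dplyr::bind_cols(tibble(constituent_id = cc$id), g)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(
    tibble(
      dataset = rep(meta$dataset %||% NA_character_, nrow(out)),
      case = rep(meta$case %||% NA_character_, nrow(out)),
      group = rep(meta$group %||% NA_character_, nrow(out)),
      area = rep(meta$area %||% NA_character_, nrow(out))
    ),
    out
  )
}
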