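CONSTITUENT_TYPES <- c("neurite", "apical_dendrite", "spine", "soma", "vessel")
RESNAME_OF_TYPE <- c(neurite = "NEU", apical_dendrite = "APD", spine = "SPI",
                     soma = "SOM", vessel = "VES")
TYPE_OF_RESNAME <- setNames(names(RESNAME_OF_TYPE), RESNAME_OF_TYPE)

#' Construct a structural node model
#'
#' A node model is the coordinate representation of a traced tissue volume: a
#' set of typed constituents (neurite, apical dendrite, spine, soma, vessel),
#' each an ordered chain of nodes carrying a position (µm) and a thickness
#' radius (µm). Spines carry an attachment to a parent constituent node.
#'
#' @param constituents List of constituents, each a list with elements `id`
#'   (unique string), `type` (one of the five types), `nodes` (a
#'   [polyline()] or data frame with `x`, `y`, `z`, `radius`), and optional
#'   `attachment = list(parent_id, parent_node)`.
#' @param metadata Named list; recognised keys `dataset`, `case`, `group`,
#'   `area`, `provenance`.
#' @return A `neuro_model` object.
#' @export
node_model <- function(constituents = list(), metadata = list()) {
  constituents <- purrr::map(constituents, function(cc) {
    stopifnot(!is.null(cc$id), !is.null(cc$nodes))
    cc$id <- as.character(cc$id)
    cc$type <- match.arg(cc$type %||% "neurite", CONSTITUENT_TYPES)
    if (!inherits(cc$nodes, "neuro_polyline")) {
      cc$nodes <- new_polyline(as.matrix(cc$nodes[, c("x", "y", "z")]),
                               cc$nodes$radius %||% 0.5, min_points = 1L)
    }
    cc
  })
  ids <- vapply(constituents, function(cc) cc$id, character(1))
  if (anyDuplicated(ids)) abort("constituent ids must be unique")
  structure(list(constituents = constituents, metadata = metadata),
            class = "neuro_model")
}

model_constituent <- function(model, id) {
  for (cc in model$constituents) if (cc$id == id) return(cc)
  NULL
}

#' @export
print.neuro_model <- function(x, ...) {
  types <- vapply(x$constituents, function(cc) cc$type, character(1))
  cat("<neuro_model> ", length(x$constituents), " constituents",
      if (length(types)) paste0(" (", paste(sprintf(
        "%s: %d", names(table(types)), as.integer(table(types))),
        collapse = ", "), ")"), "\n", sep = "")
  meta <- x$metadata
  if (length(meta)) {
    cat("  metadata: ",
        paste(names(meta), unlist(meta), sep = "=", collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Flatten a node model to a node table
#'
#' @param x A `neuro_model`.
#' @param ... Unused.
#' @return Tibble with one row per node: `constituent_id`, `type`, `node`,
#'   `x`, `y`, `z`, `radius`.
#' @export
as_tibble.neuro_model <- function(x, ...) {
  purrr::map_dfr(x$constituents, function(cc) {
    dplyr::bind_cols(
      tibble(constituent_id = cc$id, type = cc$type,
             node = seq_len(nrow(cc$nodes))),
      as_tibble(cc$nodes)[, c("x", "y", "z", "radius")]
    )
  })
}

#' Validate a node model
#'
#' Non-mutating invariant check: positive radii, resolvable attachments,
#' non-degenerate node spacing, spines attached, unique ids. Returns a report
#' rather than failing, so pipelines can log and decide.
#'
#' @param model A `neuro_model`.
#' @return A `neuro_validation` list: `violations` (tibble with
#'   `constituent_id`, `issue`), `counts` (tibble of constituents by type),
#'   `valid` (logical).
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "neuro_model"))
  viol <- list()
  note <- function(id, issue) {
    viol[[length(viol) + 1L]] <<- tibble(constituent_id = id, issue = issue)
  }
  ids <- vapply(model$constituents, function(cc) cc$id, character(1))
  for (d in unique(ids[duplicated(ids)])) note(d, "duplicate constituent id")
  for (cc in model$constituents) {
    nd <- cc$nodes
    if (nrow(nd) < 1L) note(cc$id, "constituent has no nodes")
    if (any(nd$radius <= 0)) note(cc$id, "non-positive node radius")
    p <- polyline_points(nd)
    if (nrow(p) >= 2L && any(sqrt(rowSums(diff(p)^2)) <= 1e-9)) {
      note(cc$id, "duplicate consecutive nodes")
    }
    if (identical(cc$type, "spine")) {
      if (is.null(cc$attachment)) {
        note(cc$id, "unattached spine")
      } else {
        par <- model_constituent(model, cc$attachment$parent_id)
        if (is.null(par)) {
          note(cc$id, "attachment parent not in model")
        } else if (cc$attachment$parent_node < 1L ||
                   cc$attachment$parent_node > nrow(par$nodes)) {
          note(cc$id, "attachment node index out of range")
        }
      }
    } else if (!is.null(cc$attachment)) {
      par <- model_constituent(model, cc$attachment$parent_id)
      if (is.null(par)) note(cc$id, "attachment parent not in model")
    }
  }
  types <- vapply(model$constituents, function(cc) cc$type, character(1))
  counts <- as_tibble(table(type = factor(types, levels = CONSTITUENT_TYPES)))
  names(counts) <- c("type", "n")
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble(constituent_id = character(), issue = character())
  structure(list(violations = violations, counts = counts,
                 valid = nrow(violations) == 0L),
            class = "neuro_validation")
}

#' @export
print.neuro_validation <- function(x, ...) {
  cat("<model validation> ", if (x$valid) "OK" else
    paste(nrow(x$violations), "violation(s)"), "\n", sep = "")
  if (!x$valid) print(x$violations)
  invisible(x)
}
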