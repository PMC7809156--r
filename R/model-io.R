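# Fixed-column PDB-dialect reader/writer for node models.
#
# Dialect summary (self-described in REMARK 300 headers):
#   * one ATOM record per node; serial = global 1-based counter; atom name C
#   * resName encodes constituent type (NEU/APD/SPI/SOM/VES)
#   * chainID cycles A-Z then 0-9 per constituent; resSeq = per-chain counter,
#     so (chainID, resSeq) identifies a constituent even past 36 chains
#   * coordinates carry micrometres (not Angstrom) in the 8.3 fields
#   * tempFactor carries the node thickness radius in micrometres (6.2)
#   * CONECT joins consecutive nodes of a constituent; a spine's first node
#     additionally CONECTs to its parent node
#   * REMARK 300 KEY=VALUE lines carry metadata; file ends with END

CHAIN_SYMBOLS <- c(LETTERS, as.character(0:9))

#' Write a node model to the fixed-column PDB dialect
#'
#' @param model A [node_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  stopifnot(inherits(model, "neuro_model"))
  lines <- character(0)
  meta <- model$metadata
  known <- c("dataset", "case", "group", "area", "provenance")
  extra <- setdiff(sort(names(meta)), known)
  header <- c("DIALECT=NEUROGEOM-1", "UNITS=UM", "RADIUS_FIELD=TEMPFACTOR")
  for (k in c(known, extra)) {
    if (!is.null(meta[[k]])) {
      header <- c(header, paste0(toupper(k), "=", as.character(meta[[k]])))
    }
  }
  lines <- c(lines, sprintf("REMARK 300 %s", header))

  ncon <- length(model$constituents)
  if (ncon > length(CHAIN_SYMBOLS)) {
    warn(sprintf("model has %d constituents; chain IDs reused beyond %d (resSeq disambiguates)",
                 ncon, length(CHAIN_SYMBOLS)))
  }
  serial0 <- integer(ncon)  # serial of each constituent's first node
  serial <- 0L
  atom_lines <- character(0)
  for (i in seq_len(ncon)) {
    cc <- model$constituents[[i]]
    chain <- CHAIN_SYMBOLS[((i - 1L) %% length(CHAIN_SYMBOLS)) + 1L]
    resseq <- ((i - 1L) %/% length(CHAIN_SYMBOLS)) + 1L
    res <- RESNAME_OF_TYPE[[cc$type]]
    nd <- cc$nodes
    if (any(abs(c(nd$x, nd$y, nd$z)) >= 10000) ||
        any(c(nd$x, nd$y, nd$z) <= -1000)) {
      abort(sprintf("constituent %s: coordinate overflows the fixed 8.3 field",
                    cc$id))
    }
    serial0[i] <- serial + 1L
    atom_lines <- c(atom_lines, sprintf(
      "ATOM  %5d  C   %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      serial + seq_len(nrow(nd)), res, chain, resseq,
      nd$x, nd$y, nd$z, 1.0, nd$radius))
    serial <- serial + nrow(nd)
  }
  lines <- c(lines, atom_lines)

  con_lines <- character(0)
  ids <- vapply(model$constituents, function(cc) cc$id, character(1))
  for (i in seq_len(ncon)) {
    cc <- model$constituents[[i]]
    if (!is.null(cc$attachment)) {
      j <- match(cc$attachment$parent_id, ids)
      if (is.na(j)) abort(sprintf("constituent %s: attachment parent %s not in model",
                                  cc$id, cc$attachment$parent_id))
      pser <- serial0[j] + cc$attachment$parent_node - 1L
      con_lines <- c(con_lines, sprintf("CONECT%5d%5d", serial0[i], pser))
    }
    nn <- nrow(cc$nodes)
    if (nn >= 2L) {
      s <- serial0[i] + seq_len(nn - 1L) - 1L
      con_lines <- c(con_lines, sprintf("CONECT%5d%5d", s, s + 1L))
    }
  }
  lines <- c(lines, con_lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a node model from the fixed-column PDB dialect
#'
#' Inverse of [write_model_pdb()]. Constituents are reconstructed from runs
#' of (chainID, resSeq); types from resName; radii from tempFactor; spine
#' attachments from CONECT records crossing constituents; metadata from
#' REMARK 300 lines. A file without CONECT records is accepted: each
#' (chainID, resSeq) run is one unbranched constituent.
#'
#' @param path File in the dialect written by [write_model_pdb()].
#' @return A [node_model()].
#' @export
read_model_pdb <- function(path) {
  lines <- readLines(path)
  meta <- list()
  atoms <- list()
  conect <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    rec <- substr(line, 1L, 6L)
    if (rec == "REMARK") {
      body <- sub("^REMARK 300 ", "", line)
      if (grepl("=", body, fixed = TRUE)) {
        key <- sub("=.*$", "", body)
        val <- sub("^[^=]*=", "", body)
        if (!key %in% c("DIALECT", "UNITS", "RADIUS_FIELD")) {
          meta[[tolower(key)]] <- val
        }
      }
    } else if (rec == "ATOM  ") {
      f <- function(a, b) substr(line, a, b)
      serial <- suppressWarnings(as.integer(f(7, 11)))
      res <- trimws(f(18, 20))
      chain <- f(22, 22)
      resseq <- suppressWarnings(as.integer(f(23, 26)))
      xyz <- suppressWarnings(as.numeric(c(f(31, 38), f(39, 46), f(47, 54))))
      radius <- suppressWarnings(as.numeric(f(61, 66)))
      if (is.na(serial) || is.na(resseq) || any(is.na(xyz)) || is.na(radius)) {
        abort(sprintf("malformed ATOM fixed columns at line %d: %s", ln, line))
      }
      if (!res %in% names(TYPE_OF_RESNAME)) {
        abort(sprintf("unknown resName '%s' at line %d: %s", res, ln, line))
      }
      atoms[[length(atoms) + 1L]] <- list(
        serial = serial, type = TYPE_OF_RESNAME[[res]], chain = chain,
        resseq = resseq, x = xyz[1L], y = xyz[2L], z = xyz[3L],
        radius = radius, lineno = ln)
    } else if (rec == "CONECT") {
      a <- suppressWarnings(as.integer(substr(line, 7L, 11L)))
      b <- suppressWarnings(as.integer(substr(line, 12L, 16L)))
      if (is.na(a) || is.na(b)) {
        abort(sprintf("malformed CONECT at line %d: %s", ln, line))
      }
      conect[[length(conect) + 1L]] <- c(a, b, ln)
    }
  }
  if (length(atoms) == 0L) {
    return(node_model(list(), metadata = meta))
  }
  at <- dplyr::bind_rows(purrr::map(atoms, as_tibble))
  at$key <- paste(at$chain, at$resseq, sep = "/")
  run <- cumsum(c(TRUE, at$key[-1L] != at$key[-nrow(at)]))

  serial_to <- list()  # serial -> c(constituent index, node index)
  cons <- list()
  for (r in unique(run)) {
    sub <- at[run == r, , drop = FALSE]
    type <- sub$type[[1L]]
    id <- sprintf("%s%d", sub$chain[[1L]], sub$resseq[[1L]])
    cons[[r]] <- list(id = id, type = type,
                      nodes = new_polyline(cbind(sub$x, sub$y, sub$z),
                                           sub$radius, min_points = 1L),
                      attachment = NULL)
    for (k in seq_len(nrow(sub))) serial_to[[as.character(sub$serial[[k]])]] <- c(r, k)
  }
  for (cn in conect) {
    ia <- serial_to[[as.character(cn[1L])]]
    ib <- serial_to[[as.character(cn[2L])]]
    if (is.null(ia) || is.null(ib)) {
      abort(sprintf("CONECT at line %d references unknown serial", cn[3L]))
    }
    if (ia[1L] != ib[1L]) {
      # crossing constituents: attachment; the child end must be a first node
      child <- if (ia[2L] == 1L) ia else ib
      parent <- if (ia[2L] == 1L) ib else ia
      cons[[child[1L]]]$attachment <- list(
        parent_id = cons[[parent[1L]]]$id, parent_node = parent[2L])
    }
  }
  node_model(cons, metadata = meta)
}

#' Export a node model to SWC
#'
#' SWC is the community standard for neuron morphology; this export maps
#' constituent types to SWC type codes (soma 1, neurite 2, apical dendrite 4,
#' spine 5, vessel 7) and links each spine's first node to its parent node.
#'
#' @param model A [node_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_swc <- function(model, path) {
  stopifnot(inherits(model, "neuro_model"))
  swc_type <- c(soma = 1L, neurite = 2L, apical_dendrite = 4L, spine = 5L,
                vessel = 7L)
  ids <- vapply(model$constituents, function(cc) cc$id, character(1))
  serial0 <- integer(length(ids))
  s <- 0L
  for (i in seq_along(ids)) {
    serial0[i] <- s + 1L
    s <- s + nrow(model$constituents[[i]]$nodes)
  }
  rows <- character(0)
  for (i in seq_along(ids)) {
    cc <- model$constituents[[i]]
    nd <- cc$nodes
    parent <- c(-1L, serial0[i] + seq_len(nrow(nd) - 1L) - 1L)
    if (!is.null(cc$attachment)) {
      j <- match(cc$attachment$parent_id, ids)
      parent[1L] <- serial0[j] + cc$attachment$parent_node - 1L
    }
    rows <- c(rows, sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                            serial0[i] + seq_len(nrow(nd)) - 1L,
                            swc_type[[cc$type]], nd$x, nd$y, nd$z, nd$radius,
                            parent))
  }
  writeLines(c("# SWC export (micrometre units); radius = thickness radius",
               rows), path)
  invisible(path)
}
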