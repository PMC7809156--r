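# End-to-end orchestration: config, blinded dataset codes, coverage check,
# tracing -> geometry -> statistics, with structured logging.

#' Assign blinded dataset codes
#'
#' Deterministic seeded permutation of opaque codes over dataset ids, so
#' model building and geometry extraction can run without case information;
#' decoding is the exact inverse.
#'
#' @param dataset_ids Unique character ids.
#' @param seed Integer seed.
#' @return A `blind_map` tibble with columns `dataset`, `code` and a `seed`
#'   attribute.
#' @export
assign_blind_codes <- function(dataset_ids, seed = 1L) {
  if (anyDuplicated(dataset_ids)) abort("dataset ids must be unique")
  n <- length(dataset_ids)
  perm <- withr::with_seed(as.integer(seed) %% 2147483647L, sample.int(n))
  out <- tibble(dataset = dataset_ids,
                code = sprintf("D%03d", perm))
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("blind_map", class(out))
  out
}

#' Decode blinded dataset codes
#'
#' @param codes Character codes.
#' @param map A `blind_map`.
#' @return The original dataset ids.
#' @export
decode_blind <- function(codes, map) {
  i <- match(codes, map$code)
  if (anyNA(i)) abort("unknown blind code(s)")
  map$dataset[i]
}

#' Check per-case neurite coverage
#'
#' Counts neurites (spines excluded) per case and flags cases whose
#' aggregated count falls below the threshold (strictly; a case with exactly
#' the threshold count is not flagged). Cases present in the case table but
#' absent from the geometry table count as zero.
#'
#' @param geometry Geometry table.
#' @param cases Case table (`dataset`, `case`, ...).
#' @param threshold Minimum aggregated neurite count (default 500).
#' @return Tibble: `case`, `n_neurites`, `flagged`.
#' @export
check_neurite_coverage <- function(geometry, cases, threshold = 500L) {
  counts <- geometry |>
    dplyr::filter(.data$type == "neurite") |>
    dplyr::select(-dplyr::any_of("case")) |>
    dplyr::left_join(dplyr::distinct(cases[, c("dataset", "case")]),
                     by = "dataset") |>
    dplyr::count(.data$case, name = "n_neurites")
  all_cases <- tibble(case = sort(unique(cases$case)))
  out <- dplyr::left_join(all_cases, counts, by = "case") |>
    dplyr::mutate(n_neurites = dplyr::coalesce(.data$n_neurites, 0L),
                  flagged = .data$n_neurites < threshold) |>
    dplyr::arrange(.data$case)
  out
}

#' Pipeline configuration
#'
#' @param volumes Tibble with columns `path` (TIFF file or slice directory),
#'   `dataset` (id resolvable in the case table), and optionally
#'   `voxel_size_nm`.
#' @param case_table Case table tibble (`dataset`, `case`, `group`, `area`)
#'   or path to a CSV with those columns.
#' @param params [trace_params()] or a named list of overrides.
#' @param parameters Morphometric parameters to analyse: a list of
#'   `list(name, column, type)` entries.
#' @param coverage_threshold Per-case neurite coverage threshold.
#' @param output_dir Output directory (created if missing).
#' @param seed Single integer seed; per-stage seeds derive from it via
#'   [derive_seeds()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(volumes, case_table, params = trace_params(),
                            parameters = default_parameters(),
                            coverage_threshold = 500L,
                            output_dir = tempfile("neurogeom-run-"),
                            seed = 1L) {
  if (is.character(case_table)) {
    case_table <- as_tibble(utils::read.csv(case_table,
                                            stringsAsFactors = FALSE))
  }
  if (!inherits(params, "trace_params")) {
    params <- do.call(trace_params, params)
  }
  volumes <- as_tibble(volumes)
  stopifnot(all(c("path", "dataset") %in% names(volumes)),
            all(c("dataset", "case", "group", "area") %in% names(case_table)))
  structure(list(volumes = volumes, case_table = as_tibble(case_table),
                 params = params, parameters = parameters,
                 coverage_threshold = coverage_threshold,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default analysis parameters for [run_pipeline()]
#'
#' Neurite curvature and radius (per-neurite means) and spine radius and
#' length (per-spine means).
#'
#' @return List of parameter descriptors.
#' @export
default_parameters <- function() {
  list(
    list(name = "neurite_curvature", column = "mean_curvature", type = "neurite"),
    list(name = "neurite_radius", column = "mean_radius", type = "neurite"),
    list(name = "spine_radius", column = "mean_radius", type = "spine"),
    list(name = "spine_length", column = "spine_length_um", type = "spine")
  )
}

#' Read / write a pipeline configuration file
#'
#' Flat-key YAML or JSON (by file extension). Paths are kept verbatim.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    volumes = as_tibble(raw$volumes),
    case_table = raw$case_table_path %||% as_tibble(raw$case_table),
    params = raw$params %||% trace_params(),
    coverage_threshold = raw$coverage_threshold %||% 500L,
    output_dir = raw$output_dir %||% tempfile("neurogeom-run-"),
    seed = raw$seed %||% 1L)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- list(volumes = as.data.frame(config$volumes),
              case_table = as.data.frame(config$case_table),
              params = unclass(config$params),
              coverage_threshold = config$coverage_threshold,
              output_dir = config$output_dir,
              seed = config$seed)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(lst, path) else
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full tracing-to-statistics pipeline
#'
#' For each configured volume: read, normalize, trace a structural model,
#' write it in the PDB dialect (under a blinded dataset code), and extract
#' the geometry table. Tables are concatenated, decoded, coverage-checked,
#' and pushed through the statistical battery: per-parameter Welch's ANOVA
#' across cases (dataset means, per area), KS + Holm across areas per case,
#' two-way group x area ANOVA on case-area means (with Bartlett's check),
#' and the radius-correlation and curvature-radius fits. All tabular outputs
#' are written as CSV, the statistics as one JSON report, and a structured
#' `key=value` log with per-stage timings.
#'
#' @param config A `pipeline_config` (or path to a config file).
#' @return A list: `geometry`, `summaries`, `stats`, `coverage`,
#'   `blind_map`, `output_dir` (invisibly).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$output_dir, "models"), showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "log.txt")
  log_lines <- character(0)
  logf <- function(stage, ...) {
    kv <- c(...)
    line <- paste0("stage=", stage,
                   if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=",
                                                     collapse = " ")))
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(stage, id, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed for %s: %s",
                    stage, id, conditionMessage(e)))
    })
    logf(stage, c(dataset = id,
                  elapsed_s = sprintf("%.2f", proc.time()[["elapsed"]] - t0)))
    res
  }

  seeds <- derive_seeds(config$seed, 2L)
  blind <- assign_blind_codes(config$volumes$dataset, seeds[1L])
  utils::write.csv(as.data.frame(blind),
                   file.path(config$output_dir, "blind_map.csv"),
                   row.names = FALSE)
  logf("blind", c(n = nrow(blind), seed = seeds[1L]))

  geo_parts <- list()
  for (i in seq_len(nrow(config$volumes))) {
    ds <- config$volumes$dataset[[i]]
    code <- blind$code[match(ds, blind$dataset)]
    vpath <- config$volumes$path[[i]]
    vsize <- if ("voxel_size_nm" %in% names(config$volumes))
      config$volumes$voxel_size_nm[[i]] else NULL
    vol <- run_stage("read_volume", ds, read_volume(vpath, vsize))
    nv <- run_stage("normalize", ds, normalize_volume(vol)$volume)
    model <- run_stage("trace_model", ds,
                       trace_model(nv, config$params,
                                   metadata = list(dataset = code)))
    run_stage("write_model", ds, write_model_pdb(
      model, file.path(config$output_dir, "models",
                       paste0(code, ".pdb"))))
    geo_parts[[i]] <- run_stage("geometry", ds, geometry_table(model))
  }
  geometry <- dplyr::bind_rows(geo_parts)
  # unblind and attach case labels
  geometry$dataset <- decode_blind(geometry$dataset, blind)
  geometry <- geometry |>
    dplyr::select(-dplyr::any_of(c("case", "group", "area"))) |>
    dplyr::left_join(config$case_table, by = "dataset") |>
    dplyr::select(dplyr::all_of(c("dataset", "case", "group", "area")),
                  dplyr::everything())
  utils::write.csv(as.data.frame(geometry),
                   file.path(config$output_dir, "geometry.csv"),
                   row.names = FALSE)
  logf("concatenate", c(constituents = nrow(geometry)))

  coverage <- check_neurite_coverage(geometry, config$case_table,
                                     config$coverage_threshold)
  utils::write.csv(as.data.frame(coverage),
                   file.path(config$output_dir, "coverage.csv"),
                   row.names = FALSE)
  logf("coverage", c(flagged = sum(coverage$flagged)))

  stats_report <- list()
  summaries <- list()
  for (par in config$parameters) {
    geo_t <- dplyr::filter(geometry, .data$type == par$type,
                           !is.na(.data[[par$column]]))
    if (nrow(geo_t) == 0L) next
    summ <- dataset_summary(geo_t, config$case_table,
                            .data[[par$column]], types = par$type)
    summaries[[par$name]] <- summ
    entry <- list(parameter = par$name)
    for (ar in sort(unique(summ$area))) {
      sa <- summ[summ$area == ar, ]
      ok <- tryCatch({
        w <- welch_anova(sa, mean, case)
        entry$welch[[ar]] <- as.list(tidy(w))
        TRUE
      }, error = function(e) {
        logf("welch_skip", c(parameter = par$name, area = ar))
        FALSE
      })
    }
    if (length(unique(geo_t$area)) == 2L) {
      ksr <- tryCatch(ks_holm(geo_t, .data[[par$column]], case, area),
                      error = function(e) NULL)
      if (!is.null(ksr)) entry$ks_holm <- lapply(seq_len(nrow(ksr)),
                                                 function(r) as.list(ksr[r, ]))
      cam <- case_area_means(geo_t, parameter = .data[[par$column]],
                             types = par$type)
      twa <- tryCatch(two_way_anova(cam), error = function(e) NULL)
      if (!is.null(twa)) {
        entry$two_way_anova <- lapply(seq_len(nrow(twa$terms)),
                                      function(r) as.list(twa$terms[r, ]))
        bt <- tryCatch(bartlett_test(cam, mean, group),
                       error = function(e) NULL)
        if (!is.null(bt)) entry$bartlett <- as.list(tidy(bt))
      }
    }
    stats_report[[par$name]] <- entry
  }

  # structure-relationship fits across case-area cells
  fits <- tryCatch({
    neur_r <- case_area_means(geometry, parameter = mean_radius,
                              types = "neurite")
    spin_r <- case_area_means(geometry, parameter = mean_radius,
                              types = "spine")
    both <- dplyr::inner_join(
      dplyr::rename(neur_r, neurite_radius = "mean"),
      dplyr::rename(spin_r, spine_radius = "mean"),
      by = c("case", "group", "area"))
    rc <- radius_correlation(both)
    neur_k <- case_area_means(geometry, parameter = mean_curvature,
                              types = "neurite")
    spin_k <- case_area_means(geometry, parameter = mean_curvature,
                              types = "spine")
    pts <- dplyr::bind_rows(
      dplyr::inner_join(dplyr::rename(neur_k, mean_curvature = "mean"),
                        dplyr::rename(neur_r, mean_radius = "mean"),
                        by = c("case", "group", "area")),
      dplyr::inner_join(dplyr::rename(spin_k, mean_curvature = "mean"),
                        dplyr::rename(spin_r, mean_radius = "mean"),
                        by = c("case", "group", "area")))
    crf <- curvature_radius_fit(pts)
    list(radius_correlation = as.list(tidy(rc)),
         curvature_radius = as.list(tidy(crf)))
  }, error = function(e) {
    logf("fits_skip", c(reason = gsub("[ =]", "_", conditionMessage(e))))
    NULL
  })
  if (!is.null(fits)) stats_report$fits <- fits

  summary_tbl <- dplyr::bind_rows(summaries, .id = "parameter")
  utils::write.csv(as.data.frame(summary_tbl),
                   file.path(config$output_dir, "dataset_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(stats_report,
                       file.path(config$output_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done", c(parameters = length(summaries)))
  writeLines(log_lines, log_path)
  invisible(list(geometry = geometry, summaries = summaries,
                 stats = stats_report, coverage = coverage,
                 blind_map = blind, output_dir = config$output_dir))
}
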