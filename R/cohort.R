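#' Specify a synthetic morphometry cohort
#'
#' Describes the statistical structure of a multi-case, multi-area neurite
#' morphometry study: cases assigned to groups, brain areas, several image
#' datasets per case and area, and hundreds of constituents per dataset.
#' Per-constituent mean curvatures are lognormal with a cell location built
#' from a base level plus additive group and area offsets (µm^-1) and a
#' multiplicative per-case effect `exp(N(0, case_sd))`. With coupling
#' enabled, thickness radii satisfy `r = coupling_c / kappa` exactly per
#' constituent, which makes the log-log relation between cell mean curvature
#' and cell mean radius have slope exactly -1 (constant lognormal spread).
#'
#' Defaults emulate an 8-case, two-area design with four cases per group,
#' case means bracketing 0.35-1.08 µm^-1, and a modestly higher curvature in
#' the patient group.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param cases Data frame with columns `case`, `group`.
#' @param areas Character vector of area labels.
#' @param datasets_per_case_area Datasets per case and area.
#' @param neurites_per_dataset,spines_per_dataset Constituents per dataset.
#' @param curvature_base Baseline mean neurite curvature, µm^-1.
#' @param group_offsets Named additive offsets to mean curvature (µm^-1) per
#'   group.
#' @param area_offsets Named additive offsets per area (µm^-1).
#' @param case_sd SD of the per-case lognormal location effect (log units).
#' @param curvature_sdlog Within-cell lognormal spread of curvature.
#' @param radius_mean,radius_sdlog Neurite radius distribution (µm), used
#'   when coupling is off.
#' @param coupling Logical; couple radius to curvature as `r = c / kappa`.
#' @param coupling_c Coupling constant `c` (µm * µm^-1, i.e. dimensionless
#'   product of radius and curvature).
#' @param torsion_sd SD of per-constituent mean torsion (µm^-1); torsion is
#'   zero-centred (achiral curve statistics).
#' @param spine_radius_ratio Spine radius as a fraction of the cell neurite
#'   radius location (drives the linear neurite-spine radius relation).
#' @param spine_length_meanlog,spine_length_sdlog Spine length lognormal
#'   (µm).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(seed = 1L,
                        cases = tibble(
                          case = c("S1", "S2", "S3", "S4",
                                   "N1", "N2", "N3", "N4"),
                          group = rep(c("schizophrenia", "control"), each = 4L)),
                        areas = c("BA22", "BA24"),
                        datasets_per_case_area = 2L,
                        neurites_per_dataset = 300L,
                        spines_per_dataset = 200L,
                        curvature_base = 0.5,
                        group_offsets = c(schizophrenia = 0.1, control = 0),
                        area_offsets = setNames(rep(0, length(areas)), areas),
                        case_sd = 0.25,
                        curvature_sdlog = 0.45,
                        radius_mean = 0.35,
                        radius_sdlog = 0.3,
                        coupling = FALSE,
                        coupling_c = 0.2,
                        torsion_sd = 0.05,
                        spine_radius_ratio = 0.45,
                        spine_length_meanlog = log(1.1),
                        spine_length_sdlog = 0.3) {
  cases <- as_tibble(cases)
  stopifnot(all(c("case", "group") %in% names(cases)),
            datasets_per_case_area >= 1L, neurites_per_dataset >= 1L,
            spines_per_dataset >= 0L, curvature_base > 0, radius_mean > 0,
            case_sd >= 0, curvature_sdlog >= 0, coupling_c > 0)
  fields <- as.list(environment())
  for (g in unique(cases$group)) {
    if (is.na(group_offsets[g])) abort(sprintf("no group offset for '%s'", g))
    if (curvature_base + group_offsets[[g]] <= 0) {
      abort("curvature location must stay strictly positive")
    }
  }
  structure(fields, class = "cohort_spec")
}

#' Generate a cohort-level geometry table with known structure
#'
#' Draws per-constituent morphometric summaries (mean curvature, mean
#' torsion, mean radius, length, spine length) for every dataset of a
#' [cohort_spec()], together with the case table mapping dataset ids to
#' case, group, and area. Deterministic under the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `geometry` (tibble, one row per constituent, columns as
#'   in [geometry_table()]) and `cases` (tibble `dataset`, `case`, `group`,
#'   `area`).
#' @export
generate_geometry_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  layout <- tidyr::expand_grid(
    spec$cases, area = spec$areas,
    replicate = seq_len(spec$datasets_per_case_area))
  layout$dataset <- sprintf("%s-%s-%s", layout$case, layout$area,
                            letters[layout$replicate])
  withr::with_seed(as.integer(spec$seed) %% 2147483647L, {
    case_eff <- setNames(rnorm(nrow(spec$cases), 0, spec$case_sd),
                         spec$cases$case)
    rad_case_eff <- setNames(rnorm(nrow(spec$cases), 0, spec$case_sd / 2),
                             spec$cases$case)
    rows <- purrr::pmap(layout, function(case, group, area, replicate, dataset) {
      loc <- spec$curvature_base + spec$group_offsets[[group]] +
        spec$area_offsets[[area]]
      mlog <- log(loc) + case_eff[[case]]
      nn <- spec$neurites_per_dataset
      k_n <- rlnorm(nn, meanlog = mlog - spec$curvature_sdlog^2 / 2,
                    sdlog = spec$curvature_sdlog)
      r_loc <- log(spec$radius_mean) + rad_case_eff[[case]]
      r_n <- if (spec$coupling) spec$coupling_c / k_n else
        rlnorm(nn, meanlog = r_loc - spec$radius_sdlog^2 / 2,
               sdlog = spec$radius_sdlog)
      len_n <- rlnorm(nn, meanlog = log(12), sdlog = 0.5)
      tau_n <- rnorm(nn, 0, spec$torsion_sd)
      neur <- tibble(
        dataset = dataset, case = case, group = group, area = area,
        constituent_id = sprintf("%s-n%04d", dataset, seq_len(nn)),
        type = "neurite", n_nodes = NA_integer_, length_um = len_n,
        mean_curvature = k_n, mean_torsion = tau_n, mean_radius = r_n,
        spine_length_um = NA_real_)
      ns <- spec$spines_per_dataset
      if (ns > 0L) {
        k_s <- rlnorm(ns, meanlog = mlog + log(1.6) -
                        spec$curvature_sdlog^2 / 2,
                      sdlog = spec$curvature_sdlog)
        r_s <- if (spec$coupling) spec$coupling_c / k_s else
          rlnorm(ns, meanlog = r_loc + log(spec$spine_radius_ratio) -
                   spec$radius_sdlog^2 / 2,
                 sdlog = spec$radius_sdlog)
        sl <- rlnorm(ns, spec$spine_length_meanlog, spec$spine_length_sdlog)
        spin <- tibble(
          dataset = dataset, case = case, group = group, area = area,
          constituent_id = sprintf("%s-s%04d", dataset, seq_len(ns)),
          type = "spine", n_nodes = NA_integer_, length_um = sl,
          mean_curvature = k_s, mean_torsion = rnorm(ns, 0, spec$torsion_sd),
          mean_radius = r_s, spine_length_um = sl)
        dplyr::bind_rows(neur, spin)
      } else {
        neur
      }
    })
  })
  geometry <- dplyr::bind_rows(rows)
  cases <- dplyr::distinct(layout[, c("dataset", "case", "group", "area")])
  list(geometry = geometry, cases = cases)
}
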