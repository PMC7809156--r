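# Cohort-level statistical battery: dataset summaries, Welch's ANOVA,
# two-way ANOVA on case-area means, Bartlett, KS + Holm-Bonferroni,
# quartiles, and the structure-relationship regressions.

#' Significance stars
#'
#' Star scheme used in distribution-comparison panels: `****` for p < 1e-8,
#' `***` for p < 1e-4, `**` for p < 1e-2, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p Numeric p values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p < 1e-8 ~ "****",
    p < 1e-4 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

new_stat_result <- function(test, statistic, df1, df2, p, p_adjusted = NA_real_,
                            group_sizes = integer(), extra = list()) {
  structure(c(list(test = test, statistic = statistic, df1 = df1, df2 = df2,
                   p = p, p_adjusted = p_adjusted, group_sizes = group_sizes,
                   stars = significance_stars(p)), extra),
            class = "neuro_stat")
}

#' @export
print.neuro_stat <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = (%s, %s), p = %.3g %s\n",
              x$test, x$statistic, format(x$df1), format(x$df2), x$p,
              x$stars))
  invisible(x)
}

#' @export
tidy.neuro_stat <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p.value = x$p, p.adjusted = x$p_adjusted, stars = x$stars)
}

#' @export
glance.neuro_stat <- function(x, ...) tidy(x)

#' Per-dataset summary of a morphometric parameter
#'
#' One row per dataset: sample size, mean and standard deviation (ddof = 1)
#' of the chosen parameter, joined with the case-table labels. This is the
#' dataset-level unit of analysis for case comparisons.
#'
#' @param geometry Geometry table (from [geometry_table()] or
#'   [generate_geometry_cohort()]).
#' @param cases Case table with columns `dataset`, `case`, `group`, `area`.
#' @param parameter Column to summarise (tidy-eval), e.g. `mean_curvature`.
#' @param types Constituent types to include (default `"neurite"`).
#' @return Tibble ordered by dataset id: `dataset`, `case`, `group`, `area`,
#'   `n`, `mean`, `sd` (`sd` is `NA` for single-value datasets).
#' @export
dataset_summary <- function(geometry, cases, parameter = mean_curvature,
                            types = "neurite") {
  par_q <- rlang::enquo(parameter)
  geo <- dplyr::filter(geometry, .data$type %in% types)
  unknown <- setdiff(unique(geo$dataset), cases$dataset)
  if (length(unknown) > 0L) {
    abort(sprintf("dataset id(s) not in case table: %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- geo |>
    dplyr::mutate(.value = !!par_q) |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$.value),
      sd = sd(.data$.value),
      .groups = "drop") |>
    dplyr::left_join(cases[, c("dataset", "case", "group", "area")],
                     by = "dataset") |>
    dplyr::select("dataset", "case", "group", "area", "n", "mean", "sd") |>
    dplyr::arrange(.data$dataset)
  out
}

#' Case-area cell means of a parameter
#'
#' Aggregates a geometry table to one mean per case and area, the unit on
#' which the two-way ANOVA and the structure-relationship fits operate.
#'
#' @inheritParams dataset_summary
#' @return Tibble: `case`, `group`, `area`, `n`, `mean`.
#' @export
case_area_means <- function(geometry, cases = NULL,
                            parameter = mean_curvature,
                            types = "neurite") {
  par_q <- rlang::enquo(parameter)
  geo <- dplyr::filter(geometry, .data$type %in% types)
  if (!is.null(cases)) {
    geo <- dplyr::select(geo, -dplyr::any_of(c("case", "group", "area"))) |>
      dplyr::left_join(cases, by = "dataset")
  }
  geo |>
    dplyr::mutate(.value = !!par_q) |>
    dplyr::group_by(.data$case, .data$group, .data$area) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$.value),
      .groups = "drop") |>
    dplyr::arrange(.data$case, .data$area)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Compares a parameter across cases without assuming equal variances
#' (Welch's F* with Welch-Satterthwaite denominator degrees of freedom).
#'
#' @param data Data frame with the observations.
#' @param value Value column (tidy-eval).
#' @param group Grouping column (tidy-eval), e.g. `case`.
#' @return A `neuro_stat` ([tidy()] it for a tibble row).
#' @export
welch_anova <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data = data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data = data))
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  sizes <- table(g)
  if (nlevels(g) < 2L) abort("Welch's ANOVA needs >= 2 groups")
  if (any(sizes < 2L)) abort("each group needs >= 2 values")
  if (any(tapply(v, g, stats::var) == 0)) abort("zero-variance group")
  ht <- stats::oneway.test(v ~ g, var.equal = FALSE)
  new_stat_result("Welch's ANOVA", unname(ht$statistic),
                  unname(ht$parameter[1L]), unname(ht$parameter[2L]),
                  ht$p.value, group_sizes = as.integer(sizes))
}

#' Two-way fixed-effects ANOVA on case-area means
#'
#' Classical balanced two-way ANOVA with group (e.g. patient/control) and
#' brain area as main factors, on one mean value per case and area. With the
#' interaction term the error has `n - 4` degrees of freedom (12 for 8 cases
#' x 2 areas); `interaction = FALSE` drops it (13 error df). The layout must
#' be balanced: every case exactly once per area.
#'
#' @param cell_means Tibble with columns `case`, `group`, `area`, and the
#'   value column.
#' @param value Value column (tidy-eval, default `mean`).
#' @param interaction Include the group:area interaction (default TRUE).
#' @return A `neuro_anova`: tidy() gives one row per term with `df`,
#'   `sumsq`, `statistic`, `p.value`, `stars`.
#' @export
two_way_anova <- function(cell_means, value = mean, interaction = TRUE) {
  v <- rlang::eval_tidy(rlang::enquo(value), data = cell_means)
  df <- tibble(value = v,
               group = as.factor(cell_means$group),
               area = as.factor(cell_means$area),
               case = as.factor(cell_means$case))
  tab <- table(df$case, df$area)
  if (any(tab != 1L)) {
    abort("unbalanced layout: need exactly one mean per case per area")
  }
  form <- if (interaction) value ~ group * area else value ~ group + area
  fit <- stats::lm(form, data = df)
  if (stats::df.residual(fit) < 1) {
    abort("no residual degrees of freedom: need more cases than model terms")
  }
  an <- stats::anova(fit)
  terms <- rownames(an)
  res_df <- an["Residuals", "Df"]
  out <- tibble(
    term = terms[terms != "Residuals"],
    df = an$Df[terms != "Residuals"],
    sumsq = an$`Sum Sq`[terms != "Residuals"],
    statistic = an$`F value`[terms != "Residuals"],
    p.value = an$`Pr(>F)`[terms != "Residuals"])
  out$stars <- significance_stars(out$p.value)
  structure(list(terms = out, residual_df = res_df, fit = fit,
                 interaction = interaction),
            class = "neuro_anova")
}

#' @export
print.neuro_anova <- function(x, ...) {
  cat(sprintf("two-way ANOVA (%s interaction), residual df = %d\n",
              if (x$interaction) "with" else "without", x$residual_df))
  print(x$terms)
  invisible(x)
}

#' @export
tidy.neuro_anova <- function(x, ...) x$terms

#' @export
glance.neuro_anova <- function(x, ...) {
  tibble(residual_df = x$residual_df, interaction = x$interaction,
         r.squared = summary(x$fit)$r.squared)
}

#' Bartlett's test of equal variances
#'
#' @inheritParams welch_anova
#' @return A `neuro_stat`.
#' @export
bartlett_test <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data = data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data = data))
  sizes <- table(droplevels(g))
  if (length(sizes) < 2L || any(sizes < 2L)) {
    abort("Bartlett's test needs >= 2 groups with >= 2 values each")
  }
  if (any(tapply(v, g, stats::var) == 0)) abort("zero-variance group")
  ht <- stats::bartlett.test(v, g)
  new_stat_result("Bartlett", unname(ht$statistic), unname(ht$parameter),
                  NA_real_, ht$p.value, group_sizes = as.integer(sizes))
}

#' Kolmogorov-Smirnov comparisons with Holm-Bonferroni correction
#'
#' Runs a family of two-sided two-sample KS tests — one per level of
#' `family`, comparing the two levels of `between` within it (e.g. one test
#' per case, comparing areas) — and corrects the p values with the Holm
#' step-down procedure. The exact two-sample p value is used when
#' `n * m <= 10^4`, the asymptotic form otherwise.
#'
#' @param data Data frame of per-constituent values.
#' @param value Value column (tidy-eval).
#' @param family Column naming each comparison (tidy-eval), e.g. `case`.
#' @param between Column with exactly two levels inside each family
#'   (tidy-eval), e.g. `area`.
#' @return Tibble: `name`, `n1`, `n2`, `statistic` (D), `p.value`,
#'   `p.adjusted`, `stars` (stars from the adjusted p).
#' @export
ks_holm <- function(data, value, family, between) {
  v <- rlang::eval_tidy(rlang::enquo(value), data = data)
  fam <- as.character(rlang::eval_tidy(rlang::enquo(family), data = data))
  btw <- as.character(rlang::eval_tidy(rlang::enquo(between), data = data))
  names_u <- sort(unique(fam))
  rows <- purrr::map(names_u, function(nm) {
    sel <- fam == nm
    lv <- sort(unique(btw[sel]))
    if (length(lv) != 2L) {
      abort(sprintf("family '%s' needs exactly 2 levels of the between factor", nm))
    }
    a <- v[sel & btw == lv[1L]]
    b <- v[sel & btw == lv[2L]]
    if (length(a) < 2L || length(b) < 2L) {
      abort(sprintf("family '%s': both samples need n >= 2", nm))
    }
    exact <- length(a) * length(b) <= 1e4
    ht <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                          exact = exact))
    tibble(name = nm, n1 = length(a), n2 = length(b),
           statistic = unname(ht$statistic), p.value = ht$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p.adjusted <- stats::p.adjust(out$p.value, method = "holm")
  out$stars <- significance_stars(out$p.adjusted)
  out
}

#' Quartile summary
#'
#' Linear-interpolation quantiles at 0.25, 0.5, 0.75.
#'
#' @param values Numeric vector (n >= 1).
#' @return Tibble: `q1`, `median`, `q3`.
#' @export
quartile_summary <- function(values) {
  stopifnot(length(values) >= 1L)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Linear relation between neurite and spine mean thickness radii
#'
#' Ordinary least squares of spine radius on neurite radius across case-area
#' cells, with the Pearson correlation.
#'
#' @param data Tibble with one row per case-area cell.
#' @param neurite,spine Columns holding the mean neurite and spine radii
#'   (tidy-eval).
#' @return A `neuro_fit`: tidy() gives `slope`, `intercept`, `pearson_r`,
#'   `n`.
#' @export
radius_correlation <- function(data, neurite = neurite_radius,
                               spine = spine_radius) {
  x <- rlang::eval_tidy(rlang::enquo(neurite), data = data)
  y <- rlang::eval_tidy(rlang::enquo(spine), data = data)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need >= 3 points")
  if (stats::var(x) == 0) abort("zero variance in the predictor")
  fit <- stats::lm(y ~ x)
  structure(list(
    kind = "radius_correlation",
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    pearson_r = stats::cor(x, y),
    n = length(x), fit = fit),
    class = "neuro_fit")
}

#' Reciprocal (power-law) relation between curvature and radius
#'
#' Least-squares fit of `log(kappa) = log(c) + beta * log(r)` across
#' case-area cells; `beta` close to -1 indicates the reciprocal relation
#' `kappa = c / r`.
#'
#' @param data Tibble with one row per cell.
#' @param curvature,radius Columns holding the mean curvature (µm^-1) and
#'   mean radius (µm), all positive (tidy-eval).
#' @return A `neuro_fit`: tidy() gives `exponent` (beta), `coefficient`
#'   (c), `n`.
#' @export
curvature_radius_fit <- function(data, curvature = mean_curvature,
                                 radius = mean_radius) {
  k <- rlang::eval_tidy(rlang::enquo(curvature), data = data)
  r <- rlang::eval_tidy(rlang::enquo(radius), data = data)
  ok <- !is.na(k) & !is.na(r)
  k <- k[ok]; r <- r[ok]
  if (length(k) < 3L) abort("need >= 3 points")
  if (any(k <= 0) || any(r <= 0)) abort("curvature and radius must be positive")
  fit <- stats::lm(log(k) ~ log(r))
  structure(list(
    kind = "curvature_radius_fit",
    exponent = unname(stats::coef(fit)[2L]),
    coefficient = exp(unname(stats::coef(fit)[1L])),
    n = length(k), fit = fit),
    class = "neuro_fit")
}

#' @export
print.neuro_fit <- function(x, ...) {
  if (x$kind == "radius_correlation") {
    cat(sprintf("radius correlation: slope %.4g, intercept %.4g, r = %.4f (n = %d)\n",
                x$slope, x$intercept, x$pearson_r, x$n))
  } else {
    cat(sprintf("curvature-radius power law: exponent %.4f, coefficient %.4g (n = %d)\n",
                x$exponent, x$coefficient, x$n))
  }
  invisible(x)
}

#' @export
tidy.neuro_fit <- function(x, ...) {
  if (x$kind == "radius_correlation") {
    tibble(slope = x$slope, intercept = x$intercept,
           pearson_r = x$pearson_r, n = x$n)
  } else {
    tibble(exponent = x$exponent, coefficient = x$coefficient, n = x$n)
  }
}

#' @export
glance.neuro_fit <- function(x, ...) {
  tibble(r.squared = summary(x$fit)$r.squared, n = x$n)
}
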