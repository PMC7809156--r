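# ggplot2 views of geometry tables and fitted relations.

#' Beeswarm-style distribution plot of a parameter by dataset
#'
#' Jittered per-constituent values per dataset, coloured by case, with the
#' dataset mean and +/- 1 sd overlaid — the standard view for comparing a
#' morphometric parameter across datasets and cases.
#'
#' @param geometry Geometry table.
#' @param parameter Column to plot (tidy-eval).
#' @param type Constituent type to keep.
#' @return A ggplot object.
#' @export
plot_distribution_by_dataset <- function(geometry, parameter = mean_curvature,
                                         type = "neurite") {
  par_q <- rlang::enquo(parameter)
  geo <- dplyr::filter(geometry, .data$type == !!type) |>
    dplyr::mutate(.value = !!par_q)
  summ <- geo |>
    dplyr::group_by(.data$dataset, .data$case) |>
    dplyr::summarise(mean = mean(.data$.value), sd = sd(.data$.value),
                     .groups = "drop")
  ggplot2::ggplot(geo, ggplot2::aes(x = .data$dataset, y = .data$.value,
                                    colour = .data$case)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.25, size = 0.4) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      colour = "black", fatten = 2) +
    ggplot2::labs(x = "dataset", y = rlang::as_label(par_q)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Quartile comparison of a parameter between areas per case
#'
#' @inheritParams plot_distribution_by_dataset
#' @return A ggplot object.
#' @export
plot_area_comparison <- function(geometry, parameter = mean_curvature,
                                 type = "neurite") {
  par_q <- rlang::enquo(parameter)
  geo <- dplyr::filter(geometry, .data$type == !!type) |>
    dplyr::mutate(.value = !!par_q)
  qs <- geo |>
    dplyr::group_by(.data$case, .data$area) |>
    dplyr::summarise(quartile_summary(.data$.value), .groups = "drop")
  ggplot2::ggplot(geo, ggplot2::aes(x = .data$area, y = .data$.value)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.2, size = 0.3,
                         ggplot2::aes(colour = .data$area)) +
    ggplot2::geom_errorbar(
      data = qs, ggplot2::aes(y = .data$median, ymin = .data$q1,
                              ymax = .data$q3),
      width = 0.4, colour = "black") +
    ggplot2::facet_wrap(~case) +
    ggplot2::labs(x = NULL, y = rlang::as_label(par_q)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.neuro_fit <- function(object, ...) {
  df <- stats::model.frame(object$fit)
  names(df) <- c("y", "x")
  if (object$kind == "curvature_radius_fit") {
    ggplot2::ggplot(df, ggplot2::aes(x = exp(.data$x), y = exp(.data$y))) +
      ggplot2::geom_point() +
      ggplot2::geom_line(ggplot2::aes(y = object$coefficient *
                                        exp(.data$x)^object$exponent)) +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "mean radius (um)", y = "mean curvature (1/um)",
                    title = sprintf("power-law exponent %.2f",
                                    object$exponent)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point() +
      ggplot2::geom_abline(slope = object$slope,
                           intercept = object$intercept) +
      ggplot2::labs(x = "neurite mean radius (um)",
                    y = "spine mean radius (um)",
                    title = sprintf("slope %.2f, r = %.2f", object$slope,
                                    object$pearson_r)) +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.neuro_anova <- function(object, ...) {
  ggplot2::ggplot(object$terms,
                  ggplot2::aes(x = .data$term, y = -log10(.data$p.value))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = NULL, y = "-log10 p") +
    ggplot2::theme_minimal()
}
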