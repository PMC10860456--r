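# ggplot2 figures for the main result types.

#' Plot a cumulative DVH
#'
#' @param dvhs A [compute_dvh()] result or a named list of them.
#' @return A ggplot.
#' @export
plot_dvh <- function(dvhs) {
  if (inherits(dvhs, "dvh_curve")) dvhs <- list(dvhs)
  d <- purrr::map_dfr(dvhs, function(x) {
    cd <- cumulative_dvh(x)
    cd$structure <- x$structure
    cd
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dose_gy,
                                  y = 100 * .data$volume_fraction,
                                  color = .data$structure)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot gEUD change against MLC error magnitude
#'
#' Shows the per-case measurements and the fitted linear trend per
#' direction, the standard view of dose-error sensitivity.
#'
#' @param deltas The `deltas` tibble of a [run_study()] result (or
#'   [analyze_case()]), target structure rows.
#' @return A ggplot.
#' @export
plot_sensitivity <- function(deltas) {
  d <- deltas[deltas$structure == "target", ]
  d$signed_mm <- ifelse(d$mode == "close", -d$magnitude_mm, d$magnitude_mm)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signed_mm, y = .data$delta_percent,
                                  color = .data$mode)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "MLC positional error (mm)",
                  y = "gEUD change (%)", color = "mode") +
    ggplot2::theme_minimal()
}

#' Plot sensitivity against a complexity metric
#'
#' @param study A [run_study()] result.
#' @param metric `"mu_per_gy"` or `"pi"`.
#' @return A ggplot.
#' @export
plot_complexity_correlation <- function(study, metric = c("mu_per_gy", "pi")) {
  metric <- match.arg(metric)
  d <- study$target_sensitivity
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[metric]],
                                  y = .data$sensitivity_pct_per_mm,
                                  color = .data$site)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = if (metric == "mu_per_gy") "MU/Gy" else "Plan irregularity",
                  y = "gEUD sensitivity (%/mm)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_sensitivity
#' @param object A `vmat_study` object.
#' @param ... Unused.
#' @export
autoplot.vmat_study <- function(object, ...) {
  plot_sensitivity(object$deltas)
}
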