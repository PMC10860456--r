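# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sensitivity fit
#'
#' @param x A [fit_sensitivity()] result.
#' @param ... Unused.
#' @return One-row tibble with `direction`, `slope`, `intercept`, `unit`.
#' @export
tidy.sensitivity_fit <- function(x, ...) {
  tibble::tibble(direction = x$direction, slope = x$slope,
                 intercept = x$intercept, unit = paste0(x$unit, "/mm"))
}

#' Glance at a sensitivity fit
#'
#' @param x A [fit_sensitivity()] result.
#' @param ... Unused.
#' @return One-row tibble with `r`, `r_squared`, `n`.
#' @export
glance.sensitivity_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r^2, n = x$n)
}

#' Tidy a tolerance result
#'
#' @param x A [derive_tolerance()] result.
#' @param ... Unused.
#' @return The per-scenario tolerance tibble.
#' @export
tidy.tolerance_result <- function(x, ...) x$per_scenario

#' Glance at a tolerance result
#'
#' @param x A [derive_tolerance()] result.
#' @param ... Unused.
#' @return One-row tibble with the threshold, aggregation and case counts.
#' @export
glance.tolerance_result <- function(x, ...) {
  tibble::tibble(threshold_pct = x$threshold_pct, aggregate = x$aggregate,
                 n_cases = nrow(x$per_case),
                 n_unbounded = sum(x$per_case$unbounded))
}

#' Tidy a correlation result
#'
#' @param x A [correlate()] result.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(x_metric = x$x_metric, y_metric = x$y_metric,
                 method = x$method, coefficient = x$coefficient,
                 p_value = x$p_value, strength_band = x$strength_band)
}

#' Tidy a group comparison
#'
#' @param x A [compare_groups()] result.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.stat_comparison <- function(x, ...) {
  tibble::tibble(test_used = x$test_used, p_value = x$p_value,
                 significant = x$significant,
                 normality_p_a = x$normality_p[1],
                 normality_p_b = x$normality_p[2])
}
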