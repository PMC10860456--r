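# Statistics layer: gEUD-sensitivity slopes, tolerance derivation,
# normality-gated group comparisons and correlations.

#' Fit a gEUD-sensitivity slope
#'
#' Ordinary least-squares fit of gEUD change against MLC error magnitude.
#' The zero-error point `(0, 0)` must be included by the caller; the fit
#' retains sign (close errors give negative slopes for targets).
#'
#' @param changes A data frame with columns `error_mm` (signed or unsigned
#'   magnitudes) and `delta` (gEUD change, % or Gy).
#' @param direction Label stored with the fit (`"close"`, `"open"`,
#'   `"combined"`, `"random"`, ...).
#' @param unit Unit of `delta` per mm (`"pct"` or `"gy"`).
#' @return An object of class `sensitivity_fit`: list with `slope`
#'   (delta units per mm), `intercept`, `r` (Pearson correlation of the
#'   points), `n`, `direction`, `unit`.
#' @export
fit_sensitivity <- function(changes, direction = "combined", unit = "pct") {
  stopifnot(is.data.frame(changes),
            all(c("error_mm", "delta") %in% names(changes)))
  x <- changes$error_mm
  y <- changes$delta
  if (length(unique(x)) < 2) stop("need at least 2 distinct error magnitudes")
  fit <- stats::lm(y ~ x)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = r, n = length(x), direction = direction, unit = unit),
    class = "sensitivity_fit"
  )
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat(sprintf("<sensitivity_fit> %s: %.4g %s/mm (r = %.4f, n = %d)\n",
              x$direction, x$slope, x$unit, x$r, x$n))
  invisible(x)
}

#' Derive MLC position tolerances from target sensitivities
#'
#' Per case, the tolerance is the largest error keeping the target gEUD
#' change within the threshold:
#' `tol = threshold_pct / max(|slope_close|, |slope_open|)`. Scenario
#' tolerances aggregate per-case tolerances (mean by default). Cases whose
#' slopes are all zero have unbounded tolerance; they are flagged
#' (`unbounded = TRUE`, `tolerance_mm = NA`) rather than given a number.
#'
#' @param sens A data frame with columns `case_id`, `direction` and
#'   `slope` (%/mm, sign retained), target structure only. A `scenario`
#'   column, if present, groups the aggregation.
#' @param threshold_pct Dose-change threshold (percent, default 2).
#' @param aggregate `"mean"` (default), `"median"` or `"min"`.
#' @return A list of class `tolerance_result` with `per_case` and
#'   `per_scenario` tibbles and `threshold_pct`.
#' @export
derive_tolerance <- function(sens, threshold_pct = 2,
                             aggregate = c("mean", "median", "min")) {
  if (threshold_pct <= 0) stop("threshold_pct must be positive")
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("case_id", "slope") %in% names(sens)))
  if (!"scenario" %in% names(sens)) sens$scenario <- "all"
  per_case <- sens |>
    dplyr::group_by(.data$scenario, .data$case_id) |>
    dplyr::summarise(max_abs_slope = max(abs(.data$slope)), .groups = "drop") |>
    dplyr::mutate(
      unbounded = .data$max_abs_slope == 0,
      tolerance_mm = ifelse(.data$unbounded, NA_real_,
                            threshold_pct / .data$max_abs_slope)
    )
  agg_fun <- switch(aggregate, mean = mean, median = stats::median, min = min)
  per_scenario <- per_case |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      n_unbounded = sum(.data$unbounded),
      tolerance_mm = if (all(.data$unbounded)) NA_real_
                     else agg_fun(.data$tolerance_mm[!.data$unbounded]),
      .groups = "drop"
    )
  structure(list(per_case = per_case, per_scenario = per_scenario,
                 threshold_pct = threshold_pct, aggregate = aggregate),
            class = "tolerance_result")
}

#' Compare two samples with a normality-gated test
#'
#' Shapiro-Wilk normality is assessed per group at p < 0.05; if any group
#' departs from normality a Wilcoxon (signed-rank when paired) test is
#' used, otherwise a t-test.
#'
#' @param a,b Numeric samples (each n >= 3; equal lengths when paired).
#' @param paired Paired comparison? Default `FALSE`.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `stat_comparison` with `normality_p` (length 2),
#'   `test_used`, `p_value`, `significant`.
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  if (paired && length(a) != length(b)) stop("paired samples must have equal length")
  sw_p <- function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }
  normality_p <- c(sw_p(a), sw_p(b))
  if (any(normality_p < 0.05)) {
    test_used <- "wilcoxon_signed_rank"
    p <- suppressWarnings(stats::wilcox.test(a, b, paired = paired)$p.value)
  } else {
    test_used <- "t_test"
    p <- stats::t.test(a, b, paired = paired)$p.value
  }
  structure(
    list(normality_p = normality_p, test_used = test_used, p_value = p,
         significant = p < alpha),
    class = "stat_comparison"
  )
}

#' Normality-gated correlation with strength band
#'
#' Pearson when both samples pass Shapiro-Wilk normality (p >= 0.05),
#' Spearman otherwise. The strength band uses the cut points: |r| <= 0.2
#' zero, (0.2, 0.4] weak, (0.4, 0.7] moderate, > 0.7 strong.
#'
#' @param x,y Numeric samples of equal length >= 3.
#' @param x_metric,y_metric Labels stored with the result.
#' @return A list of class `correlation_result` with `coefficient`,
#'   `method`, `p_value`, `strength_band`.
#' @export
correlate <- function(x, y, x_metric = "x", y_metric = "y") {
  if (length(x) != length(y)) stop("samples must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  normal <- stats::shapiro.test(x)$p.value >= 0.05 &&
    stats::shapiro.test(y)$p.value >= 0.05
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  coef <- unname(ct$estimate)
  band <- correlation_band(coef)
  structure(
    list(x_metric = x_metric, y_metric = y_metric, coefficient = coef,
         method = method, p_value = ct$p.value, strength_band = band),
    class = "correlation_result"
  )
}

correlation_band <- function(coef) {
  a <- abs(coef)
  if (a <= 0.2) "zero" else if (a <= 0.4) "weak"
  else if (a <= 0.7) "moderate" else "strong"
}
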