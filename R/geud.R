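# Generalized equivalent uniform dose: gEUD = (sum_i v_i * D_i^a)^(1/a)
# over differential DVH bins, with bin-center doses floored at a small
# positive value so strongly negative exponents stay finite when a
# structure has zero-dose voxels.

#' gEUD parameters
#'
#' @param a Volume-effect exponent (non-zero). Negative values weight cold
#'   spots (targets); large positive values weight hot spots (serial OARs).
#' @param dose_floor_gy Positive floor applied to bin-center doses before
#'   exponentiation (default 0.01 Gy).
#' @return A list of class `geud_params`.
#' @export
geud_params <- function(a, dose_floor_gy = 0.01) {
  stopifnot(is.numeric(a), length(a) == 1)
  if (a == 0) stop("a = 0 (geometric-mean limit) is not supported")
  stopifnot(dose_floor_gy > 0)
  structure(list(a = as.numeric(a), dose_floor_gy = dose_floor_gy),
            class = "geud_params")
}

#' Generalized equivalent uniform dose of a DVH
#'
#' Computed as `(sum_i v_i * D_i^a)^(1/a)` with differential fractional
#' volumes `v_i` and bin-center doses `D_i`. The sum is evaluated in a
#' numerically stable form (factoring out the maximum occupied dose) so
#' that large-magnitude exponents do not overflow.
#'
#' @param dvh A [compute_dvh()] result.
#' @param params A [geud_params()] (or a bare numeric `a`).
#' @return gEUD in Gy.
#' @export
geud <- function(dvh, params) {
  if (is.numeric(params)) params <- geud_params(params)
  stopifnot(inherits(params, "geud_params"))
  occ <- dvh$diff_volume > 0
  d <- pmax(dvh$bin_centers_gy[occ], params$dose_floor_gy)
  v <- dvh$diff_volume[occ]
  a <- params$a
  # Stable generalized mean: factor out the dominant dose.
  dref <- if (a > 0) max(d) else min(d)
  dref * sum(v * (d / dref)^a)^(1 / a)
}

#' Change in gEUD between a reference and an error DVH
#'
#' @param ref,err [compute_dvh()] results for the same structure.
#' @param params A [geud_params()] (or bare numeric `a`).
#' @return An object of class `geud_change`: list with `ref_geud_gy`,
#'   `err_geud_gy`, `delta_percent` (`100 * (err - ref) / ref`) and
#'   `delta_gy`.
#' @export
geud_change <- function(ref, err, params) {
  if (!identical(ref$structure, err$structure)) {
    stop("reference and error DVHs are for different structures")
  }
  g_ref <- geud(ref, params)
  g_err <- geud(err, params)
  if (g_ref <= 0) stop("reference gEUD is zero; percent change undefined")
  structure(
    list(ref_geud_gy = g_ref, err_geud_gy = g_err,
         delta_percent = 100 * (g_err - g_ref) / g_ref,
         delta_gy = g_err - g_ref),
    class = "geud_change"
  )
}
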