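# Dose-volume histograms: differential curves per structure, cumulative
# queries (D_x%, V_xGy, D_max, D_cc) and CSV export.
#
# Binning convention: bins of width `bin_width_gy` centered on integer
# multiples of the bin width (edges at (k - 1/2) * width), so that doses on
# the natural grid fall exactly on bin centers and queries on uniform doses
# are exact.

#' Differential DVH of a structure
#'
#' @param dose A [compute_dose()] result.
#' @param phantom The matching [make_phantom()] result.
#' @param structure Structure name in `phantom$masks`.
#' @param bin_width_gy Dose bin width (Gy, default 0.05).
#'
#' @return An object of class `dvh_curve`: list with `structure`,
#'   `bin_edges_gy` (ascending), `bin_centers_gy`, `diff_volume`
#'   (fractional volume per bin, sums to 1) and `total_volume_cc`.
#' @export
compute_dvh <- function(dose, phantom, structure, bin_width_gy = 0.05) {
  m <- phantom$masks[[structure]]
  if (is.null(m)) stop("no such structure: ", structure)
  if (!any(m)) stop("empty mask for structure: ", structure)
  d <- dose$values_gy[m]
  if (any(!is.finite(d)) || any(d < 0)) stop("dose grid contains invalid values")
  bw <- bin_width_gy
  k <- round(d / bw)
  kmax <- max(k)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  centers <- (0:kmax) * bw
  structure(
    list(
      structure = structure,
      bin_edges_gy = c(centers - bw / 2, centers[kmax + 1L] + bw / 2),
      bin_centers_gy = centers,
      diff_volume = counts / length(d),
      total_volume_cc = length(d) * phantom$spacing_mm^3 / 1000
    ),
    class = "dvh_curve"
  )
}

#' Cumulative DVH from a differential curve
#'
#' @param dvh A [compute_dvh()] result.
#' @return A tibble with `dose_gy` (bin centers) and `volume_fraction`
#'   receiving at least that dose; non-increasing, starting at 1.
#' @export
cumulative_dvh <- function(dvh) {
  tibble::tibble(
    dose_gy = dvh$bin_centers_gy,
    volume_fraction = rev(cumsum(rev(dvh$diff_volume)))
  )
}

#' Query a DVH curve
#'
#' * `D_percent`: minimum dose received by the hottest `arg`% of the volume.
#' * `V_gy`: fractional volume receiving at least `arg` Gy.
#' * `D_max`: highest occupied dose bin (no `arg`).
#' * `D_cc`: minimum dose received by the hottest `arg` cc.
#'
#' @param dvh A [compute_dvh()] result.
#' @param kind One of `"D_percent"`, `"V_gy"`, `"D_max"`, `"D_cc"`.
#' @param arg Query argument (percent, Gy or cc depending on `kind`).
#' @return A scalar (Gy for D-queries, fraction for `V_gy`).
#' @export
dvh_query <- function(dvh, kind = c("D_percent", "V_gy", "D_max", "D_cc"),
                      arg = NULL) {
  kind <- match.arg(kind)
  centers <- dvh$bin_centers_gy
  v <- dvh$diff_volume
  d_hot_fraction <- function(frac) {
    if (frac <= 0 || frac > 1) stop("volume fraction out of range (0, 1]")
    cum_top <- cumsum(rev(v))
    idx <- which(cum_top >= frac - 1e-12)[1]
    rev(centers)[idx]
  }
  switch(kind,
    D_percent = {
      if (is.null(arg)) stop("D_percent requires a percentage argument")
      d_hot_fraction(arg / 100)
    },
    V_gy = {
      if (is.null(arg) || arg < 0) stop("V_gy requires a non-negative dose argument")
      sum(v[centers >= arg - 1e-12])
    },
    D_max = max(centers[v > 0]),
    D_cc = {
      if (is.null(arg)) stop("D_cc requires a volume argument (cc)")
      if (arg <= 0 || arg > dvh$total_volume_cc) {
        stop("D_cc volume out of range (0, total volume]")
      }
      d_hot_fraction(arg / dvh$total_volume_cc)
    }
  )
}

#' Export DVH curves to CSV
#'
#' One row per bin: `structure`, `bin_lo_gy`, `bin_hi_gy`, `diff_volume`.
#'
#' @param dvhs A single [compute_dvh()] result or a list of them.
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_dvh_csv <- function(dvhs, path) {
  if (inherits(dvhs, "dvh_curve")) dvhs <- list(dvhs)
  rows <- purrr::map_dfr(dvhs, function(d) {
    n <- length(d$diff_volume)
    tibble::tibble(
      structure = d$structure,
      bin_lo_gy = d$bin_edges_gy[seq_len(n)],
      bin_hi_gy = d$bin_edges_gy[seq_len(n) + 1],
      diff_volume = d$diff_volume
    )
  })
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
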