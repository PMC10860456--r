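# Surrogate forward dose engine. For each control-point interval it builds
# the 2-D aperture fluence at isocenter (1 inside the MLC-and-jaw opening, 0
# outside), blurs it with a Gaussian penumbra, weights it by the interval's
# meterset, and back-projects it through the phantom along the interval's
# mean gantry direction with parallel rays (optional exponential depth
# attenuation). The sum over intervals is scaled once so the reference
# plan's target mean dose equals the prescribed dose per fraction; that
# calibration factor is stored and must be reused unchanged for the plan's
# error variants, otherwise renormalization would erase the dose error
# being measured.
#
# This engine is aperture-driven plumbing: it reproduces ordering, linearity
# and correlation structure, not the absolute dosimetry of a clinical
# Monte-Carlo or collapsed-cone algorithm.

#' Dose engine configuration
#'
#' @param penumbra_sigma_mm Gaussian penumbra sigma (mm, default 3).
#' @param fluence_spacing_mm Fluence grid spacing (mm, default 2).
#' @param attenuation_per_mm Exponential depth-attenuation coefficient
#'   (1/mm, default 0 = off).
#' @param calibration Frozen calibration factor (Gy per weighted-fluence
#'   unit). `NULL` (default) calibrates the plan so the target mean dose
#'   equals the prescription's dose per fraction.
#'
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(penumbra_sigma_mm = 3, fluence_spacing_mm = 2,
                          attenuation_per_mm = 0, calibration = NULL) {
  stopifnot(penumbra_sigma_mm >= 0, fluence_spacing_mm > 0,
            attenuation_per_mm >= 0)
  structure(
    list(penumbra_sigma_mm = penumbra_sigma_mm,
         fluence_spacing_mm = fluence_spacing_mm,
         attenuation_per_mm = attenuation_per_mm,
         calibration = calibration),
    class = "engine_config"
  )
}

# Separable Gaussian blur of a matrix, zero-padded at the borders.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    padded <- c(numeric(r), v, numeric(r))
    out <- numeric(n)
    for (i in seq_along(k)) out <- out + k[i] * padded[i:(i + n - 1)]
    out
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

# Aperture fluence of one control point on the (u, v) grid, using
# fractional cell coverage so the fluence varies continuously with leaf
# position (pointwise rasterization would quantize sub-cell leaf shifts).
cp_fluence <- function(cp, geometry, ug, vg) {
  du <- ug[2] - ug[1]
  dv <- vg[2] - vg[1]
  bounds <- geometry$leaf_boundaries_mm
  f <- matrix(0, nrow = length(vg), ncol = length(ug))
  for (s in seq_len(geometry$n_pairs)) {
    lo <- max(cp$x1_mm[s], cp$jaw_x_mm[1])
    hi <- min(cp$x2_mm[s], cp$jaw_x_mm[2])
    if (hi <= lo) next
    ylo <- max(bounds[s], cp$jaw_y_mm[1])
    yhi <- min(bounds[s + 1], cp$jaw_y_mm[2])
    if (yhi <= ylo) next
    cov_v <- pmin(pmax((pmin(yhi, vg + dv / 2) - pmax(ylo, vg - dv / 2)) / dv, 0), 1)
    cov_u <- pmin(pmax((pmin(hi, ug + du / 2) - pmax(lo, ug - du / 2)) / du, 0), 1)
    nzv <- which(cov_v > 0)
    nzu <- which(cov_u > 0)
    if (length(nzv) == 0 || length(nzu) == 0) next
    f[nzv, nzu] <- f[nzv, nzu] + outer(cov_v[nzv], cov_u[nzu])
  }
  pmin(f, 1)
}

#' Compute a per-fraction dose grid for a plan on a phantom
#'
#' @param plan A [vmat_plan()].
#' @param phantom A [make_phantom()] result.
#' @param config An [engine_config()]. Pass the reference plan's stored
#'   calibration (via `config$calibration <- dose$calibration`) when
#'   recomputing dose for that plan's error variants.
#'
#' @return An object of class `dose_grid`: list with `values_gy` (3-D array
#'   matching the phantom shape), `spacing_mm`, `shape`, and `calibration`
#'   (the Gy-per-fluence scale factor actually used).
#' @export
compute_dose <- function(plan, phantom, config = engine_config()) {
  stopifnot(inherits(plan, "vmat_plan"), inherits(phantom, "phantom"))
  nx <- phantom$shape[1]; ny <- phantom$shape[2]; nz <- phantom$shape[3]
  xs <- phantom$xs; ys <- phantom$ys; zs <- phantom$zs
  # Voxel coordinates in the gantry rotation plane, flattened over (x, z).
  X <- rep(xs, times = nz)
  Z <- rep(zs, each = nx)
  raw <- matrix(0, nrow = nx * nz, ncol = ny)   # dose as (x*z) x y

  for (b in plan$beams) {
    geom <- b$geometry
    cps <- b$control_points
    n_cp <- length(cps)
    # Fluence grid fixed per beam: covers the whole-arc jaw envelope.
    jaw_lo <- min(vapply(cps, function(cp) cp$jaw_x_mm[1], numeric(1)))
    jaw_hi <- max(vapply(cps, function(cp) cp$jaw_x_mm[2], numeric(1)))
    pad <- 3 * config$penumbra_sigma_mm + 2 * config$fluence_spacing_mm
    du <- config$fluence_spacing_mm
    ug <- seq(jaw_lo - pad, jaw_hi + pad, by = du)
    vg <- seq(min(ys) - pad, max(ys) + pad, by = du)
    # Precompute interpolation of the v-axis onto the phantom y grid.
    iv <- findInterval(ys, vg)
    iv <- pmin(pmax(iv, 1L), length(vg) - 1L)
    wv <- (ys - vg[iv]) / du
    sigma_px <- config$penumbra_sigma_mm / du

    for (j in seq_len(n_cp - 1)) {
      w <- b$beam_mu * (cps[[j + 1]]$cum_weight - cps[[j]]$cum_weight)
      if (w <= 0) next
      # Interval aperture = start control point; direction = interval mean.
      f <- gaussian_blur(cp_fluence(cps[[j]], geom, ug, vg), sigma_px)
      th <- (cps[[j]]$gantry_deg +
               (cps[[j + 1]]$gantry_deg - cps[[j]]$gantry_deg) / 2) * pi / 180
      u <- X * cos(th) + Z * sin(th)
      iu <- floor((u - ug[1]) / du) + 1
      iu <- pmin(pmax(iu, 1L), length(ug) - 1L)
      wu <- (u - ug[iu]) / du
      wu <- pmin(pmax(wu, 0), 1)
      # Bilinear gather: rows = v (phantom y), cols = u.
      f00 <- f[iv, iu, drop = FALSE]        # ny x (nx*nz)
      f01 <- f[iv, iu + 1L, drop = FALSE]
      f10 <- f[iv + 1L, iu, drop = FALSE]
      f11 <- f[iv + 1L, iu + 1L, drop = FALSE]
      wu_row <- matrix(wu, nrow = ny, ncol = length(wu), byrow = TRUE)
      fl <- (1 - wu_row) * ((1 - wv) * f00 + wv * f10) +
        wu_row * ((1 - wv) * f01 + wv * f11)
      if (config$attenuation_per_mm > 0) {
        s <- X * sin(th) - Z * cos(th)      # distance along the beam axis
        depth <- s - min(s)
        att <- exp(-config$attenuation_per_mm * depth)
        raw <- raw + w * t(fl) * att
      } else {
        raw <- raw + w * t(fl)
      }
    }
  }

  # Reshape (x*z) x y -> x, y, z.
  dose <- aperm(array(raw, dim = c(nx, nz, ny)), c(1, 3, 2))
  calib <- config$calibration
  if (is.null(calib)) {
    mt <- mean(dose[phantom$masks$target])
    if (mt <= 0) stop("cannot calibrate: zero target dose")
    calib <- plan$fractionation$dose_per_fraction_gy / mt
  }
  structure(
    list(values_gy = dose * calib, spacing_mm = phantom$spacing_mm,
         shape = phantom$shape, calibration = calib),
    class = "dose_grid"
  )
}
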