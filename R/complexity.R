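# Plan-complexity metrics: MU/Gy and plan irregularity (PI) after Du et al.
# PI chains three levels: aperture irregularity AI = perimeter^2 / (4 pi
# area) per control point, beam irregularity BI = MU-weighted mean AI over a
# beam's segments, and PI = beam-MU-weighted mean BI over beams.

#' MU per Gy of a plan
#'
#' Total plan meterset divided by the fraction dose - the simplest
#' modulation-complexity surrogate.
#'
#' @param plan A [vmat_plan()].
#' @return MU/Gy.
#' @export
mu_per_gy <- function(plan) {
  d <- plan$fractionation$dose_per_fraction_gy
  if (is.null(d) || d <= 0) stop("dose per fraction must be positive")
  total_mu(plan) / d
}

#' Aperture geometry of one control point
#'
#' The open region is the union over leaf pairs of
#' `[max(x1, jaw_x_lo), min(x2, jaw_x_hi)] x (leaf strip intersect jaw_y)`;
#' strips with non-positive extent are excluded. Area and perimeter are
#' computed analytically for the rectilinear union (leaf-end verticals,
#' inter-strip horizontal steps, top/bottom caps); disconnected sub-regions
#' are summed.
#'
#' @param cp A [control_point()].
#' @param geom An [mlc_geometry()].
#' @return An object of class `aperture_geometry`: list with `area_mm2`,
#'   `perimeter_mm`, `n_subapertures`.
#' @export
aperture_geometry <- function(cp, geom) {
  bounds <- geom$leaf_boundaries_mm
  lo_y <- pmax(bounds[-length(bounds)], cp$jaw_y_mm[1])
  hi_y <- pmin(bounds[-1], cp$jaw_y_mm[2])
  h <- pmax(hi_y - lo_y, 0)
  a <- pmax(cp$x1_mm, cp$jaw_x_mm[1])
  b <- pmin(cp$x2_mm, cp$jaw_x_mm[2])
  open <- h > 0 & b > a
  if (!any(open)) {
    return(structure(list(area_mm2 = 0, perimeter_mm = 0, n_subapertures = 0L),
                     class = "aperture_geometry"))
  }
  # Represent every strip; closed strips carry empty intervals.
  a[!open] <- 0; b[!open] <- 0; h[!open] <- 0
  w <- b - a
  area <- sum(w * h)
  n <- length(w)
  # Verticals: left and right leaf ends of each open strip.
  perim <- sum(2 * h[open])
  # Horizontals between consecutive strips: symmetric difference of the two
  # open intervals; top/bottom caps fall out of the same formula with empty
  # neighbors. Strips separated by closed strips contribute full caps.
  a_ext <- c(0, a); b_ext <- c(0, b); w_ext <- c(0, w)
  for (i in seq_len(n + 1)) {
    w1 <- w_ext[i]
    w2 <- if (i <= n) w[i] else 0
    ov <- max(0, min(b_ext[i], if (i <= n) b[i] else 0) -
                   max(a_ext[i], if (i <= n) a[i] else 0))
    if (w1 == 0 || w2 == 0) ov <- 0
    perim <- perim + w1 + w2 - 2 * ov
  }
  # Count connected sub-apertures: consecutive open strips with overlapping
  # intervals belong to one component.
  comp <- 0L
  prev_open <- FALSE
  for (i in seq_len(n)) {
    if (w[i] > 0) {
      joined <- prev_open &&
        min(b[i - 1], b[i]) - max(a[i - 1], a[i]) > 0
      if (!joined) comp <- comp + 1L
      prev_open <- TRUE
    } else {
      prev_open <- FALSE
    }
  }
  structure(list(area_mm2 = area, perimeter_mm = perim, n_subapertures = comp),
            class = "aperture_geometry")
}

#' Aperture irregularity
#'
#' `AI = perimeter^2 / (4 * pi * area)`: 1 for a circle, `4 / pi` for a
#' square (the axis-aligned lower bound), larger for elongated or jagged
#' apertures.
#'
#' @param ag An [aperture_geometry()].
#' @return AI (unitless).
#' @export
aperture_irregularity <- function(ag) {
  if (ag$area_mm2 <= 0) stop("aperture irregularity undefined for zero area")
  ag$perimeter_mm^2 / (4 * pi * ag$area_mm2)
}

#' Plan irregularity and MU/Gy of a plan
#'
#' Segment meterset of interval `j` is `beam_mu * (cum_weight[j+1] -
#' cum_weight[j])`, attributed to the interval's start control-point
#' aperture. Beam irregularity is the segment-MU-weighted mean AI over open
#' segments; PI is the beam-MU-weighted mean BI. Zero-area control points
#' are skipped and (by default) their MU excluded from the denominator.
#'
#' @param plan A [vmat_plan()].
#' @param include_closed_mu Include the MU of zero-area segments in the BI
#'   denominator (default `FALSE`).
#' @return An object of class `complexity_result`: list with `mu_per_gy`,
#'   `pi`, `per_beam_bi` (tibble) and `per_cp_ai` (tibble).
#' @export
plan_irregularity <- function(plan, include_closed_mu = FALSE) {
  per_cp <- list()
  bi_rows <- list()
  for (bi_idx in seq_along(plan$beams)) {
    b <- plan$beams[[bi_idx]]
    cps <- b$control_points
    n_seg <- length(cps) - 1
    mu_j <- ai_j <- numeric(n_seg)
    open_j <- logical(n_seg)
    for (j in seq_len(n_seg)) {
      mu_j[j] <- b$beam_mu * (cps[[j + 1]]$cum_weight - cps[[j]]$cum_weight)
      ag <- aperture_geometry(cps[[j]], b$geometry)
      open_j[j] <- ag$area_mm2 > 0
      ai_j[j] <- if (open_j[j]) aperture_irregularity(ag) else NA_real_
    }
    per_cp[[bi_idx]] <- tibble::tibble(
      beam = b$beam_id, segment = seq_len(n_seg), segment_mu = mu_j, ai = ai_j
    )
    denom <- if (include_closed_mu) sum(mu_j) else sum(mu_j[open_j])
    if (denom <= 0) {
      bi_rows[[bi_idx]] <- tibble::tibble(beam = b$beam_id, beam_mu = b$beam_mu,
                                          bi = NA_real_)
    } else {
      bi_rows[[bi_idx]] <- tibble::tibble(
        beam = b$beam_id, beam_mu = b$beam_mu,
        bi = sum(mu_j[open_j] * ai_j[open_j]) / denom
      )
    }
  }
  bi_tbl <- dplyr::bind_rows(bi_rows)
  if (all(is.na(bi_tbl$bi))) stop("all apertures closed; PI undefined")
  ok <- !is.na(bi_tbl$bi)
  pi_val <- sum(bi_tbl$beam_mu[ok] * bi_tbl$bi[ok]) / sum(bi_tbl$beam_mu[ok])
  structure(
    list(mu_per_gy = mu_per_gy(plan), pi = pi_val,
         per_beam_bi = bi_tbl, per_cp_ai = dplyr::bind_rows(per_cp)),
    class = "complexity_result"
  )
}

#' Complexity metrics of one or more plans as a tibble
#'
#' @param plans A [vmat_plan()] or list of them.
#' @return A tibble with `plan_id`, `site`, `mu_per_gy`, `pi`.
#' @export
complexity_metrics <- function(plans) {
  if (inherits(plans, "vmat_plan")) plans <- list(plans)
  purrr::map_dfr(plans, function(p) {
    cr <- plan_irregularity(p)
    tibble::tibble(plan_id = p$plan_id, site = p$site,
                   mu_per_gy = cr$mu_per_gy, pi = cr$pi)
  })
}
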