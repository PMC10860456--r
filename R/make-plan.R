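# Synthetic VMAT sequence generator. Produces a single 360-degree arc whose
# apertures conform to the target's beam's-eye-view (BEV) outline, with
# per-leaf sinusoidal/random perturbations, gap narrowing and MU roughening
# scaled by a `modulation` knob in [0, 1]. The knob is explicit: the cohort
# needs plans spanning a wide complexity range, not clinically optimized
# deliverable plans.

#' Generate a synthetic VMAT plan for a phantom
#'
#' Builds one full arc whose aperture at each control point conforms to the
#' target outline in the beam's eye view, then modulates it.
#'
#' @param template A [site_template()].
#' @param phantom A [make_phantom()] result built from the same template.
#' @param modulation Real in `[0, 1]`. Scales per-leaf aperture
#'   perturbations, leaf-gap narrowing, MU-weight roughening and total MU.
#'   At 0 every aperture is exactly the target outline plus margin; higher
#'   values raise both MU/Gy and plan irregularity (MU/Gy spans a > 3x range
#'   over modulation 0.1-0.9).
#' @param tps_profile `"jaw_tracking"` (jaws fit the open leaves per control
#'   point) or `"fixed_jaw"` (jaws fixed to the whole-arc envelope, with
#'   slightly larger leaf-position jitter) - two sequence styles emulating
#'   different planning systems.
#' @param beam_type `"FF"` or `"FFF"`; a label only.
#' @param case_seed Integer seed; generation is deterministic given all
#'   arguments.
#' @param fractionation `"standard"` or `"hypo"`, selecting the template
#'   prescription.
#' @param n_control_points Control points per arc (default 90).
#' @param geometry MLC geometry (default [mlc_geometry()]).
#'
#' @return A validated [vmat_plan()] carrying `modulation` and `case_seed`
#'   as attributes.
#' @export
make_plan <- function(template, phantom, modulation = 0.5,
                      tps_profile = c("jaw_tracking", "fixed_jaw"),
                      beam_type = c("FF", "FFF"),
                      case_seed = 1,
                      fractionation = c("standard", "hypo"),
                      n_control_points = 90,
                      geometry = mlc_geometry()) {
  stopifnot(inherits(template, "site_template"), inherits(phantom, "phantom"),
            modulation >= 0, modulation <= 1, n_control_points >= 2)
  tps_profile <- match.arg(tps_profile)
  beam_type <- match.arg(beam_type)
  fx_label <- match.arg(fractionation)
  rx <- template$prescriptions[[fx_label]]
  margin <- template$aperture_margin_mm

  tgt <- which(phantom$masks$target, arr.ind = TRUE)
  xt <- phantom$xs[tgt[, 1]]; yt <- phantom$ys[tgt[, 2]]; zt <- phantom$zs[tgt[, 3]]
  bounds <- geometry$leaf_boundaries_mm
  strip_of <- findInterval(yt, bounds, rightmost.closed = TRUE)
  keep <- strip_of >= 1 & strip_of <= geometry$n_pairs
  if (!any(keep)) stop("target projects onto no MLC leaf strip")
  xt <- xt[keep]; yt <- yt[keep]; zt <- zt[keep]; strip_of <- strip_of[keep]
  by_strip <- split(seq_along(strip_of), strip_of)
  open_strips <- as.integer(names(by_strip))

  n_cp <- as.integer(n_control_points)
  theta <- (seq_len(n_cp) - 1) * 360 / n_cp
  th_rad <- theta * pi / 180

  local_seed(case_seed, {
    # Per-leaf modulation pattern parameters; drawn once so that `modulation`
    # only scales amplitudes (monotone complexity response at fixed seed).
    np <- geometry$n_pairs
    freq1 <- sample(2:5, np, replace = TRUE)
    freq2 <- sample(2:5, np, replace = TRUE)
    phase1 <- stats::runif(np, 0, 2 * pi)
    phase2 <- stats::runif(np, 0, 2 * pi)
    depth1 <- stats::runif(np, 0.5, 1)
    depth2 <- stats::runif(np, 0.5, 1)
    jitter <- array(stats::rnorm(np * n_cp * 2), dim = c(np, n_cp, 2))
    wk <- 1 + 1.5 * modulation * stats::runif(n_cp - 1)
    mu_noise <- stats::rnorm(1, 0, 0.06)
    avoid_phase <- stats::runif(1, 0, 2 * pi)
    alt <- rep_len(c(0, 1), np)

    tps_jitter <- if (tps_profile == "fixed_jaw") 1.3 else 1
    amp <- modulation * template$complexity_scale * 10 * tps_jitter  # mm
    gap_floor <- max(geometry$min_gap_mm, 2)

    cord <- template$oars$spinal_cord
    x1_mat <- matrix(NA_real_, np, n_cp)
    x2_mat <- matrix(NA_real_, np, n_cp)

    for (k in seq_len(n_cp)) {
      u <- xt * cos(th_rad[k]) + zt * sin(th_rad[k])
      x1 <- rep(NA_real_, np); x2 <- rep(NA_real_, np)
      for (j in seq_along(open_strips)) {
        s <- open_strips[j]
        us <- u[by_strip[[j]]]
        x1[s] <- min(us) - margin
        x2[s] <- max(us) + margin
      }
      # Open one extra strip beyond each end of the target extent (margin in
      # the leaf-stack direction), mirroring the adjacent strip's interval;
      # without it the target poles sit in the field's Y penumbra and pin
      # the cold-spot-weighted gEUD.
      s_lo <- min(open_strips); s_hi <- max(open_strips)
      if (s_lo > 1) { x1[s_lo - 1] <- x1[s_lo]; x2[s_lo - 1] <- x2[s_lo] }
      if (s_hi < np) { x1[s_hi + 1] <- x1[s_hi]; x2[s_hi + 1] <- x2[s_hi] }
      # Spinal template: block the cord shadow, opening one side of the wrap
      # (the concave geometry that drives high modulation).
      if (template$site == "spine_met" && !is.null(cord)) {
        uc <- cord$center_mm[1] * cos(th_rad[k]) + cord$center_mm[3] * sin(th_rad[k])
        hb <- cord$radius_mm + 1
        open <- which(!is.na(x1))
        prefer_left <- sin(2 * th_rad[k] + avoid_phase) >= 0
        for (s in open) {
          wl <- (uc - hb) - x1[s]
          wr <- x2[s] - (uc + hb)
          use_left <- if (prefer_left) wl >= 4 || wl >= wr else !(wr >= 4 || wr >= wl)
          if (use_left) x2[s] <- min(x2[s], uc - hb) else x1[s] <- max(x1[s], uc + hb)
        }
      }
      # Modulation: inward sinusoidal narrowing, a deterministic alternating
      # leaf-end zig-zag (tongue-like stair-stepping that raises perimeter
      # monotonically with modulation), and random jitter per leaf.
      open <- which(!is.na(x1))
      p1 <- 0.5 * (1 + sin(2 * pi * freq1 * k / n_cp + phase1))
      p2 <- 0.5 * (1 + sin(2 * pi * freq2 * k / n_cp + phase2))
      x1[open] <- x1[open] + amp * depth1[open] * p1[open] +
        0.4 * amp * alt[open] + 0.25 * amp * jitter[open, k, 1]
      x2[open] <- x2[open] - amp * depth2[open] * p2[open] -
        0.4 * amp * (1 - alt[open]) - 0.25 * amp * jitter[open, k, 2]
      # Keep a mechanical floor on the gap (symmetric clamp).
      bad <- open[x2[open] - x1[open] < gap_floor]
      if (length(bad) > 0) {
        mid <- (x1[bad] + x2[bad]) / 2
        x1[bad] <- mid - gap_floor / 2
        x2[bad] <- mid + gap_floor / 2
      }
      x1_mat[, k] <- x1
      x2_mat[, k] <- x2
    }

    # Jaws: per-control-point fit (tracking) or whole-arc envelope (fixed).
    s_all_lo <- max(min(open_strips) - 1, 1)
    s_all_hi <- min(max(open_strips) + 1, np)
    ylo <- bounds[s_all_lo]; yhi <- bounds[s_all_hi + 1]
    jx_cp <- sapply(seq_len(n_cp), function(k) {
      ok <- !is.na(x1_mat[, k])
      c(min(x1_mat[ok, k]), max(x2_mat[ok, k]))
    })
    if (tps_profile == "jaw_tracking") {
      jaw_x <- jx_cp
    } else {
      env <- c(min(jx_cp[1, ]), max(jx_cp[2, ]))
      jaw_x <- matrix(env, nrow = 2, ncol = n_cp)
    }

    # Park closed pairs well behind the low X jaw so they never contribute.
    for (k in seq_len(n_cp)) {
      closed <- is.na(x1_mat[, k])
      px <- jaw_x[1, k] - 10
      x1_mat[closed, k] <- px - geometry$min_gap_mm / 2
      x2_mat[closed, k] <- px + geometry$min_gap_mm / 2
    }

    cum_w <- c(0, cumsum(wk)) / sum(wk)
    cum_w[n_cp] <- 1

    mu_per_gy_val <- 85 * (1 + 3.5 * modulation) *
      (0.85 + 0.3 * template$complexity_scale) * exp(mu_noise)
    beam_mu <- mu_per_gy_val * rx$dose_per_fraction_gy

    cps <- lapply(seq_len(n_cp), function(k) {
      control_point(
        index = k - 1L, gantry_deg = theta[k], cum_weight = cum_w[k],
        x1_mm = x1_mat[, k], x2_mm = x2_mat[, k],
        jaw_x_mm = jaw_x[, k], jaw_y_mm = c(ylo, yhi)
      )
    })
    b <- beam("arc1", beam_mu, cps, geometry)
    p <- vmat_plan(
      plan_id = sprintf("%s_%s_%s_%s_s%d", template$site, tps_profile,
                        fx_label, beam_type, case_seed),
      site = template$site, fractionation = rx, beams = list(b),
      tps_profile = tps_profile, beam_type = beam_type
    )
    attr(p, "modulation") <- modulation
    attr(p, "case_seed") <- case_seed
    attr(p, "fractionation_label") <- fx_label
    p
  })
}
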