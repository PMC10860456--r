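# Domain types for VMAT plans: MLC geometry, control points, beams, plans.
# Coordinates follow IEC 61217: leaf positions in mm projected to the
# isocenter plane, bank 1 (x1) is the negative-X bank, leaf strips are
# stacked along Y. All lengths are mm, meterset in MU, dose in Gy.

#' MLC geometry
#'
#' Describes a single-layer MLC: the number of opposed leaf pairs, their
#' physical widths projected to the isocenter plane, and the smallest
#' mechanically allowed gap between opposing leaves.
#'
#' @param n_pairs Number of opposed leaf pairs.
#' @param leaf_width_mm Leaf width(s) at isocenter (mm). Either a scalar
#'   (uniform leaves) or a vector of length `n_pairs`.
#' @param min_gap_mm Smallest mechanically allowed leaf gap (mm, >= 0).
#' @param center_mm Y coordinate of the center of the leaf bank (mm).
#'
#' @return An object of class `mlc_geometry` with fields `n_pairs`,
#'   `leaf_width_mm`, `leaf_boundaries_mm` (length `n_pairs + 1`, ascending)
#'   and `min_gap_mm`.
#'
#' @details The default (80 pairs of 5-mm leaves) is a generic modern
#'   single-layer MLC; it is a package default, not a vendor datum.
#'
#' @examples
#' g <- mlc_geometry(n_pairs = 40, leaf_width_mm = 5)
#' range(g$leaf_boundaries_mm)
#' @export
mlc_geometry <- function(n_pairs = 80, leaf_width_mm = 5, min_gap_mm = 0.5,
                         center_mm = 0) {
  stopifnot(n_pairs >= 1, min_gap_mm >= 0)
  widths <- rep_len(leaf_width_mm, n_pairs)
  if (any(widths <= 0)) stop("leaf widths must be positive")
  bounds <- center_mm + cumsum(c(0, widths)) - sum(widths) / 2
  structure(
    list(
      n_pairs = as.integer(n_pairs),
      leaf_width_mm = widths,
      leaf_boundaries_mm = bounds,
      min_gap_mm = min_gap_mm
    ),
    class = "mlc_geometry"
  )
}

#' Control point of a VMAT arc
#'
#' A snapshot of machine state along the arc: gantry angle, cumulative
#' meterset weight, per-leaf bank positions and jaw positions.
#'
#' @param index Ordinal of the control point within its beam (0-based).
#' @param gantry_deg Gantry angle in degrees, `[0, 360)`.
#' @param cum_weight Cumulative meterset weight in `[0, 1]`.
#' @param x1_mm,x2_mm Bank-1 / bank-2 leaf positions at isocenter (mm);
#'   bank 1 is the negative-X bank, so `x1_mm[i] <= x2_mm[i]` pairwise.
#' @param jaw_x_mm,jaw_y_mm Length-2 jaw position pairs `(lo, hi)` in mm.
#'
#' @return An object of class `control_point`.
#' @export
control_point <- function(index, gantry_deg, cum_weight, x1_mm, x2_mm,
                          jaw_x_mm, jaw_y_mm) {
  structure(
    list(
      index = as.integer(index),
      gantry_deg = as.numeric(gantry_deg) %% 360,
      cum_weight = as.numeric(cum_weight),
      x1_mm = as.numeric(x1_mm),
      x2_mm = as.numeric(x2_mm),
      jaw_x_mm = as.numeric(jaw_x_mm),
      jaw_y_mm = as.numeric(jaw_y_mm)
    ),
    class = "control_point"
  )
}

#' Treatment beam (one VMAT arc)
#'
#' @param beam_id Beam label.
#' @param beam_mu Beam meterset (MU, > 0).
#' @param control_points Ordered list of [control_point()] objects (>= 2).
#' @param geometry An [mlc_geometry()].
#'
#' @return An object of class `beam`.
#' @export
beam <- function(beam_id, beam_mu, control_points, geometry) {
  structure(
    list(
      beam_id = as.character(beam_id),
      beam_mu = as.numeric(beam_mu),
      control_points = control_points,
      geometry = geometry
    ),
    class = "beam"
  )
}

#' Prescription (fractionation)
#'
#' @param dose_per_fraction_gy Dose per fraction (Gy, > 0).
#' @param n_fractions Number of fractions (>= 1).
#'
#' @return A list with `dose_per_fraction_gy`, `n_fractions` and the derived
#'   `total_dose_gy`.
#' @export
prescription <- function(dose_per_fraction_gy, n_fractions) {
  stopifnot(dose_per_fraction_gy > 0, n_fractions >= 1)
  list(
    dose_per_fraction_gy = as.numeric(dose_per_fraction_gy),
    n_fractions = as.integer(n_fractions),
    total_dose_gy = as.numeric(dose_per_fraction_gy) * as.integer(n_fractions)
  )
}

#' VMAT treatment plan
#'
#' @param plan_id Plan label.
#' @param site Treatment site, one of `"prostate"`, `"lung"`, `"brain_met"`,
#'   `"spine_met"`.
#' @param fractionation A [prescription()].
#' @param beams List of [beam()] objects.
#' @param tps_profile Sequence-style label (e.g. `"jaw_tracking"` or
#'   `"fixed_jaw"`); emulates planning-system sequencing differences only.
#' @param beam_type `"FF"` or `"FFF"` (label only; the dose engine ignores it).
#' @param validate Validate invariants on construction (default `TRUE`).
#'
#' @return An object of class `vmat_plan`.
#' @export
vmat_plan <- function(plan_id, site, fractionation, beams,
                      tps_profile = "jaw_tracking", beam_type = "FF",
                      validate = TRUE) {
  p <- structure(
    list(
      plan_id = as.character(plan_id),
      site = match.arg(site, c("prostate", "lung", "brain_met", "spine_met")),
      tps_profile = as.character(tps_profile),
      fractionation = fractionation,
      beam_type = match.arg(beam_type, c("FF", "FFF")),
      beams = beams
    ),
    class = "vmat_plan"
  )
  if (validate) validate_plan(p)
  p
}

#' Total meterset of a plan
#'
#' @param plan A [vmat_plan()].
#' @return Sum of beam metersets (MU).
#' @export
total_mu <- function(plan) {
  sum(vapply(plan$beams, function(b) b$beam_mu, numeric(1)))
}

#' Validate a plan against its structural invariants
#'
#' Checks leaf-pair ordering (`x1 <= x2`), monotone cumulative meterset
#' weights spanning `[0, 1]`, jaw ordering, positive metersets and
#' per-beam leaf counts matching the MLC geometry.
#'
#' @param plan A [vmat_plan()].
#' @return Invisibly `TRUE`; otherwise an error listing the offending
#'   beam / control-point / leaf indices.
#' @export
validate_plan <- function(plan) {
  if (!inherits(plan, "vmat_plan")) stop("not a vmat_plan object")
  fx <- plan$fractionation
  if (is.null(fx) || fx$dose_per_fraction_gy <= 0 || fx$n_fractions < 1) {
    stop("invalid fractionation: dose_per_fraction_gy must be > 0, n_fractions >= 1")
  }
  if (length(plan$beams) == 0) stop("plan has no beams")
  problems <- character(0)
  for (bi in seq_along(plan$beams)) {
    b <- plan$beams[[bi]]
    if (b$beam_mu <= 0) problems <- c(problems, sprintf("beam %d: beam_mu <= 0", bi))
    if (length(b$control_points) < 2) {
      problems <- c(problems, sprintf("beam %d: fewer than 2 control points", bi))
      next
    }
    n_pairs <- b$geometry$n_pairs
    cw <- vapply(b$control_points, function(cp) cp$cum_weight, numeric(1))
    if (abs(cw[1]) > 1e-9 || abs(cw[length(cw)] - 1) > 1e-9 || any(diff(cw) < -1e-12)) {
      problems <- c(problems, sprintf(
        "beam %d: cum_weight must be non-decreasing from 0 to 1", bi))
    }
    for (ci in seq_along(b$control_points)) {
      cp <- b$control_points[[ci]]
      if (length(cp$x1_mm) != n_pairs || length(cp$x2_mm) != n_pairs) {
        problems <- c(problems, sprintf(
          "beam %d cp %d: leaf vector length != n_pairs (%d)", bi, ci, n_pairs))
        next
      }
      crossed <- which(cp$x1_mm > cp$x2_mm + 1e-9)
      if (length(crossed) > 0) {
        problems <- c(problems, sprintf(
          "beam %d cp %d: crossed leaf pair(s) %s (x1 > x2)",
          bi, ci, paste(utils::head(crossed, 5), collapse = ", ")))
      }
      if (cp$jaw_x_mm[1] > cp$jaw_x_mm[2] || cp$jaw_y_mm[1] > cp$jaw_y_mm[2]) {
        problems <- c(problems, sprintf("beam %d cp %d: jaws out of order", bi, ci))
      }
    }
  }
  if (length(problems) > 0) {
    stop("plan validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' @export
print.vmat_plan <- function(x, ...) {
  fx <- x$fractionation
  cat(sprintf(
    "<vmat_plan> %s  site=%s  %s/%s  %g Gy x %d fx  %d beam(s)  %.1f MU total\n",
    x$plan_id, x$site, x$tps_profile, x$beam_type,
    fx$dose_per_fraction_gy, fx$n_fractions, length(x$beams), total_mu(x)))
  invisible(x)
}

# ---- JSON serialization -----------------------------------------------------
# JSON dialect (units: mm, MU, Gy):
# {
#   "plan_id": str, "site": str, "tps_profile": str, "beam_type": "FF"|"FFF",
#   "fractionation": {"dose_per_fraction_gy": num, "n_fractions": int},
#   "beams": [{
#     "beam_id": str, "beam_mu": num,
#     "geometry": {"n_pairs": int, "leaf_width_mm": [num], "min_gap_mm": num,
#                  "leaf_boundaries_mm": [num]},
#     "control_points": [{
#       "index": int, "gantry_deg": num, "cum_weight": num,
#       "x1_mm": [num], "x2_mm": [num], "jaw_x_mm": [lo, hi], "jaw_y_mm": [lo, hi]
#     }]
#   }]
# }

plan_to_list <- function(plan) {
  list(
    plan_id = plan$plan_id,
    site = plan$site,
    tps_profile = plan$tps_profile,
    beam_type = plan$beam_type,
    fractionation = list(
      dose_per_fraction_gy = plan$fractionation$dose_per_fraction_gy,
      n_fractions = plan$fractionation$n_fractions
    ),
    beams = lapply(plan$beams, function(b) {
      list(
        beam_id = b$beam_id,
        beam_mu = b$beam_mu,
        geometry = list(
          n_pairs = b$geometry$n_pairs,
          leaf_width_mm = b$geometry$leaf_width_mm,
          min_gap_mm = b$geometry$min_gap_mm,
          leaf_boundaries_mm = b$geometry$leaf_boundaries_mm
        ),
        control_points = lapply(b$control_points, function(cp) {
          list(
            index = cp$index, gantry_deg = cp$gantry_deg,
            cum_weight = cp$cum_weight,
            x1_mm = cp$x1_mm, x2_mm = cp$x2_mm,
            jaw_x_mm = cp$jaw_x_mm, jaw_y_mm = cp$jaw_y_mm
          )
        })
      )
    })
  )
}

plan_from_list <- function(x) {
  beams <- lapply(x$beams, function(b) {
    g <- b$geometry
    geom <- structure(
      list(
        n_pairs = as.integer(g$n_pairs),
        leaf_width_mm = as.numeric(g$leaf_width_mm),
        leaf_boundaries_mm = as.numeric(g$leaf_boundaries_mm),
        min_gap_mm = as.numeric(g$min_gap_mm)
      ),
      class = "mlc_geometry"
    )
    cps <- lapply(b$control_points, function(cp) {
      control_point(cp$index, cp$gantry_deg, cp$cum_weight,
                    cp$x1_mm, cp$x2_mm, cp$jaw_x_mm, cp$jaw_y_mm)
    })
    beam(b$beam_id, b$beam_mu, cps, geom)
  })
  vmat_plan(
    plan_id = x$plan_id, site = x$site,
    fractionation = prescription(x$fractionation$dose_per_fraction_gy,
                                 x$fractionation$n_fractions),
    beams = beams, tps_profile = x$tps_profile, beam_type = x$beam_type
  )
}

#' Read a plan from disk
#'
#' @param path File path.
#' @param dialect Serialization dialect. Only the package's JSON dialect is
#'   implemented; `"dicom_rtplan"` is recognised but unsupported in this
#'   build and raises an error.
#'
#' @return A validated [vmat_plan()].
#' @export
read_plan <- function(path, dialect = c("json", "dicom_rtplan")) {
  dialect <- match.arg(dialect)
  if (dialect == "dicom_rtplan") {
    stop("dialect 'dicom_rtplan' is not supported in this build; ",
         "use the JSON plan dialect")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE),
    error = function(e) stop("malformed JSON plan file '", path, "': ",
                             conditionMessage(e))
  )
  for (field in c("plan_id", "site", "fractionation", "beams")) {
    if (is.null(x[[field]])) stop("malformed plan file: missing element '", field, "'")
  }
  plan_from_list(x)
}

#' Write a plan to disk
#'
#' Round trips through [read_plan()] reproduce every numeric field to better
#' than 0.001 mm.
#'
#' @param plan A valid [vmat_plan()].
#' @param path Output file path.
#' @param dialect See [read_plan()].
#' @return Invisibly `path`.
#' @export
write_plan <- function(plan, path, dialect = c("json", "dicom_rtplan")) {
  dialect <- match.arg(dialect)
  if (dialect == "dicom_rtplan") {
    stop("dialect 'dicom_rtplan' is not supported in this build; ",
         "use the JSON plan dialect")
  }
  validate_plan(plan)
  jsonlite::write_json(plan_to_list(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
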