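# MLC positional-error injection: systematic close/open bank displacements
# and per-leaf Gaussian random displacements, applied at every control point.

#' Specify an MLC positional error
#'
#' @param mode `"systematic_close"`, `"systematic_open"` or `"random"`.
#'   Close moves both banks toward each other by `magnitude_mm` each (the
#'   gap shrinks by twice the magnitude); open is the reverse; random adds
#'   an independent zero-mean Gaussian displacement with SD `magnitude_mm`
#'   to every non-parked leaf position.
#' @param magnitude_mm Positive displacement (mm). The study grid is
#'   `c(0.25, 0.5, 1, 2)` but any positive value is allowed.
#' @param seed Integer seed (required for `mode = "random"`).
#' @param perturb_parked Also displace parked leaf pairs (closed and fully
#'   outside the Y jaws)? Default `FALSE`.
#'
#' @return An object of class `error_spec`.
#' @export
error_spec <- function(mode = c("systematic_close", "systematic_open", "random"),
                       magnitude_mm, seed = NULL, perturb_parked = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(magnitude_mm), magnitude_mm > 0)
  if (mode == "random" && is.null(seed)) stop("random mode requires a seed")
  structure(
    list(mode = mode, magnitude_mm = as.numeric(magnitude_mm),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         perturb_parked = isTRUE(perturb_parked)),
    class = "error_spec"
  )
}

# A leaf pair is parked when it is closed (gap <= min_gap) and its strip lies
# fully outside the jaw-defined field in Y. Perturbing parked pairs is
# physically meaningless and would flood the clamp log.
parked_pairs <- function(cp, geometry) {
  bounds <- geometry$leaf_boundaries_mm
  lo <- bounds[-length(bounds)]
  hi <- bounds[-1]
  closed <- (cp$x2_mm - cp$x1_mm) <= geometry$min_gap_mm + 1e-9
  outside_y <- hi <= cp$jaw_y_mm[1] + 1e-9 | lo >= cp$jaw_y_mm[2] - 1e-9
  closed & outside_y
}

# Shared displacement applier: `d1`/`d2` are per-leaf displacement vectors for
# bank 1 / bank 2 at one control point. Returns the clamped positions plus the
# indices of clamped pairs.
displace_cp <- function(cp, geometry, d1, d2, perturb_parked) {
  sel <- if (perturb_parked) rep(TRUE, geometry$n_pairs) else !parked_pairs(cp, geometry)
  x1 <- cp$x1_mm; x2 <- cp$x2_mm
  x1[sel] <- x1[sel] + d1[sel]
  x2[sel] <- x2[sel] + d2[sel]
  min_gap <- geometry$min_gap_mm
  clamped <- which(sel & (x1 > x2 - min_gap + 1e-12))
  if (length(clamped) > 0) {
    mid <- (x1[clamped] + x2[clamped]) / 2
    x1[clamped] <- mid - min_gap / 2
    x2[clamped] <- mid + min_gap / 2
  }
  list(x1 = x1, x2 = x2, clamped = clamped)
}

apply_error_cps <- function(plan, make_displacements, perturb_parked) {
  log_beam <- integer(0); log_cp <- integer(0); log_leaf <- integer(0)
  for (bi in seq_along(plan$beams)) {
    b <- plan$beams[[bi]]
    for (ci in seq_along(b$control_points)) {
      cp <- b$control_points[[ci]]
      d <- make_displacements(b$geometry$n_pairs)
      res <- displace_cp(cp, b$geometry, d$d1, d$d2, perturb_parked)
      cp$x1_mm <- res$x1
      cp$x2_mm <- res$x2
      plan$beams[[bi]]$control_points[[ci]] <- cp
      if (length(res$clamped) > 0) {
        log_beam <- c(log_beam, rep(bi, length(res$clamped)))
        log_cp <- c(log_cp, rep(ci, length(res$clamped)))
        log_leaf <- c(log_leaf, res$clamped)
      }
    }
  }
  attr(plan, "clamp_log") <- tibble::tibble(beam = log_beam, cp = log_cp,
                                            leaf = log_leaf)
  plan
}

#' Apply a systematic close/open MLC error
#'
#' Close: `x1 + delta, x2 - delta` (the gap shrinks by `2 * delta`); open is
#' the reverse. Applied to every non-parked leaf pair at every control
#' point. Pairs whose gap would fall below the geometry's minimum gap are
#' clamped symmetrically about their midpoint and recorded in the clamp log
#' (`attr(plan, "clamp_log")`, a tibble of beam/cp/leaf indices). Jaws and
#' MU weights are untouched; the input plan is not modified.
#'
#' @param plan A [vmat_plan()].
#' @param spec An [error_spec()] with a systematic mode.
#' @return A new plan with displaced leaves and a `clamp_log` attribute.
#' @export
apply_systematic <- function(plan, spec) {
  stopifnot(inherits(plan, "vmat_plan"), inherits(spec, "error_spec"))
  if (!spec$mode %in% c("systematic_close", "systematic_open")) {
    stop("apply_systematic requires mode systematic_close or systematic_open")
  }
  delta <- spec$magnitude_mm * if (spec$mode == "systematic_close") 1 else -1
  out <- apply_error_cps(
    plan,
    function(n) list(d1 = rep(delta, n), d2 = rep(-delta, n)),
    spec$perturb_parked
  )
  out$plan_id <- paste0(plan$plan_id, "_", spec$mode, "_", spec$magnitude_mm)
  out
}

#' Apply random per-leaf Gaussian MLC errors
#'
#' Every non-parked leaf position (each bank, each leaf, each control point)
#' receives an independent zero-mean Gaussian displacement with standard
#' deviation `spec$magnitude_mm`. Deterministic for a given `spec$seed`;
#' crossing pairs are clamped as in [apply_systematic()].
#'
#' @inheritParams apply_systematic
#' @return A new plan with displaced leaves and a `clamp_log` attribute.
#' @export
apply_random <- function(plan, spec) {
  stopifnot(inherits(plan, "vmat_plan"), inherits(spec, "error_spec"))
  if (spec$mode != "random") stop("apply_random requires mode 'random'")
  if (is.null(spec$seed)) stop("random mode requires a seed")
  sigma <- spec$magnitude_mm
  out <- local_seed(spec$seed, {
    apply_error_cps(
      plan,
      function(n) list(d1 = stats::rnorm(n, 0, sigma),
                       d2 = stats::rnorm(n, 0, sigma)),
      spec$perturb_parked
    )
  })
  out$plan_id <- paste0(plan$plan_id, "_random_", sigma, "_s", spec$seed)
  out
}

#' Apply any MLC error spec
#'
#' Dispatches to [apply_systematic()] or [apply_random()] by `spec$mode`.
#'
#' @inheritParams apply_systematic
#' @return The perturbed plan.
#' @export
apply_error <- function(plan, spec) {
  if (spec$mode == "random") apply_random(plan, spec) else apply_systematic(plan, spec)
}

#' Build the full error-plan set for a cohort
#'
#' Cross product of reference plans x modes x magnitudes (x replicates for
#' the random mode). With 640 reference plans, the two systematic modes and
#' the four-magnitude study grid this enumerates 5120 systematic error
#' plans.
#'
#' @param plans List of reference [vmat_plan()]s (or anything with a
#'   length; only the enumeration is materialized here).
#' @param grid Numeric vector of error magnitudes (mm); must be non-empty.
#' @param modes Character vector of [error_spec()] modes.
#' @param n_replicates Replicates per magnitude for the random mode
#'   (default 1).
#' @param base_seed Seed from which random-mode spec seeds derive.
#'
#' @return A tibble with one row per error plan: `plan_index`, `mode`,
#'   `magnitude_mm`, `replicate`, `seed` and a list-column `spec`.
#' @export
build_error_set <- function(plans, grid, modes = c("systematic_close", "systematic_open"),
                            n_replicates = 1, base_seed = 1) {
  if (length(grid) == 0) stop("empty error-magnitude grid")
  stopifnot(all(grid > 0), n_replicates >= 1)
  modes <- match.arg(modes, c("systematic_close", "systematic_open", "random"),
                     several.ok = TRUE)
  out <- vector("list", length(modes))
  for (mi in seq_along(modes)) {
    mode <- modes[mi]
    reps <- if (mode == "random") n_replicates else 1
    g <- expand.grid(plan_index = seq_along(plans), magnitude_mm = grid,
                     replicate = seq_len(reps))
    g$mode <- mode
    out[[mi]] <- g
  }
  out <- tibble::as_tibble(do.call(rbind, out))
  out$seed <- NA_integer_
  is_rand <- out$mode == "random"
  if (any(is_rand)) {
    out$seed[is_rand] <- vapply(which(is_rand), function(i) derive_seed(base_seed, i),
                                integer(1))
  }
  out$spec <- purrr::pmap(
    out[, c("mode", "magnitude_mm", "seed")],
    function(mode, magnitude_mm, seed) {
      error_spec(mode, magnitude_mm,
                 seed = if (is.na(seed)) NULL else seed)
    }
  )
  out[, c("plan_index", "mode", "magnitude_mm", "replicate", "seed", "spec")]
}
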