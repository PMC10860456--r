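# Cohort design and enumeration: the full factorial of sites x sequence
# profiles x fractionations x beam types x cases, with deterministic
# per-case seeds and modulation values.

#' Define a cohort design
#'
#' @param sites Character vector of site labels (see [site_template()]).
#' @param tps_profiles Sequence-style profiles (default both
#'   `"jaw_tracking"` and `"fixed_jaw"`).
#' @param fractionations Fractionation labels (default `"standard"` and
#'   `"hypo"`).
#' @param beam_types Beam labels (default `"FF"` and `"FFF"`).
#' @param n_cases Cases per design cell (default 20).
#' @param base_seed Integer master seed; all per-case seeds and modulation
#'   values derive from it.
#' @param modulation_range Range from which per-case modulation values are
#'   drawn uniformly (default `c(0.2, 0.8)`).
#'
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(sites = c("prostate", "lung", "brain_met", "spine_met"),
                          tps_profiles = c("jaw_tracking", "fixed_jaw"),
                          fractionations = c("standard", "hypo"),
                          beam_types = c("FF", "FFF"),
                          n_cases = 20, base_seed = 1,
                          modulation_range = c(0.2, 0.8)) {
  stopifnot(n_cases >= 0, length(modulation_range) == 2,
            all(sites %in% c("prostate", "lung", "brain_met", "spine_met")))
  structure(
    list(sites = sites, tps_profiles = tps_profiles,
         fractionations = fractionations, beam_types = beam_types,
         n_cases = as.integer(n_cases), base_seed = as.integer(base_seed),
         modulation_range = modulation_range),
    class = "cohort_design"
  )
}

#' Enumerate a cohort design into a case manifest
#'
#' Expands the full factorial of the design into one row per reference plan.
#' The default study-shaped design (4 sites x 2 profiles x 2 fractionations
#' x 2 beam types x 20 cases) yields 640 rows. Enumeration is a pure
#' function of the design: seeds and modulation values depend only on
#' `base_seed` and the row's position in the factorial.
#'
#' @param design A [cohort_design()].
#' @return A tibble with columns `case_id`, `site`, `tps_profile`,
#'   `fractionation`, `beam_type`, `case_index`, `modulation`, `case_seed`.
#' @export
enumerate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  grid <- expand.grid(
    case_index = seq_len(design$n_cases),
    beam_type = design$beam_types,
    fractionation = design$fractionations,
    tps_profile = design$tps_profiles,
    site = design$sites,
    stringsAsFactors = FALSE
  )
  if (nrow(grid) == 0) {
    return(tibble::tibble(
      case_id = character(), site = character(), tps_profile = character(),
      fractionation = character(), beam_type = character(),
      case_index = integer(), modulation = numeric(), case_seed = integer()
    ))
  }
  grid <- tibble::as_tibble(grid)[, c("site", "tps_profile", "fractionation",
                                      "beam_type", "case_index")]
  n <- nrow(grid)
  mods <- local_seed(design$base_seed,
                     stats::runif(n, design$modulation_range[1],
                                  design$modulation_range[2]))
  grid$modulation <- mods
  grid$case_seed <- vapply(seq_len(n), function(i) derive_seed(design$base_seed, i),
                           integer(1))
  grid$case_id <- sprintf("%s_%s_%s_%s_c%02d", grid$site, grid$tps_profile,
                          grid$fractionation, grid$beam_type, grid$case_index)
  grid[, c("case_id", "site", "tps_profile", "fractionation", "beam_type",
           "case_index", "modulation", "case_seed")]
}

#' Materialize one cohort row into phantom and plan
#'
#' @param row One-row data frame (or list) from [enumerate_cohort()].
#' @param spacing_mm,shape Phantom grid settings (see [make_phantom()]).
#' @param n_control_points Control points per arc (see [make_plan()]).
#' @return A list with `template`, `phantom` and `plan`.
#' @export
build_case <- function(row, spacing_mm = 2, shape = c(50, 48, 50),
                       n_control_points = 90) {
  tpl <- site_template(row$site)
  ph <- make_phantom(tpl, case_seed = row$case_seed, spacing_mm = spacing_mm,
                     shape = shape)
  pl <- make_plan(tpl, ph, modulation = row$modulation,
                  tps_profile = row$tps_profile, beam_type = row$beam_type,
                  case_seed = row$case_seed, fractionation = row$fractionation,
                  n_control_points = n_control_points)
  list(template = tpl, phantom = ph, plan = pl)
}

#' Write a cohort manifest to CSV
#'
#' @param cohort Tibble from [enumerate_cohort()].
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_cohort_manifest <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
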