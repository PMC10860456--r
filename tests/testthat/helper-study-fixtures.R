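# Shared, lazily computed study fixtures for the pipeline-level tests.
# Cached per session so several test blocks can reuse one run.
.fixture_cache <- new.env(parent = emptyenv())

# Reduced spinal cohort: the site with the largest systematic errors is the
# one the random-error analysis uses. 4 cases, full error grid, both
# systematic directions plus random realizations.
reduced_spine_study <- function() {
  if (is.null(.fixture_cache$spine)) {
    des <- cohort_design(sites = "spine_met", tps_profiles = "jaw_tracking",
                         fractionations = "standard", beam_types = "FF",
                         n_cases = 4, base_seed = 101)
    .fixture_cache$spine <- run_study(
      des, systematic_grid = c(0.25, 0.5, 1, 2),
      random_grid = c(0.25, 0.5, 1, 2), compare = FALSE)
  }
  .fixture_cache$spine
}

# 20-case single-site cohort spanning the full modulation range, for the
# complexity-sensitivity correlation structure.
complexity_cohort_study <- function() {
  if (is.null(.fixture_cache$complexity)) {
    des <- cohort_design(sites = "lung", tps_profiles = "jaw_tracking",
                         fractionations = "standard", beam_types = "FF",
                         n_cases = 20, base_seed = 202,
                         modulation_range = c(0.1, 0.9))
    .fixture_cache$complexity <- run_study(des, systematic_grid = c(0.5, 2),
                                           compare = FALSE)
  }
  .fixture_cache$complexity
}
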