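# End-to-end study pipeline: generate -> perturb -> dose -> DVH -> gEUD ->
# sensitivity -> complexity -> correlations -> tolerances.

#' Analyze one cohort case
#'
#' Builds the case's phantom and reference plan, computes complexity
#' metrics, runs the dose engine on the reference plan (calibrating the
#' target mean dose to the prescription) and on every error variant (with
#' the reference calibration frozen), and fits gEUD-sensitivity slopes per
#' structure and direction. gEUD is reported on the total-dose scale
#' (per-fraction gEUD times the number of fractions), so percent changes
#' are scale-free and Gy/mm slopes refer to the full course.
#'
#' @param row One row of [enumerate_cohort()].
#' @param systematic_grid Systematic error magnitudes (mm).
#' @param random_grid Random error magnitudes (mm), or `NULL` to skip
#'   random-mode analysis.
#' @param n_random_replicates Random realizations per magnitude.
#' @param structures `"target"` or `"all"` (target plus OARs).
#' @param engine An [engine_config()].
#' @param error_base_seed Seed stream for random-mode error realizations.
#' @param spacing_mm,shape,n_control_points Passed to [build_case()].
#'
#' @return A list with tibbles `complexity`, `deltas`, `sensitivities` and
#'   `reference` (per-structure reference gEUD).
#' @export
analyze_case <- function(row,
                         systematic_grid = c(0.25, 0.5, 1, 2),
                         random_grid = NULL,
                         n_random_replicates = 1,
                         structures = c("target", "all"),
                         engine = engine_config(),
                         error_base_seed = 1,
                         spacing_mm = 2, shape = c(50, 48, 50),
                         n_control_points = 90) {
  structures <- match.arg(structures)
  case <- build_case(row, spacing_mm = spacing_mm, shape = shape,
                     n_control_points = n_control_points)
  tpl <- case$template; ph <- case$phantom; plan <- case$plan
  n_fx <- plan$fractionation$n_fractions

  comp <- plan_irregularity(plan)
  comp_tbl <- tibble::tibble(
    case_id = row$case_id, site = row$site, tps_profile = row$tps_profile,
    fractionation = row$fractionation, beam_type = row$beam_type,
    modulation = row$modulation, mu_per_gy = comp$mu_per_gy, pi = comp$pi
  )

  structs <- "target"
  a_map <- c(target = tpl$a_value_target)
  if (structures == "all") {
    structs <- c("target", names(tpl$oars))
    a_map <- c(a_map, tpl$a_values_oar)
  }

  ref_dose <- compute_dose(plan, ph, engine)
  frozen <- engine
  frozen$calibration <- ref_dose$calibration
  ref_dvh <- lapply(structs, function(s) compute_dvh(ref_dose, ph, s))
  names(ref_dvh) <- structs
  ref_geud <- vapply(structs, function(s) geud(ref_dvh[[s]], a_map[[s]]),
                     numeric(1))

  ref_tbl <- tibble::tibble(
    case_id = row$case_id, structure = structs,
    a_value = unname(a_map[structs]),
    ref_geud_gy = unname(ref_geud) * n_fx
  )

  measure <- function(err_plan, mode, magnitude, replicate = 1L) {
    dose <- compute_dose(err_plan, ph, frozen)
    purrr::map_dfr(structs, function(s) {
      gc <- geud_change(ref_dvh[[s]], compute_dvh(dose, ph, s), a_map[[s]])
      tibble::tibble(
        case_id = row$case_id, structure = s, mode = mode,
        magnitude_mm = magnitude, replicate = replicate,
        delta_percent = gc$delta_percent, delta_gy = gc$delta_gy * n_fx
      )
    })
  }

  deltas <- list()
  for (m in systematic_grid) {
    deltas[[length(deltas) + 1]] <-
      measure(apply_systematic(plan, error_spec("systematic_close", m)),
              "close", m)
    deltas[[length(deltas) + 1]] <-
      measure(apply_systematic(plan, error_spec("systematic_open", m)),
              "open", m)
  }
  if (!is.null(random_grid)) {
    ri <- 0
    for (m in random_grid) {
      for (rep_i in seq_len(n_random_replicates)) {
        ri <- ri + 1
        seed <- derive_seed(error_base_seed + row$case_seed, ri)
        deltas[[length(deltas) + 1]] <-
          measure(apply_random(plan, error_spec("random", m, seed = seed)),
                  "random", m, as.integer(rep_i))
      }
    }
  }
  deltas <- dplyr::bind_rows(deltas)

  fit_rows <- purrr::map_dfr(structs, function(s) {
    ds <- deltas[deltas$structure == s, ]
    one_fit <- function(pts, direction, col) {
      f <- fit_sensitivity(
        tibble::tibble(error_mm = pts$error_mm, delta = pts[[col]]),
        direction = direction)
      tibble::tibble(direction = direction, slope = f$slope, r = f$r, n = f$n)
    }
    zero <- tibble::tibble(error_mm = 0, delta_percent = 0, delta_gy = 0)
    res <- list()
    for (mode_i in intersect(c("close", "open"), unique(ds$mode))) {
      sub <- ds[ds$mode == mode_i, ]
      pts <- dplyr::bind_rows(
        zero, tibble::tibble(error_mm = sub$magnitude_mm,
                             delta_percent = sub$delta_percent,
                             delta_gy = sub$delta_gy))
      pct <- one_fit(pts, mode_i, "delta_percent")
      gy <- one_fit(pts, mode_i, "delta_gy")
      res[[mode_i]] <- tibble::tibble(
        direction = mode_i, slope_pct_per_mm = pct$slope,
        slope_gy_per_mm = gy$slope, r = pct$r, n = pct$n)
    }
    if (all(c("close", "open") %in% ds$mode)) {
      sub <- ds[ds$mode %in% c("close", "open"), ]
      signed <- ifelse(sub$mode == "close", -sub$magnitude_mm, sub$magnitude_mm)
      pts <- dplyr::bind_rows(
        zero, tibble::tibble(error_mm = signed,
                             delta_percent = sub$delta_percent,
                             delta_gy = sub$delta_gy))
      pct <- one_fit(pts, "combined", "delta_percent")
      gy <- one_fit(pts, "combined", "delta_gy")
      res$combined <- tibble::tibble(
        direction = "combined", slope_pct_per_mm = pct$slope,
        slope_gy_per_mm = gy$slope, r = pct$r, n = pct$n)
    }
    if ("random" %in% ds$mode) {
      sub <- ds[ds$mode == "random", ]
      pts <- dplyr::bind_rows(
        zero, tibble::tibble(error_mm = sub$magnitude_mm,
                             delta_percent = sub$delta_percent,
                             delta_gy = sub$delta_gy))
      pct <- one_fit(pts, "random", "delta_percent")
      gy <- one_fit(pts, "random", "delta_gy")
      res$random <- tibble::tibble(
        direction = "random", slope_pct_per_mm = pct$slope,
        slope_gy_per_mm = gy$slope, r = pct$r, n = pct$n)
    }
    dplyr::bind_rows(res) |>
      dplyr::mutate(case_id = row$case_id, structure = s, .before = 1)
  })
  fit_rows <- dplyr::left_join(
    fit_rows,
    comp_tbl[, c("case_id", "site", "tps_profile", "fractionation",
                 "beam_type", "modulation")],
    by = "case_id")

  list(complexity = comp_tbl, deltas = deltas, sensitivities = fit_rows,
       reference = ref_tbl)
}

#' Run the full study pipeline over a cohort design
#'
#' Executes generate -> perturb -> dose -> DVH -> gEUD -> sensitivity ->
#' complexity -> correlations -> tolerances for every case of the design
#' and collects tidy result tables.
#'
#' @inheritParams analyze_case
#' @param design A [cohort_design()].
#' @param threshold_pct Tolerance threshold on target gEUD change
#'   (percent, default 2).
#' @param tolerance_aggregate Aggregation of per-case tolerances
#'   (`"mean"`, `"median"`, `"min"`).
#' @param compare Run close-vs-open paired comparisons per site (default
#'   `TRUE` when every site has >= 3 cases).
#' @param progress Print per-case progress lines.
#'
#' @return An object of class `vmat_study`: list of tibbles `cases`,
#'   `complexity`, `deltas`, `sensitivities`, `reference`, `tolerances`
#'   (per case and per scenario), `correlations`, `comparisons`, plus a
#'   `manifest` recording seeds and settings.
#' @export
run_study <- function(design,
                      systematic_grid = c(0.25, 0.5, 1, 2),
                      random_grid = NULL,
                      n_random_replicates = 1,
                      structures = "target",
                      engine = engine_config(),
                      threshold_pct = 2,
                      tolerance_aggregate = "mean",
                      compare = TRUE,
                      spacing_mm = 2, shape = c(50, 48, 50),
                      n_control_points = 90,
                      progress = FALSE) {
  cohort <- enumerate_cohort(design)
  if (nrow(cohort) == 0) stop("empty cohort design")
  results <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    if (progress) message(sprintf("[%d/%d] %s", i, nrow(cohort), row$case_id))
    results[[i]] <- tryCatch(
      analyze_case(row, systematic_grid = systematic_grid,
                   random_grid = random_grid,
                   n_random_replicates = n_random_replicates,
                   structures = structures, engine = engine,
                   error_base_seed = design$base_seed,
                   spacing_mm = spacing_mm, shape = shape,
                   n_control_points = n_control_points),
      error = function(e) stop("case '", row$case_id, "' failed: ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  complexity <- purrr::map_dfr(results, "complexity")
  deltas <- purrr::map_dfr(results, "deltas")
  sens <- purrr::map_dfr(results, "sensitivities")
  reference <- purrr::map_dfr(results, "reference")

  # Per-case target sensitivity summary (mean |slope| over close/open).
  target_sens <- sens |>
    dplyr::filter(.data$structure == "target",
                  .data$direction %in% c("close", "open")) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(sensitivity_pct_per_mm = mean(abs(.data$slope_pct_per_mm)),
                     .groups = "drop") |>
    dplyr::left_join(complexity, by = "case_id")

  tolerances <- sens |>
    dplyr::filter(.data$structure == "target",
                  .data$direction %in% c("close", "open")) |>
    dplyr::mutate(scenario = paste(.data$site, .data$tps_profile,
                                   .data$fractionation, sep = "_"),
                  slope = .data$slope_pct_per_mm) |>
    derive_tolerance(threshold_pct = threshold_pct,
                     aggregate = tolerance_aggregate)

  correlations <- study_correlations(target_sens)

  comparisons <- NULL
  if (isTRUE(compare)) comparisons <- study_comparisons(sens)

  structure(
    list(cases = cohort, complexity = complexity, deltas = deltas,
         sensitivities = sens, reference = reference,
         target_sensitivity = target_sens,
         tolerances = tolerances, correlations = correlations,
         comparisons = comparisons,
         manifest = list(
           design = unclass(design), systematic_grid = systematic_grid,
           random_grid = random_grid,
           n_random_replicates = n_random_replicates,
           structures = structures, engine = unclass(engine),
           threshold_pct = threshold_pct,
           tolerance_aggregate = tolerance_aggregate,
           spacing_mm = spacing_mm, shape = shape,
           n_control_points = n_control_points
         )),
    class = "vmat_study"
  )
}

# Complexity-sensitivity correlations, pooled overall and per sequence
# profile (the per-profile pooling mirrors reporting per planning system).
study_correlations <- function(target_sens) {
  pools <- c(list(all = target_sens),
             split(target_sens, target_sens$tps_profile))
  purrr::imap_dfr(pools, function(d, pool) {
    if (nrow(d) < 3) return(NULL)
    pairs <- list(
      c("sensitivity_pct_per_mm", "mu_per_gy"),
      c("sensitivity_pct_per_mm", "pi"),
      c("mu_per_gy", "pi")
    )
    purrr::map_dfr(pairs, function(p) {
      cr <- tryCatch(correlate(d[[p[1]]], d[[p[2]]], p[1], p[2]),
                     error = function(e) NULL)
      if (is.null(cr)) return(NULL)
      tibble::tibble(pooling = pool, x_metric = p[1], y_metric = p[2],
                     method = cr$method, coefficient = cr$coefficient,
                     p_value = cr$p_value, strength_band = cr$strength_band)
    })
  })
}

# Close-vs-open paired comparison of target |slopes| per site.
study_comparisons <- function(sens) {
  tg <- sens[sens$structure == "target" &
               sens$direction %in% c("close", "open"), ]
  purrr::map_dfr(split(tg, tg$site), function(d) {
    w <- tidyr::pivot_wider(
      d[, c("case_id", "direction", "slope_pct_per_mm")],
      names_from = "direction", values_from = "slope_pct_per_mm")
    if (nrow(w) < 3 || !all(c("close", "open") %in% names(w))) return(NULL)
    cmp <- tryCatch(compare_groups(abs(w$close), abs(w$open), paired = TRUE),
                    error = function(e) NULL)
    if (is.null(cmp)) return(NULL)
    tibble::tibble(
      site = d$site[1], comparison = "close_vs_open",
      n = nrow(w), test_used = cmp$test_used, p_value = cmp$p_value,
      significant = cmp$significant
    )
  })
}

#' @export
print.vmat_study <- function(x, ...) {
  cat(sprintf("<vmat_study> %d cases, %d delta measurements\n",
              nrow(x$cases), nrow(x$deltas)))
  print(x$tolerances$per_scenario)
  invisible(x)
}

#' Write study result tables to CSV files
#'
#' Writes `cases.csv`, `complexity.csv`, `sensitivities.csv`,
#' `tolerances.csv`, `correlations.csv` (and `comparisons.csv` when
#' present) plus `manifest.json` into `dir`.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly `dir`.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$cases, file.path(dir, "cases.csv"), row.names = FALSE)
  utils::write.csv(study$complexity, file.path(dir, "complexity.csv"),
                   row.names = FALSE)
  utils::write.csv(study$sensitivities, file.path(dir, "sensitivities.csv"),
                   row.names = FALSE)
  utils::write.csv(study$tolerances$per_scenario,
                   file.path(dir, "tolerances.csv"), row.names = FALSE)
  utils::write.csv(study$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  if (!is.null(study$comparisons)) {
    utils::write.csv(study$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
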