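# Site templates: target/OAR geometry, prescriptions, gEUD exponents and
# DVH reporting constraints for the four treatment sites in the cohort.

#' Site template
#'
#' Bundles everything the cohort generator needs for one treatment site:
#' target and organ-at-risk (OAR) geometry, the standard and hypofractionated
#' prescriptions, gEUD volume-effect exponents (`a`-values), DVH reporting
#' constraints, and a site-intrinsic sequence-complexity scale.
#'
#' @param site One of `"prostate"`, `"lung"`, `"brain_met"`, `"spine_met"`.
#'
#' @return An object of class `site_template`: a list with fields `site`,
#'   `target` (shape spec), `oars` (named list of shape specs),
#'   `prescriptions` (`$standard`, `$hypo`, each a [prescription()]),
#'   `a_value_target`, `a_values_oar`, `dose_constraints` (tibble),
#'   `complexity_scale` and `aperture_margin_mm`.
#'
#' @details
#' Prescriptions follow common clinical schedules per site (prostate
#' 78 Gy/39 fx and 36.25 Gy/5 fx; lung 60 Gy/30 fx and 52 Gy/4 fx; brain
#' metastasis 42 Gy/10 fx and 30 Gy/3 fx; spinal metastasis 30 Gy/10 fx and
#' a 16 Gy single fraction). Target `a`-values are negative
#' (cold-spot-weighted): prostate -25, lung -20, brain metastasis -10,
#' spinal metastasis -20. OAR exponents default to Burman-model values
#' (`a = 1/n`): rectum 8.33, bladder 2, normal lung 1.15, spinal cord 20,
#' normal brain 4.
#'
#' `complexity_scale` in `[0, 1]` encodes how aggressively the sequence
#' generator modulates apertures for this site; it is what makes spinal
#' (concave cord-wrap) plans the most complex and brain-metastasis plans the
#' least, mirroring clinical sequence complexity. Target sizes and OAR
#' placements are package choices of plausible magnitudes, not measured
#' patient data.
#'
#' @examples
#' tpl <- site_template("prostate")
#' tpl$prescriptions$standard$total_dose_gy
#' @export
site_template <- function(site = c("prostate", "lung", "brain_met", "spine_met")) {
  site <- match.arg(site)
  tpl <- switch(site,
    prostate = list(
      target = list(shape = "sphere", radius_mm = 22, center_mm = c(0, 0, 0)),
      oars = list(
        rectum = list(shape = "cylinder_y", radius_mm = 13,
                      center_mm = c(0, 0, -32), half_length_mm = 40),
        bladder = list(shape = "sphere", radius_mm = 18,
                       center_mm = c(0, 14, 28))
      ),
      prescriptions = list(standard = prescription(2, 39),
                           hypo = prescription(7.25, 5)),
      a_value_target = -25,
      a_values_oar = c(rectum = 8.33, bladder = 2),
      complexity_scale = 0.45,
      dose_constraints = tibble::tribble(
        ~structure, ~fractionation, ~kind, ~arg, ~limit, ~limit_unit,
        "target", "any", "D_percent", 95, 90, "pct_of_rx",
        "target", "any", "D_percent", 2, 110, "pct_of_rx",
        "rectum", "standard", "V_gy", 63, 17, "pct_volume",
        "rectum", "standard", "V_gy", 21, 60, "pct_volume",
        "rectum", "hypo", "V_gy", 36.25, 4.6, "pct_volume",
        "rectum", "hypo", "V_gy", 18.13, 50, "pct_volume",
        "bladder", "standard", "V_gy", 63, 25, "pct_volume",
        "bladder", "standard", "V_gy", 21, 50, "pct_volume",
        "bladder", "hypo", "V_gy", 36.25, 7.8, "pct_volume",
        "bladder", "hypo", "V_gy", 18.13, 49, "pct_volume"
      )
    ),
    lung = list(
      target = list(shape = "sphere", radius_mm = 12, center_mm = c(24, 0, 10)),
      oars = list(
        normal_lung = list(shape = "cylinder_y", radius_mm = 26,
                           center_mm = c(20, 0, 6), half_length_mm = 44)
      ),
      prescriptions = list(standard = prescription(2, 30),
                           hypo = prescription(13, 4)),
      a_value_target = -20,
      a_values_oar = c(normal_lung = 1.15),
      complexity_scale = 0.6,
      dose_constraints = tibble::tribble(
        ~structure, ~fractionation, ~kind, ~arg, ~limit, ~limit_unit,
        "target", "any", "D_percent", 95, 90, "pct_of_rx",
        "target", "any", "D_percent", 2, 110, "pct_of_rx",
        "normal_lung", "any", "V_gy", 20, 35, "pct_volume",
        "normal_lung", "any", "V_gy", 5, 60, "pct_volume"
      )
    ),
    brain_met = list(
      target = list(shape = "sphere", radius_mm = 18, center_mm = c(0, 0, 14)),
      oars = list(
        normal_brain = list(shape = "sphere", radius_mm = 40,
                            center_mm = c(0, 0, 8))
      ),
      prescriptions = list(standard = prescription(4.2, 10),
                           hypo = prescription(10, 3)),
      a_value_target = -10,
      a_values_oar = c(normal_brain = 4),
      complexity_scale = 0.2,
      dose_constraints = tibble::tribble(
        ~structure, ~fractionation, ~kind, ~arg, ~limit, ~limit_unit,
        "target", "any", "D_percent", 95, 90, "pct_of_rx",
        "target", "any", "D_percent", 2, 110, "pct_of_rx",
        "normal_brain", "standard", "V_gy", 38.37, 7, "cc",
        "normal_brain", "hypo", "V_gy", 23.1, 7, "cc"
      )
    ),
    spine_met = list(
      target = list(shape = "annulus_y", outer_radius_mm = 24,
                    inner_radius_mm = 13, center_mm = c(0, 0, 0),
                    half_length_mm = 30),
      oars = list(
        spinal_cord = list(shape = "cylinder_y", radius_mm = 6,
                           center_mm = c(0, 0, 0), half_length_mm = 46)
      ),
      prescriptions = list(standard = prescription(3, 10),
                           hypo = prescription(16, 1)),
      a_value_target = -20,
      a_values_oar = c(spinal_cord = 20),
      complexity_scale = 0.8,
      dose_constraints = tibble::tribble(
        ~structure, ~fractionation, ~kind, ~arg, ~limit, ~limit_unit,
        "target", "any", "D_percent", 90, 80, "pct_of_rx",
        "target", "any", "D_percent", 2, 110, "pct_of_rx",
        "spinal_cord", "standard", "D_max", NA, 25, "gy",
        "spinal_cord", "hypo", "D_cc", 0.35, 10, "gy"
      )
    )
  )
  tpl$site <- site
  tpl$aperture_margin_mm <- switch(site, prostate = 4, lung = 4,
                                   brain_met = 8, spine_met = 7)
  structure(tpl, class = "site_template")
}

#' Default gEUD a-value registry
#'
#' Site-level target exponents and Burman-model OAR exponents used by the
#' analysis layer. Shipped as a JSON config in `inst/extdata/a_values.json`
#' so deployments can override it.
#'
#' @param path Optional path to an alternative JSON registry.
#' @return A list with `target_a` (named by site) and `oar_a` (named by
#'   structure).
#' @export
a_value_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "a_values.json", package = "vmatsens")
  }
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(reg$target_a < 0))
  reg
}
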