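Package: vmatsens
Title: Dose Sensitivity of VMAT Plans to Multileaf Collimator Positional Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the dosimetric consequences of multileaf collimator
    (MLC) positional errors in volumetric modulated arc therapy (VMAT).
    Provides a synthetic cohort generator for four treatment-site templates,
    systematic (close/open) and random per-leaf error injection, a surrogate
    forward dose engine with dose-volume histogram (DVH) queries, generalized
    equivalent uniform dose (gEUD) metrics, plan-complexity metrics (MU/Gy and
    plan irregularity after Du et al.), and a statistics layer that fits
    gEUD-sensitivity slopes, compares groups with normality-gated tests,
    correlates sensitivity with complexity, and derives site-specific MLC
    position tolerances from a dose-change threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
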