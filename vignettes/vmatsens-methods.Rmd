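---
title: "Methods: simulating MLC positional-error dose sensitivity in VMAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating MLC positional-error dose sensitivity in VMAT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters and the design
choices behind `vmatsens`: what the simulation does, what it deliberately
does not do, and what its passing tests do and do not demonstrate about
clinical plans.

## The pipeline

The analysis chains seven stages:

1. **Cohort enumeration** (`cohort_design()`, `enumerate_cohort()`): the
   full factorial of sites x sequence profiles x fractionations x beam-type
   labels x cases. The study-shaped design (4 x 2 x 2 x 2 x 20) enumerates
   640 reference plans; crossing them with two systematic directions and
   the four-magnitude error grid gives 5120 systematic error plans.
2. **Phantom generation** (`make_phantom()`): isotropic voxel grids
   (default 2 mm, 50 x 48 x 50 voxels) with boolean structure masks.
3. **Plan generation** (`make_plan()`): a single 360-degree arc (default
   90 control points) whose apertures conform to the target's
   beam's-eye-view outline.
4. **Error injection** (`apply_systematic()`, `apply_random()`).
5. **Dose and DVH** (`compute_dose()`, `compute_dvh()`, `dvh_query()`).
6. **gEUD and complexity** (`geud()`, `mu_per_gy()`, `plan_irregularity()`).
7. **Statistics** (`fit_sensitivity()`, `compare_groups()`, `correlate()`,
   `derive_tolerance()`), orchestrated by `run_study()`.

## Site templates

Each template fixes geometry, prescriptions and gEUD exponents:

| site | target | prescriptions (standard / hypo) | target a | complexity scale | aperture margin |
|---|---|---|---|---|---|
| prostate | 22-mm sphere | 78 Gy/39 fx / 36.25 Gy/5 fx | -25 | 0.45 | 4 mm |
| lung | 12-mm sphere | 60 Gy/30 fx / 52 Gy/4 fx | -20 | 0.60 | 4 mm |
| brain_met | 18-mm sphere | 42 Gy/10 fx / 30 Gy/3 fx | -10 | 0.20 | 8 mm |
| spine_met | annulus 24/13 mm around a 6-mm cord | 30 Gy/10 fx / 16 Gy/1 fx | -20 | 0.80 | 7 mm |

Target sizes and OAR placements are plausible magnitudes chosen for this
simulation, not patient measurements. They are chosen so that the
geometric drivers of error sensitivity reproduce the clinically expected
site ordering: the spinal template's concave cord wrap forces narrow
one-sided apertures (most sensitive), the small lung target gives narrow
fields, the large prostate target wide ones, and the brain-metastasis
template combines a large target with a generous margin and the mildest
cold-spot exponent (least sensitive). Per-case jitter (sizes +/-10%,
positions +/-4 mm) decorrelates cases within a cell.

OAR exponents default to Burman-model volume-effect values (`a = 1/n`):
rectum 8.33, bladder 2, normal lung 1.15, spinal cord 20, normal brain 4.
They ship as a JSON registry (`inst/extdata/a_values.json`) and are
configuration, not measured facts.

## The sequence generator and the modulation knob

Clinical plans come from inverse optimizers; their complexity is an
emergent property. Here complexity is an explicit input: `modulation`
(0-1) scales four effects, all drawn from the case seed so that the knob
only scales amplitudes:

* sinusoidal per-leaf gap narrowing (amplitude
  `modulation * complexity_scale * 10 mm`, per-leaf random frequency 2-5
  cycles/arc, depth 0.5-1);
* a deterministic alternating leaf-end zig-zag (0.4 of the amplitude) that
  raises aperture perimeter monotonically;
* Gaussian leaf-end jitter (0.25 of the amplitude);
* MU-weight roughening and a total-MU scale,
  `MU/Gy = 85 * (1 + 3.5 * modulation) * (0.85 + 0.3 * complexity_scale)`
  with 6% lognormal noise, spanning a >3x MU/Gy range over modulation
  0.1-0.9.

One extra leaf strip is opened beyond each end of the target extent. This
is the Y-direction analogue of the aperture margin: without it the
target's poles sit in the field's Y penumbra, and the cold-spot-weighted
gEUD of the *reference* plan is pinned by voxels that leaf-end (X) errors
cannot move, which would mask the error signal the study measures.

The two sequence profiles emulate planning-system differences at the
sequence level only: `jaw_tracking` fits the jaws to the open leaves per
control point; `fixed_jaw` freezes them at the whole-arc envelope and adds
30% more leaf jitter. Beam type (FF/FFF) is a label; the engine ignores
it, consistent with treating spectral differences as out of scope.

## Error injection

Systematic close moves bank 1 by +delta and bank 2 by -delta (gap shrinks
by 2 delta); open is the reverse. The per-bank (rather than per-gap)
convention is used because sensitivities are reported per millimeter of
leaf displacement. Random errors draw i.i.d. zero-mean Gaussians with SD
equal to the magnitude for every non-parked leaf position at every control
point. Pairs whose gap would fall below the mechanical minimum (default
0.5 mm) are clamped symmetrically about their midpoint and logged, so
analyses can quantify how much clamping occurred. Parked pairs — closed
and fully outside the Y jaws — are skipped by default; perturbing them is
physically meaningless and floods the clamp log.

## The surrogate dose engine

Per control-point interval the engine builds the binary MLC-and-jaw
aperture at the isocenter plane with fractional cell coverage (2-mm
fluence grid; sub-cell coverage keeps the fluence continuous in leaf
position, which matters at 0.25-mm errors), blurs it with a Gaussian
penumbra (sigma 3 mm), weights it by the interval meterset, and
back-projects with parallel rays along the interval's mean gantry
direction. Optional exponential depth attenuation is off by default. The
sum over intervals is scaled once so the reference plan's mean target dose
equals the prescribed fraction dose; that calibration factor is frozen and
reused for the plan's error variants — recalibrating each variant would
normalize away exactly the dose error being measured.

The engine has no scatter, no heterogeneity, no spectral model and no
absolute dosimetry. Consequently the package's absolute sensitivities and
tolerances are properties of the simulation, not clinical values; only
ordering, linearity and correlation structure are meaningful, and only
those are asserted by tests.

## DVH and gEUD conventions

DVHs are differential histograms over mask voxels with 0.05-Gy bins whose
*centers* sit on integer multiples of the bin width, so uniform doses fall
on a bin center and queries on constructed cases are exact. `D_x%` is the
minimum dose of the hottest x% of the volume (discrete accumulation from
the top bin); `V_xGy` sums bins with centers at or above the threshold.
gEUD uses bin centers with a 0.01-Gy dose floor so strongly negative
exponents remain finite when a structure contains zero-dose voxels; the
generalized mean is evaluated with the dominant dose factored out to avoid
overflow at |a| = 100. gEUD is reported on the total-dose scale
(per-fraction gEUD times fraction number). Percent changes are identical
on either scale by the degree-1 homogeneity of gEUD; Gy/mm slopes refer to
the full course.

Halving the bin width moves gEUD by under 0.1% for the convex-target
cases; the spinal template, whose gEUD is dominated by the steep
cord-interface gradient, is more bin-sensitive (about 0.5%), which is a
known property of cold-spot-weighted generalized means on sparse cold
tails.

## Complexity metrics

MU/Gy is total meterset over fraction dose. Aperture irregularity is
`perimeter^2 / (4 pi area)` computed analytically on the rectilinear union
of open leaf strips (jaw truncation applied first; disconnected
sub-apertures summed, one AI per control point). Segment meterset is
attributed to the interval's *start* control point — a deterministic
convention chosen over midpoint interpolation for bit-exact
reproducibility. Beam irregularity is the segment-MU-weighted mean AI over
open segments (zero-area segments excluded, their MU excluded from the
denominator by default); plan irregularity is the beam-MU-weighted mean.
An independent 0.1-mm rasterization oracle agrees with the analytic
area/perimeter to well under 1%.

## Statistics

Sensitivity slopes are ordinary least squares through the zero-error point
and the signed or per-direction error grid; the per-direction fits (close,
open) and the combined signed fit are all first-class outputs because
close/open asymmetry is itself of interest. Group comparisons gate on
Shapiro-Wilk normality (p < 0.05 in either group selects the Wilcoxon
test); correlations gate the same way between Pearson and Spearman and
band the coefficient at 0.2/0.4/0.7. No multiple-testing correction is
applied by default, matching per-comparison alpha = 0.05 reporting.

Tolerances divide the +/-2% target-gEUD-change threshold by the binding
(larger) of the two directional slopes per case; scenario tolerances
aggregate per-case tolerances by the mean (median and min are available).
The mean is the default because a per-case tolerance is already the
worst-direction value; zero-slope cases are flagged unbounded rather than
averaged in.

## Problem sizes and determinism

The packaged analyses run at desk scale by design: 2-mm phantoms
(50 x 48 x 50), 90 control points per arc, a reduced 4-case spinal cohort
for the linearity and random-error properties, and a 20-case single-site
cohort spanning modulation 0.1-0.9 for the correlation structure. Every
random draw (phantom jitter, sequence parameters, random-mode errors,
statistical fixtures) flows from one base seed through deterministic
per-case substreams, so `run_study()` is a pure function of its arguments
and reruns reproduce tables bit-exactly.

## Known limitations

* The generator produces modulation-spanning, physically valid sequences,
  not deliverable clinical plans; no inverse optimization against the
  dose constraints is performed (constraints are DVH reporting targets
  only).
* Parallel-ray dose with a fixed penumbra exaggerates the absolute
  sensitivity of very narrow apertures (the spinal template) relative to
  clinical dose engines; comparisons across sites are ordinal, not
  calibrated.
* Serialization supports the package's JSON plan dialect; DICOM-RT import
  and export are not included in this build.
* FF vs FFF is carried as a label only, so the package cannot exhibit
  beam-quality effects on sensitivity.
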