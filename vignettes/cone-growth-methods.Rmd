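---
title: "The cone-growth model of powder flowability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cone-growth model of powder flowability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowcone)
```

## The measurement and its model

The method this package implements characterizes the flowability of
pharmaceutical multiparticulates (pellets and granules) by filming the
pile they form while discharging from a standard funnel onto a plane.
Each frame of the recording is cut vertically into equal bands; the
bright-pixel area of one band, plotted against time, is the *flow
curve*. Because a freely flowing powder builds a nearly conical pile,
the curve carries a simple geometric signature. A cone of height $h$
and flank angle $\alpha$ (the static angle of repose, measured from the
horizontal) has base radius $r = h/\tan\alpha$ and volume

$$V = \frac{\pi h^3}{3\tan^2\alpha},$$

so under a constant volumetric feed $V = Qt$ the height grows as

$$h(t) = \left(\frac{3\tan^2\alpha}{\pi}\right)^{1/3} (Qt)^{1/3}.$$

A slice area proportional to the height therefore follows the
three-parameter power law

$$y(t) = a + b\,t^{c},$$

with the *ideal-cone* exponent $c = 1/3$ and a growth coefficient
proportional to $(3/\pi)^{1/3}\tan^{2/3}\alpha$
(`geometry_coefficients()`). Fitted exponents on real recordings run
above $1/3$ (roughly 0.34–0.50): the pile is not a perfect cone, feed
is not perfectly constant, and the observation window is finite. The
intercept $a$ is treated as a free parameter; it absorbs the offset of
the analysed band from the apex (and is typically negative for
off-center bands).

On top of the smooth trend the pile relaxes by discrete slip events:
the local slope steepens past a critical angle, a wedge of material
sheds, and the slice area drops — the stick–slip picture of
self-organized criticality. These avalanches appear as a sawtooth
oscillation of the detrended curve and are summarized by their count,
mean amplitude (px) and mean wavelength (frames; one frame is 0.04 s
at 25 fps).

## Pipeline parameters and defaults

* **Frame geometry** — 25 fps, 128 × 160 px frames, matching the
  reference rig; both are arguments everywhere they matter.
* **Binarization** (`binarize_frame()`) — Otsu's global threshold by
  default: forward illumination against a black pane gives strongly
  bimodal histograms, for which Otsu is the standard choice. A fixed
  threshold is available for controlled inputs; constant frames return
  an empty mask with a warning rather than an arbitrary split.
* **Slice choice** (`default_slice_index()`) — the analysed band should
  sit near the middle of the frame but outside the falling bulk jet
  (nozzle ~10 mm versus a 100 mm funnel top). The default places it
  `max(1, n_slices/8)` bands left of center — index 11 of 32 — which
  the simulator confirms is clear of a 12 px central jet. The exact
  band used in any given rig is a configuration knob, not a constant.
* **Static angle of repose** (`measure_static_angle()`) — least-squares
  lines through the upper envelope of each flank of the final pile,
  averaging the two sides. Points above 90% of the pile height (apex
  rounding) and in the bottom 2 rows (base spreading) are excluded;
  this is conventional slope-extraction practice. On rendered wedges
  the measurement is accurate to well under 0.5° between 25° and 45° at
  the reference resolution.
* **Flow time** (`measure_flow_time()`) — first time from which the
  area stays within 0.5% of its final value for 25 consecutive frames
  (one second). A curve with no such plateau raises an error that
  flags a truncated recording.
* **Power-law fit** (`fit_power_law()`) — bounded Levenberg–Marquardt
  least squares (via minpack.lm) with an analytic Jacobian; the
  exponent is confined to (0.05, 1.5). Starts: $a_0$ = first area,
  $c_0 = 1/3$, $b_0$ from the curve endpoints, with restarts at
  $c_0 = 0.25$ and $0.5$ if needed. At $t = 0$ the model value is $a$
  (taking $0^c = 0$). In the full pipeline (`analyze_curve()`) the fit
  runs on the pre-plateau window when a flow time is found, and leading
  frames recorded before any material reached the band are dropped:
  the band carries no signal there, and keeping those zeros forces the
  fit through a point the growth law does not describe, biasing the
  exponent upward by several hundredths.
* **AUFC** (`area_under_flow_curve()`) — trapezoidal integral over the
  *frame index* rather than seconds. This matches the magnitude
  convention of the packaged study values (AUFC of order $2$–$3\times
  10^4$ for ~500-frame recordings of ~60 px areas) and the frame-based
  wavelength unit.
* **Avalanche detection** (`detect_avalanches()`) — a local maximum of
  the residual followed by a drop of at least 2 px (prominence) to the
  following trough, with at least 5 frames between accepted peaks.
  Amplitude is the peak-to-trough drop; wavelength the peak-to-peak
  spacing (events, not zero crossings). These thresholds, and the rule
  itself, are this package's operationalization — the source study
  reports avalanche statistics without defining the counting rule —
  so avalanche numbers from other software are comparable only in
  trend.
* **Sphericity** (`crofton_perimeter()`, `particle_sphericity()`) —
  $\psi = 4\pi A_f/P_{Cr}^2$ with the Crofton perimeter estimated from
  intercept counts along 0°, 45°, 90° and 135° line families. The
  four-direction estimator is excellent on isotropic shapes (0.15%
  error on a 50 px digital disk) but systematically reads axis-aligned
  rectangles about 5% short — its analytic limit there is
  $(\pi/4)(1+\sqrt 2)(w+h)$; more directions would be needed to remove
  that anisotropy. Values marginally above 1 on pixelated inputs are
  clamped to 1 (the raw value is kept as an attribute). Pellet versus
  granule classification uses the study's thresholds: pellet above
  0.91, granule at or below 0.90, with the unassigned (0.90, 0.91]
  band resolved as granule plus a warning.

## The design-of-experiments layer

The packaged dataset is a 24-run central composite design in particle
size (725 ± 375 µm), moisture (2 ± 1%), glidant/lubricant ratio
(coded) and the categorical granule (−1) / pellet (+1) factor. Each
categorical block holds a half-fraction $2^{3-1}$ factorial (defining
relation $x_3 = -x_1x_2$), six axial runs (axial distances ≈ 1.41, 1.4,
1.4) and two center points. `build_ccd()` reconstructs this layout;
`read_design_table()` codes the packaged actual levels.

`fit_response_surface()` fits linear, two-factor-interaction or
quadratic polynomials on the coded factors by QR-based OLS (the
categorical factor never enters squared) and reports per-term t-tests,
the model F-test, $R^2$ and the PRESS-based predicted $R^2$; the latter
can be negative, meaning the response mean out-predicts the model, as
happens for the packaged intercept column `a`. `reduce_model()`
performs backward elimination at $\alpha = 0.05$ preserving hierarchy.
Because the categorical column is orthogonal to every other model
column in this design, its slope always equals half the
pellet-minus-granule mean difference — a property the tests verify
against direct group means, and the reason the published slopes are
exactly reproducible from the printed tables.

Two reproducibility caveats, both documented rather than patched:
the published intercepts differ slightly from the packaged-table grand
means (e.g. 21.15 printed versus 21.08 recomputed for the avalanche
wavelength), indicating software-specific estimation details upstream,
so intercepts are reported but never asserted; and the published
correlation matrix cannot be reproduced elementwise from the printed
tables — the exponent column is printed to two decimals and the
amplitude column is inconsistent with its own printed correlations by
up to 0.4 — while the strong pairings (e.g. $r(b,c) = -0.970$,
$r(\mathrm{SAOR},\mathrm{FT}) = 0.728$, $r(\mathrm{FT},\mathrm{AUFC})
= -0.701$) do reproduce to ±0.005. P-values use the t-distribution on
residual degrees of freedom with no multiplicity correction, matching
the original analysis.

## What the simulator does and does not emulate

`simulate_pile_stack()` renders the growing pile as a clean triangular
silhouette (binary 0/255 intensities, no anti-aliasing) with height
following the exact cube-root law, optionally with a saturated central
jet band. `simulate_flow_curve()` produces the corresponding slice
areas directly, with optional stick–slip sawtooth avalanches
(inter-event gaps drawn as 5 frames plus a Poisson excess, fixed drop
amplitude) and additive Gaussian pixel noise. All stochastic paths
require an explicit seed and are bit-for-bit reproducible.

The simulator deliberately omits: 3-D effects and perspective, camera
noise beyond additive Gaussian, segmentation artifacts, inconstant
feed, particle-scale physics (no DEM), and avalanche amplitude/shape
heterogeneity. Passing the end-to-end tests therefore demonstrates
that the *measurement chain* is unbiased on data obeying the model
assumptions — angle recovery to 0.5°, exponent $c$ in [0.30, 0.36] on
ideal cones — not that real powders obey the ideal-cone law; on real
recordings the fitted exponent and the avalanche statistics are
empirical descriptors, not geometric constants.

Default simulation sizes used in the test-suite (10 s at 25 fps,
128 × 160 px, three angles) are chosen as the smallest runs on which
the angle and exponent recoveries are already stable well inside their
acceptance bands.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_pile_stack(alpha = 35, duration = 10)
res <- analyze_stack(sim)
res[, c("saor_deg", "a", "b", "c")]

rep <- reproduce_study()
rep$slopes
rep$correlations$r["b", "c"]
```

## Known limitations

* The power-law trend is the only growth model offered; logistic or
  exponential alternatives are out of scope.
* Areas are reported in pixels throughout — no mm-per-pixel
  calibration, as in the original rig.
* Video containers are not decoded; frames must be pre-extracted to
  PNG/TIFF.
* The avalanche counting rule is an operationalization (see above);
  absolute counts depend on the prominence and gap settings.
* The four-direction Crofton perimeter carries a ~5% anisotropy bias
  on axis-aligned shapes.
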