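---
title: "Methods: quantifying stromal ultrastructure, mechanics and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying stromal ultrastructure, mechanics and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromaquant)
```

stromaquant measures four properties of corneal stroma that degrade in
ectatic disease and recover under matrix-reinforcing treatment: collagen
fibril packing density and diameter (TEM), tensile stiffness, collagen
denaturation temperature (DSC), and keratocyte/inflammatory gene
expression (qPCR). This vignette documents the models behind each
estimator, the tunable parameters, the synthetic-data generators used to
validate them, and the design decisions taken where the underlying
protocols leave details open.

## Fibril segmentation

TEM micrographs of stromal cross-sections show fibrils as dark,
near-circular profiles on a brighter background. Segmentation is mean−C
adaptive thresholding: pixel `(r, c)` is foreground iff

    I(r, c) < mean(I over the k x k neighborhood) − offset,

with edge-reflected padding and `k = local_window_px` (default 51 px, odd).
The local mean is computed with an integral image, so cost is independent
of `k`. A Gaussian-weighted local mean (`method = "gaussian"`) is available;
the arithmetic mean is the default because it is the simplest member of the
adaptive-threshold family and its behavior under the offset is exactly
monotone (raising `offset` can only shrink the foreground).

Connected components (default 8-connectivity; 4 available) are filtered by
area (`[20, 10^4]` px² by default) and by circularity `4πA/P²` (default
minimum 0.6), which removes merged multi-fibril blobs. The perimeter `P` is
the count of exposed 4-neighbor pixel edges scaled by π/4; for convex
digital disks this estimator is exact in expectation (a digital disk of
radius `r` exposes almost exactly `8r` edges, giving `P ≈ 2πr`), so ideal
fibril profiles score circularity ≈ 1 while fused pairs score well below.
Diameters are equivalent-circle diameters, `2·sqrt(A/π)·pixel_size_nm`,
appropriate because fibril cross-sections are nearly circular; no
Feret/caliper measure is provided.

**Threshold offset.** The default `offset = 0.2` gray levels was chosen by
recovery calibration against the generator: across noise-free and noisy
synthetic fields the blurred edge profile crosses `local mean − 0.2` almost
exactly at the true disk boundary, making equivalent-diameter recovery
unbiased to ~0.2 nm at 2 nm/px (smaller offsets dilate detections by about
one pixel; larger ones erode them). Images with very different contrast
should recalibrate `offset` the same way.

## Density estimation by random windows

Density is estimated stereologically rather than from a single global
count: square windows of `window_px` (default 300 px) are dropped uniformly
at random — independent draws with replacement — with top-left corners on
the integer grid `[0, H−w] × [0, W−w]`, so windows always lie fully inside
the image. A fibril belongs to a window iff its centroid falls in the
half-open square `[r0, r0+w) × [c0, c0+w)`; half-open bounds mean abutting
windows never double-count. Per image, 200 windows are drawn (the protocol
constant); at least 3 images per specimen are required, their 600 counts
are pooled, and the density is the **pooled median count** divided by the
window area in µm². The median makes the estimate robust to windows that
land on preparation artifacts; its cost is quantization (one count step
equals `1/window_area` ≈ 2.8 fibrils/µm² at 300 px and 2 nm/px), which
dominates the estimator's error at low densities. An alternative
median-of-per-image-medians can be obtained by aggregating manually; the
pooled median is the default reading of a single final median.

Windows must fit inside the image, and fibril centroids inside the image
are counted even when their profile is clipped by the field of view. This
is a small positive bias at the image border (no guard-frame correction is
applied); the acceptance tests therefore bound per-fibril diameter errors
on unclipped fibrils only.

## Tensile reduction

Records are reduced with engineering conventions — stress `σ = F/A₀` in
MPa (`A₀` = initial width × thickness, mm²), strain `ε = Δl/l₀` against the
gauge length — because thin corneal strips give no cross-section updates
during the pull. Young's modulus is the OLS slope of `σ(ε)` restricted to
`[fit_lo_frac, fit_hi_frac] × max(ε)`, default `[0.7, 0.9]`. Soft collagen
tissue has a J-shaped curve; the high-strain window targets the
fibril-recruited, nearly linear regime where group differences in
stiffness express themselves, and for a truly linear specimen any window
returns the same slope. `R²` is reported from the fit window; fewer than
two points in the window is an error, not a silent extrapolation.

## DSC reduction

A thermogram is modeled as a linear instrument baseline plus a single
endothermic transition. The baseline is the line through the mean heat
flow of a pre- and a post-transition window (defaults: first and last 10%
of the scanned range); Td is the extremum of the baseline-subtracted
residual under the endotherm-down convention (`sign = "endo_up"` flips
it). Two numerical choices matter:

- **Smoothing before peak picking.** The residual is convolved with a
  Gaussian kernel (`smooth_sigma_C`, default 1 °C) before the extremum is
  located. With a broad endotherm (σ ≈ 2.5 °C) sampled every 0.1 °C, the
  raw argmin under realistic detector noise scatters by far more than a
  sampling interval, because the peak top is nearly flat; smoothing at
  roughly the peak width acts as a matched filter and brings the extremum
  scatter to a few hundredths of a degree. Smoothing with a symmetric
  kernel does not shift a symmetric peak.
- **Sub-grid refinement.** A parabola through the extremum and its two
  neighbors refines Td below the sampling interval.

Td is reported as the *peak* temperature, not the onset, matching how
single denaturation temperatures are usually quoted for collagen. Traces
whose peak height is under 3× the noise MAD (estimated from the baseline
windows) raise a no-peak error; baseline windows overlapping the peak's
half-height span are flagged as a warning in the result rather than an
error, since the baseline may still be serviceable.

## ΔΔCt and group statistics

Per sample, `ΔCt = Ct(target) − Ct(housekeeping)`; per gene,
`ΔΔCt = ΔCt − mean(ΔCt over control samples)`; fold change `= 2^(−ΔΔCt)`.
Referencing the control *mean* makes the control group's geometric-mean
fold exactly 1 by construction, and normalizing within sample cancels any
per-sample plate shift exactly. Group summaries are geometric means with
SDs on the log2 scale, the appropriate location/spread for ratio data. The
amplification-efficiency-corrected (Pfaffl) model is deliberately out of
scope; the 2^(−ΔΔCt) assumption of equal efficiencies is standard when a
validated housekeeping gene (here Gapdh) is used.

The t statistics (pooled-variance Student with `df = n₁+n₂−2`, and Welch
with Satterthwaite df) and the one-way ANOVA decomposition are computed
from their formulas — necessary anyway to support summary-statistics input
`(mean, sd, n)` for published group summaries — with p-values from the t/F
distributions. The test suite cross-checks them against `stats::t.test`
and `stats::aov` and verifies nominal size (type-I error within
[0.03, 0.07] at α = 0.05 over 10,000 null replicates) and the two-group
identity `F = t²`. No multiple-testing correction is applied by default,
matching common practice for small designed panels; apply
`stats::p.adjust` downstream if desired.

## Synthetic-data generators

Each generator is a first-class, seeded, bit-reproducible simulator whose
defaults define the study conditions used throughout the tests.

**Fibril fields.** A hard-core point process by random sequential
adsorption: diameters are drawn from a lognormal (default; right-skewed,
as diseased distributions tend to be) or zero-truncated normal law,
candidate centers uniformly, and a candidate is accepted only if every
edge-to-edge distance is ≥ `min_gap_nm` (default 6 nm). The attempt budget
is 100× the target count; a packing request with area fraction
`density·π/4·(d̄+gap)²·10⁻⁶ ≥ 0.55` (the practical RSA jamming limit) is
rejected up front. Accepted disks render with area-weighted anti-aliasing
(8×8 supersampling at boundary pixels), then Gaussian optics blur
(σ 0.8 px), then additive Gaussian detector noise (SD 0.05 gray levels)
clipped to [0, 1] — noise atop optics, as in a real detector chain.
Defaults (2 nm/px, densities of tens per µm², diameters 22–34 nm) are
plausible for corneal stroma at TEM magnifications.

**Tensile records.** `σ = A(exp(bε) − 1)` (toe-exponential; `E·ε` linear
variant) sampled on a uniform strain grid, converted to load via the 5 mm ×
0.4 mm default strip, displacement via an 8 mm gauge, and time via the
0.1 mm/s crosshead rate; load noise SD 0.005 N reflects a fine load cell.
The gauge length has no protocol default anywhere, so it is an explicit
required parameter.

**Thermograms.** Linear baseline minus a Gaussian endotherm (depth 2 mW,
σ 2.5 °C — a broad transition spanning the 60–70 °C band) plus white noise
of SD 0.05 mW, a realistic DSC noise floor giving peak SNR ≈ 40; scan
10–95 °C sampled every 0.1 °C at a nominal 5 °C/min.

**Ct tables.** `Ct = baseline_ct(gene) − log2_effect(group, gene) + ε`
with ε of SD 0.3 cycles and 6 replicates per group; the housekeeping gene
must carry zero effect in every group, which the constructor enforces.

**What the generators do not emulate.** Real micrographs contain lamellar
orientation texture, longitudinal fibril views, stain gradients and
proteoglycan deposits; real tensile records contain slack, slippage and
viscoelastic hysteresis; real thermograms have curved baselines and
asymmetric, multi-component endotherms; real Ct tables have
efficiency differences and outlier wells. Passing recovery tests therefore
demonstrates correctness of the estimators under their stated models, not
robustness to every artifact of real data; parameters exposed here
(threshold offset, circularity bound, baseline windows, fit window) are
the knobs a user would retune on real inputs.

## Group presets and the pipeline

`group_presets()` loads five groups — control, KC (enzyme-weakened ectatic
model), and KC treated with cornea- (COR), cartilage- (CART) or
lymph-node-derived (LN) particles — from a YAML file under
`inst/extdata/presets/`. Only their ordering is meaningful: KC is least
dense, largest-fibril, weakest and least thermally stable; COR restores
stiffness nearly to control; LN is densest with the smallest fibrils; Td
presets use the group means customarily reported for this assay family
(62.57–66.96 °C). Absolute densities and moduli are arbitrary plausible
values, since no public numbers exist for them.

`run_pipeline()` derives every stage's seed deterministically from the one
configuration seed (stage-name hashing), so stages are independently
reproducible and a fixed configuration yields a byte-identical JSON report.
`validate_config()` merges a YAML file over the defaults and returns either
a valid configuration or the complete list of violations, including unknown
keys. Per-endpoint statistics mirror the usual reporting of such studies:
one-way ANOVA across the five groups plus pairwise Student t tests against
the control and KC references; degenerate endpoints (e.g. the housekeeping
gene's identically-1 folds) are skipped rather than fabricated.

## Problem sizes and tolerances in the test suite

Recovery tests run at 2048² px (density/diameter recovery; the protocol
scale) and 1024² px (group-ordering replicates), with 20 seeded fields for
density recovery (10–100 fibrils/µm²), 100 seeded thermograms for Td
recovery, and 10,000 null replicates for test calibration. The density
tolerance (within 10% on ≥ 18/20 fields) reflects the median-count
quantization discussed above, which is the binding error source below
~15 fibrils/µm²; diameter recovery is bounded by one pixel per fibril
(unclipped fibrils) and 2 nm on the distribution median; Td recovery by
0.1 °C (one sampling interval). Determinism contracts are exact
(`identical()` on repeated runs).

## Known limitations

- Border fibrils carry an uncorrected counting/measurement bias (no
  guard frame); at 2048² px this affects a few percent of fibrils.
- The median density estimator is quantized by window area; enlarging
  windows trades quantization against within-image coverage.
- Overlapping anti-aliasing fringes of nearly touching fibrils can bridge
  at permissive offsets; the hard-core gap (≥ 3 px at default scale)
  plus the circularity filter keeps this negligible under defaults.
- Td detection assumes a single dominant transition; multi-peak
  deconvolution and enthalpy integration are out of scope.
- ANOVA/t tests assume approximate normality within groups; for n = 6 and
  the effect sizes simulated this is innocuous, but heavy-tailed real
  endpoints may warrant rank-based alternatives not provided here.
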