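---
title: "Quantifying filtration-slit morphology and claudin-5 recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying filtration-slit morphology and claudin-5 recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slitmorph)
```

## The measurement problem

The podocyte filtration slit (FS) is a curvilinear structure: nephrin
staining traces the slit diaphragm between interdigitating foot processes.
Two scalar read-outs summarize its state in two-channel super-resolution
images:

* the **CLDN5/nephrin area ratio** — after maximum intensity projection
  (MIP) and per-channel binarization, the claudin-5-positive area inside a
  selected FS region divided by the nephrin-positive area. Healthy slits
  show focal claudin-5 (low ratio); injured slits accumulate continuous
  claudin-5 lines, and in severe effacement claudin-5 persists where
  nephrin has vanished, pushing the ratio above 1;
* the **filtration slit density** (FSD) — the total nephrin-positive slit
  length `l_FS` in the region divided by the region's area `A`, in 1/µm.
  Effacement linearizes and spreads the slits, so FSD falls.

`slitmorph` implements both, a rule-based effacement-phase classifier, the
rank-based cohort statistics connecting them, and a synthetic image
generator that provides vector-level ground truth for validation.

## The synthetic slit model

Real micrographs of this kind are typically not publicly deposited, so the
generator stands in for them. It emulates what the estimators actually
see, not the optics that produced it:

* **Geometry.** Slit curves are vertical sinusoids
  `x(y) = x0 + a sin(2πy/λ + φ)` spanning a rectangular evaluable region.
  Interdigitation is a damped meander: amplitude `a = A0 (1 − e)` and
  spacing `s = S0 (1 + e)` with effacement `e ∈ [0, 1]`, reproducing the
  two observable endpoints — meandering, tightly packed slits at `e = 0`
  and sparse, linearized slits at `e = 1`.
* **Claudin-5 decoration.** An exact arc fraction
  `c(e) = c0 + (1 − c0) e^γ` of each curve is decorated in randomly
  placed segments (default mean length 1 µm). `c0 = 0.2` models focal
  basal co-localization; `γ < 1` lets recruitment lead effacement.
* **Nephrin gaps.** Beyond `e = 0.5`, an exact arc fraction
  `g(e) = g1 · max(0, 2e − 1)` of nephrin is erased in segments (default
  mean 2 µm), so continuous-nephrin (phase 1) states precede discontinuous
  ones (phase 2). Claudin-5 decoration is deliberately retained on erased
  arcs, producing claudin-5-positive/nephrin-negative segments and ratios
  above 1 in the severe regime.
* **Rendering.** Curves are stamped as line integrals on a 4×
  supersampled grid (avoiding aliasing of sub-pixel-width lines),
  convolved with an isotropic Gaussian PSF (FWHM 0.115 µm, the effective
  lateral resolution scale of the images this emulates), box-downsampled
  to the acquisition pixel size (default 1/5.853 ≈ 0.171 µm/px), and
  replicated over 21 z-slices (0.2 µm apart) under a Gaussian focal
  envelope (sd 0.35 µm).
* **Noise and clutter.** Per-voxel Poisson noise at `photon_scale`
  (default 200 photons per unit intensity) plus additive Gaussian read
  noise (sd 0.02); `photon_scale = Inf` with zero read noise gives the
  noise-free phantom regime. Optional claudin-5 blobs outside the
  evaluable region mimic endothelial/arteriolar signal and exercise the
  ROI confinement.

Ground truth is kept at vector level: polyline arc lengths (not raster
sums), decorated and retained fractions, and the analytic FSD
`l_FS / A`.

### Why these geometric defaults

The defaults (spacing 0.58 µm, amplitude 0.25 µm, wavelength 1.4 µm) were
chosen once, against a representability constraint of the raster: the
*perpendicular* distance between neighboring slit curves is
`s / sqrt(1 + k²)` at peak meander slope `k = 2πa/λ`, and it must stay
above roughly two pixels (≈ 0.35 µm at the default pixel size) for
binarization to keep neighboring slits separate. Steeper or denser
defaults fuse adjacent slits into a mesh that no length estimator can
untangle — a sampling limit, not an estimator flaw. The resulting healthy
truth FSD is ≈ 2.2 /µm and drops to ≈ 0.45 /µm at `e = 1`; this matches
the qualitative healthy-versus-effaced contrast, but the absolute healthy
value is not calibrated to human measurements (which are not stated
numerically in the source text for these acquisitions).

What the generator does **not** model: the structured-illumination optical
chain (grating phases, reconstruction filters and their artifacts), 3D
slit topology (slits live on one focal surface), tissue autofluorescence,
staining variability, and chromatic offsets between channels. Passing
recovery tests on synthetic fields therefore demonstrates estimator
correctness under this image model, not robustness to every property of
real biopsy images.

## The measurement pipeline

`measure_area()` composes, per region of interest:

1. **MIP** over the full z-range (a config z-window can exclude other
   focal planes, standing in for manual projection curation that keeps
   endothelial claudin-5 out of the FS area);
2. **binarization** — per-channel Otsu threshold on the ROI-restricted
   histogram by default (deterministic and parameter-free; the original
   macro's fixed thresholds are available as a config override). The
   comparison is strictly greater-than: pixels equal to the threshold are
   background. Otsu on a constant region is an error, not a guess;
3. **areas and ratio** — a pixel counts as inside the ROI iff its center
   (0-based, integer coordinates) lies inside the polygon, boundary
   inclusive; areas are pixel counts × pixel area. A nephrin-negative ROI
   yields a flagged invalid record rather than an error or a silent drop;
4. **skeletonization** — Zhang-Suen parallel thinning of the
   ROI-restricted nephrin mask, spur branches shorter than 3 px pruned
   (configurable), followed by a sequential simple-point cleanup that
   reduces 4-connected staircase corners and junction-glue pixels to
   minimal 8-connected chains. Without that cleanup, the pair-counting
   length rule double-counts staircase corners on oblique curves;
5. **chain length** — sum over unique 8-connected neighbor pairs, one
   pixel size per orthogonal step and √2 per diagonal step, with no
   global calibration factor. The known raster bias on smooth oblique
   curves (bounded by ≈ +8% at 22.5°, averaging ≈ +5% over orientations)
   is absorbed into stated tolerances rather than hidden behind an opaque
   correction; the test suite bounds it at ≤ 6% on rasterized circles;
6. **FSD** = chain length / polygon area;
7. **gap density and phase** — see below.

### Continuity: two measures, one lesson

For a skeleton viewed in isolation, `continuity_index()` reports
`(n_components − 1) / l_FS`. That is the natural definition on a whole
field, but on small tiled regions every slit that *crosses* the tile
contributes a component, so tiles over perfectly healthy fields would read
as discontinuous. `measure_area()` therefore records and classifies on a
boundary-aware **gap density** (`slit_gap_density()`): chain endpoints
lying in the ROI interior (more than 2 px from the boundary) are counted
and halved — a genuine nephrin break produces two interior endpoints,
whereas a slit ending at the tile edge produces none.

`classify_phase()` is deliberately simple: `phase2` if gap density exceeds
`continuity_max` (default 0.1 /µm), else `phase1` if the ratio reaches
`ratio_up` (default 0.5), else `healthy`. The phases are described only
qualitatively in the source literature; both thresholds are package
choices, exposed in the configuration, and the tests assert ordering
(healthy → phase1 → phase2 along the effacement axis), not absolute
boundaries. At default noise a minority of healthy tiles (roughly one in
six in the suite's fixtures) shows enough noise-induced skeleton breaks to
misclassify as phase2; users wanting a hard phase read-out should average
over many areas, as the aggregation rule below enforces anyway.

## Aggregation and inference

Per-glomerulus summaries are arithmetic means of ratio and FSD over valid
areas; glomeruli with fewer than 20 valid areas (the established inclusion
rule for this measurement) are rejected with a named exclusion error and
logged, never silently dropped. Cohort tables carry one row per sample —
the average of its glomerular means.

* **Mann-Whitney U** (two-sided): `U = min(U1, U2)` with
  `U1 = n1·n2 + n1(n1+1)/2 − R1`. The p-value is the exact U distribution
  when `n1 + n2 ≤ 12` and the data are tie-free (oracle-tested against
  full enumeration of rank splits), otherwise a normal approximation with
  tie and continuity correction. The exact/approximate boundary balances
  fidelity against runtime and is tested on both sides.
* **Spearman correlation**: Pearson correlation of mid-ranks; p from the
  `t = ρ√((n−2)/(1−ρ²))` reference distribution, except that a perfect
  monotone relation reports the exact permutation bound `2/n!`. `R²` is
  reported as `ρ²`, matching how paired `r`/`R²` values are conventionally
  reported for this statistic.
* No multiple-testing correction is applied (per-contrast reporting, as in
  the source analyses); the report says so explicitly. Contrast syntax
  allows pooling (`"control:MCD+FSGS"`), since a pooled diseased group is
  the smallest design in which an exact-floor-limited 5-vs-4 comparison
  can reach p < 0.01.
* The hierarchical nesting (area within glomerulus within sample) is
  handled by averaging, not by mixed-effects modeling — a deliberate
  mirror of the established analysis, and a known limitation.

## Problem sizes and determinism

The shipped experiment sizes are package choices: 160 × 160 px fields
(≈ 27 µm) with a 2 µm margin, 21 z-slices, 24 px (≈ 4.1 µm) square tiles
giving 25 areas per sample, and a 4/5/5 cohort. Every random element —
curve phases, decoration placement, noise, per-sample seeds — derives from
a single integer seed; identical configuration and seed reproduce
byte-identical arrays, CSVs, and JSON reports (run logs deliberately
contain no timestamps). The generator restores the caller's RNG state.

## Numerical choices and degenerate inputs

* Otsu uses a 256-bin histogram; the argmax of between-class variance is a
  plateau between classes, and the left plateau edge is returned (tests
  compare induced partitions, not raw thresholds).
* Effective slit spacing below two pixels is rejected as degenerate
  geometry; constant images under Otsu, zero-area ROIs, self-intersecting
  or sub-3-vertex polygons, duplicate ROI ids, and page counts not
  divisible by the channel count are all explicit errors.
* Empty nephrin masks skeletonize to an empty skeleton with length 0 and
  infinite (flagged) gap density; nephrin-negative ROIs yield invalid
  records that summaries exclude before the 20-area rule is applied.
* TIFF output is 32-bit float, channel-interleaved in z-major page order,
  with pixel size, z-step, channel names, and an intensity scale in a JSON
  sidecar; values are normalized to [0, 1] for storage (baseline-TIFF
  float constraint) and rescaled on read.

## Known limitations

* Absolute FSD values depend on the geometry defaults and are not
  calibrated to human biopsy measurements; comparisons across effacement
  levels and groups are the supported use.
* The chain-length estimator carries the uncorrected oblique-raster bias
  discussed above; whether proprietary implementations of slit-length
  measurement apply such a correction is unknown, so absolute FSD
  comparisons against them should be made with care.
* Skeleton-based length measurement degrades when inter-slit spacing
  approaches the pixel pitch (slits fuse); the generator refuses clearly
  degenerate geometry but cannot flag near-degenerate real data.
* The phase classifier is threshold-based and per-area; it is a
  reproducible operationalization of a qualitative taxonomy, not a
  validated diagnostic.
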