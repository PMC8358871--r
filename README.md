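# slitmorph

Morphometry of podocyte filtration slits in two-channel super-resolution
fluorescence images.

In healthy glomeruli, podocyte foot processes interdigitate and the
filtration slit (FS) between them — stained by the slit-diaphragm protein
nephrin — traces a dense, meandering curve. During injury the foot
processes efface: the slit pattern linearizes and thins out, and the tight
junction protein claudin-5 (CLDN5) is recruited to the slit, first focally,
then as continuous lines, and finally along segments where nephrin has
disappeared. `slitmorph` quantifies this process from two-channel
(nephrin / CLDN5) z-stacks, for image analysts and renal researchers who
want an open, tested implementation of the two standard read-outs:

- **CLDN5/nephrin area ratio** — within a manually (or automatically)
  selected FS region, each channel's maximum intensity projection is
  binarized and the ratio of positive areas
  `ratio = A_CLDN5 / A_nephrin` is computed. Ratios above 1 indicate
  CLDN5-positive but nephrin-negative slit segments (severe effacement).
- **Filtration slit density (FSD)** — the nephrin mask is thinned to a
  one-pixel skeleton whose weighted chain length estimates the total slit
  length `l_FS`; then `FSD = l_FS / A` (per µm), where `A` is the area of
  the evaluated region. FSD falls as effacement progresses.
- **Effacement phases** — a rule-based classifier labels each region
  `healthy` (low ratio, continuous nephrin), `phase1` (CLDN5 up-regulated,
  nephrin continuous), or `phase2` (nephrin discontinuous), using a
  boundary-aware nephrin gap density.
- **Cohort statistics** — per-glomerulus means over at least 20 evaluable
  areas, two-sided Mann-Whitney U contrasts between groups, and the
  Spearman correlation of the per-sample mean ratio with the mean FSD.

Because raw biopsy micrographs of this kind are rarely public, the package
includes a first-class synthetic generator: slit fields with known
vector-level ground truth (arc lengths, decorated fractions, gap
fractions) across an effacement continuum `e ∈ [0, 1]`, rendered with a
Gaussian PSF (FWHM 0.115 µm), realistic pixel sizes (≈ 0.17 µm), a z-stack
focal envelope, Poisson + Gaussian noise, and off-region endothelial
clutter. Every estimator in the package is validated against that ground
truth.

## Worked example

```r
library(slitmorph)

f <- generate_slit_field(synth_params(effacement = 0.7, seed = 42))
f$truth
#> ground_truth: 72 slit segments, l_FS = 460.3 um, A = 544.6 um2,
#>   FSD = 0.845 /um, coverage = 0.950

m <- measure_area(f$stack, f$roi, sample_id = "demo")
round(m[, c("ratio", "l_fs_um", "roi_area_um2", "fsd_per_um",
            "continuity_gaps_per_um")], 3)
#>   ratio l_fs_um roi_area_um2 fsd_per_um continuity_gaps_per_um
#> 1 0.976 444.146      544.588      0.816                   0.11
m$phase
#> [1] "phase2"
```

At effacement 0.7 the generator decorated 95% of the slit arc with CLDN5
and erased 20% of the nephrin; the measured ratio (0.98, approaching 1)
and FSD (0.82 /µm, versus ≈ 2.2 /µm for a healthy field) recover the truth
(0.845 /µm) within a few percent, and the discontinuous nephrin puts the
region in phase 2.

A full synthetic cohort (4 controls, 5 MCD-like, 5 FSGS-like samples, 25
tiled areas per sample) with group contrasts and the pooled ratio-FSD
correlation:

```r
res <- run_cohort_analysis(pipeline_config(seed = 1))
res$report
#> cohort_report: 14 samples
#>   pooled ratio-vs-FSD Spearman rho = -0.987 (R^2 = 0.974), p = 7.4e-11, n = 14
#>   ...
```

`run_end_to_end(config, out_dir)` writes the same experiment to disk:
TIFF stacks with JSON metadata sidecars, ROI files, measurement and
summary CSVs, `report.json`, and a deterministic `log.json` (config,
seeds, excluded glomeruli). A thin command-line front end with
`simulate` / `measure` / `stats` / `run-all` subcommands is installed at
`inst/cli/slitmorph`.

## ROI file schema

ROIs are JSON: an object with a `rois` array, each entry carrying
`roi_id`, `glomerulus_id`, `pixel_size_um`, and `vertices` (a list of
`[x, y]` pixel coordinates, ≥ 3 vertices, simple polygon). Pixel centers
sit at integer coordinates (0-based); a pixel belongs to an ROI iff its
center is inside the polygon (boundary counts as inside).

Measurement CSVs have a fixed column order: `sample_id, glomerulus_id,
roi_id, nephrin_area_um2, cldn5_area_um2, ratio, l_fs_um, roi_area_um2,
fsd_per_um, phase`, followed by provenance columns (gap density,
per-channel thresholds, validity flag).

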