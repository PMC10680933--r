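---
title: "Quantifying tumor-stroma ratio from tissue class maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-stroma ratio from tissue class maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrquant)
```

## The problem

The tumor-stroma ratio (TSR) — the proportion of stroma among the
tumor-bearing tissue of a hematoxylin-eosin slide — is a prognostic marker in
several epithelial cancers, including high-grade serous ovarian carcinoma:
stroma-rich tumors (TSR at or above 50%) carry a worse prognosis.
Pathologists score TSR visually in one 10x field of view at the most invasive
(MI) part of the tumor, or over the whole tumor (WT) bed, excluding necrosis,
adipose tissue, psammoma bodies and vessels. `tsrquant` reproduces this
measurement computationally from a *tissue class map* — a raster labeling
every pixel tumor / stroma / background (with a NODATA code for unscanned
area) at a known physical resolution (micrometers per pixel, `mpp`) — and
supplies the survival machinery used to evaluate the resulting stratification
in a treatment cohort.

The package deliberately does *not* ship a trained segmentation network. The
scientific content is downstream of segmentation: region-of-measurement
geometry, TSR tallies, cutoff search and survival analysis. The classifier
slot accepts any callable mapping an RGB tile to class probabilities; the
package ships a deterministic palette classifier for synthetic fixtures and a
small trainable color baseline for demonstrations.

## Pipeline

1. **Segmentation** (optional, for RGB input): overlapping square patches
   (default 256 px, stride 128 px, i.e. 50% overlap) are classified into
   (background, tumor, stroma) probabilities; overlapping contributions are
   averaged per pixel and the label is the per-pixel argmax. Exact
   probability ties resolve to the *lowest* class code, so ambiguous tissue
   falls into background and stays out of TSR tallies. Uncovered pixels
   become NODATA. Probability averaging (rather than majority vote of hard
   labels) gives smooth boundaries at patch seams.
2. **Most-invasive field of view**: the disk of radius 1.6 mm (a 10x
   objective field) maximizing the tumor fraction `tumor / (tumor + stroma)`
   over a regular grid of centers (default grid spacing radius/16). A
   candidate is valid only when *more than* 2/3 of the disk's in-bounds area
   is tissue; glass, necrosis and unscanned NODATA all count against
   validity, which rejects fields hanging off the tissue edge. Ties break by
   higher tissue fraction, then row-major center order, making the search a
   pure function of the map. Border-clipped disks are normalized by in-bounds
   area rather than zero-padded.
3. **Whole-tumor bed**: all pixels whose *local tumor density* (fraction of
   tumor pixels in a surrounding disk, default radius 500 um) strictly
   exceeds a threshold, after removing connected components smaller than
   0.1 mm^2. The density denominator includes background by default so that
   necrotic cores inside tumor lower the density smoothly instead of
   puncturing the bed; `tissue_only = TRUE` switches to a tumor+stroma
   denominator.
4. **TSR and stratification**: within either region,
   `stroma% = 100 * n_stroma / (n_stroma + n_tumor)`; background and NODATA
   are excluded. Stroma-rich means stroma% >= cutoff (default 50, inclusive).
   A survival-optimal cutoff can instead be searched on a grid (below).

### The dynamic tumor-bed threshold

For small tumors a fixed density threshold would keep a disproportionately
wide stroma margin around the tumor. The threshold therefore rises linearly
as the total tumor area `A` (mm^2) falls below a reference area:

$$\tau(A) = \begin{cases}
\tau_{base} & A \ge A_{ref}\\
\tau_{base} + (\tau_{max}-\tau_{base})\,(1 - A/A_{ref}) & A < A_{ref}
\end{cases}$$

The functional form and constants of the original empirical calibration are
unpublished (they were tuned against pathologist tumor-bed annotations), so
this piecewise-linear form is this package's own choice: it is the simplest
monotone interpolation with the two stated behaviours (a fixed threshold for
large tumors, a tighter margin for small ones). Defaults:
`tau_base = 0.15`, `tau_max = 0.50`, `area_ref_mm2 = 50`,
`kernel_radius_um = 500`, `min_component_mm2 = 0.1` — all configurable, all
recorded in every region's parameter block. On desk-scale phantoms
(tumors of 0.2-3 mm^2) the dynamic regime is only visible with a smaller
`area_ref_mm2`; the acceptance test uses 5 mm^2 for that reason.

### Working resolution

Region geometry does not need the native 0.25 um/px of a 40x scan.
`run_slide` majority-vote downsamples the class map to a working resolution
(default 8 um/px) before the searches; majority vote per block with
lowest-code ties preserves class-area fractions up to a boundary term of
order `2kP/A` (perimeter P, area A, factor k), which the test suite asserts
on disk phantoms. All thresholds and radii are specified in physical units
and converted through `mpp`, so results are resolution-stable.

## Manual scoring, consensus and concordance

Manual TSR is scored per tenfold percentage (0, 10, ..., 100) by two raters;
a discordant pair requires a third rater. The original protocol resolves
discordance by discussion; as a deterministic stand-in the package returns
the **median of the three scores** and labels the result
`method = "median_of_three"` so downstream users can distinguish adjudicated
values. Agreement between automated and manual scores is reported as Pearson
r together with ICC(2,1) — two-way random effects, absolute agreement,
single rater — computed from the two-way ANOVA mean squares. The ICC variant
is not stated in the source protocol; ICC(2,1) is fixed and labeled in the
output (`icc_model`) so alternative variants can be compared externally.
Absolute-agreement ICC penalizes systematic shifts between methods that
Pearson ignores, which is the property of interest when one method is to
replace the other.

## Survival machinery

* **Kaplan-Meier / log-rank** via the `survival` package (events precede
  censorings at tied times; df = groups - 1). Survival at 120 months gives
  "10-year OS probability" style summaries.
* **Cox regression** with Efron tie handling (month-resolution data are
  heavily tied; Efron is the better approximation and is labeled in the
  result). Wald 95% intervals; suspiciously large coefficients are flagged
  as possible separation.
* **Model building** mirrors the conventional epidemiological recipe:
  univariable screen at p < 0.10 (likelihood-ratio test, so multi-level
  factors are handled as one term), then backward elimination dropping the
  worst candidate while its p >= 0.05. The exposure (TSR category) is
  *forced*: never screened, never dropped — automated selection must not
  silently un-adjust the effect of interest. The full selection trace is
  kept on the result. The stay threshold of 0.05 is this package's default;
  the source protocol does not state one.
* **Association tests** dispatch per the classical rule: Pearson chi-square
  *without* continuity correction unless more than 20% of expected cell
  counts fall below 5, in which case Fisher's exact test is used. The
  uncorrected chi-square is required to reproduce published cross-table
  p-values (e.g. p = 0.002 on the CD68 2x2 of the motivating study).
* **Optimal cutoff search** scans a grid (default 5-95% in 1% steps),
  dichotomizes at each cutoff and maximizes the two-group log-rank
  chi-square. Cutoffs leaving fewer than 5 patients on a side are skipped
  (degeneracy guard). No multiple-testing correction is applied — the use is
  exploratory and the full grid is returned so callers can correct; note
  that under the null the *maximum* of the grid exceeds nominal significance
  far more often than 5% (about a third of null cohorts show some cutoff
  with p < 0.05), so the grid minimum p must not be read as a calibrated
  p-value.

## TIL integration and the joint classifier

Immunohistochemistry lymphocyte counts (CD8, CD20, CD68, CD103) are binned
ordinally: 0, 1-5, 6-19, 20-49, 50-100, >100 positive cells (codes 0..5),
with the highest count per tumor retained. The TIL-high group is the highest
quartile of the empirical bin distribution; because bins are coarse, the
quartile boundary frequently falls inside a tied mass, and the whole tied
value then goes to the *upper* side (threshold = ceiling of the 75th
percentile, assignment by >=). An all-equal input cannot be split and is
returned all-LOW with a `degenerate` flag rather than an arbitrary cut. The
joint prognostic classifier is then:

| stroma category | TIL high | TIL low |
|---|---|---|
| stroma-poor | LOW risk | MEDIUM risk |
| stroma-rich | MEDIUM risk | HIGH risk |

## The synthetic world

Every pipeline stage is testable without patient data through two
generators, both pure functions of their spec (seed included; the caller's
RNG stream is untouched).

**`generate_mask`** paints a planted 1.6 mm disk plus random tissue nests
into a background field, carves background blobs (necrosis/adipose
stand-ins, default 8% of the map) from thresholded smoothed noise, and
assigns tumor versus stroma inside each region by thresholding an
independent smoothed-noise field at the empirical quantile of the target
stroma fraction. Quantile thresholding makes the realized fraction match the
target to within one pixel, and the ground-truth record reports exact pixel
tallies — so TSR tests compare against counted truth, not a nominal target.
Thresholded smooth noise produces organically interdigitated tumor/stroma
patterns loosely resembling papillary versus solid growth; it does **not**
emulate real histology (no nuclei, no texture, no staining variation), so a
green segmentation test establishes correct plumbing, not histology-grade
accuracy.

**`generate_cohort`** simulates an advanced-stage ovarian-cancer-like
cohort: exponential baseline calibrated to a median OS, per-patient hazard
multiplied by `hr_stroma_rich` for stroma-rich patients and `hr_til_low` for
TIL-low patients, independent uniform censoring with the bound solved
numerically to hit the requested censoring fraction, and progression times
generated as a Beta(2, 3) fraction of the latent death time sharing the
censoring time (so PFS <= OS by construction; the true PFS/OS dependence is
unknown and this constant is a stated convention). Defaults state the
motivating cohort: n = 340, median OS 38.3 months, 14% censoring (86% of
patients died), stroma-rich prevalence 0.33, PDS treatment-arm fraction
0.415, hazard ratios 1.6 (stroma-rich) and 1.5 (TIL-low) on the crude scale.
Automated TSR scores are drawn consistently with the latent category
(rich: uniform 50-95%, poor: uniform 2-49.9%) and manual scores are the
automated ones plus noise, rounded to tenfolds. Non-causal covariates and
the three non-causal TIL markers are sampled independently. Note the Cox
hazard ratio is non-collapsible: when both hazards are active, the marginal
stroma-rich HR is slightly below `hr_stroma_rich`; recovery tests therefore
switch the TIL hazard off when asserting exact marginal recovery.

## Numerical choices and degenerate inputs

* Coordinates are 1-based matrix indices internally, 0-based in patch
  origins (documented per function); rasters are row-major matrices.
* Disk membership is pixel-centered: `(dr^2 + dc^2) <= radius_px^2`. Disk
  sums use row prefix sums plus one vectorized pass per disk row —
  exact integer counts, no FFT rounding — and are checked against explicit
  offset enumeration in the tests.
* Validity comparisons are strict where the rule says "more than" (tissue
  fraction > 2/3, density > tau); stratification is inclusive (>= cutoff).
* Empty or degenerate inputs raise classed conditions
  (`tsrq_no_valid_fov_error`, `tsrq_empty_rom_error`,
  `tsrq_empty_tissue_error`, ...) rather than returning silent empties;
  batch drivers record them as per-slide skip reasons, mirroring how
  unscorable slides are excluded rather than crashing a cohort run.
* Class maps and region masks serialize as ASCII netpbm (PGM) with a JSON
  sidecar carrying metadata and the full parameter record; every region is
  replayable from its sidecar. (No binary raster codec is assumed to exist
  in the toolchain; the format choice is deliberately plain text.)

## Known limitations

* No vendor WSI decoding, stain normalization, or GPU inference; inputs are
  class maps or simple RGB rasters.
* The palette classifier is exact only on palette-colored fixtures; the
  color baseline is a demonstration, not a histology model.
* The dynamic-threshold constants are this package's defaults, not the
  original empirical calibration, which is unpublished.
* Single slide per patient; no multi-slide aggregation, competing risks,
  time-varying covariates, or missing-data imputation.
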