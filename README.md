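# tsrquant

Tumor-stroma ratio (TSR) quantification from whole-slide tissue class maps,
with the survival machinery to evaluate it as a prognostic marker.

## What problem this solves

In several epithelial cancers — high-grade serous ovarian carcinoma in
particular — patients whose tumors are *stroma-rich* (stroma ≥ 50% of the
tumor-bearing tissue) have worse overall survival than *stroma-poor*
patients. TSR is cheap to obtain (it needs only a routine H&E slide) but
manual scoring is subject to inter-observer variability. `tsrquant`
implements the computational counterpart for people working in computational
pathology and clinical biostatistics: starting from a pixel-level tissue
class map (tumor / stroma / background, plus a NODATA code, with
micrometers-per-pixel metadata), it

1. finds the **most-invasive (MI) region** — the 1.6 mm-radius field of view
   (a 10x objective field) with the highest tumor fraction
   `tumor/(tumor+stroma)`, considering only fields that are more than 2/3
   tissue;
2. estimates the **whole-tumor (WT) bed** — all tissue whose local tumor
   density exceeds a threshold `τ(A)` that rises for smaller tumors
   (`τ(A) = τ_base` for tumor area `A ≥ A_ref`, rising linearly to `τ_max`
   as `A → 0`), with small disconnected components removed;
3. measures **TSR** in either region as
   `stroma% = 100·n_stroma/(n_stroma + n_tumor)` (background excluded) and
   stratifies stroma-rich vs stroma-poor at an inclusive cutoff
   (default 50%), or searches the survival-optimal cutoff by maximizing the
   two-group log-rank χ² over a grid;
4. provides the **cohort statistics** used to evaluate the marker:
   Kaplan-Meier and log-rank, Cox regression (Efron ties) with a p < 0.10
   univariable screen and backward selection around a forced exposure,
   χ²/Fisher association tests with the expected-count dispatch rule,
   ordinal tumor-infiltrating-lymphocyte (TIL) binning, and the three-tier
   joint TSR×TIL risk classifier (LOW = stroma-poor/TIL-high,
   HIGH = stroma-rich/TIL-low, MEDIUM = the mixed combinations);
5. ships a **synthetic-data module** — label rasters with exactly known
   stromal fractions and proportional-hazards cohorts with known hazard
   structure — so every stage is verifiable without patient data.

Patch extraction, pluggable patch classification and probability-map
stitching are included for RGB input; the trained CNN of a production
pipeline is deliberately out of scope (the classifier slot takes any
function; a palette classifier for synthetic fixtures and a small trainable
color baseline are included).

## Worked example

```r
library(tsrquant)

# a synthetic slide: planted MI disk with 55% stroma, known ground truth
g   <- generate_mask(mask_spec(target_stroma_fraction_mi = 0.55, seed = 42))
rep <- run_slide(g$classmap)
rep
#> <slide_report> synthetic-42 (params 3e5c0ebabecf)
#>      slide_id rom_kind stroma_percent n_tumor_px n_stroma_px    category
#>  synthetic-42       MI       51.04041      21835       22763 STROMA_RICH
#>  synthetic-42       WT       41.19250       9498        6653 STROMA_POOR
```

The MI search maximizes *tumor* fraction, so it settles on a
tumor-enriched disk: 51.0% stroma, slightly below the planted disk average
of 55% — still stroma-rich at the 50% cutoff. The WT bed keeps only tissue
above the tumor-density threshold, hence its lower 41.2%.

```r
# a synthetic cohort stated like an advanced-stage ovarian-cancer study:
# n = 340, median OS 38.3 months, HR 1.6 for stroma-rich, HR 1.5 for TIL-low
co <- generate_cohort(cohort_spec(seed = 42))
run_cohort(co$records)
#> <cohort_report> exposure tsr_auto_mi at cutoff 50%, n = 340
#>   combined (n = 340): log-rank chi2 = 17.58, p = 2.75e-05
#>   PDS (n = 140): log-rank chi2 = 6.69, p = 0.0097
#>   NACT (n = 200): log-rank chi2 = 11.13, p = 0.00085

run_cohort(co$records)$combined$crude_cox
#> <cox_result> OS, n = 340 (295 events), ties = efron
#>                        term               hr            p
#>  stroma_categorySTROMA_RICH 1.67 (1.31-2.13) 3.327794e-05
```

The crude hazard ratio 1.67 (95% CI 1.31-2.13) recovers the generative
HR 1.6 within sampling error. Agreement between automated and tenfold
"manual" scores of the same cohort:

```r
concordance(co$records$tsr_auto_mi, co$records$tsr_manual_mi)
#> <concordance> n = 340: Pearson r = 0.977, ICC = 0.977
#>   [ICC(2,1) two-way random, absolute agreement, single rater]
```

A thin CLI wraps the same functions
(`inst/cli/tsrquant segment|rom|tsr|cohort|simulate`); see the script header
for usage and exit codes. Class maps and region masks serialize as
plain-text PGM with JSON sidecars, so every region of measurement is
auditable and replayable.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end demonstration from scratch: it generates
a synthetic slide with known stromal fractions, runs the full MI + WT TSR
pipeline on it, simulates a 340-patient proportional-hazards cohort, and
runs the complete survival analysis (KM, log-rank, crude and adjusted Cox,
joint risk groups) before writing the results JSON to `--out`. All
randomness derives from `--seed`.

## Vignette

`vignettes/tsrquant-methods.Rmd` documents the model and its assumptions:
the region-of-measurement definitions, the dynamic tumor-bed threshold, tie
and tied-mass rules, the ICC variant, what the synthetic world does and does
not emulate, and the package's choices where the underlying protocol is
unpublished.
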