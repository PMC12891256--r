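# gciplvf

Structure–function analysis linking widefield OCT ganglion cell–inner
plexiform layer (GCIPL) thickness maps to 24-2 visual-field (VF) results
across the glaucoma spectrum.

Widefield OCT protocols (55° × 45°) capture GCIPL thickness over essentially
the whole retinal area sampled by 24-2 perimetry, which makes two questions
tractable for clinicians and vision scientists working on glaucoma:

1. **Quantitative**: how well do ganglion-cell (GC) counts estimated from
   GCIPL thickness predict co-localised VF thresholds?
2. **Binarised**: how well do normative-deviation GCIPL parameters predict
   whether a VF location (or hemi-cluster of locations) is defective?

This package implements the full analysis chain for both questions, plus a
synthetic cohort generator with coupled structure and function so every
stage is testable end to end without clinical data.

## What the package computes

**Projection and GC estimation.** 24-2 locations are projected onto
fovea-centred 160 × 160 thickness rasters (100 μm squares) with Bennett-style
ocular magnification scaling `q = 0.01306·(AL − 1.82)` mm/deg, a Goldmann III
stimulus footprint (0.43°) plus a 0.5° microsaccade allowance, and
Drasdo-style Henle-fibre displacement of the central 16 locations. Sampled
GCIPL is converted to GCL thickness by `GCL = 0.5651·GCIPL − 0.9026` (μm) and
multiplied by co-localised volumetric GC density to give counts per stimulus
area, expressed in dB (10·log₁₀ cells).

**Segmented regression.** VF threshold (dB) against GC count (dB) is fitted
with the continuous broken-stick model

    y = β₀ + β₁·x + β₂·(x − ψ)₊

by Muggeo-style iterative linearisation from an initial breakpoint of
15.5 dB, safeguarded by a profile scan and verified against an exhaustive
grid search; Davies' test assesses breakpoint existence and
extra-sum-of-squares F tests compare stratified against pooled models, with
MAE/RMSE per model.

**Normative deviation.** A per-grid-square normative model (linear age and
fovea–disc tilt adjustment with empirical residual quantiles) yields 5th
percentile flag maps and a within-eye relative thickness map re-zeroed at
the 85th percentile of total deviation, mirroring pattern-deviation logic.

**Hemi-cluster classification.** VF locations are grouped into five
eccentricity-ordered cluster groups per hemifield (hemi-clusters). Defective
VF hemi-clusters are labelled from Hodapp–Parrish–Anderson defects (≥3
contiguous points at p<5%, ≥1 at p<1%) with an inclusive 25% criterion.
Three classifiers are compared: the flagged-proportion "percentile" score,
PCA + logistic regression on five hemi-cluster GCIPL parameters with
backward elimination, and a cascaded "PCA plus central" variant feeding each
ring the adjacent more-central ring's predicted probability.

**Evaluation.** ROC curves with DeLong AUC standard errors, paired DeLong
comparisons, Youden thresholds derived on a ROCC cohort (healthy +
perimetric glaucoma) and carried unchanged to the held-out test cohort, and
sensitivity/specificity with participant-level bootstrap CIs.

## Worked example

```r
library(gciplvf)

cfg <- generator_config(n_healthy = 24, n_suspect = 4, n_glaucoma = 16,
                        seed = 19, defect_pattern_probs = c(0.2, 0.6, 0.2),
                        defect_depth_um = c(30, 45),
                        rocc_n_healthy = 16, rocc_n_glaucoma = 8)
cohort <- generate_cohort(cfg, n_reference = 30)
eye <- cohort$eyes[[30]]

est <- project_and_estimate(eye$map, eye$biometry)
summary(est$count_dB)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.    NA's
#>   20.30   20.65   22.39   23.06   22.94   33.71       2

set.seed(42)
x <- runif(300, 5, 30)
y <- 10 + 0.5 * x + 1.0 * pmax(x - 17, 0) + rnorm(300, 0, 2)
fit_segmented(x, y)
#> Segmented fit (n=300, muggeo): intercept 9.90, slope1 0.51, breakpoint 17.40 dB, slope2 1.54
#>   adj R2 0.94, F 148.68 (p 2e-45), MAE 1.50 dB, RMSE 1.88 dB
```

This eye is a glaucomatous example: estimated GC counts per stimulus
location run from ~34 dB (≈2,300 cells) centrally down to ~20 dB in the
defect, and two far-nasal locations fall off the scanned raster (`NA`). The
segmented fit recovers the generating broken-stick model: the left-segment
slope (0.51 dB/dB), the breakpoint in GC count (17.40 dB) and the
right-segment total slope (1.54 dB/dB), with residual errors around the
2 dB noise floor.

The numbered scripts under `analysis/` run the full workflow on the
study-scale synthetic cohort and write Table-shaped CSVs under `results/`:
`01_simulate_cohort.R` (cohort + demographics + tidy structure–function
dataset), `02_structure_function.R` (segmented fits, Davies and nested-F
tests), `03_normative_deviation.R` (normative calibration),
`04_classification_evaluation.R` (AUROCC comparisons, method selection,
sensitivities/specificities, structure–function concordance).

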