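---
title: "Methods: widefield OCT GCIPL to 24-2 visual field structure-function analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: widefield OCT GCIPL to 24-2 visual field structure-function analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gciplvf)
```

This vignette documents the models, parameter choices and numerical
decisions behind `gciplvf`, and what the synthetic cohort generator does and
does not emulate.

## The measurement chain

The structural measurement is a fovea-centred raster of ganglion cell-inner
plexiform layer (GCIPL) thickness: 160 × 160 squares of 100 × 100 μm
(16 × 16 mm), right-eye normalised, with `NA` marking squares where
segmentation failed. The functional measurement is a 24-2 perimetric result:
52 analyzable locations on a 6° grid (two blind-spot locations excluded),
with thresholds, total deviation (TD), pattern deviation (PD), ordinal
probability categories, MD, PSD and a false-positive rate (records with
FP ≥ 15% are considered unreliable).

### Field-to-retina projection

Retinal coordinates are fovea-centred with x positive temporal and y
positive superior *retina*; projection from field coordinates flips both
axes. Visual angle converts to retinal distance with linear Bennett-style
scaling, q = 0.01306·(AL − 1.82) mm/deg; a nonlinear tangential-plane model
can be plugged in as a function because published corrections differ in
detail and the package should not hard-code one. There is no emmetropic
default: axial length is required, since silently assuming AL = 24 mm would
bias peripheral projections by several hundred μm.

Each stimulus region is an ellipse with angular radius 0.43°/2 + 0.5°
= 0.715°. The 0.5° microsaccade allowance is interpreted as an addition to
the stimulus *radius*; the alternative (diameter) interpretation is
configurable via `microsaccade_deg`. For the central 16 locations
(|x|, |y| ≤ 9°) the region margins are displaced radially outward by a
Drasdo-style Henle-fibre displacement curve — a gamma-shaped bump peaking at
0.37 mm near 1 mm eccentricity and clamped to zero beyond 3.4 mm. The exact
published displacement formula is not reproducible from text sources, so
the curve is a documented stand-in with the correct shape, peak and support;
it is applied to the region margins (centre and radial half-width), not to
individual sampled squares.

Sampling averages valid squares whose centres fall in the ellipse and
reports coverage = valid overlapped area / ellipse area. Locations with
coverage < 0.5 are flagged `excluded` and dropped from regressions and
classification: partial sampling of a stimulus region biases the mean
toward whichever side of the region survived segmentation. Long eyes
(AL near 27.6 mm) genuinely project the far nasal locations off the 16 mm
raster; the generator and pipeline treat those as missing, not zero.

### GC count estimation

GCIPL converts to GCL thickness by the published linear equation
GCL = 0.5651·GCIPL − 0.9026 μm, clamped at zero because a thickness cannot
be negative (the equation's root is at GCIPL ≈ 1.6 μm). Counts are
GCL(mm) × ellipse area (mm²) × mean volumetric density (cells/mm³), reported
both as cells and in dB (10·log₁₀ cells). Counts below 1 cell are floored at
0 dB and flagged rather than propagating −∞; by default floored points are
excluded from regressions (flag to include). The default density field is a
smooth elliptically-symmetric analytic stand-in (peak ≈ 5×10⁵ cells/mm³ near
1 mm eccentricity decaying to 10⁵ peripherally, the right order of magnitude
for human histology); it is labelled synthetic, and real analyses should
supply a histology-derived raster through the same `density_field`
interface.

## Segmented structure-function regression

The model is the continuous broken stick
y = β₀ + β₁x + β₂(x − ψ)₊, with x the GC count in dB and y the VF threshold
in dB. Expressing counts in dB is a deliberate choice documented here: the
breakpoint is quoted in dB in the literature this analysis follows, and
classic structure-function models operate on log-transformed GC numbers.
"Slope2" is reported as the right-segment *total* slope β₁ + β₂.

The breakpoint is estimated by Muggeo-style iterative linearisation (fit
y ~ x + (x−ψ)₊ + ψ-gradient term, update ψ, iterate to |Δψ| < 1e-8, max 100
iterations with progressive damping because the working-linear update can
oscillate between data gaps) from ψ₀ = 15.5 dB with jittered restarts. The
RSS profile in ψ is piecewise-smooth and can be multimodal, so the best
iterate is safeguarded by a 512-point profile scan whose leading local
minima are polished with golden-section refinement; an exhaustive
grid-search fallback (step 0.01 dB) runs if the iteration fails outright.
The test suite asserts agreement with an independent exhaustive grid search
to within the grid step, and exact recovery (≤1e-6) on noiseless data.

Davies' test uses the maximum of Wald statistics for the hinge coefficient
over K = 10 candidate breakpoints evenly spaced between the 10th and 90th
x-percentiles, with the two-sided p-value equal to twice the one-sided
Davies upcrossing bound, p = 2·[Φ(−M) + V·exp(−M²/2)/√(8π)] where V is the
total variation of the statistic sequence. This form was chosen over the
variant that doubles only the Gaussian tail because only it is calibrated:
simulated type-I error at α = 0.05 on pure linear Gaussian data falls inside
the binomial 95% interval, which the acceptance suite re-verifies on 1,000
simulations.

Stratified versus pooled model comparisons use the extra-sum-of-squares F
with 4 parameters per segmented fit; a degenerate guard returns F = 0 when
both models interpolate noiseless data. `max_model_divergence` scans
predictions on a 0.001 dB grid to report the maximum spread between models
over the observed count range.

## Normative model and deviation maps

"Matching for age and tilt" is implemented as a per-square linear
adjustment, thickness ~ age + tilt, fitted across reference eyes with the
empirical residual distribution stored per square. All squares share one
design matrix, so the raster fits in a single multi-response least-squares
solve; squares valid in fewer than 20 reference eyes are masked.
Rank-deficient covariates (e.g. a reference set with constant age)
contribute zero adjustment rather than `NA`.

A square is flagged when observed − adjusted mean falls strictly below the
5% residual quantile (type-7 linear interpolation). The relative map
subtracts the eye's own 85th percentile of total deviation over valid
squares, mirroring pattern-deviation logic; by construction at most 15% of
valid squares are positive (up to interpolation ties), and the whole-map
choice (rather than a sub-region) follows from treating every valid square
as part of the eye's "hill" of thickness. Calibration is a tested property:
held-out healthy synthetic eyes flag at ≈5%, and an injected age slope is
recovered within its confidence interval.

## Hemi-cluster classification

The shipped cluster template is an explicitly *synthetic* eccentricity-ring
schematic: per hemifield, the 26 analyzable locations are ranked by
eccentricity (deterministic tie-break by |x|, then x, then y) and split
central → peripheral into groups of 2/4/7/9/4, labelled C6-8, C4-5, C3, C2,
C1; raster squares take the hemi-cluster of the nearest projected location
within the matching retinal hemifield. True cluster boundaries from
normative studies are not publicly reproducible, so every analysis accepts a
user-supplied grid-label map.

VF hemi-clusters are labelled defective when ≥25% (inclusive) of assigned
locations are defective under the Hodapp-Parrish-Anderson rule. Contiguity
for that rule defaults to 8-neighbour adjacency restricted to within a
hemifield — glaucomatous defects respect the horizontal midline — and both
choices are configurable because the underlying clinical rule does not
specify them. The inclusive criterion makes the two-point central
hemi-cluster defective at one defective point (50%), which is the intended
behaviour of the 25% compromise between central and peripheral hemi-cluster
sizes.

The five classification features per hemi-cluster are the mean and SD of
GCIPL thickness, asymmetry (mean minus the mirror hemi-cluster's mean), and
the mean and asymmetry of relative thickness. Backward elimination assesses
each parameter's Wald p-value in a multiple logistic regression on the
*standardised raw parameters*, dropping the least significant while any
p ≥ 0.05: significance of an original parameter inside a PC regression is
not well defined, and this interpretation keeps the elimination step
conventional and reproducible. PCA runs on the survivors; PCs are retained
by the Kaiser rule (eigenvalue > 1, minimum one PC), and a logistic
regression is fitted on the retained scores. Complete separation triggers a
small-ridge penalised fit with a warning. The cascade trains central →
peripheral, passing each ring the adjacent more-central ring's predicted
*probability* (information-preserving, rather than a hard class) as an
additional candidate parameter subject to the same elimination.

## Evaluation

AUCs are Mann-Whitney concordances with tie correction; standard errors and
paired comparisons use DeLong structural components (verified in tests
against brute-force pairwise concordance and an independent reference
implementation). The method-selection rule keeps the percentile score
unless an alternative's AUROCC is significantly higher (two-sided DeLong
p < 0.05, no multiplicity adjustment, matching the reporting convention of
the clinical analysis); Youden thresholds break ties toward higher
specificity, the right default for a screening tool where false referrals
are the main cost. Thresholds are derived exclusively on the ROCC cohort
(healthy + perimetric glaucoma) and applied unchanged to the test cohort
and diagnosis strata; the report object records this and the acceptance
suite asserts it structurally by perturbing test-cohort scores.
Sensitivity/specificity CIs default to a participant-level nonparametric
bootstrap (2,000 replicates, percentile intervals) because hemi-clusters
within an eye are correlated; the exact clustered estimator of the cited
methodological literature is not reproducible from text, so the bootstrap
is the documented stand-in, with a Wilson fallback for independent data.

## The synthetic cohort generator

The generator is first-class, tested code whose defaults are the study
conditions the analysis assumes: 311 healthy / 268 suspect / 269 glaucoma
eyes; ages around 55/62/65 ± 13 years by diagnosis; axial lengths
N(24, 1.1²) truncated to the 21.03-27.60 mm range; fovea-disc tilt
N(7, 3.8²)°. Healthy GCIPL surfaces are a gamma-shaped annulus (floor 25 μm,
peak 100 μm near 1.1 mm eccentricity) plus a per-eye offset (SD 4 μm), an
age effect of −0.1 μm/yr, a tilt effect of 0.1 μm/°, and i.i.d. 2 μm
measurement noise. Glaucomatous defects are arcuate, hemifield or
paracentral regions of one retinal hemifield (mixed 50/30/20%) with
raised-cosine margins, depths 20-60 μm, clamped at a 15 μm residual
(non-neural) floor; suspects get mild diffuse thinning and occasional
shallow focal loss below treatment-level defects. The depth range and
pattern mix were set so the simulated glaucoma cohort's MD distribution
approaches the early-dominated severity profile of the emulated
population.

Visual fields are generated *through* the structural pipeline: each eye's
noiseless map is projected and converted to per-location GC counts, and
thresholds follow a state-dependent segmented forward model — the pooled
non-defective parameters (24.26, 0.41, 17.8, 0.14) at non-defective
locations with 2 dB noise, and the pooled defective parameters (10.85,
0.51, 17.31, 1.00) with 9 dB noise at locations substantially covered by
the defect — echoing the reported contrast between small non-defective and
large defective errors. TD/PD probability categories are graded against the
generator's own simulated healthy reference distribution, mirroring how
perimeters derive their normative limits; MD and PSD are the mean and SD of
TD. A location counts as functionally defective when the defect weight
averaged over its projected region is ≥ 0.25.

Two configurations are fixed choices rather than dials:

* `generator_config()` — the study-condition defaults above.
* `high_coupling_config()` — the validation condition for end-to-end
  classification: deep (60-80 μm) hemifield defects only, inter-eye SD
  halved to 2 μm, VF noise 1 / 1.5 dB, and two VFs per eye with the
  repeatable-defect rule. Hemifield defects are used because their spatial
  footprint aligns exactly with the hemi-cluster aggregation; arcuate and
  paracentral patterns deliberately produce the geometric
  structure-function discordance seen clinically (defects straddling the 6°
  grid, central deficits saturating against the thick central GCIPL), which
  is realistic but is noise from the point of view of validating that the
  classifiers recover a strong signal.

What the generator does **not** emulate: OCT speckle and B-scan artefacts,
blood-vessel masking, temporal-raphe anatomy, disease-related changes in GC
density or soma size, perimetric response nonstationarity beyond Gaussian
state-dependent noise, and spatial correlation of measurement noise. Tests
passing on synthetic cohorts therefore demonstrate the *pipeline's*
correctness and calibration, not clinical performance: real-data AUCs and
sensitivities will be lower and the clinical tables cannot be reproduced
from synthetic data.

## Problem sizes and determinism

The test and validation runs use deliberately modest sizes chosen as the
smallest that make the statistical assertions stable: 1,000 random maps for
the defect-rule oracle, 50 datasets of n = 200 for the grid-search
comparison, 1,000 simulations for Davies calibration, 200 reference + 40
held-out eyes for normative calibration, a 180-eye high-coupling cohort for
the end-to-end check, and a 300-eye noiseless cohort for forward-model
recovery. All randomness flows from explicit seeds; `generate_cohort()`
seeds the RNG from its config so a cohort is a pure function of its
configuration.

## Known limitations

* The schematic ring template only approximates real cluster maps; grid
  labelling by nearest projected location makes central hemi-cluster areas
  extend halfway to the neighbouring ring.
* The Henle displacement curve and density field are shape-correct
  stand-ins, not fitted to histology.
* The percentile method inherits the classic weakness of absolute normative
  comparison: globally thin (or thick) healthy eyes flag everywhere; the
  relative-map features exist precisely to compensate.
* Under the generator's physiology a 40 μm defect barely depresses central
  VF thresholds (counts stay above the breakpoint), so central hemi-cluster
  labels are intrinsically noisy at study-condition depths — an emergent
  property that mirrors clinical reports of late central involvement.
* The cascade's peripheral advantage only expresses itself when peripheral
  structural information is weak relative to central information; on
  high-coupling cohorts both PCA variants saturate and the cascade is
  merely non-inferior.
* Simulated severity saturates: with a 15 μm residual floor, defective GC
  counts cannot fall far below ~20 dB, so thresholds at defective locations
  bottom out around the mid-20s dB and moderate/advanced MD values
  (≤ −6 dB) are underrepresented relative to a clinical population. The
  synthetic cohort is therefore an early-glaucoma-dominated population, and
  Table-2-shaped fits on it produce breakpoints above the clinical range
  (the kink reflects the floor, not the physiological ceiling).
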