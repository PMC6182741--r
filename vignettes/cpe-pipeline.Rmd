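---
title: "Methods: contralateral parenchymal enhancement and IPW survival analysis"
author: "cpemri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contralateral parenchymal enhancement and IPW survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpemri)
```

# The problem

Background parenchymal enhancement — how strongly the healthy
fibroglandular tissue of the breast takes up gadolinium contrast — is a
perfusion measure of the *normal* parenchyma, as opposed to the tumour.
In ER-positive/HER2-negative breast cancer, stronger enhancement of the
breast *contralateral* to the cancer (CPE) has been associated with better
long-term survival, independently of age, grade, receptor status, nodal
load and systemic therapy. `cpemri` packages the two halves of that
analysis: (i) an image-processing chain that turns a five-volume DCE-MRI
acquisition into one unitless CPE number per patient, and (ii) an
observational-causal survival analysis that relates CPE tertiles to
invasive disease-free survival (IDFS) and overall survival (OS) under
confounding.

Because no patient data ship with the package, a synthetic phantom and
cohort generator provides inputs with *known ground truth*; every claim
the test suite makes is a claim about recovering that ground truth.

# The imaging chain

The acquisition model is one non-fat-suppressed T1-weighted volume plus
four fat-suppressed T1-weighted volumes (pre-contrast and three
post-contrast, nominally 120 s apart), all on a common grid with
anisotropic voxels (default 0.7 x 0.7 x 3.0 mm).

**Bias-field correction** (`correctBiasField`). MR coil inhomogeneity is
modelled as a smooth multiplicative field. The estimator alternates
(a) 1-D k-means classification of foreground voxels into `nClasses`
(default 3: here air-adjacent fat, parenchyma/muscle, bright fat) on the
bias-corrected log intensity with deterministic quantile initialisation,
and (b) a least-squares fit of a degree-2 polynomial in the scaled voxel
coordinates to the log-residuals around the class means. Iteration stops
after `maxIter = 8` sweeps or when the log-field changes by less than
1e-6. The exponentiated polynomial is normalised to mean 1 over the
foreground, so corrected intensities keep their scale. Two properties
anchor the design: on a piecewise-constant volume with no bias the
residuals vanish and the estimated field is exactly 1; and a broad
Gaussian bump (the generator's bias model) is captured by the quadratic
to correlation > 0.95 inside the breast. A constant volume short-circuits
to a unit field; non-positive tissue intensities are an error since the
model is multiplicative in the log domain.

**Breast segmentation** (`segmentBreast`). Two-class intensity clustering
separates tissue from air; the chest-wall slab is removed by cutting at
the most anterior posterior-axis row whose cross-section is almost fully
foreground (`slabCoverage = 0.9` — the breasts' elliptical cross-sections
never reach that coverage); in-plane holes are filled (the dark
fibroglandular interior falls below the air/fat threshold); 6-connected
components are labelled and the two largest become the left and right
breast, assigned by centroid along the left-right axis. "Contralateral"
is resolved against the recorded cancer laterality in patient
coordinates. A single cross-midline component is split at the
mid-sagittal plane; an empty foreground raises a segmentation error.

**Parenchyma segmentation** (`segmentParenchyma`). Within the
contralateral breast mask, two-class clustering of the (bias-corrected)
non-fat-suppressed intensities; the darker class is fibroglandular
tissue. The function refuses a mask on the cancer side.

**Erosion** (`erodeInplane`). One in-plane voxel: a 3 x 3 box structuring
element applied slice-wise, never through-slice — with 3 mm slices a 3-D
erosion would be anatomically asymmetric. This trims partial-volume
boundary voxels that would dilute enhancement.

**Registration** (`registerSeries`). Patient motion between time points is
compensated by translation-only registration: Hann-windowed 3-D phase
correlation gives the integer shift, a three-point parabolic fit on the
correlation peak the subvoxel remainder, and trilinear interpolation
resamples each post-contrast volume into the pre-contrast frame.
Estimates below `minShiftVox = 0.2` voxels on every axis are treated as
no motion and skip resampling — this is the estimator's accuracy floor
(~0.15 mm on phantoms) and it makes registration idempotent instead of
accumulating interpolation blur. Estimates above `maxShiftVox`
(default 8, 8, 3 voxels) raise an error rather than silently applying an
implausible transform. An `identity` mode passes pre-aligned data
through. Deformable motion is out of scope: the phantom's ground-truth
motion is rigid, and the package makes no claim about non-rigid
recovery.

# The biomarker

Late enhancement at each eroded-mask voxel is
`E(v) = (S_last(v) - S_first(v)) / S_first(v)`, a unitless ratio, so any
common rescaling of the volumes cancels. Negative values (washout) are
retained — they never reach the top decile and clipping would bias the
distribution. Voxels with non-positive `S_first` are an error by default
(they indicate an upstream mask or registration fault); a documented
`exclude` mode drops them instead.

`computeCpe` averages the `ceiling(0.1 * N)` largest values. The
count-based reading of "top 10%" is deterministic and convention-free for
small masks, where interpolated percentile definitions diverge; the
interpolated 90th percentile is reported alongside for reference. At
least 10 voxels are required.

`assignTertiles` ranks patients by CPE and cuts equal-size groups, the
remainder going to the outer groups with low served first — the unique
rule consistent with a 302-patient cohort splitting 101/100/101. Ties at
a boundary are broken by stable original order, making the assignment
reproducible and permutation-equivariant in distinct values.

# The survival analysis

**Design.** CPE tertiles are an exposure nobody randomised: in the
synthetic cohorts (and plausibly in reality) younger, lower-grade,
node-negative patients have higher CPE, and those covariates also carry
prognosis. Inverse probability weighting targets the marginal
(population-average) hazard ratio: a 3-category multinomial logistic
propensity model `P(tertile | covariates)` with age and diameter entering
through restricted cubic splines (3 knots at the 10th/50th/90th
percentiles; natural cubic splines, linear beyond the boundary knots —
the right default flexibility at a few hundred patients) and grade, PR
status, nodal category, therapy as factors. Weights are stabilised by
the marginal tertile frequencies (so they sum to about n) and winsorised
at their 1st/99th percentiles; both behaviours are arguments. A fitted
probability below 1e-6 is an error naming the patient, not a silent
giant weight.

**Weighted Cox** (`fitWeightedCox`): weighted partial likelihood on the
tertile factor, robust sandwich variance (model-based variance is wrong
under weighting; treating weights as known is slightly conservative),
Wald CIs and p-values, and a trend test from the same model with the
tertile coded ordinally 0/1/2. Unit weights reduce everything exactly to
the unweighted fit. Zero events overall, or in the reference tertile,
are errors — the partial likelihood is degenerate there.

**Multiple imputation** (`imputeMissing`): missingness is confined to the
tumour characteristics (grade, diameter, nodal category). Chained
equations with proper predictive draws: diameter by a Bayesian linear
regression on the log scale (posterior draws of coefficients and
residual variance, prediction with noise), grade and nodes by multinomial
models refitted on bootstrap resamples of the observed rows (the
bootstrap stands in for posterior parameter draws). Predictors include
the outcome indicators and log follow-up time, keeping the imputation
model congenial with the analysis model. Default `m = 20`, 5 sweeps;
`m = 1` is allowed but warned. Per-imputation fits are pooled on the
log-HR scale by Rubin's rules with Barnard-Rubin degrees of freedom;
zero between-imputation variance returns the common fit unchanged.

**Kaplan-Meier** (`weightedKm`): the weighted product-limit estimator is
implemented directly (a dozen vectorised lines) so that the 2,000
patient-level bootstrap resamples per group stay fast; it agrees with
`survival::survfit` to 1e-12 in the tests, which is the package's
cross-check that the hand-rolled estimator is not drifting. Bands are
pointwise percentile intervals; resampling is stratified by tertile; a
`weightFun` argument allows recomputing weights per resample. Survival
at the 120-month horizon is reported per group.

# The synthetic generator

**Phantom** (`generatePhantom`). Geometry: a posterior chest-wall slab,
two anterior half-ellipsoid breasts, and per breast a central parenchyma
blob whose boundary is roughened by six random Gaussian bumps; exactly
`round(fraction x breast voxels)` voxels are parenchyma, so volume
fractions are testable to a voxel. Kinetics are piecewise linear over
the five acquisitions — parenchyma rises by `uptake` (default 0.6) to the
first post-contrast volume and by `late` (default 0.4, the quantity CPE
measures) from first to last; fat and muscle do not enhance. No
pharmacokinetic compartment model is used because the biomarker is a
pure signal ratio. The bias field is a broad multiplicative Gaussian
bump (default amplitude 0.15), motion a per-volume in-plane translation
of `motionMm`, noise additive Gaussian (default SD 10 against a fat
signal of 1000). What the phantom does *not* emulate: partial-volume
fade, Rician noise statistics, coil-array sensitivity patterns,
fat-suppression failure, lesions. Passing phantom tests therefore shows
the chain recovers known structure under idealised contrast — not that
segmentation accuracy transfers to clinical images.

**Cohort** (`generateCohort`). Covariate distributions default to the
validation cohort being emulated: age ~ N(49, 10) (median 48), diameter
log-normal (median 1.3 cm), grade 9/37/54%, PR+ 84%, nodes 55/33/12%,
therapy 4/30/3/63%, menopausal status cut on age, weeks-since-LMP
recorded for 59% of premenopausal patients, ER/PR staining percentages
available in about half. Latent CPE is Normal(0.37, 0.10) — matching the
reported median and IQR — with its mean shifted by standardised
covariates times `confoundingStrength` (default 1). Events come from
independent exponential recurrence and death clocks sharing one linear
predictor (per-tertile log HR plus covariate effects), so hazards are
proportional by construction, IDFS = min(recurrence, death), OS = death,
and OS events are automatically a subset of IDFS events. Censoring is
independent exponential (rate 0.0079/month) capped at the 120-month
administrative horizon. The default low-tertile hazard 0.0025/month with
mortality fraction 0.4 and HRs (1, 0.84, 0.25) reproduces the target
regime: ~13% IDFS events, ~5% deaths, median follow-up near 85 months.
Missingness is injected MCAR (default 4%) into grade/diameter/nodes
only; nothing in the generator creates informative missingness, so the
imputation tests validate the machinery, not MNAR robustness.

# Validation experiments and their sizes

The acceptance suite (and `scripts/acceptance.R`) runs six experiments,
sized to be decisive yet quick:

- *Worked examples*: the 302-patient tertile split (101/100/101) and NPI
  arithmetic (0.2 x diameter + grade + nodal stage; 2.0 cm/grade 2/stage 1
  gives exactly 3.4, not high risk under the strict > 3.4 rule).
- *Oracle equivalence*: 1,000 random enhancement maps (10-2,000 voxels,
  including heavily tied ones) against a brute-force sort-and-mean
  oracle, agreement to 1e-12.
- *Round trip*: a 48 x 48 x 14 noise-free phantom with true late
  enhancement 0.40; the full chain must return CPE = 0.400 +- 0.005.
- *IPW recovery*: 200 cohorts of n = 2,000 with true high-vs-low HR 0.25
  and `confoundingStrength = 3`. That strength was chosen by a power
  argument, not by the data: it biases the crude log HR by about 0.4,
  roughly twice its sampling SE at this n, so "adjusted beats crude" is
  informative; at the generator's default strength the crude bias drowns
  in Monte-Carlo noise and the comparison is a coin flip. The adjusted
  HR median must land in [0.22, 0.28] and beat the crude HR in >= 90% of
  replicates.
- *Trend-test calibration*: 1,000 cohorts of n = 300 under the full null
  (zero log HRs *and* zero confounding — with confounded tertiles and
  prognostic covariates the marginal association is not null, so 0.05
  would be the wrong target), at baseline hazard 0.0017/month to give
  about 37 events per cohort; empirical type-I error must be 0.05 +- 0.02.
- *KM coverage*: 100 replicates of 3 x 100 exponential survivors
  (rate 0.0017/month); the 2,000-resample percentile band at 120 months
  must cover exp(-0.204) with ~95% frequency.

# Known limitations

- The imaging chain assumes bilateral anatomy with an intact
  contralateral breast and rigid inter-timepoint motion; deformable
  registration and atlas-based segmentation are intentionally absent.
- CPE values shift systematically with vendor, field strength and
  protocol; the package provides no cross-institution harmonisation, so
  tertile boundaries must not be pooled naively across scanners.
- PREDICT is consumed as an external per-patient 10-year OS probability
  (`predict_os10` column); its equations are version-dependent and not
  re-implemented.
- The sandwich variance treats estimated weights as known —
  conservative in theory; the calibration experiment shows the trend
  test holding its level at the study's event count.
- The imputation bootstrap-draw scheme for categorical variables is an
  approximation to full posterior draws; with the package's MCAR
  missingness at a few percent the pooled estimates track complete-data
  means well within sampling error.
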