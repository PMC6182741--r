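# cpemri

Background parenchymal enhancement of the disease-free breast, quantified
from pre-treatment dynamic contrast-enhanced (DCE) MRI, stratifies survival
in ER-positive/HER2-negative breast cancer: patients whose contralateral
parenchyma enhances strongly tend to do better, independently of the usual
clinicopathological factors. `cpemri` implements the full analysis pipeline
behind that observation for R users — radiologists' image-processing chain
included — together with a synthetic phantom and cohort generator so every
stage can be exercised and validated without any patient data.

## What it computes

**The biomarker.** For each patient, the breast contralateral to the known
cancer is processed on the non-fat-suppressed T1-weighted volume:
multiplicative bias-field correction, breast segmentation (intensity
clustering, chest-wall cut, connected components), fibroglandular-tissue
segmentation (two-class clustering: fat bright, parenchyma dark), and a
one-voxel in-plane morphological erosion. The four fat-suppressed volumes
(pre-contrast + three post-contrast, 120 s apart) are registered to the
pre-contrast frame. Late enhancement at voxel *v* is

```
E(v) = (S_last(v) - S_first(v)) / S_first(v)
```

with `S_first`, `S_last` the first and last post-contrast signals. The
**contralateral parenchymal enhancement (CPE)** is the mean of the top 10%
of `E(v)` over the eroded parenchyma mask (the `ceiling(N/10)` largest
values; the 90th percentile is reported alongside).

**The survival analysis.** Cohort CPE values are trichotomised into
equal-size tertiles (302 patients split 101/100/101). Confounding by age,
tumour diameter (both as restricted cubic splines), grade, PR status,
axillary nodal category and systemic therapy is removed by inverse
probability weighting: a 3-category multinomial propensity model yields
stabilised, truncated weights `w_i = P(T = t_i) / P(T = t_i | x_i)`. The
weighted Cox model (robust sandwich variance) gives hazard ratios of the
intermediate and high tertiles versus low for invasive disease-free
survival (IDFS) and overall survival (OS) at a 120-month horizon, plus an
ordinal (0/1/2) trend test. Missing tumour characteristics are multiply
imputed (chained equations) and fits pooled by Rubin's rules.
Kaplan-Meier curves per tertile carry pointwise 95% bands from 2,000
patient-level bootstrap resamples. Risk-model subgrouping (Nottingham
Prognostic Index > 3.4, or PREDICT 10-year OS < 85% via an externally
supplied score) re-runs the weighted analysis inside the high-risk
subgroup.

## Worked example

```r
library(cpemri)

report <- runPipeline(list(
  phantom = phantomSpec(gridShape = c(48, 48, 14), seed = 1),
  cohort  = cohortSpec(nPatients = 302, seed = 2),
  m = 5, nBoot = 500, seed = 3))

report$cpe
#> CpeResult: CPE = 0.457 (p90 = 0.443, n = 225 voxels)

report$cox$idfs
#> WeightedCoxFit (IDFS), pooled over 5 imputations
#>   low (reference): 28/101 events
#>   intermediate: HR 0.89 (0.48-1.65), p = 0.719 [21/100 events]
#>   high: HR 0.19 (0.07-0.51), p = 0.00103 [5/101 events]
#>   trend test: p = 0.000284

report$km
#> WeightedKmFit (IDFS), 500 bootstrap resamples
#>   low: S(120 mo) = 0.63 (0.50-0.76)
#>   intermediate: S(120 mo) = 0.69 (0.57-0.81)
#>   high: S(120 mo) = 0.93 (0.86-0.99)
```

The phantom's parenchyma was built with a true late enhancement of 0.40;
the measured CPE of 0.457 reflects the additive noise pushing up the top
decile (the noise-free phantom returns 0.400 exactly). The synthetic
cohort was generated with protective high-CPE hazard ratios (0.25 for
high vs low) plus covariate confounding; the IPW-adjusted fit recovers
the protective effect (HR 0.19, CI 0.07-0.51), and the high-CPE tertile
shows 93% 10-year IDFS versus 63% for low CPE.

Individual stages are exported (`generatePhantom`, `correctBiasField`,
`segmentBreast`, `segmentParenchyma`, `erodeInplane`, `registerSeries`,
`computeEnhancementMap`, `computeCpe`, `assignTertiles`,
`administrativeCensor`, `imputeMissing`, `fitPropensity`,
`computeIpwWeights`, `fitWeightedCox`, `poolFits`, `weightedKm`,
`computeNpi`, `selectHighRisk`, `compareGroups`, `rankCorrelation`,
`menstrualCycleAnalysis`), with NIfTI/CSV readers and writers
(`readDceSeries`, `writeDceSeries`, `writeMask`, `readCohort`,
`writeCohort`) for interoperating with other tools.

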