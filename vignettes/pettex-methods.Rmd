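---
title: "Textural heterogeneity analysis of amyloid PET: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Textural heterogeneity analysis of amyloid PET: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Amyloid-beta deposition measured with amyloid PET tracers (such as
[18F]florbetaben) shows, region by region, essentially no dependence of its
*mean* uptake on the age at which Alzheimer's disease begins. Clinically,
however, early-onset disease (EOAD, onset before 65) runs a more aggressive
course than late-onset disease (LOAD). PETtex implements the hypothesis that
the difference lives not in how much amyloid a region carries but in *how
irregularly* it is laid down: three-dimensional radiomic texture features of
the regional uptake distribution may correlate with onset age even when mean
SUV does not.

The pipeline therefore has four stages:

1. **Atlas-based VOI extraction.** Spatially normalized PET volumes (SUV
   units, one per subject) are masked with an 83-region Hammers-style
   parcellation on the same 2 mm grid; each region's voxels form one volume
   of interest (VOI).
2. **Texture battery.** Within each VOI the SUV range is discretized to 256
   gray levels and rebinned at widths W in {1, 2, 8, 16, 32, 64, 128};
   at each width 93 features are computed: 14 from the gray-level dependence
   matrix (GLDM), 16 from the size-zone matrix (GLSZM), 24 from the
   co-occurrence matrix (GLCM), 5 from the neighborhood gray-tone difference
   matrix (NGTDM), 16 from the run-length matrix (GLRLM), and 18 first-order
   statistics.
3. **Per-region reduction.** For every feature the bin width maximizing the
   absolute Spearman correlation with the AD onset ages is kept (one width
   per feature shared across regions by default — see below — retaining
   93 x 83 = 7719 (feature, region) parameters), each region's feature
   matrix is z-scored and decomposed by PCA, and the smallest number of
   leading components reaching 90% cumulative explained variance
   (N_ind per region) is retained.
4. **Screening and threshold-age scan.** A retained component with scores
   f_i is significant when its Spearman correlation with onset age satisfies
   |rho| > 0.5 and p < 0.05 / N_ind (Bonferroni within the region). For each
   significant component, AD subjects are split at every integer threshold
   age A in 55..75 into onset < A versus onset >= A and compared with a
   two-sided pooled-variance Student's t-test; the significant range is the
   set of A with p < 0.05 / N_ind.

## Quantization and matrix conventions

Several conventions are fixed here once and mirrored exactly by the
brute-force oracles in the test suite:

* **Fixed bin count, then rebinning.** Levels are
  `floor((x - min) / (max - min) * 256)` over the VOI's own range, the
  maximum mapping to level 255 and a constant VOI to level 0; rebinning is
  floor division by W, giving `ceiling(256 / W)` levels. Matrices span the
  full level range of the quantization, and formulas that reference the
  number of gray levels Ng (Idmn, Idn) use that full count.
* **Merged 26-neighborhood.** All families use 26-connectivity. Counts are
  summed over the 13 unique direction offsets into a single matrix per
  family rather than averaged per angle; the GLCM is symmetrized. Zones
  (GLSZM) are 26-connected components; runs (GLRLM) are maximal collinear
  segments per direction, merged, so run lengths weighted by counts sum to
  13 x nVoxels and RunPercentage is normalized by `nVoxels * 13` to stay in
  (0, 1].
* **Gray values are 1-based.** Intensity-weighted formulas
  (HighGrayLevelEmphasis, NGTDM Busyness, ...) use level + 1, so the lowest
  level carries weight 1, never 0.
* **Degenerate inputs.** `0 log 0 = 0` everywhere; ratios with vanishing
  denominators (GLCM Correlation and Imc1, first-order Skewness and
  Kurtosis at zero variance, NGTDM Busyness and Strength) are defined as 0;
  NGTDM Coarseness of a perfectly flat region is capped at 1e6; the GLCM of
  a single-voxel VOI (no neighbor pairs) yields all-zero features; MCC of a
  single-level VOI is 1. These constants make every one of the 93 features
  finite on every non-empty VOI, which the extraction layer asserts.
* **First-order features** are statistics of the raw SUV values
  (percentiles by linear interpolation, population variance, kurtosis not
  excess-corrected), except Entropy and Uniformity, which are histogram
  statistics of the quantized levels at the vector's own bin width.
  TotalEnergy multiplies Energy by the voxel volume in cubic mm.
* **Feature 80.** The canonical 18-name first-order battery this package
  reproduces lists Entropy twice where the otherwise-standard set has the
  interquartile range; PETtex computes the interquartile range as feature
  80 by default and offers `duplicateEntropy = TRUE` to reproduce the
  listed battery verbatim — the duplicate is a redundant column that the
  PCA stage would otherwise carry with double weight.

## Statistical choices

* **Spearman p-values** use the t approximation
  `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 degrees of freedom and
  average ranks for ties; `p = 0` at `|rho| = 1`. The test suite
  cross-checks the rho estimate against `cor.test`.
* **Bin-width selection** maximizes |rho| against the AD onset ages; exact
  ties and constant feature vectors (|rho| defined as 0) resolve to the
  smallest width, keeping the choice deterministic. Because selection is
  rank-based it is invariant to monotone transforms of the age variable.
  The pipeline's default selects **one width per feature, shared across
  regions**, by maximizing the mean |rho| over regions
  (`selectCohortWidths()`): a single interpretable selection per feature
  — the form in which optimal widths are conventionally reported — that,
  more importantly, keeps the downstream screen calibrated. Selecting a width independently within every region
  (`widthSelection = "region"`, also available) uses the same onset ages
  twice — once to pick the most age-correlated of seven width variants per
  feature, once to screen the components — and that double dipping injects
  a common age-aligned direction into all 93 selected features of a
  region; the PCA concentrates it into a component that clears the
  |rho| > 0.5 Bonferroni gate in roughly a third of *null* phantom studies.
  Sharing the selection across R regions dilutes each region's
  contribution to the choice by 1/R and restores the null behavior, while
  regions carrying real signal still dominate the average and keep the
  selection sensitive.
* **Z-scoring before PCA** uses population (divide-by-n) normalization;
  zero-variance features are dropped with a log entry rather than imputed.
  Whether the original analysis standardized features is not stated in the
  literature this package follows; without standardization the battery's
  wildly different feature scales (TotalEnergy versus Idn, say) would let a
  handful of features dominate every component, so standardization is the
  package's choice.
* **PCA** is an eigendecomposition of the resulting correlation matrix;
  component signs are fixed by making each component's largest-magnitude
  loading positive. N_ind is the smallest k whose cumulative explained
  variance reaches the 90% threshold (strictly: at N_ind - 1 it is below).
  With n subjects and p > n features the spectrum has at most n - 1 nonzero
  eigenvalues; the rule operates on the normalized spectrum either way.
* **Bonferroni correction is per region only** (0.05 / N_ind within each
  region), exactly as the method prescribes; no correction is applied
  across the 83 regions, and the package reproduces that choice rather than
  "fixing" it. The mean-SUV null check, which runs one test per region,
  instead divides by the number of regions tested.
* **The threshold-age scan** uses the pooled-variance Student's t-test
  (a `welch = TRUE` switch selects the unequal-variance form), groups
  defined as onset < A versus onset >= A, and requires at least two
  subjects per group for a defined test; undefined ages stay NA and the
  scan continues. Degenerate zero-pooled-variance splits give p = 1 when
  the means agree and p = 0 otherwise.
* **Top features of a component** are those with loading magnitude within
  90% of the component's largest, reported as `family_Name` identifiers.

## The synthetic phantom cohort

Real amyloid PET volumes cannot ship with the package, so every stage is
exercised on a synthetic testbed designed to have exactly the statistical
structure the analysis assumes:

* **Atlas.** An ellipsoidal brain mask (semi-axes 90% of the half-grid) on
  the standard 91 x 109 x 91 grid of 2 mm voxels is partitioned into 83
  contiguous regions by nearest-seed growth: random interior seeds relaxed
  by a few Lloyd iterations, then Voronoi assignment. Voronoi cells of
  points are convex, hence connected. The real Hammers N30R83 geometry is
  deliberately not emulated (and the licensed atlas is not distributed);
  only the label count and the label-to-name map are shared, so region 8 of
  the phantom is "left anterior temporal lobe, lateral part" in name only.
* **Volumes.** Every in-mask voxel draws `baseSuv + N(0, noiseSd^2)`
  (defaults 1.4 and 0.1 SUV — plausible cortical florbetaben magnitudes,
  chosen once as phantom calibration knobs, not literature values). For AD
  subjects, each designated signal region adds a spatially clustered
  perturbation: Gaussian blobs of alternating sign, widths 1.5-3 voxels,
  centered at random region voxels, rescaled to standard deviation
  `max(0, intercept + slope * (65 - onset age))` and recentered to exactly
  zero mean over the region. Mean uptake therefore carries no onset-age
  signal — the property the analysis must reproduce as a null — while the
  *texture* of earlier-onset subjects is progressively more heterogeneous.
  The recentering removes the perturbation's mean contribution but leaves
  the background noise in place, so region means stay stochastic and rank
  correlations against them remain well defined.
* **Changepoint structure.** With the default intercept of 0 the amplitude
  is positive only below onset 65: a ramp anchored at the clinical
  EOAD/LOAD boundary, which gives the threshold-age scan a true
  changepoint to find.
* **Calibration.** The default `heterogeneitySlope = 0.007` SUV/year was
  fixed by a one-off calibration experiment: simulate the 43-AD-subject
  phantom study, run the full pipeline, and choose the slope at which the
  leading planted component's correlation with onset age lands near
  |rho| = 0.6 (the observed median is about 0.65 across seeds) — strong
  enough to be recovered reliably, weak enough that recovery is a
  statistical question rather than a foregone conclusion.
* **Reproducibility.** Subject volumes are seeded by a hash of the global
  seed and the subject id, so a subject's volume does not change when the
  cohort around it grows, and two runs of `simulateCohort()` with one
  configuration are byte-identical.
* **What the phantom does not emulate:** radiotracer kinetics, scanner
  point-spread, partial-volume effects, anatomical asymmetry, registration
  error, or any MRI channel. Passing tests demonstrate that the pipeline's
  statistics behave as designed on data with known truth; they say nothing
  about effect sizes in real cohorts.

## Problem sizes in the test suite

The automated tests run the complete pipeline repeatedly, so they use
deliberately compact study geometries: the oracle comparisons use 200
random VOIs of at most 5^3 voxels; the 83-region battery checks run five
subjects on a 48 x 56 x 48 grid (about 600 voxels per region); the
null-calibration and signal-recovery studies run twenty seeded phantom
studies of 43 AD subjects each, with eight regions of roughly a thousand
2 mm voxels on a 28^3 grid. These sizes keep region VOIs large enough for
stable texture estimates while letting forty end-to-end studies run in a
test session; the acceptance script uses the full default grid.

## Known limitations

* Reslicing of atlases is nearest-neighbor through the two affines;
  estimating a registration is out of scope, and volumes whose grid differs
  from the atlas are rejected rather than silently resampled.
* The Spearman p-value is the t approximation also at small n, where exact
  permutation tails differ; the method's thresholds were formulated for the
  approximation.
* With more features than subjects the PCA spectrum is rank-deficient; the
  90% rule then counts components of a (n - 1)-dimensional spectrum, which
  is the regime both the reference analysis and the phantom studies
  operate in.
* The per-region Bonferroni correction leaves the cross-region family-wise
  error uncontrolled by design fidelity; interpret multi-region summaries
  accordingly.
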