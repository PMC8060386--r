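# PETtex

Textural heterogeneity analysis of amyloid brain PET.

Amyloid-beta deposition, measured with tracers such as [18F]florbetaben,
shows no regional *mean*-uptake dependence on the age at which Alzheimer's
disease begins — yet early-onset disease (EOAD, onset < 65 years) behaves
clinically very differently from late-onset disease (LOAD). PETtex is for
neuroimaging researchers who want to ask whether the *spatial texture* of
amyloid deposition carries the onset-age signal the mean does not: it
implements an atlas-based 3D radiomics pipeline over 83 brain regions and
the statistics to screen texture-derived principal components against onset
age.

## The method

For each subject's spatially normalized PET volume (SUV units) and each
region r of an 83-label parcellation:

1. The region's voxels are discretized to 256 gray levels over their own
   intensity range and rebinned at widths W in {1, 2, 8, 16, 32, 64, 128}.
2. At each width, 93 texture features are computed from five 26-connected
   matrix families — GLCM (24), GLDM (14), GLRLM (16), GLSZM (16),
   NGTDM (5) — plus 18 first-order statistics.
3. Per (feature, region), the bin width W* maximizing the absolute
   Spearman correlation |rho| with the AD onset ages is retained, giving
   93 x 83 = 7719 parameters.
4. Per region, the retained features are z-scored and reduced by PCA; the
   smallest number of components N_ind^r reaching 90% cumulative explained
   variance is kept. A component f_i^r is *significant* when
   |rho(f_i^r, onset age)| > 0.5 with p < 0.05 / N_ind^r (Spearman,
   Bonferroni within region).
5. For each significant component, subjects are split at every threshold
   age A in 55..75 into onset < A versus onset >= A and compared with a
   two-sided pooled Student's t-test; the range of A with
   p < 0.05 / N_ind^r localizes where EOAD and LOAD separate.

Alongside, regional mean SUV and SUVR (amygdala reference) are tested
against onset age — the expected null — and control subjects are projected
onto the AD-derived components as a background reference.

Because patient volumes cannot ship with a package, PETtex includes a
synthetic cohort generator (`simulateCohort()`): a Hammers-like 83-region
ellipsoidal phantom and per-subject volumes in which designated regions
carry spatially clustered, exactly mean-free perturbations whose amplitude
grows with earlier onset. Mean uptake stays uninformative by construction;
only texture carries the planted signal. See the methods vignette
(`vignettes/pettex-methods.Rmd`) for every convention and calibration.

## Worked example

A complete toy study — simulate, analyze, inspect — in a few lines:

```r
library(PETtex)

cfg <- synthConfig(gridShape = c(28L, 28L, 28L), nRegions = 8L,
                   nAd = 43L, nControl = 5L, signalRegions = 1:4,
                   seed = 7L)
dir <- tempfile("study")
cohort <- simulateCohort(cfg, dir)
res <- runPipeline(cohort, readAtlas(file.path(dir, "atlas.nii")), seed = 7L)
res
#> TextureAnalysis
#>   feature table: 249984 rows
#>   regions analyzed: 8
#>   components retained: 63, significant: 4
#>   seed: 7, config hash: 412f28cd

subset(res@components, significant,
       select = c(region, component, explainedVar, rho, p))
#>    region component explainedVar        rho            p
#> 1       1         0    0.4644340  0.6799336 5.312170e-07
#> 8       2         0    0.4790587 -0.7600635 3.390398e-09
#> 15      3         0    0.5110572 -0.7733555 1.210205e-09
#> 22      4         0    0.4808529  0.7453365 9.854566e-09
```

Heterogeneity was planted in regions 1-4 of the phantom with an amplitude
ramp below onset age 65, and exactly those four regions are flagged through
their leading component, which explains 46-51% of the region's feature
variance and correlates strongly with onset age (the sign convention fixes
only the loadings, so the score-age correlation may carry either sign).
The threshold-age scan (`res@scans`) marks ages 57-71 as the separation
range, containing the planted changepoint at 65, and `res@suvStats` flags
no region whose mean SUV correlates with onset age — the structural null
the method requires.

The same stages run from the shell through `exec/pettex`
(`simulate | extract | analyze | report`, file-based, `--config`/`--seed`
flags; config keys are the `synthConfig()`/`runPipeline()` arguments in
snake_case, e.g. `grid_shape = 28,28,28`, `rho_threshold = 0.5`).

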