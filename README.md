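# dscnorm

Reference-region normalization analysis for DSC-MRI cerebral blood flow.

## The problem

Cerebral blood flow (CBF) maps from dynamic susceptibility contrast
(DSC) MRI are relative: every subject carries an unknown multiplicative
scale, and across elderly cohorts the resulting inter-subject coefficient
of variation (CV) reaches 40–50% — far above the 10–20% regional effects
of early neurodegeneration. Analyses therefore divide regional values by
the mean of a *reference region* (cerebellum, whole-brain white matter,
or whole-brain cortical gray matter, cGM) before comparing groups. The
choice of reference changes the residual noise and can change which
group differences reach significance. `dscnorm` is a toolkit for
studying that dependence end to end, for neuroimaging methodologists and
statisticians: it implements the CBF quantification chain, the ROI
normalization machinery, the group-level statistics, and a synthetic
phantom generator with known ground truth that stands in for clinical
cohorts.

## The core model

Quantification (`computeCBFMap()`): per voxel, the baseline
S<sub>0</sub> is the mean of the six pre-bolus frames; concentration is
C(t) = −(k/TE)·ln(S(t)/S<sub>0</sub>); the first pass is denoised with a
gamma-variate fit C(t) = K(t−t₀)^α e^{−(t−t₀)/β} by a weighted
linearization; the arterial input function (AIF) is detected
automatically from voxels jointly in the lowest arrival decile, highest
peak decile and lowest FWHM decile; and CBF is the maximum of the residue
function obtained by truncated-SVD deconvolution of the Toeplitz system
C<sub>m</sub> = CBF·(AIF ⊛ R).

Statistics (`compareAll()`): per region and normalization, one-way
ANOVA, Dunnett's many-to-one comparisons against controls (k-variate t
with pooled MSE), Cohen's d, pooled CVs, and a two-way random-effects
variance-components decomposition separating the diagnosis-group from
the normalization-method contribution.

Phantoms (`generateCohort()`): block-layout label volumes with ten
cortical lobe regions, white matter, cerebellum and a small artery;
lognormal global (CV 45%) and regional (CV 6%) inter-subject factors;
group effects of −15% (AD, parietal) and +12% (AD, right medial
temporal); full forward signal synthesis through the same equations the
quantifier inverts.

## Worked example

Simulate a study-sized cohort at the ROI level, normalize by the three
references, and compare groups:

```r
library(dscnorm)

spec <- cohortSpec(seed = 99L)           # 20 controls / 15 MCI / 28 AD
tab  <- simulateCohortValues(spec)       # absolute ROITable
tabs <- list(absolute = tab,
             cer = normalizeTable(tab, "cer"),
             wm  = normalizeTable(tab, "wm"),
             cgm = normalizeTable(tab, "cgm"))
rep <- compareAll(tabs)
rep$cv_table
#>               lobe cv_absolute    cv_cer     cv_wm   cv_cgm
#> 1          frontal    45.05852  6.796212  7.044978 3.799044
#> 2         parietal    44.42776 11.896300 12.152137 8.662415
#> 3 temporal_lateral    43.76694  6.282890  6.938784 3.625951
#> 4  temporal_medial    44.19434  7.489134  7.431449 5.521125
#> 5        occipital    43.05970  6.893366  6.541084 3.319669
```

Absolute CBF varies by ~44% across subjects; after normalization the CV
drops to single digits, with the cGM reference lowest — the parietal row
stays higher because the simulated AD hypoperfusion widens the pooled
spread. The same report contains the per-region Dunnett comparisons:

```r
subset(rep$group_comparisons, normalization == "cgm" &
       region %in% c("parietal_rh", "temporal_medial_rh"),
       c(region, anova_p, dunnett_p_AD, cohens_d_AD))
#>                region      anova_p dunnett_p_AD cohens_d_AD
#> 37        parietal_rh 5.709764e-13 1.593614e-11   -2.481928
#> 39 temporal_medial_rh 1.149324e-14 1.652589e-11    2.419031
```

AD shows parietal hypoperfusion (negative d) and right-medial-temporal
relative hyperperfusion (positive d) after cGM normalization, as encoded
in the generator.

The full image-level pipeline (simulate → quantify → extract → normalize
→ compare) runs from one config:

```r
runPipeline(makeFixtures("tiny"), "out/tiny-run")
```

or from the shell via `inst/scripts/dscnorm run-all --config cfg.yaml
--out DIR`.

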