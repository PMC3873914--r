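---
title: "Reference-region normalization of DSC-MRI CBF maps: models and methods"
author: "dscnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-region normalization of DSC-MRI CBF maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscnorm)
```

## The problem

Cerebral blood flow (CBF) maps from dynamic susceptibility contrast (DSC)
MRI are quantitative only up to a subject-specific scale: the
proportionality between the transverse relaxation change and gadolinium
concentration, the partial-volume contamination of the arterial input
function, and physiological state all multiply into a per-subject global
factor. Across elderly cohorts this produces inter-subject coefficients of
variation (CV) around 40–50%, which swamps disease effects of 10–20%.
The standard remedy divides every regional value by the mean of a
*reference region* assumed disease-unbiased — cerebellum, whole-brain
white matter (WM), or whole-brain cortical gray matter (cGM). Because the
choice of reference changes both the residual noise and (when the
reference itself is affected by disease) the apparent direction of
effects, a group-comparison result can depend on it. This package
implements the full analysis chain needed to study that dependence, with a
synthetic phantom generator standing in for clinical cohorts whose raw
data are unavailable.

## Signal model and quantification chain

The acquisition follows a bolus-tracking echo-planar protocol with
TR = 1.439 s, TE = 30 ms, 40 dynamic frames, the first 6 pre-bolus
(`acquisitionParams()`). The chain implemented in `computeCBFMap()` is:

1. **Baseline**: $S_0$ is the mean of the first 6 frames
   (`estimateBaseline()`); a nonpositive baseline frame invalidates the
   voxel rather than zero-filling it.
2. **Concentration**: $C(t) = -(k/TE)\,\ln(S(t)/S_0)$
   (`signalToConcentration()`), with $k$ fixed to 1 so all flows are in
   relative units; negative concentrations (noise pushing $S > S_0$) are
   clipped to 0 before fitting. Because the conversion is a log-ratio
   against the voxel's own baseline, the resulting map is exactly
   invariant to global rescaling of the raw signal.
3. **Gamma-variate denoising** (`fitGammaVariate()`): the first pass of
   each voxel's bolus curve is fitted with
   $C(t) = K (t-t_0)^{\alpha} e^{-(t-t_0)/\beta}$ by the linearization
   $\ln C = \ln K + \alpha \ln(t-t_0) - (t-t_0)/\beta$, solved by weighted
   linear least squares for each candidate $t_0$ on the frame grid
   strictly before the peak; the candidate with the smallest weighted
   residual sum of squares wins. The weights are $C^2$, which makes the
   log-domain objective approximate the linear-domain one; without them
   the log transform amplifies noise at small concentrations enough to
   bias the fitted curve substantially at realistic tissue SNR. The
   first-pass window runs from the first frame above 10% of peak to the
   last frame before the post-peak curve falls below 30% of peak, which
   excludes recirculation. Grid-restricted $t_0$ keeps the fit exactly
   linear and deterministic; a noiseless gamma-variate whose arrival lies
   on the grid is recovered exactly.
4. **AIF detection** (`detectAIF()`): among voxels with successful fits,
   candidates must lie jointly in the lowest decile of fitted arrival
   time, the highest decile of fitted peak, and the lowest decile of
   fitted FWHM — arterial curves arrive early, are tall, and are narrow.
   The 10 candidates with the highest peaks are averaged (as fitted
   curves) into the AIF. Two robustness measures matter on small volumes:
   voxels whose fitted peak is below a quarter of the largest plausible
   fitted peak are excluded from the quantile computation (low-signal
   voxels produce unstable fits whose spurious early arrivals would
   otherwise crowd the arrival decile), and if the joint decile criteria
   intersect in no voxel the quantiles are relaxed stepwise (factor 1.5,
   capped at the half-mass point). Realistic volumes resolve at the first
   step, and final selectivity rests on the top-peak ranking either way.
5. **Deconvolution** (`deconvolve()`): the tissue curve satisfies
   $C_m = \mathrm{CBF}\,(AIF \circledast R)$ with residue function
   $R(0)=1$, nonincreasing. On the frame grid this is a lower-triangular
   Toeplitz system $A x = C_m$ with $A_{ij} = TR \cdot AIF(t_{i-j})$,
   solved by truncated SVD with singular values below $0.05\,\sigma_1$
   zeroed (the threshold is exposed as `regThreshold`). CBF is the
   maximum of $x$.

By default the *fitted* tissue curves are deconvolved
(`gammaDenoise = TRUE`); the raw curves are available via
`gammaDenoise = FALSE`. Denoised deconvolution carries a known
multiplicative bias (the gamma fit truncates the residue tail, narrowing
the tissue curve), but the bias is shared across regions of equal
kinetics, so region *ratios* — which is what normalized analyses consume —
are recovered accurately: the package's tests verify a 2:1 two-region
ratio to 5% noiseless and 15% at 1% signal noise. Tissue bolus delay is
also tolerated for positive delays, which shift the deconvolved residue
without changing its maximum appreciably.

## The phantom generator

`generateCohort()` / `generateSubject()` synthesize cohorts with known
ground truth. The geometry is a parameterized block layout (default
32×32×8 voxels; the test fixtures use 8×8×4) with one rectangular block
per region: five cortical lobes per hemisphere (frontal, parietal,
lateral temporal, medial temporal, occipital), whole-brain WM,
cerebellum, and a feeding artery restricted to a 2×2 in-plane core,
reflecting that arterial voxels are rare relative to tissue. Ground-truth
CBF sits on the relative scale of uncalibrated DSC maps: cortical lobes
near 0.11, cerebellum 0.30, WM 0.07; MTT is 4 s for gray matter and
cerebellum, 6 s for WM, with exponential residue functions; tissue bolus
arrival lags the artery by 2 s.

Inter-subject variability is multiplicative and lognormal, which
guarantees positivity and matches the ratio logic of normalization:

* a **global factor** per subject with CV 45% (the defaults are the study
  conditions: intra-group CBF variability around 40% in controls and 50%
  in patients);
* independent **regional factors** with CV 6%, representing genuine
  regional physiology that no global normalization can remove;
* Gaussian **voxel noise** with SD 1% of the baseline signal.

Group structure follows a three-group design of 20 controls, 15 MCI and
28 AD subjects. AD carries regional effects of −15% in both parietal
lobes (hypoperfusion) and +12% in the right medial temporal lobe
(relative hyperperfusion); MCI carries none. Ages are normal(73, 7)
truncated at 60 and feed only the ANCOVA stage. Per-subject seeds are
derived deterministically from the cohort seed, so identical
specifications reproduce bit-identical cohorts.

`simulateCohortValues()` is the ROI-level fast path: it draws exactly the
same per-subject factors as the voxel generator (same RNG stream) but
skips image synthesis, returning ground-truth region means directly.
Statistical properties of the cohort design (CV reductions, detection
rates, type-I error) are studied on this path at hundreds to thousands of
cohorts; imaging properties run the full voxel chain on single subjects
or tiny cohorts. The methods tests use 100 cohorts for CV bands, 200 for
detection rates, and 1000 for the null error rate — sizes at which the
Monte Carlo error of the assessed rates is a few percent of their value.

What the phantom does **not** emulate: anatomy (blocks, not brains),
motion and susceptibility artifacts, recirculation beyond the first pass,
partial-volume mixtures at region borders, and any absolute flow
calibration. Passing tests therefore demonstrate the correctness of the
quantification and statistical machinery under the stated variability
model, not clinical performance on real data.

## ROI extraction and normalization

`extractROITable()` computes per-label means over valid voxels (invalid
voxels are excluded, not zero-filled), aggregates cortical gyri to
per-hemisphere lobes by voxel-count weighting (identical to a direct mean
over lobe voxels, which the tests verify to 1e−12), and pools WM and
cerebellum labels. `referenceValue()` builds the three candidate
denominators:

* `cer` — cerebellum mean;
* `wm` — whole-brain WM mean;
* `cgm` — whole-brain cortical gray matter, computed as the *unweighted*
  average of the lobe means (hemispheres averaged within each lobe
  first). This follows the literal definition of averaging "perfusion
  data for every lobe"; a voxel-weighted variant is available via
  `cgmWeighting = "voxel"`.

`normalizeTable()` divides every region by the subject's reference and
drops (with a message) subjects whose reference is missing or zero.
Normalized values are exactly invariant to per-subject global rescaling.

## Group statistics

`compareAll()` reproduces the study's statistical framework on one
cohort:

* **Reference-region bias check** — per-group mean, SD and CV of each
  candidate reference value, with a one-way ANOVA across groups: a biased
  reference would manufacture spurious effects after normalization.
* **Group comparisons** — per region and normalization: one-way ANOVA,
  Dunnett's many-to-one comparisons of each patient group against
  controls, and Cohen's d with the convention
  $d = (\bar y_{patient} - \bar y_{control})/s_{pooled}$ (negative =
  hypoperfusion relative to controls). Dunnett's adjusted p values use
  the k-variate t distribution with correlations
  $\rho_{ij} = \sqrt{n_i n_j / ((n_i+n_0)(n_j+n_0))}$ and the MSE pooled
  over all groups, evaluated by deterministic (seeded) quadrature; the
  implementation agrees with `multcomp` to three decimals and with a
  $10^6$-draw Monte Carlo calibration to ±0.005 at the 5% level.
  Comparisons are two-sided, since both signs of effect are of interest.
  p values are reported exactly for every region; following the source
  framework, no correction is applied across regions beyond Dunnett's
  within-region family, and that choice is deliberate — the object of
  study is the sensitivity of each regional comparison to the reference
  choice, not a whole-brain discovery procedure.
* **CV table** — pooled CV per bilateral lobe (hemispheres averaged
  within subject, then all subjects of all groups pooled) for the
  absolute values and each normalization.
* **Variance components** — per region, a two-way random-effects
  decomposition of the normalized values into diagnosis-group,
  normalization-method and residual variance
  (`varianceComponents()`), by method of moments from the expected mean
  squares, negative estimates truncated to 0. The normalization factor
  spans the three normalized variants (cer/wm/cgm) — their scale
  differences (typical normalized means near 0.4, 1.6 and 1.0) are
  exactly what makes this component dominate when normalization works.
  The layout is crossed (every subject under every normalization) and
  unbalanced in diagnosis; EMS coefficients use the standard unbalanced
  one-way form $c = (M - \sum m_i^2/M)/(a-1)$. The model is additive by
  default; an interaction component is available via
  `interaction = TRUE`. These were open design choices: factors are
  treated as random (components-of-variance language), and the additive
  default reflects that the diagnosis-by-normalization interaction is
  exactly the quantity under study in the comparison tables, not a
  nuisance to absorb.

`ancovaVolume()` covers the volumetric side analysis: a linear model
`volume ~ group + age`, the group effect tested by extra sum of squares,
and Dunnett-type comparisons of age-adjusted means using the model's
coefficient covariance. With a constant age covariate it falls back to
plain one-way ANOVA with a warning.

## Numerical choices and degenerate inputs

* Dunnett probabilities use Genz–Bretz quadrature with absolute error
  1e−5 under a fixed local RNG state, so repeated runs are bit-identical
  without disturbing the caller's random stream.
* The gamma fit requires at least 4 usable points and rejects
  $\alpha \le 0$ or $\beta \le 0$; all-zero curves, absent bolus, and
  voxels with nonpositive baselines are flagged, and flagged voxels are
  excluded from ROI means.
* An all-zero AIF, an empty candidate set after relaxation, and a cohort
  mismatch between tables are hard errors with typed conditions.
* Constant data yield zero variance components with all-zero proportions
  rather than NaN; zero pooled SD or zero mean yield `NA` effect
  size / CV with a warning.
* AIF selection ties are broken by higher peak, then lower voxel index,
  keeping the result deterministic.

## Pipeline and reproducibility

`runPipeline()` executes simulate → quantify → extract → normalize →
compare from one YAML-serializable configuration, writing per-subject
NIfTI volumes, ROI TSV tables, the four report TSVs, JSON run metadata
and an MD5 manifest. A single seed fans out to per-subject seeds through
a fixed affine scheme, and every stochastic step (including quadrature)
is seeded, so identical configurations reproduce byte-identical outputs.
`makeFixtures("tiny")` (3 subjects per group, 8×8×4 voxels) runs end to
end in well under a minute and shares its schema with the study-sized
default.

## Known limitations

* Absolute CBF units are deliberately out of reach ($k = 1$): the study
  design only consumes relative and normalized values.
* The denoised deconvolution inflates absolute CBF by a
  kinetics-dependent factor; analyses must stay within equal-kinetics
  comparisons or normalized values (as here).
* The variance-components EMS coefficients are exact for the balanced
  crossed layout and a standard approximation under the mild group-size
  imbalance used here.
* Delay correction, block-circulant deconvolution, CBV/MTT maps and
  partial-volume handling are out of scope.
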