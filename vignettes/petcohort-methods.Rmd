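---
title: "Models and methods behind petcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind petcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcohort)
```

## What the package models

petcohort re-implements, as a tested and reusable pipeline, the
quantification-and-inference chain of a dual-tracer PET study of cognitive
aging: regional kinetic modeling of a reversible dopamine-transporter (DAT)
ligand and an irreversible MAO-B ligand, composite scoring of brain and
cognitive measures, and the cohort-level correlational and
hierarchical-regression statistics. Because the human data behind such
studies are not shareable, the package ships a synthetic-cohort generator
whose structure is calibrated so that the full pipeline — simulate, fit,
score, analyze — reproduces the published desk-scale quantities. Everything
downstream of image processing is covered; image reconstruction,
segmentation and lesion mapping are out of scope and the pipeline starts
from regional time-activity curves (TACs) and per-subject scalars.

## Kinetic models

Both estimators are reference-tissue methods: the cerebellum stands in for
arterial blood sampling.

**Reversible tracer (DAT ligand).** The simplified reference tissue model
(SRTM) gives the forward solution

$$C_T(t) = R_1 C_R(t) + \left(k_2 - R_1 k_{2a}\right)\,
  \left[C_R \otimes e^{-k_{2a} t}\right](t), \qquad
  k_{2a} = \frac{k_2}{1 + BP_{ND}},$$

where $R_1$ is the delivery ratio, $k_2$ the reference efflux constant
(1/min) and $BP_{ND}$ the non-displaceable binding potential. Estimation
uses the multilinear reference tissue model (MRTM): ordinary least squares
over *all* frames of

$$C_T(T) = \beta_1 \int_0^T C_R + \beta_2 \int_0^T C_T + \beta_3 C_R(T),
\qquad BP_{ND} = -\beta_1/\beta_2 - 1.$$

For SRTM data the identification is exact ($\beta_1 = k_2$,
$\beta_2 = -k_{2a}$, $\beta_3 = R_1$). The three-parameter MRTM is
implemented (not the two-parameter variant with a fixed reference $k_2'$):
the source study names the multilinear model without specifying the
variant, and the three-parameter form is the one that needs no external
constant. Singular designs (e.g. a target proportional to the reference)
raise errors; a silently pseudo-inverted fit would contaminate cohort
summaries unnoticed.

**Irreversible tracer (MAO-B ligand).** Reference-Patlak with an
exponential reference-kinetics correction: the plotted reference is
$C_{ref}(t) = C_{cer}(t)\, e^{-\bar\lambda t}$ with $\bar\lambda =
0.04\,\mathrm{min}^{-1}$ (this corrects the reference region's own slow
irreversible uptake; it is *not* isotope decay — TACs are decay-corrected
throughout, and `decay_remaining_fraction()` is a separate utility). Over
the steady-state frame window (frames 4–26 of the 26-frame schedule,
1-based inclusive) the package regresses

$$\frac{C_T(t)}{C_{ref}(t)} \;=\; K_i\,
  \frac{\int_0^t C_{ref}(u)\,du}{C_{ref}(t)} + V_0,$$

so the slope is $K_i^{ref}$ (1/min) and the estimate is invariant under
joint rescaling of the two curves. The normalized form uses the corrected
reference on both axes; whether the original analysis did so on the x-axis
is not documented, and the standard normalized form was chosen.

**Time units and quadrature.** Schedules are stored in seconds (both
printed acquisitions: 26 frames of 9×20 + 6×60 + 5×120 + 6×360 s, and 18
frames of 9×120 + 3×180 + 3×260 + 3×300 s; each 55 min) and converted to
minutes exactly once. Frame activities are frame *averages*, so the
integral of a TAC over a whole frame is exactly activity × duration; the
fitters therefore use a cumulative frame-integral (all previous frames plus
half the current one) rather than trapezoids over midpoints. On the
18-frame schedule, whose earliest frames are 2 min long, midpoint
trapezoids leave a 1.2–1.4% bias in the recovered $BP_{ND}$; the frame
scheme keeps all noise-free round trips within 0.4% (the contract tested is
1%). The trapezoid variant remains available in `running_integral()`.

**Analytic simulation.** The reference family is a two-exponential
difference $C_R(t) = A(e^{-\lambda_1 t} - e^{-\lambda_2 t})$. That family
is closed under everything the forward models need — convolution with an
exponential, running integration, multiplication by $e^{\pm\bar\lambda t}$
— so simulated curves are represented as sums of exponentials and per-frame
averages are computed by exact integration instead of grid convolution.
The emitted cerebellum curve of the irreversible simulator is
$C_{ref}(t)e^{+\bar\lambda t}$, so the estimator's correction inverts it
exactly; fitting without the correction biases the slope by >10%, which is
kept as a regression test that the correction is live. If $k_{2a}$
coincides with a reference rate constant the convolution is degenerate
($t e^{-at}$); rather than extend the representation with polynomial terms
the rate is nudged by $10^{-7}$/min, perturbing the curve by under
$10^{-5}$ of its value across a 55-min scan.

**Noise model.** Framewise zero-mean Gaussian noise with
$SD_j = s\sqrt{C_j/\Delta t_j}$, the standard count-statistics
approximation for decay-corrected data. The source study states no noise
level; the default $s = 0.15$ yields 1–3% noise on late frames, typical of
ROI-averaged (not voxel) TACs over large regions. At that level, kinetic
fit error is negligible against between-subject spread for $BP_{ND}$
(~0.5% vs 23%) and small for $K_i$ (~2% vs 10%), so measured correlations
are attenuated by well under the 0.03 acceptance tolerance.

## The synthetic cohort: a stated world

Constructs {age, sex, BMI, DAT, MAO-B, lesion burden, cognition} are drawn
from a multivariate normal. The default target correlations are the
published ones: age correlations (DAT −0.20, MAO-B 0.36, lesions 0.42,
cognition −0.50), age-adjusted partials among the brain/cognition
constructs (DAT–MAO-B 0.53, DAT–lesions −0.39, MAO-B–lesions −0.33,
DAT–cognition 0.42) converted to zero-order values in closed form, sex
effects converted from the reported t statistics (men higher on the DAT
composite), and BMI associations (−0.53 with DAT, −0.43 with MAO-B).

Those published values are *observed-scale*: they concern the DAT
z-composite of two correlated regions (caudate–putamen correlation 0.78),
the first-principal-component factor of three MAO-B regions
(inter-regional correlation 0.67 — exactly the structure whose PC1
explains 78% of variance with leading eigenvalue 2.3), a median-split
binary sex, and a nine-test cognitive battery with the published
reliabilities (0.58–0.96) in three domains. Each of those measurements is
attenuated relative to its latent construct by a factor computable in
closed form (0.936 for the DAT composite, 0.927 for the MAO-B factor,
$\sqrt{2/\pi}$ for binary sex, ≈0.886 for general cognition with domain
loadings $\sqrt{0.6}$). The generator therefore divides each target by the
attenuations of the composites involved before drawing latents, projects
the result to the nearest positive semi-definite correlation matrix
(eigenvalue clipping, rejected if any entry must move by more than 0.1),
and maps latents to observables. The measured pipeline output is then
centered on the printed correlations — which is what the end-to-end
acceptance test verifies at n = 10,000 to ±0.03.

Other mapped quantities:

* **Regional truths**: region scores share the construct latent with
  loading $\sqrt{\rho}$ plus uniqueness; means/SDs follow the published
  table ($BP_{ND}$: caudate 2.24 ± 0.52, putamen 3.31 ± 0.59; $K_i$ means
  0.04–0.07/min). Printed $K_i$ SDs of "0.00" are rounding artifacts and
  were set to 0.004/min (0.01 for caudate as printed). Truths are clamped
  at physiologic floors ($BP_{ND} \ge 0.1$, $K_i \ge 0.005$) to avoid
  degenerate fits in the tails.
* **Lesion volumes**: log-normal matched to mean 2.0 ml, SD 2.9 ml. This
  single choice also reproduces, with no further tuning, the published
  stratum structure: a 2% population quantile of 0.13 ml (the printed
  minimum is 0.1), and conditional means of 0.86 / 4.8 ml for the
  mild/moderate severity strata (printed: 0.8 / 4.9). Severity grades are
  assigned by fixed volume cuts at those quantiles; an optional injected
  extreme value (e.g. 14.7 ml) exercises the outlier rule.
* **Cognition**: tests load $\sqrt{\text{reliability}}$ on their domain,
  domains load $\sqrt{0.6}$ on the general factor (an inter-domain
  correlation of 0.6 is typical for batteries of this kind). Accuracy
  scores are rounded and clamped to the published maxima (32, 16, 24, 48,
  108, 30); speed tests emit (n_correct, total response time) pairs whose
  quotient ×60,000 is the correct-responses-per-minute score. Rounding and
  clamping cost well under 1% of variance and are ignored in the
  attenuation algebra.
* **Missingness emulation** (optional, off by default): first 10 subjects
  episodic-only, one subject working-memory-only, 4 subjects without the
  DAT scan — reproducing the published effective sample sizes (54 / 45 /
  44, and 51 with DAT).

What a green test does **not** establish: the generator draws Gaussian
latents with linear maps, so it cannot probe robustness to nonlinear
age effects, floor/ceiling pathologies, scanner batch effects, motion, or
partial-volume bias — none of which are modeled. Agreement with the
printed correlations is by calibration, not discovery; the meaningful
content of the end-to-end test is that the estimation chain is unbiased
enough not to *lose* the structure it is given.

## Composites and PCA conventions

All z-scores use complete-case means and sample (n−1) SDs. The DAT
composite averages caudate and putamen on the raw $BP_{ND}$ scale and then
standardizes (raw-then-z; the alternative z-then-average differs only
through the regional SD ratio and the published description is ambiguous).
The MAO-B factor is the first principal component of the *correlation*
matrix of cortex, hippocampus and thalamus (striatum deliberately excluded
to avoid circularity with the DAT composite); correlation rather than
covariance PCA is implied by the published eigenvalue structure (2.3 of
3). Factor scores are direct projections re-standardized to unit variance
— the regression-method alternative differs by a scale factor that the
re-standardization absorbs. Loading signs are fixed so the mean loading is
positive. Domain scores are means of available test z-scores; the general
score is the mean of domain scores and by default requires all three
domains (matching the published effective-n drop), with a policy switch
for partial batteries.

## The inferential layer

* **Outliers**: univariate rule at ±3.29 sample SDs (two-sided p < 0.001
  under normality; the alternative printed "3.3" is display rounding),
  pairwise deletion semantics, moments computed before exclusion, with
  optional externally supplied center/scale for worked examples.
  Multivariate rule: squared Mahalanobis distance against the
  $\chi^2_p$ quantile at p = 0.001.
* **Partial correlations**: residuals of each variable on the covariates,
  Pearson r between them, df = n − 2 − k; verified against the
  single-covariate closed form at 1e-10.
* **Hierarchical regression**: cumulative predictor blocks on the
  standardized outcome and predictors (binary covariates 0/1-coded then
  standardized, so coefficients are standardized betas); per-predictor t,
  partial r ($t/\sqrt{t^2 + df}$) and p; model F, R², adjusted R²; the
  R²-change F test between consecutive blocks refits the smaller model on
  the larger model's case set so the comparison is nested on identical
  data (each cumulative model otherwise keeps its own complete cases, so
  reported n shrinks as variables accumulate, as in the source tables).
* **Power**: smallest N with
  $P\!\left[F' > F^{-1}_{1-\alpha}\right] \ge$ target where $F'$ is
  noncentral F with $df_1 = q$, $df_2 = N - q - k - 1$ and
  $\lambda = f^2 N$ — the common power-software convention, which
  reproduces the published lower bound of 55 subjects for $f^2 = 0.15$,
  α = 0.05, one tested predictor and one covariate. The alternative
  convention $\lambda = f^2(df_1 + df_2 + 1)$ is exposed as an option.
  Note the fixed-design reading: with random regressors, empirical power
  at N = 55 is ≈0.78 rather than 0.805; the simulation oracle in the test
  suite fixes the design at exact noncentrality.
* **Group comparisons**: pooled-variance t by default (matching the
  reported df style), Welch as an option, ANCOVA as a linear-model F for
  the group term, Pearson chi-square without continuity correction.
* **Multiplicity**: Bonferroni with a user-declared family size (the
  source never defines its families; the default family is the set of
  p-values supplied).

## Numerical and degenerate-input choices

OLS throughout is QR with an explicit rank check — rank-deficient designs
raise errors naming the collinear set, never pseudo-inverse answers.
Zero-SD vectors are errors for z-scoring, a warning (no flags) for the
outlier rule. The PSD projection tolerance (max entry shift 0.1) separates
"mildly indefinite because targets were reported separately" from
"inconsistent". All randomness flows from a single integer seed per
cohort spec; `add_frame_noise()` can use a private RNG stream that leaves
the global state untouched. Identical spec + seed reproduces cohorts and
pipeline outputs byte-identically.

## Known limitations

Plasma-input modeling, metabolite and partial-volume correction, voxelwise
analyses and longitudinal designs are out of scope. The MRTM variant and
the Patlak x-axis normalization are documented choices, not reconstructions
of the original analysis code, so coefficient-level agreement with the
source tables is expected only in distribution (the package's regression
machinery is exercised on calibrated cohorts of the same size instead).
Reported degrees of freedom depend on the missingness pattern and are the
package's own, not forced to match the source.
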