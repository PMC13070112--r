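# petcohort

Reference-tissue PET kinetics and cohort statistics for brain-aging
studies, end to end: simulate regional time-activity curves (TACs) for a
reversible dopamine-transporter (DAT) ligand and an irreversible MAO-B
ligand on realistic frame schedules, estimate the kinetic parameters,
build the composite analysis variables, and run the cohort inferential
layer — all on synthetic cohorts calibrated to a published dual-tracer
cognitive-aging design, so that every stage is testable without access to
human subject data.

## Who it is for

Researchers and methodologists working on PET quantification pipelines or
on the statistics of small imaging cohorts who need a fully reproducible,
data-free testbed: ground-truth simulation, estimator validation,
composite scoring, and hierarchical-regression inference in one package
with a command-line surface.

## The models

**Binding potential (reversible tracer).** The multilinear reference
tissue model (MRTM) regresses, over all frames,

    C_T(T) = b1 * int_0^T C_R + b2 * int_0^T C_T + b3 * C_R(T)

and reports `BP_ND = -b1/b2 - 1`. Data are simulated from the simplified
reference tissue model, for which this identification is exact.

**Uptake rate constant (irreversible tracer).** Reference-Patlak with an
exponential reference-kinetics correction `C_ref(t) = C_cer(t) e^(-0.04 t)`
(t in minutes): over the steady-state frame window (frames 4–26), the
slope of `C_T/C_ref` against `int C_ref / C_ref` is `Ki_ref` (1/min).

**Inference.** ±3.29-SD univariate and Mahalanobis (p < 0.001) outlier
rules, log-transformed lesion volumes, zero-order and partial Pearson
correlations, standardized-beta hierarchical regression with R²-change F
tests, pooled t / ANCOVA / chi-square group comparisons, Bonferroni
adjustment, and exact noncentral-F power analysis (λ = f²·N).

## Worked example

```r
library(petcohort)

# forward-simulate and recover a putamen-like binding potential
ref <- make_reference_tac(pe2i_frame_schedule())
target <- simulate_reversible_tac(ref, R1 = 0.9, k2 = 0.15, bp_nd = 3.31)
fit_mrtm(target, ref)
#> <kinetic_fit> MRTM: BP_ND = 3.299 (R^2 = 0.99980, 18 frames)

# irreversible tracer: the emitted cerebellum curve is corrected internally
sim <- simulate_irreversible_tac(
  make_reference_tac(ded_frame_schedule(), 80, 0.06, 0.8), ki = 0.07, v0 = 1.5)
fit_reference_patlak(sim$target, sim$cerebellum)
#> <kinetic_fit> refPatlak: Ki_ref = 0.0702 (R^2 = 1.00000, 23 frames)

# a-priori power for an R^2-change test (f^2 = 0.15, 1 tested + 1 covariate)
power_min_n(f2 = 0.15, n_tested = 1, n_covariates = 1)
#> [1] 55

# full pipeline on a calibrated 55-subject synthetic cohort
res <- run_pipeline(cohort_spec(n_subjects = 55, seed = 1))
res$analysis$partials$dat_maob$r   # age-adjusted DAT-MAOB partial correlation
#> [1] 0.55
res$analysis$dat_model             # brain correlates of the DAT composite
#> ...
#> Model 3 (n = 53): F = 9.9, p = 6.38e-06, adj R^2 = 0.41
#>   age          beta =  -0.20  t =  -1.6  r = -0.23  p = 0.115
#>   sex          beta =   0.27  t =   2.4  r =  0.33  p = 0.0189
#>   log_lesion   beta =  -0.24  t =  -1.9  r = -0.26  p = 0.0632
#>   maob_factor  beta =   0.42  t =   3.6  r =  0.46  p = 0.000729
#>   dR^2 = 0.149, F(1,48) = 13.0, p = 0.000729 vs model 2
```

The noise-free kinetic round trips recover truth within 1%; the cohort
generator is calibrated so that at large n the measured composites
reproduce the design's correlation structure (e.g. the age-adjusted
DAT–MAO-B partial correlation of 0.53) within ±0.03 — at n = 55 any
single seed scatters around those targets, as above. The MAO-B factor
comes from a PCA whose calibrated 3-region structure puts 78% of variance
on the first component (eigenvalue 2.3).

## Command line

```sh
Rscript inst/exec/petcohort run --seed 1 --n 55 --out results_dir
Rscript inst/exec/petcohort power --f2 0.15
Rscript inst/exec/petcohort simulate --seed 3 --n 20 --out sim_dir
Rscript inst/exec/petcohort fit --tac sim_dir/tacs/s0001_ded.tsv --out fits.csv
```

`run` writes `cohort.csv`, `fitted.csv`, `scored.csv`, `results.csv`
(regression tables with one R²-change row per model comparison),
`partials.csv`, and JSON sidecars recording seed, configuration and
package version; identical seeds reproduce identical files.

## Layout

- `R/` — schedules/TACs, analytic simulators, kinetic fitters, cohort
  generator, composites, statistics, pipeline, CLI
- `tests/testthat/` — unit + property tests and `test-acceptance.R`
- `vignettes/petcohort-methods.Rmd` — models, calibration, and design
  choices in detail
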