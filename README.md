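# dynmix

Dynamic mixed-effects prediction models for clustered data: a simulation
and evaluation framework.

## The problem

Clinical prediction models derived in a few centres routinely fail to
generalize across a clustered population, because outcome levels and
covariate effects vary by cluster (clinic, hospital, surgical centre).
A linear mixed-effects model describes that heterogeneity, but its
prediction for a *novel* cluster is the hypothetical mean cluster
(*b*<sub>*i*</sub> = 0), so out of sample it behaves like an ordinary
fixed-effects model. A **dynamic** strategy — predict with the current
model, capture realized outcomes, refit every θ predictions — turns novel
clusters into known clusters over time, letting a single model calibrate
itself to every site where it is used.

`dynmix` quantifies that mechanism end to end:

* **simulate** — clustered populations: log-normal clinic sizes
  (*N<sub>i</sub>* ~ ⌈exp 𝒩(ln 65, (ln 2)²)⌉), correlated clinic-level
  random intercepts/slopes, an unobserved patient-level predictor, a
  volume–outcome effect γ·*f*(*N<sub>i</sub>*), and a residual variance
  calibrated analytically so the residual share of total outcome variance
  equals α (default 0.2);
* **models** — the three study models (linear; + random intercept;
  + random intercept and slope on *x*₁, optionally with size-quintile
  fixed effects), fit by penalized REML with a weak Wishart-type penalty
  on the random-effects covariance, with empirical-Bayes (BLUP) cluster
  effects and mean-cluster prediction for novel clinics;
* **dynamic** — the update engine: one global random prediction
  permutation, refits after every θ predictions, 80% outcome
  incorporation (loss to follow-up), previous-fit fallback on
  non-convergence;
* **evaluate** — mean absolute error and the relative improvement

  RI = (φ₀ − φ<sub>model</sub>) / (φ₀ − φ₁),

  where φ₀ is the MAE of the training-mean (intercept-only) null and φ₁
  the MAE of the true data-generating means: RI = 0 is null-equivalent,
  1 is oracle-equivalent, >1 in-sample overfitting, <0 worse than the
  null. Also per-quintile RI, within-clinic learning curves, and the
  80%-of-total-gains index;
* **experiments** — seeded Monte-Carlo cells and sweep grids
  (τ₀² × τ₁² main grid, β₂, γ with/without quintile fixed effects, θ),
  with resumable runs and tidy CSV/JSON outputs.

## Worked example

```r
library(dynmix)

pop  <- generate_population(sim_params(n_clinics = 60), seed = 1)
ids  <- select_training_clinics(pop, seed = 1, counts = c(2L, 2L, 2L, 2L, 2L))
run_s <- run_static(pop, ids, default_model_specs(), seed = 1)
run_d <- run_dynamic(pop, ids, default_model_specs(), theta = 500, seed = 1)
bl <- ri_baselines(pop, ids, run_s$traces$linear)
data.frame(
  model      = names(run_s$traces),
  static_ri  = sapply(run_s$traces, function(tr) score_trace(tr, bl)$ri),
  dynamic_ri = sapply(run_d$traces, function(tr) score_trace(tr, bl)$ri))
```

```
  model static_ri dynamic_ri
 linear     0.389      0.427
     ri     0.429      0.807
    ris     0.441      0.915
```

Read: out of sample, the static mixed models are barely better than the
plain linear model (~0.39–0.44 — shrinkage only, every testing clinic is
novel), while dynamic updating lifts the random-intercept model to RI 0.81
and the intercept+slope model to 0.91 — most of the way to the true model
(RI = 1). At the full study scale (500 clinics, ~41,500 patients, 20
training clinics, θ = 500) static models sit at RI ≈ 0.33–0.34 out of
sample and the dynamic intercept+slope model reaches ≈ 0.94, with 80% of
the within-clinic gains arriving by about the 7th–9th prediction at a
clinic.

Command-line wrappers live in `inst/scripts/`:
`simulate-population.R` writes a population to CSV/JSON,
`run-experiment.R` runs a sweep grid from a YAML/JSON config.

## Package layout

```
R/                  simulator, penalized-REML fitter, dynamic engine,
                    metrics, experiment grids
tests/testthat/     unit + property tests (incl. brute-force REML oracle,
                    lme4 cross-checks) and the acceptance suite
scripts/            acceptance.R (reproduction entry point)
inst/scripts/       CLI wrappers
vignettes/          methods vignette: model, estimation, design choices
```
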