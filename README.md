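# zinbsim

Simulation-based comparison of negative binomial (NB) and
zero-inflated negative binomial (ZINB) regression for count outcomes
in randomized trials.

## The problem

Trial count outcomes — serious illness episodes, hospital days, care
days outside the home — are frequently *zero-inflated*: 60–75% of
patients contribute a zero, and the rest are overdispersed and
right-skewed. A widespread reflex is to reach for a zero-inflated
model whenever the zero percentage is high. `zinbsim` is a package
for stress-testing that reflex. It is aimed at biostatisticians and
trial methodologists who want to know, for data shaped like their
own: does a ZINB analysis actually beat a plain NB analysis, and
which properties of an outcome predict when it would?

## What it computes

The count model is NB regression with a log link and log-exposure
offset, `log m_i = x_i'β + o_i`, where the NB pmf in
mean/dispersion form is

    Pr(X = x) = Γ(r+x) / (x! Γ(r)) · (r/(r+m))^r · (m/(r+m))^x,
    Var(X) = m + m²/r.

The ZINB adds a structural-zero mixture with logit link
`logit p_i = z_i'γ`, so `Pr(Y=0) = p + (1-p)(1+m/r)^(-r)` and
`E(Y) = (1-p) m`. The package provides:

* **`fit_count_model()`** — exact maximum likelihood for Poisson, NB,
  ZIP and ZINB regression (multi-start BFGS with analytic gradients
  plus a Newton polish), with convergence and boundary diagnostics;
* **`profile_ci()`** — profile-likelihood confidence intervals that
  invert the likelihood-ratio statistic, profiling every nuisance
  parameter;
* **`generative_model()` / `calibrate_intercepts()` /
  `simulate_trial()`** — a synthetic two-arm trial generator (n = 422
  by default) built on published data-derived coefficients, with the
  unreported intercept and dispersion calibrated so the synthetic
  outcomes hit target marginals (primary outcome: overall mean 0.68,
  69.9% zeros);
* **`run_simulation()` / `summarize_metrics()` /
  `preference_fraction()`** — the Monte-Carlo replicate loop with
  per-family exclusion of pathological fits, bias / MSE / coverage of
  the treatment coefficient, and the AIC model-preference tally;
* **`compute_characteristics()` / `build_preference_dataset()` /
  `fit_ridge_logistic()`** — the meta-regression relating eight
  marginal outcome characteristics to ZINB preference via ridge
  logistic regression, with adjusted and univariable odds ratios;
* **`run_study()`** — full-study orchestration from a YAML config to
  five CSV reports and a run log.

See `vignettes/zinbsim-methods.Rmd` for the modelling details and
every reconstruction decision.

## Worked example

Calibrate the primary-outcome NB generative model, run 200 replicates
of the trial at n = 422, and summarise:

```r
library(zinbsim)

model <- calibrate_intercepts(generative_model("serious_illness", "nb"))
model
#> <generative_model> NB | serious_illness
#> count part: (Intercept)   treatment     age_ge2       risk2       risk3
#>      1.0273     -0.4900     -0.7400     -0.7400     -1.8600
#> dispersion r: 0.4705 | offset_log: 0

records <- run_simulation(model, reps = 200, n = 422, seed = 1,
                          ci_families = "nb")
ex <- apply_exclusions(records)
ex$report
#> # A tibble: 2 × 7
#>   family     n n_excluded pct_excluded n_non_convergence n_boundary n_fit_failed
#> 1 nb       200          4            2                 4          0            0
#> 2 zinb     200         26           13                 2         24            0

summarize_metrics(ex$kept, true_beta_treatment(model))
#> # A tibble: 2 × 9
#>   family absolute_bias signed_bias relative_bias    mse coverage n_used  n_ci
#> 1 nb             0.159      0.0377         0.324 0.0395    0.939    196   196
#> 2 zinb           0.221      0.0461         0.451 0.0786   NA        174     0

pf <- preference_fraction(ex$kept)
cat(sprintf("NB preferred by AIC in %.1f%% of %d replicates\n",
            100 * pf, attr(pf, "n_pairs")))
#> NB preferred by AIC in 83.5% of 170 replicates
```

Reading the output: the treatment coefficient used to generate the
data is −0.49. The NB analysis recovers it with a mean absolute
error of 0.16 (about a third of the coefficient magnitude), MSE 0.04,
and 93.9% of its 95% profile-likelihood intervals cover the truth at
this replicate count. Although the outcome has ~70% zeros, the plain
NB model attains the lower AIC in 83.5% of replicates — the ZINB's
two extra parameters rarely pay for themselves. ZINB fits also fail
more often (13% flagged, mostly boundary solutions of the logit
part); exclusions are per family, so those replicates still
contribute NB estimates.

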