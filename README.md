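# fvcjoint

Shared-parameter joint models linking the decline of forced vital
capacity (FVC, % predicted) to the time to first hospitalisation or death
in systemic sclerosis associated interstitial lung disease (SSc-ILD)
trials.

FVC measured repeatedly during a trial is an *endogenous* time-dependent
covariate: it is observed intermittently, with error, and its follow-up is
truncated by the very events it predicts, so a Cox model with a
time-varying covariate is biased.  `fvcjoint` fits the standard remedy —
a joint model in which shared subject-level random effects drive both
processes:

* **Longitudinal sub-model** — a normal linear mixed-effects model of
  FVC % predicted with ATA (anti-topoisomerase I antibody) status and
  baseline FVC as level covariates, separate mean slopes per treatment
  arm, and correlated random intercepts and slopes (unstructured 2×2
  covariance):
  `y_i(t) = β0 + βa·ATA + βb·(FVC0 − c) + (βt + βtx·arm)·t + b0 + b1·t + ε`.
* **Time-to-event sub-model** — a piecewise-exponential baseline hazard
  with five internal knots (event-time quantiles), stratified by ATA
  status, for the composite of first hospitalisation (all-cause,
  SSc-related, ER/ICU, ICU, or ventilation category) or death, restricted
  to the treatment period plus a 28-day window.
* **Association** — the hazard is multiplied by `exp(α · slope_i)` where
  `slope_i = βt + βtx·arm + b1` is the subject's annual rate of FVC
  change (primary), or by `exp(α · m_i(t))` with `m_i(t)` the error-free
  current FVC value (secondary).  The hazard ratio for a k-percentage-
  point *faster* annual decline is `HR(k) = exp(−kα)`.

Estimation is maximum likelihood with per-subject adaptive Gauss–Hermite
quadrature over the random effects (closed-form Gaussian centring, exact
at `α = 0`), an analytic gradient for the slope association, and Wald
inference from a finite-difference Hessian.  Because patient-level data
for this indication are not publicly deposited, the package ships a
calibrated trial simulator (`simulate_trial()`) that inverts the model's
own cumulative hazard, plus `recovery_experiment()` for bias and coverage
studies.

## Worked example

```r
library(fvcjoint)

cfg  <- sim_config(n_subjects = 300)         # SENSCIS-like defaults
sim  <- simulate_trial(cfg, seed = 6)
data <- build_joint_dataset(sim$trial, endpoint = "all_cause",
                            period = "52w")
data
#> Joint-model dataset: endpoint all_cause, period 52w
#>   300 subjects, 38 with event (12.7%), 2001 FVC measurements

fit <- fvcjm(data, association = "slope")
fit
#> Shared-parameter joint model (slope association)
#>   endpoint: all_cause (52w); 300 subjects, 38 events
#>   log-likelihood: -5937.687
#>   association alpha: -0.1941 (SE 0.1320); HR per 1-unit faster annual decline: 1.214
#>   slope difference (active - control): 0.452 %/yr

hazard_ratio_report(fit)
#> Hazard ratios per k-unit decrease in annual FVC % predicted slope
#>  unit    hr ci_low ci_high
#>     1 1.214  0.937   1.573
#>     3 1.790  0.824   3.890
#>     5 2.639  0.724   9.622
#> alpha = -0.1941 (SE 0.1320); Wald p = 0.1414
```

Read as: in this simulated trial (generated with a true per-unit hazard
ratio of 1.13 and a true slope difference of 1.2 %/yr), a subject whose
annual FVC decline is one percentage point steeper has a fitted 1.21-fold
hazard of first hospitalisation or death (a single 38-event replicate; the
estimate carries the SE shown); the 3- and 5-unit rows are the same
coefficient raised to the 3rd and 5th power.  `risk_curve(fit)`
tabulates `HR(d)` with delta-method bands over declines d in (0, 10], and
`plot(fit)` draws it.  `summary(fit)`, `coef()`, `confint()`,
`predict()`, `residuals()` and `simulate()` behave as for other R model
objects.

A thin command-line wrapper (`inst/scripts/fvcjm.R`) exposes `fit`,
`simulate` and `recover` subcommands over CSV inputs; see the methods
vignette (`vignettes/joint-modelling-fvc.Rmd`) for the model, its
assumptions, the simulator calibration and the package's design choices.

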