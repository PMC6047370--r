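# binaryiv

Instrumental-variable estimation of a treatment effect when **both the
outcome and the exposure are binary** and an unmeasured confounder makes
the exposure endogenous — the standard predicament of
pharmacoepidemiologic safety studies, where a rare adverse event is
regressed on a rarely prescribed drug and prescription channels
unmeasured patient frailty.

The structural model is double-logistic:

    P(Y = 1 | T, X1, X2, Xu) = expit(b0 + T*bt + X1*b1 + X2*b2 + Xu*bu)
    P(T = 1 | Z, X1, X2, Xu) = expit(a0 + Z*az + X1*a1 + X2*a2 + Xu)

with `Xu` unobserved and `Z` an instrument: here the prescribing
physician's latent preference for the treatment, proxied from observed
prescribing history either by the previous patient's treatment
(`zstar`) or by the running proportion of the physician's earlier
patients who were treated (`pr`).

The package provides, for biostatisticians and methods researchers:

* **Estimators** (`iv_fit()`): benchmark logistic fit with `Xu`
  observed, conventional fit omitting it, **two-stage residual
  inclusion** (2SRI) with a two-step sandwich covariance that accounts
  for first-stage estimation (`fit_2sri()`,
  `sandwich_covariance_2sri()`), and an exactly identified **nonlinear
  IV-GMM** solving `mean((Y - expit(X b)) * w) = 0` by Newton iteration
  (`fit_gmm()`), plus a nonparametric bootstrap
  (`bootstrap_variance()`).
* **Diagnostics**: closed-form instrument strength `Corr(Z, T*)` and
  `Corr(T, Z)`, confounding level `Corr(Xu, T*)`, and a first-stage
  instrument-exclusion F-equivalent (squared Wald z) —
  `diagnose_scenario()`, `first_stage_F()`.
* **Simulator** (`simulate_cohort()`, `attach_proxies()`):
  physician-clustered cohorts (100 patients/physician) on a named
  3×3 grid of instrument strength (`az` = 1, 2, 3) by confounding level
  (`sigma_u` = 0.5, 1, 1.5), in a rare-exposure regime (~2–7% exposed,
  rare events) or a balanced regime (26–45% exposed).
* **Monte-Carlo engine** (`run_scenario()`, `report_tables()`):
  relative bias, Monte-Carlo and asymptotic sd, rMSE and CI
  non-coverage per method, with explicit outlier/failure bookkeeping.

A thin command-line wrapper over these functions ships in
`inst/cli/binaryiv.R` (`fit`, `diagnose`, `study` subcommands).

## Worked example

Simulate one cohort at the strong-instrument / high-confounding cell
(n = 30000, true `bt = 3`), attach the preference proxies and fit 2SRI:

```r
library(binaryiv)
cfg <- scenario_preset("strong", "high", n = 30000, seed = 7)
coh <- attach_proxies(simulate_cohort(cfg))
summary(iv_fit(coh, "2sri", instrument = "pr"))
#> Method: 2sri (instrument: pr)
#> Observations used: 29700 ; converged: TRUE
#>
#>              Estimate Std. Error z value  Pr(>|z|)
#> (Intercept) -1.379279   0.396990 -3.4743 0.0005121
#> T            3.122252   0.520827  5.9948 2.037e-09
#> X1           0.464146   0.107954  4.2995 1.712e-05
#> X2           0.615432   0.079996  7.6933 1.434e-14
#> residual     0.612508   0.516618  1.1856 0.2357763
#>
#> 95% Wald confidence intervals:
#>               lower   upper
#> (Intercept) -2.1574 -0.6012
#> T            2.1015  4.1431
#> X1           0.2526  0.6757
#> X2           0.4586  0.7722
#> residual    -0.4000  1.6251
```

The treatment coefficient (3.12, CI 2.10–4.14) brackets the generating
value 3 even though the confounder was withheld from the fit — the
first-stage residual column absorbs it. The 100 first-patients-per-
physician have no proxy and are excluded (29700 used). For the same
cohort, the conventional fit returns about 3.8 (a ~26% overestimate of
the log odds ratio).

Scenario diagnostics come from closed forms plus the fitted first
stage:

```r
diagnose_scenario(cfg, coh)
#> Instrument strength Corr(T, Z):    0.0569
#> Instrument strength Corr(Z, T*):   0.4442
#> Confounding level Corr(Xu, T*):    0.4846
#> First-stage F-equivalent:          252.54
```

A full Monte-Carlo comparison of the four estimators at one grid cell:

```r
run_scenario(scenario_preset("strong", "high", n = 30000, ns = 200,
                             seed = 7), instrument = "pr")
```

which prints relative bias (%), Monte-Carlo and asymptotic sd, rMSE and
non-coverage per method, with counts of dropped replications.

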