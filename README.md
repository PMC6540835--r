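# apexds

Abundance estimation for aerial line-transect surveys in which detection
peaks *away* from the transect line and is imperfect even at that peak.

## The problem

Small two-person aircraft with flat (non-bubble) windows cannot see the
strip directly beneath them, so the probability of detecting an animal —
a bear, in the surveys this package is built around — rises from the line
to an **apex** at roughly 100–125 m and falls off beyond it. Conventional
distance sampling (CDS) assumes detection is *certain* at the curve's
maximum; aerial double-observer data consistently show pooled apex
detection probabilities of 0.83–0.95 instead, which biases CDS abundance
estimates low by roughly the same factor. Un-modeled heterogeneity in
detectability adds a second trap: it inflates detection probabilities
estimated from double-observer (mark–recapture) data under the assumption
of *full* independence between observers, biasing those estimates low as
well.

`apexds` implements the estimator family built for this situation:

* **CDS / MCDS** (`fit_cds()`) — conditional maximum likelihood for
  half-normal and **two-piece normal** detection functions
  (`g(x) = exp(-(x-θ)²/2σ₁²)` rising to the apex θ, falling with σ₂
  beyond it), covariates acting log-linearly on both scales, AIC ranking
  (`aic_select()`) and Kolmogorov–Smirnov goodness of fit (`gof_ks()`);
* **Double-observer mark–recapture** (`fit_mr_conditional()`) —
  conditional likelihood for capture histories of detected groups, with
  logit or log links and distance bases up to an apex-centered piecewise
  quadratic;
* **MRDS** (`fit_mrds()`) — the combination: the distance model supplies
  the shape, the mark–recapture model supplies absolute detectability —
  everywhere (*full independence*) or only at the apex
  (*point independence*, the robust choice under heterogeneity).
  Abundance is the Horvitz–Thompson sum `N = (A/a) Σ sᵢ/Pa(zᵢ)` with
  delta-method + encounter-rate variance (`encounter_rate_variance()`)
  or a transect bootstrap (`bootstrap_variance()`);
* a **simulator** (`simulate_survey()`, `simulate_stakes()`,
  `simulate_availability_series()`) generating double-observer surveys
  with shared group-level frailty, availability (denning) dynamics,
  hotspot transects and covariates, plus known-truth records;
* a **benchmark harness** (`run_experiment()`, `stake_experiment()`,
  `relative_bias()`) reproducing the bias orderings that motivate the
  design.

## Worked example

Simulate a survey with a true apex at 110 m, pooled apex detection 0.90,
and about 1000 detections, then fit both estimators:

```r
library(apexds)
scn <- scenario_recovery()
sim <- simulate_survey(scn, seed = 7)
#> detections: 959   true N: 12437

mrds <- fit_mrds(sim$obs, sim$design, "two_piece_normal",
                 independence = "point")
mrds
#> MRDS fit (point independence, two_piece_normal detection, n = 959)
#>   apex theta = 105.9 m
#>   mean apex MR p = 0.818 (SE 0.030), range [0.818, 0.818]
#>   N = 13295.8 (SE 816.3)

cds <- fit_cds(sim$obs, sim$design, "two_piece_normal")
cds
#> Conventional distance sampling fit (n = 959, w = 600 m)
#> Detection function: two_piece_normal
#>   apex theta = 121.98 m, sigma1 = 84.39, sigma2 = 153.14
#>   logLik = -5809.641, k = 3, AIC = 11625.283
#>   N = 11126.8 (SE 508.0)

relative_bias(cds$abundance$N, mrds$abundance$N)
#> [1] -16.31
truncation_fraction(sim$obs, mrds$theta)$percent
#> [1] 27.2
```

The MRDS estimate brackets the truth (12437); the CDS estimate, which
assumes certain detection at the apex, sits ~16% below the MRDS one —
the size of bias this estimator family exists to remove. The last line
shows how much data a half-normal analysis would have to discard by
left-truncating at the apex.

A command-line wrapper over the same functions ships in
`inst/scripts/apexds.R`:

```sh
Rscript inst/scripts/apexds.R simulate --config inst/extdata/config-template.yml --seed 7 --out sim/
Rscript inst/scripts/apexds.R fit --model mrds-pi --obs sim/obs.csv \
    --transects sim/transects.csv --config inst/extdata/config-template.yml --out report
```

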