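---
title: "Models and design of apexds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of apexds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apexds)
```

## The estimation problem

Line-transect distance sampling estimates abundance from the
perpendicular distances of detected groups: if detection falls off with
distance according to a curve $g(x)$ scaled so that its maximum is 1,
the *effective strip half-width* $\mu = \int_0^w g(u)\,du$ converts the
count of detections into density. Two assumptions carry all the weight:
that the shape $g$ is adequately modeled, and that detection is certain
where $g$ peaks.

Aerial surveys from small fixed-wing aircraft break the second
assumption twice. Because the strip below the aircraft is hidden, $g$
peaks at an apex distance $\theta$ (around 100–125 m in practice) rather
than on the line; and even at the apex, double-observer data show pooled
detection probabilities well short of 1. `apexds` implements the
estimator family developed for exactly this regime.

## Detection models

**Two-piece normal.** The detection curve rises to the apex with a
near-side scale and falls with a far-side scale,
$$
g(x) = \begin{cases}
\exp\{-(x-\theta)^2 / 2\sigma_1^2\} & x \le \theta\\
\exp\{-(x-\theta)^2 / 2\sigma_2^2\} & x > \theta,
\end{cases}
$$
with $g(\theta)=1$ by construction. The half-normal is the special case
$\theta = 0$, $\sigma_2 = \sigma_1$. All parameters are in metres.
Covariates $z$ act log-linearly on *both* scales through a single shared
coefficient vector, $\sigma_k(z) = \sigma_k e^{\beta^\top z}$
(treatment-coded dummies for factors). Sharing $\beta$ between the
pieces keeps the model identifiable at the 60–1000-detection sample
sizes these surveys produce; the apex $\theta$ is likewise shared across
covariate levels, matching how a survey reports one apex distance.
Internally the optimizer works on $\log\sigma_1$, $\log\sigma_2$ and a
logistic transform of $\theta$ onto $(0, w)$, so the likelihood search
is unconstrained. The effective half-width has a closed form through the
normal CDF; adaptive quadrature is kept alongside as a cross-check (the
two agree to $10^{-6}$ over random parameter draws — this is a tested
invariant, not an aspiration).

The conditional likelihood of the observed distances is
$\sum_i \log\{g(x_i; z_i)/\mu(z_i)\}$. Distances are treated as exact;
interval-censored recording is out of scope. Left truncation at $t$
(used when forcing a half-normal onto apex-peaked data) shifts distances
to $x - t$ and integrates over $[0, w-t]$; `left_truncation = "apex"`
takes $t$ from a two-piece-normal pre-fit, which is where a monotone
model first becomes defensible — at the cost, in our simulations, of
discarding roughly a quarter of the data.

**Abundance.** All estimators end in the Horvitz–Thompson sum
$\hat N = (A/a)\sum_i s_i / \hat P_a(z_i)$ over detected groups, with
$s_i$ the group size, $A$ the study area, $a$ the covered area
(`sides × w × L`; one-sided by default since pilot and rear observer
search the same side), and $\hat P_a$ the estimated inclusion
probability of a group in the covered strip — $\mu(z)/w$ for CDS, which
amounts to assuming certain detection at the apex. Group size enters
only through the HT weighting unless listed as a covariate.

**Variance.** The default standard error adds a delta-method
detection-parameter component to the between-transect encounter-rate
component
$$
\widehat{\mathrm{var}}(n/L) = \frac{K}{L^2(K-1)}
  \sum_k l_k^2 (n_k/l_k - n/L)^2,
$$
computed within strata, with transects that saw nothing counted as
zeros. This between-line term is typically the dominant component and
omitting it understates uncertainty. The reference method is a transect
bootstrap (`bootstrap_variance()`): transects resampled with replacement
within strata and the *entire* two-stage estimator refitted per
replicate, so encounter-rate variance and apex-estimation uncertainty
are captured by construction. The delta method treats the apex estimate
as fixed across stages; that is a known understatement and the reason
the bootstrap is the reference.

## Double-observer mark–recapture

Each detected group carries a capture history over the two observers;
conditioning on detection by at least one, the three observable
histories have probabilities
$\{p_1(1-p_2),\,(1-p_1)p_2,\,p_1p_2\}/(1-(1-p_1)(1-p_2))$ under
independence. Each observer's $p_j(x, z)$ is a link function of a linear
predictor in distance and covariates, with an optional observer-role
offset (pilot versus rear seat).

Two link/basis combinations matter:

* the classical logistic regression with distance entering linearly —
  retained as the default surface of `fit_mr_conditional()` and
  appropriate when detection is monotone in distance;
* a **log link with an apex-centered piecewise basis**
  $\{d,\ d^2 1_{d\le 0},\ d^2 1_{d>0}\}$, $d = x - \hat\theta$ — the
  specification `fit_mrds()` uses. Under a log link the model factorizes
  as (apex detectability) × (distance decay), which is the structure
  aerial detection actually has: $\log\{q\,g(x)\}$ is exactly an
  intercept plus a piecewise quadratic in $d$. A logit-linear (or even
  single-quadratic) predictor cannot represent a curve that rises to an
  interior maximum and falls asymmetrically, and we found by direct
  asymptotic computation that forcing it into the apex evaluation
  carries a 7–17% abundance bias under this package's own generative
  model. That computation — not taste — drove the default.

Degenerate data are flagged rather than silently fitted: histories with
no duplicates make the conditional probabilities inestimable (an error),
all-duplicate histories pin the fit to the $p=1$ boundary (a flagged
boundary fit), and diverging coefficients trigger a small ridge penalty
with a warning.

## Full versus point independence

*Full independence* trusts the fitted mark–recapture model at every
distance: $\hat P_a(z) = w^{-1}\int_0^w [1 - (1-\hat p_1)(1-\hat p_2)]\,dx$.
Any shared, un-modeled heterogeneity between the observers — the same
group being easy or hard for both — inflates these estimates (duplicated
detections look "too frequent" to an independence model), most severely
where detection is weak, and the abundance estimate drops accordingly.

*Point independence* assumes independence only at the apex, where
detection is near its maximum and heterogeneity has the least room to
act. `fit_mrds()` implements it in stages:

1. a two-piece-normal (or half-normal) conditional distance fit on the
   pooled detections gives an initial apex;
2. the mark–recapture stage (log link, apex-centered basis) is fitted
   and evaluated *only* at the apex, giving per-observer apex scales
   $\hat q_j(z)$;
3. the distance stage is then *refitted through the pooled-curve
   likelihood*: single-observer curves $\hat q_j(z)\, g(x;z)$ combine to
   $p_\bullet(x,z) = 1-(1-\hat q_1 g)(1-\hat q_2 g)$, and the two-piece
   normal parameters maximize the conditional likelihood of the
   distances under $p_\bullet$. Stages 2–3 alternate twice so the
   mark–recapture basis is centered on the final apex.

Step 3 departs from the more common shortcut of fitting the detection
family directly to the pooled distances and multiplying by
$\hat p_\bullet(\theta)$. The pooled curve of two imperfect observers is
$2qg - q^2g^2$, which is *not* two-piece normal; treating it as such
biases both the apex (plim error +12.6 m under our reference scenario)
and the effective strip width (−4.5%), for a net +4.7% abundance bias
even with a perfect mark–recapture stage. Modeling the pooled curve as
the combination of two scaled single-observer shapes removes that
asymptotic bias; the parameter-recovery experiment in the acceptance
suite (200 simulated surveys of ~1000 detections) checks the result
empirically. The first-stage MCDS fit is retained on the returned object
(`$ds`) and its AIC is the distance-component AIC — the only AIC that is
comparable across CDS and MRDS fits, since the mark–recapture likelihood
has no counterpart on the CDS side. Cross-type AIC tables therefore use
the distance component only; `aic_select()` refuses to rank across
likelihood types.

Inclusion probabilities below 0.01 trigger an extreme-extrapolation
warning; apex estimates within 2% of the boundary of $(0, w)$ are
flagged.

## What the simulator generates — and what it does not

`simulate_survey()` draws groups across strata in proportion to area,
marks those inside covered strips (assigned to transects in proportion
to line length, with optional "nugget" transects whose local intensity
is multiplied — emulating a carcass or sedge meadow that concentrates
animals), gives each group a perpendicular distance uniform on $[0,w]$,
covariates (4-level percent cover, 3-level activity, an
effective-search-distance measurement binned as $[0,w]$ versus $>w$ so
the binned covariate stays independent of distance), a zero-truncated
Poisson group size (rate 1.1, mean ≈ 1.6), a daily availability state
(bears in dens are never detectable), and a *shared* logit-scale frailty
$\varepsilon \sim N(0, \tau^2)$ added to both observers' predictors.
Observer $j$ detects with probability
$\mathrm{logit}^{-1}(\eta_j(z)+\varepsilon)\, g_{\mathrm{true}}(x;z)$.
Only groups detected at least once are returned, alongside a full truth
record. Identical seeds reproduce surveys byte for byte.

Availability follows a two-state Markov chain with stationary
probability $\psi$ and lag-one autocorrelation $\rho$
(`simulate_availability_series()`), so $\rho > 0$ encodes "a denned bear
tends to stay denned". No quantitative denning rates are established for
these surveys; the defaults ($\psi = 1$, $\rho = 0$) deliberately switch
the process off, and scenarios that exercise it label their values as
nominal.

The stake simulator (`simulate_stakes()`) reproduces the classical
known-population design: 150 stakes at uniform distances from a 1-km
walked line, surveyed independently by several observers whose curves
peak *on* the line. Two stake-level frailties are shared between
observers: one on the apex logit and one on $\log\sigma$ (visibility —
vegetation that hides a stake from everyone at distance but not up
close). The scale frailty is load-bearing: by direct asymptotic
computation, a frailty acting only on the apex logit biases the full-
and point-independence estimators *identically*, and no ordering between
them can emerge; heterogeneity in the decay scale is what full
independence cannot survive and point independence can.

What the simulator does **not** emulate: spatially explicit movement,
responsive animals, distance measurement error, observer learning across
days, or multi-day recapture identity. Passing tests therefore say that
the estimators behave as theory predicts under the stated generative
assumptions — not that any particular field survey satisfies them.

## Calibration of the study scenarios

The canonical scenarios in `?scenarios` are fixed study conditions,
chosen once from asymptotic (plim) calculations made before any test
was run:

* `scenario_recovery()`: apex 110 m, $\sigma_1 = 60$, $\sigma_2 = 150$,
  $w = 600$ m — the apex and scales sit in the ranges aerial bear
  surveys report; both observers at apex detection 0.684 so the pooled
  apex probability is exactly 0.90; effort sized for ~1000 detections.
  Used for parameter recovery (200 replicates in the test suite, 100 in
  the acceptance script — sizes chosen so the whole suite stays
  comfortably inside a few minutes).
* `scenario_stakes_heterogeneous()`: apex logit 1.1, $\sigma = 14$ m,
  apex frailty 0.25, scale frailty 0.5. Gauss–Hermite integration over
  the frailties gives a marginal pooled apex probability of 0.934 —
  inside the 0.83–0.95 band seen in real double-observer surveys — and
  asymptotic biases of about −7% (CDS), −10% (full independence) and
  −3.5% (point independence). The same calculation shows the intrinsic
  trade-off: scale frailty strong enough to produce the textbook −20%
  CDS bias also erodes the point-independence shape fit past useful
  bounds, so the scenario sits where the *ordering* is unambiguous and
  point independence stays within a few percent of truth.
* `scenario_pooling_baseline()`: half-normal truth with a two-level
  cover covariate scaling $\sigma$ between 75 and 85 m and certain apex
  detection. Pooling robustness — the insensitivity of pooled CDS to
  un-modeled heterogeneity — is a first-order property: fitting one
  half-normal to a mixture of half-normals is exactly unbiased only in
  the limit of matching shapes. The plim bias is −0.6% at the 75/85
  spread but −8.2% at a 60/100 spread; the scenario uses the moderate
  spread so the baseline isolates the pooling property itself rather
  than parametric misfit.
* `scenario_stratified_intensity()`: two equal-area strata, four-fold
  different coverage (16% versus 4%) and stratum-dependent detection
  ($\sigma$ 110 versus 60 m). Here pooling fails by design — the pooled
  detection fit is dominated by the heavily sampled stratum — and
  stratum-wise estimation repairs it.

## Numerical choices

Optimization is Nelder–Mead followed by a BFGS polish (a bounded 1-D
`optimize` for the single-parameter half-normal); standard errors come
from the numerically differentiated Hessian at the optimum, with
singular Hessians degrading to `NA` rather than failing the fit.
Integrals of pooled curves use 41-point Gauss–Legendre rules; the
mark–recapture log link caps the linear predictor just below 0 so
probabilities stay in $(0,1)$. AIC ties within $10^{-6}$ resolve in
favour of fewer parameters. The Kolmogorov–Smirnov test transforms each
distance by its own fitted conditional CDF (a per-observation
probability-integral transform), so covariate models need no binning;
the p-value uses the asymptotic distribution. Starting values for the
two-piece normal come from a kernel-density mode (apex) and one-sided
RMS spreads (scales). Seeds derived for replicate streams stay below
$2^{31}$.

## Known limitations

* The delta-method variance ignores correlation between the distance
  and mark–recapture stages and treats the apex as fixed; use the
  bootstrap when the SE matters.
* Point independence inherits some sensitivity to shape misspecification
  of the single-observer curve: under strong latent scale heterogeneity
  its shape stage erodes like any pooled parametric fit (quantified
  above). Observable visibility covariates should be modeled, not left
  to the frailty.
* Only two observers, trial-free, single-platform configurations are
  supported; interval-censored distances and series-expansion detection
  families are out of scope.
* The availability process is simulator-side only: the estimators
  correct for detectability of *available* groups, and abundance refers
  to the available population unless $\psi = 1$.
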