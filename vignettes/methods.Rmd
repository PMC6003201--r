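---
title: "Simulating outlier classification of health-care providers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating outlier classification of health-care providers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When hospitals are compared on risk-adjusted mortality — the canonical
example being isolated coronary artery bypass grafting (CABG) — each provider
is classified as performing as expected (*normal*) or better/worse than
expected (*outlying*). Whether a provider is flagged depends jointly on the
risk-adjustment model and the decision rule, and misclassification has real
consequences in both directions. `profilesim` is a Monte-Carlo laboratory for
that question: it generates cohorts in which the true status of every
provider is known by construction, applies six commonly used risk-adjustment
methods to identical data, and measures classification accuracy
(sensitivity, specificity, PPV, NPV) together with *eagerness* — the
proportion of simulated datasets in which a method flags anyone at all.

The six methods are:

* **`lr_f`** — fixed-effects logistic regression. Stage 1 fits
  `y ~ case-mix` and extracts the overall intercept; stage 2 fits an
  intercept-free model with all K provider dummies plus the case-mix
  variables. A provider is an outlier when its 95% Wald interval excludes
  the stage-1 intercept. The stage-1 intercept is treated as a known
  constant — no uncertainty propagation — which is the way the rule is used
  in practice.
* **`lr_r`** — random-effects (random-intercept) logistic regression with
  the case-mix variables as fixed effects; a provider is flagged when its
  empirical-Bayes (EB) deviation from the overall intercept exceeds two
  observed standard deviations (see below).
* **`gps_a`** — generalized propensity score (gPS) adjustment: the K − 1
  non-reference gPS columns enter a providers-as-random-effects model as
  linear fixed effects, and the same two-SD EB rule is applied.
* **`gps_w`**, **`gps_wt`** — inverse-probability-of-attendance weighting,
  raw and with the top 2% of weights trimmed to the 98th percentile; the
  weighted analysis model contains only the providers as random effects.
* **`gps_mws`** — marginal mean weighting through stratification: per
  provider, all patients are binned into L = 5 quintile strata of that
  provider's gPS, and each attendee is weighted by
  stratum size × marginal attendance share / attendees-in-stratum.

## The data-generating design

**Case-mix.** Each patient carries eight predictors of in-hospital
mortality: centered age plus seven binary risk factors (female sex, chronic
pulmonary disease, extracardiac arteriopathy, unstable angina, moderate LV
dysfunction, recent myocardial infarction, emergency intervention) — the
EuroSCORE variables common enough (> 5% prevalence) to be estimable per
provider. The generator is parametric: age is a centered normal (default SD
10 years, truncated at ±3 SD), binaries are Bernoulli with configurable
prevalences, and an optional latent-Gaussian copula induces correlation. The
default prevalences are plausible values for a CABG cohort, all above the 5%
floor; they are synthetic stand-ins, not estimates from any registry, and
real joint distributions (in particular age–risk-factor correlation, which
the independent default omits) are not reproduced. Anything that depends
fine-grainedly on the joint case-mix distribution should therefore be read
qualitatively, not quantitatively.

**Provider assignment.** Attendance follows a multinomial logit in which
every non-reference provider has a single coefficient
`beta_k ~ Uniform(0, 1)` applied identically to all eight predictors, so
high-`beta` providers systematically attract high-risk patients — the
confounding the adjustment methods must undo. Coefficients are redrawn for
every replicate dataset. Intercepts are all zero: provider volumes are fixed
exactly by quota filling (draw a patient, draw one provider from the
patient's attendance probabilities, discard the patient entirely if that
provider is full), so intercepts would only change rejection rates, not the
realized design. The whole-patient rediscard is the literal reading of
resampling until every provider reaches its volume; it induces mild
conditioning near quota completion, which we accept. A safety cap of
1000 × N candidate draws turns pathological configurations into a
diagnosable error.

**Outcomes.** Mortality is drawn from a random-intercept logistic model:
`logit(p_ik) = gamma00 + alpha0_k + Z beta'`. Provider intercepts are
`alpha0_k ~ N(mu, sigma^2)` with `mu = 0` for normal providers and
`mu = ±H·sigma` for true outliers; the default `sigma = 0.1942` is the
between-provider SD reported for a national isolated-CABG registry, so at
`H = 2` the outlier distributions sit at ±0.3884 on the log-odds scale
(odds ratios 1.475 and 0.678). The sign convention is that a *positive*
intercept means excess mortality, i.e. *below-average performance*; with
one-sided outliers (`S = 1`) all outliers are drawn on that side. The
case-mix coefficients default to the logistic EuroSCORE coefficients with
age entered per year of centered age; the original model's age coding
(increments above 60) is not reproduced, and the whole vector is replaceable
via the `beta` argument throughout. The overall intercept `gamma00` is
calibrated per replicate by bisection so that the realized sample's mean
fitted probability equals the target incidence exactly (residual < 1e-6);
calibrating on the realized sample rather than in expectation guarantees the
stated incidence for every generated dataset. Finally every provider must
realize at least 1% incidence (preventing separation downstream): the
outcome vector is redrawn up to 100 times, after which the provider
intercepts themselves are redrawn and recalibrated.

**Scenario grid.** Seven one-at-a-time sweeps around the baseline
(K = 50, p·· = 0.10, P(out) = 0.2, H = 2, S = 2, min(n_k) = 1000,
P(nmin) = 0.5): K ∈ {10..50}, p·· ∈ {0.03, 0.10, 0.20},
P(out) ∈ {0.08, 0.20, 0.40}, H ∈ {1..4}, S ∈ {1, 2},
min(n_k) ∈ {500, 1000}, P(nmin) ∈ {0.5, 1}. Half the providers have volume
`min_nk`, half 1000; each outlier independently takes a small volume with
probability `P(nmin)` (excess demand for small slots is reallocated and
recorded). `round(P(out)·K)` must be even when S = 2 so the two sides split
equally.

## The two-SD empirical-Bayes rule

"More than two observed standard deviations from the overall intercept"
admits two readings: the model-estimated random-intercept SD
(`rule_sd = "model"`) or the sample SD of the EB deviations themselves
(`rule_sd = "empirical"`). Both are implemented. The default is `"model"`:
it is the quantity the mixed model actually estimates, and in our
simulations it is the reading consistent with the full pattern of published
behavior of these methods — in particular the near-zero sensitivity of all
random-effects methods when the outcome is rare (p·· = 0.03). The empirical
SD of shrunken deviations is systematically smaller than the model SD, so
the `"empirical"` rule flags more providers; users comparing against
analyses that computed the threshold from the EB estimates should switch the
flag.

## Numerical choices

* **GLMM engine.** All random-intercept models are fit with `lme4::glmer`.
  The `nAGQ` argument selects the integration scheme; the simulation
  pipeline defaults to `nAGQ = 0` (fixed effects estimated within the
  penalized least-squares step). With the cluster sizes of this design
  (≥ 500 patients per provider) the test suite shows `nAGQ = 0`, the Laplace
  approximation and 9-node adaptive quadrature agree on `sigma-hat` and the
  EB deviations to about three decimals, while differing by an order of
  magnitude in runtime. `fit_random_intercept_logistic()` defaults to the
  Laplace approximation (`nAGQ = 1`) for standalone use, and the marginal
  log-likelihood it reports is verified against dense-grid numeric
  integration on small fixtures to 1e-6.
* **Weights** are frequency-type multipliers of per-patient log-likelihood
  contributions (the `glmer` convention). Note that the random-effect prior
  does not rescale with the weights, so — unlike a fixed-effects GLM — a
  common weight factor is not exactly neutral in a mixed model: `sigma-hat`
  shifts, and fixed effects move slightly. At the design's cluster sizes the
  effect on point estimates is negligible (tested), and all weighting
  methods use weights on their natural scale.
* **gPS estimation** uses a Newton–Raphson maximum-likelihood fit of the
  multinomial logit written for this package (analytic Hessian assembled
  with two BLAS products per iteration, step-halving, covariates
  standardized internally). It typically converges in under ten iterations;
  `nnet::multinom` is available behind `engine = "multinom"` and the test
  suite checks both engines attain the same optimum. The reference category
  is provider 1, matching the assignment model's reference.
* **Quantiles.** All percentiles (weight trimming cap, MMWS quintile strata,
  90th-percentile summary intervals) use the linear-interpolation sample
  quantile (R type 7), fixed so results are bit-reproducible. Ties that
  collapse MMWS strata reduce the effective stratum count, which is
  recorded rather than hidden. No common-support filtering is applied before
  MMWS weighting — deliberately, so the method is evaluated under the same
  conditions as the other weighting schemes.
* **Seeds.** Replicate seeds derive from (master seed, design point,
  replicate index) by an affine map modulo a prime below 2^31 — injective
  over the practical index range and independent of execution order, so any
  subset of replicates can be reproduced in isolation.
* **Failure handling.** A method whose fit errors out (separation,
  non-convergence, a positivity violation in the weights) is recorded as
  failed for that replicate and excluded from that method's summaries, with
  failure counts reported; other methods still consume the identical
  dataset. Undefined measures (PPV with no flags, NPV with all flagged) are
  excluded from means rather than set to zero — eagerness already accounts
  for no-flag replicates — and exclusion counts are reported.

## Problem sizes

The packaged tests and the acceptance script run the design at reduced
scale: 50–100 replicates per design point and K ∈ {10, 20, 30} with 1000
patients per provider (K = 20 for the PPV contrast, K = 30 for fixed-effects
specificity, K = 10 elsewhere, exploiting the reported insensitivity of most
measures to K). Engine-level checks use the full K = 50 × 1000 size. At
these scales per-replicate accuracy measures are coarse — with K = 10 and
P(out) = 0.2 a replicate's sensitivity can only be 0, 0.5 or 1 — so means
carry Monte-Carlo error of a few percentage points; production use should
run `run_grid(scenario_grid(), reps = 1000, ...)`.

## Known limitations

* The case-mix generator preserves the marginal structure of a CABG cohort,
  not its joint distribution; confounding strength depends on that joint
  structure (almost entirely through centered age, whose scale dominates the
  shared-coefficient assignment logit), and with it the absolute sensitivity
  of every method. Orderings between methods are robust to this; absolute
  accuracy levels are not, and should be compared across configurations
  rather than read as universal constants.
* Both the gPS and the outcome models are always correctly specified here
  (they use exactly the eight generating covariates); results say nothing
  about misspecification or unmeasured confounding.
* The outcome generator is a random-intercept model, which structurally
  favors the random-effects analysis methods; a different generating
  mechanism would change the comparison.
* gPS matching and plain gPS stratification are not implemented, nor are
  balance diagnostics across K providers.
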