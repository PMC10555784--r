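---
title: "Measurement error, regression dilution and its correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement error, regression dilution and its correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(undilute)
```

## The problem

When a continuous covariable is measured with random error, the regression
coefficient of an outcome on the *observed* values is attenuated toward the
null relative to the coefficient on the *true* values — regression dilution
bias. Under the classical error model

$$X_{obs} = X_{true} + e, \qquad e \sim N(0, \sigma_e^2), \quad e \perp X_{true},$$

the attenuation factor is the reliability
$R = \mathrm{var}(X_{true}) / \mathrm{var}(X_{obs})$: a simple regression slope
converges to $R\,\beta_{true}$. The same mechanism operates in confounders,
where its net effect on the exposure coefficient can go in either direction.
Cohorts that re-measure a subsample on a second occasion make $R$ estimable,
and `undilute` implements the two standard corrections built on that repeat
subsample, together with the agreement statistics, eligibility screening and a
synthetic cohort generator used to validate the whole chain.

## Agreement statistics

For $n$ participants measured on $k = 2$ occasions, the balanced two-way
(subjects × occasions) ANOVA gives mean squares $MS_R$ (between subjects),
$MS_C$ (between occasions) and $MS_E$ (residual). `anova_decompose()` computes
them through the exact $k=2$ identities
$MS_R = \mathrm{var}(x_1 + x_2)/2$, $MS_C = n\,\overline{(x_1 - x_2)}^2/2$,
$MS_E = \mathrm{var}(x_1 - x_2)/2$, verified in the tests against brute-force
sums over all cells.

`icc_estimate()` supports both single-measurement conventions of the two-way
mixed-effects model:

* **absolute agreement** (default):
  $(MS_R - MS_E) / \{MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E)\}$ — the
  recommended form for test–retest data, since a systematic difference
  between occasions *should* lower agreement;
* **consistency**: $(MS_R - MS_E) / (MS_R + MS_E)$, which ignores the
  occasion effect.

Confidence intervals use the standard F-based closed forms (exact F bounds
for consistency; the Satterthwaite-approximated denominator degrees of
freedom for absolute agreement). Which convention an existing catalogue used
is often unstated; we default to absolute agreement and expose the flag, and
the tests confirm that the two agree under a pure random-error simulation
while absolute agreement drops below consistency once a shift is added.

Systematic error is summarised by Lin's accuracy coefficient
$C_b = 2\sigma_1\sigma_2 / \{\sigma_1^2 + \sigma_2^2 + (\mu_1-\mu_2)^2\}$,
computed with population ($1/n$) moments as originally defined (a sample-
moments variant is available). $C_b \in (0, 1]$, equals 1 exactly when the
occasions agree in mean and spread, and is invariant to swapping occasions or
rescaling both by a common factor.

The correction factor is $\hat\lambda = 1/\widehat{ICC}$. Its sampling
variance is derived from the variance of the ICC estimate by the first-order
delta method, $\mathrm{var}(\hat\lambda) = \mathrm{var}(\widehat{ICC}) /
\widehat{ICC}^4$, so the pair always satisfies
$\mathrm{var}(1/\hat\lambda) = \mathrm{var}(\hat\lambda)/\hat\lambda^4$.
Because no closed-form variance is assumed, `var_icc()` uses a seeded
nonparametric bootstrap over participants (default $B = 1000$), vectorised
through the $k=2$ identities above; the tests calibrate it against the
empirical variance of the estimator over 500 independent simulated datasets.
Negative ICC estimates are reported but flagged, and no correction factor is
emitted for them.

## Correcting a fitted estimate: the reciprocal-ICC route

Given an uncorrected coefficient $\hat\beta$ (difference in means, log odds
or log hazard), the corrected estimate is $\hat\beta^* = \hat\lambda
\hat\beta$. `frost_ci()` propagates the uncertainty of both inputs through
the quadratic-root construction

$$f_0 = \hat\beta^2 - z^2\,\mathrm{var}(\hat\beta), \quad
  f_1 = \hat\beta/\hat\lambda - z^2\,\mathrm{cov}(\hat\beta, 1/\hat\lambda), \quad
  f_2 = 1/\hat\lambda^2 - z^2\,\mathrm{var}(1/\hat\lambda),$$

$$CI = \frac{f_1 \pm \sqrt{f_1^2 - f_0 f_2}}{f_2}.$$

The covariance defaults to 0, appropriate when the repeat subsample is
disjoint from — or a small fraction of — the main sample; a nonzero value is
accepted for sensitivity analyses. $z$ enters symbolically (default 1.96).
Two numerical choices are deliberate: when every variance is zero the
discriminant is an algebraic zero, so tiny negative floating-point residues
(relative to $f_1^2$) are clamped to zero and the interval collapses onto the
point $\hat\lambda\hat\beta$; any genuinely negative discriminant, or
$f_2 \le 0$ (a correction factor too imprecise to support an interval), is an
error rather than a silently clamped bound, because clamping would fabricate
coverage. A simulation test confirms ~95% coverage of the true effect over
500 replicated cohorts.

```{r frost}
correct_ratio_measure(1.203, 1.194, 1.212,
                      lambda = 1.9356, var_inv_lambda = 0.000029)
```

This route corrects the exposure only; random error in confounders needs the
calibration route below.

## Regression calibration with whole-process bootstrap

The two-stage procedure replaces each error-prone covariable by its
conditional expectation given the observed data:

1. **first stage** — on the repeat subsample, OLS of the occasion-2 measure
   on the occasion-1 measure plus all other covariables of the main model
   (occasion-1 values; categorical confounders as indicator contrasts,
   reference = first observed level), complete cases only;
2. **second stage** — the outcome model (linear, logistic or Cox) refit with
   each error-prone covariable's column replaced by its first-stage fitted
   values, predicted for *every* participant.

With several error-prone covariables, one first-stage model runs per
covariable, each adjusted for the *observed* occasion-1 values of the others
(simultaneous, not iterated — the natural reading of the procedure; an
iterated variant would feed calibrated values back in, which we do not do).
Calibration yields consistent estimates for linear models and approximately
unbiased ones for Cox and logistic models.

Naive second-stage standard errors ignore the first-stage uncertainty, so
`bootstrap_calibration()` bootstraps the whole process: participants are
resampled with replacement (one row each, preserving repeat-subsample
membership, so both stages' sampling variability is reproduced jointly),
both stages are refit within each replicate, and the interval is the 2.5/97.5
percentile of the replicate estimates (a normal-approximation interval is
available by flag). Replicates whose repeat subsample is smaller than the
number of first-stage coefficients + 1, or rank deficient, are skipped and
counted; more than 10% skipped aborts. The reference analysis scale is
10 000 replicates; the package tests use a few hundred, which is enough for
the coverage and stability properties they assert. Internally the bootstrap
runs on a prebuilt model matrix (`lm.fit`/`glm.fit`/`coxph` on row subsets);
a test pins its point estimates to the public
`calibrate_cohort()` + `fit_second_stage()` path.

## The four-model comparison

`run_corrected_analysis()` assembles the presentation recommended for
transparency: (i) the uncorrected confounder-adjusted model with Wald
intervals, (ii) the reciprocal-ICC correction of the exposure with the
quadratic-root interval, (iii) regression calibration of the exposure only
and (iv) of the exposure plus all error-prone continuous confounders, both
with whole-process bootstrap percentile intervals. Ratio-family estimates
(Cox, logistic) are reported on the ratio scale. Correcting the exposure
alone can only move the association away from the null (the corrected
coefficient is $\hat\lambda\hat\beta$ with $\hat\lambda \ge 1$ for any
positive ICC $\le 1$); correcting confounders can move it either way.

`person_years_rate()` provides the descriptive event rate per 1000
person-years with a log-normal interval $rate \cdot \exp(\pm z/\sqrt{d})$ by
default (the exact Poisson-quantile interval is available by flag; the two
agree within 1% beyond ~100 events).

## Variable screening

`screen_variables()` reproduces a catalogue-style eligibility pipeline for
wide `<var>__i1` / `<var>__i2` tables. Exclusion reasons are assigned in a
fixed precedence so the reason counts are deterministic: `no_repeat` →
`not_continuous` → `too_many_ties` → `too_few_repeats`. Boundary semantics
are exact: a variable is excluded when more than 20% of participants share
one value (a share of exactly 0.20 passes), when fewer than 100 complete
repeat pairs exist (100 passes), and an integer-valued variable counts as
continuous only with more than 20 distinct values (20 fails). The tie share
is assessed on occasion-1 values, the analysis measure. Threshold-coded
strings such as `"<=1"` are resolved by boundary substitution by default
(configurable to missing): with the originating study's field-specific rules
unavailable, boundary substitution is conservative and exactly invertible in
tests. Multiple readings within a visit collapse by arithmetic mean of the
valid readings (configurable to first-valid). Variables that are unsuitable
as covariables for non-statistical reasons (e.g. data-processing fields) are
left to a user-supplied allowlist; no heuristic is attempted.

## What the synthetic cohort does and does not emulate

`simulate_cohort()` draws latent truths from a multivariate Gaussian with
configured means, sds and correlation; observes them twice under classical
additive error at configured reliability, with an optional constant additive
shift at occasion 2 (emulating an instrument change between visits); samples
the repeat subsample (default 10%, the typical scale of designed repeat
visits) by simple random sampling; and generates outcomes either as Gaussian
responses or as exponential survival times under exact proportional hazards
with administrative censoring at the horizon (default 15 years). When a
target event fraction is requested, the baseline hazard is calibrated by
root-finding on the expected event fraction — this keeps the censoring purely
administrative and non-informative, rather than tuning an artificial
censoring distribution. Every stage is separately seeded from the config
seed, so each generator operation is bit-reproducible on its own.

The generator deliberately satisfies the assumptions under which the
corrections are unbiased: classical (not Berkson) error, independent across
occasions and of the truth; error-free categorical confounders; exact
proportional hazards; missingness in repeats completely at random. Passing
tests therefore demonstrate that the estimators recover known truth *when
the model holds* — they do not certify behaviour under differential error,
true biological change between occasions, seasonal structure, informative
repeat attendance or non-proportional hazards, all of which real cohorts can
exhibit and which the accompanying statistics (notably the accuracy
coefficient) can only partially flag.

```{r example}
cfg <- sim_config(
  n = 4000,
  variables = sim_variables(c("exposure", "conf"),
                            reliability = c(0.5, 0.9),
                            role = c("exposure", "confounder"),
                            beta = c(0.4, 0.2)),
  true_correlation = matrix(c(1, 0.3, 0.3, 1), 2),
  repeat_fraction = 0.2,
  outcome = sim_outcome("cox", target_event_fraction = 0.3),
  seed = 11
)
cohort <- simulate_cohort(cfg)
roles <- covariable_roles("exposure", confounders = "conf",
                          error_prone = c("exposure", "conf"))
run_corrected_analysis(cohort, roles, "cox", reps = 200, boot = 200, seed = 5)
```

## Problem sizes and numerical conventions

The validation suite exercises the estimators at the scales where their
asymptotic properties are visible without waste: moment and correlation
recovery at $n = 10^5$; ICC/reliability recovery at $n$ = 5 000–20 000
(tolerance ±0.02–0.03); attenuation and calibration recovery at
$n$ = 20 000–50 000; interval coverage with 200–500 simulated cohorts of
$n = 2000$ and a few hundred bootstrap replicates. Quantiles for category
summaries use linear interpolation between order statistics
(`stats::quantile` type 7), fixed so interquartile ranges are reproducible.
Complete-case analysis is used at both calibration stages; no imputation is
attempted since none is part of the procedure being implemented.

## Known limitations

* Two measurement occasions only; no rater-population inference, and only
  the accuracy component of Lin's concordance correlation is provided.
* Misclassification of categorical covariables is out of scope — the
  methods here address random error in continuous measures only.
* Non-linear confounder forms, SIMEX, Bayesian measurement-error models,
  competing risks and informative repeat missingness are not implemented.
* The reciprocal-ICC route corrects the exposure only; by construction it
  cannot address confounder error, which is what the calibration route is
  for.
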