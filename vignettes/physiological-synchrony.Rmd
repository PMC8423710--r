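---
title: "Stability-and-influence models for group physiological synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-and-influence models for group physiological synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Physiological synchrony (PS) is the co-occurrence and interdependence of
physiological activity between interaction partners. In a group
stress-induction setting, every member of a small group (2--4 people)
provides a short endocrine time series -- here seven saliva samples at
roughly 13-minute intervals, assayed for cortisol (HPA axis) and
alpha-amylase (sympathetic activity), alongside self-rated stress. The
question is whether one member's level helps predict another member's level
*beyond* that person's own dynamics, and how a stressor changes this.

`groupsync` implements the full analysis chain: exclusion screening,
baseline-anchored response summaries (AUC-I), dyad expansion, the
stability-and-influence multilevel model, stepwise model building,
cross-correlation descriptives, and a synthetic-data generator with known
ground truth, because the motivating study's raw data are not publicly
deposited. Every stage is exercised by simulation-based recovery tests.

## The model

Groups are expanded into all ordered sender--receiver dyads (a triad
A, B, C yields A-B, B-C, A-C, B-A, C-B, C-A), each participant acting as
sender and as receiver. For receiver *i* at occasion *t* the dyadic growth
model is

y_ti = b00 + b10 * time_ti + b20 * y_(t-1)i + b30 * condition_i
     + b40 * S_ti + b50 * S_(t-1)i + U_0i + U_1i * time_ti + e_ti

with raw (non-orthogonal) linear, quadratic and cubic time, the receiver's
own lagged value (the *stability* portion), the sender's concurrent and
lagged values (the *influence* portion -- the operational definition of PS),
condition, their interaction products, participant-level random intercept
and time slopes, and Gaussian residuals. Level-1 predictors (`y_lag`, `s`,
`s_lag`) are grand-mean centred; time is left uncentred. Term names in
`silm_spec()` say what they measure: `receiver_lagged`, `sender`,
`sender_lagged`, `minute`, `minute2`, `minute3`, `condition`, and `:`
products thereof.

```{r}
library(groupsync)
sim <- simulate_panel(sim_config(), seed = 1)
dy  <- build_dyad_table(sim$panel, "cortisol", k = 1, roster = sim$roster)
st  <- stepwise_build(dy, candidates = silm_candidates("core"))
st$trail
sequential_f_tests(st$fit)
```

Estimation is by `nlme` (the natural tool for this two-level design, with
containment-style denominator degrees of freedom: tests of
participant-constant terms use `n_participants - p_outer - 1`, tests of
within-participant terms `n_obs - n_participants - p_inner`). Convergence
uses a relative log-likelihood tolerance of 1e-8 and at most 500 iterations;
an unstructured random-effects covariance that fails to converge triggers an
automatic diagonal refit with a warning.

### Stepwise building

Candidates are tested in a fixed order -- random intercept, random time
slopes, then fixed blocks (condition, its trajectory interactions,
stability, sender influence), then screened covariates. A more complex model
is adopted only when the likelihood-ratio test is significant at 0.05 *and*
AIC improves; ties go to the simpler model. Random-structure steps are
compared under REML with identical fixed effects, fixed-effect steps under
ML, and the final model is refit with REML for reporting. The `"core"`
preset deliberately includes the time-by-condition block before the sender
candidates: without it, shared condition-specific mean-trajectory misfit
masquerades as sender influence, and an uncoupled channel acquires spurious
sender terms.

### ICC and variance explained

The intraclass correlation is reported from the random-intercept model
(`sigma2_U0 / (sigma2_U0 + sigma2_e)`); once random slopes enter, the
intercept variance changes meaning, so the pipeline reports the
intercept-step ICC separately (`icc_intercept_model`). R-squared follows the
variance-partition convention: marginal = var(X beta) over the sum of fixed,
random and residual variance; conditional adds the (design-averaged) random
variance to the numerator.

## Cross-correlation descriptives

`cross_correlation()` uses the standard sample CCF convention -- full-series
means and n-denominator standard deviations -- and `ccsl()` the conventional
white-noise limit z_(1-alpha/2)/sqrt(n). With n = 7 samples the limit is
about 0.741. Two caveats are documented rather than hidden: the bound is
asymptotic (the exact null exceedance of |r| at n = 7 is about 5.7%, not
5%), and it presumes white noise, so autocorrelated or co-trending series
exceed it more often -- which is precisely why many lag-0 pairs in a
stress-pulse panel look "significant". The critical multiplier is a config
value (`multiplier = 2` gives the rougher conventional bound).

## AUC with respect to increase

`auc_increase()` is the baseline-anchored trapezoid:
`sum((m_i + m_{i+1})/2 * (t_{i+1} - t_i)) - m_1 * (t_M - t_1)`. Positive
values mean an overall rise from the first sample, negative an overall
decline; it is invariant to shifting the whole series.

## Exclusion rules and covariate screening

Three screening rules mirror endocrine practice: *prior responders* (first
sample is the series maximum and the series never increases afterwards --
non-strict monotonicity tolerates plateaus, since no numeric threshold is
published), *3-SD outliers* (person-mean more than three SD above the grand
mean of person-means -- a person-mean captures "very high levels throughout"),
and *all-zero* series (an amylase assay artifact). Covariates are screened by
Pearson correlation with the person-mean outcome (one value per participant,
avoiding pseudo-replication; the original report does not state which
variant was used) and selected at p < 0.05, per analyte.

## The synthetic generator

`sim_config()` encodes the study conditions: 44 groups with size weights
giving a mean near 3.1, about half the groups stressed, M = 7 samples at
13-minute intervals (midpoint of the reported 12--15-minute scheme). Each
analyte channel (`channel_config()`) has:

* a condition-specific mean trajectory -- controls drift linearly
  (`baseline + delta*t`); the stress arm follows a single-peaked pulse
  `baseline + A*u*exp(1-u)`, `u = (t - t0)/theta`. The pulse shape is a
  modelling choice (no functional form is published): it is single-peaked
  with delayed onset like observed cortisol curves and has a closed-form
  maximum `baseline + A` at `t0 + theta`, which the tests exploit;
* a person baseline offset `b_i ~ N(0, sigma_b^2)` plus additive covariate
  effects, both folded into the person-specific level and subtracted when
  forming deviations `d`;
* deviation dynamics: stability `rho*d_(t-1)`, coupling
  `(gamma + gamma_mod*d_(t-1,i)) * mean of the other members' lagged
  deviations`, a shared within-group shock `eta*g_t`, and residual noise.
  Defining coupling on deviations from the person-specific mean curve keeps
  `rho` and `gamma` stationary and separable from the shared trajectory;
* optional per-person amplitude heterogeneity (`amplitude_sd`, default 0)
  and a clamp for bounded scales (VAS 0--10).

Channel defaults: cortisol sigma_b = 2.4, sigma_e = 1.5 nmol/l (an
intercept-share around 0.7), rho = 0.5, gamma = 0.3, eta = 0.5; amylase is
coupled with a receiver-state moderation (gamma_mod > 0); subjective stress
is generated *uncoupled* (gamma = eta = 0), reflecting the absence of
emotional synchrony. The cortisol time-of-day slope (-0.8 nmol/l per hour,
earlier sessions higher) and the amylase BMI slope (-1.5 U/ml per kg/m2,
higher BMI lower amylase) are calibrated so that the covariates' share of
person-level variance matches the strength of the published covariate
statistics (F around 35--39 at 130-ish denominator df).

What the generator does **not** emulate: log-normal assay error and
heteroskedasticity, pulsatile ultradian secretion, circadian shape beyond a
linear time-of-day term, missing samples, or floor effects in cortisol.
Passing recovery tests therefore show the *method* recovers known structure
of this generative family -- not that real saliva data satisfy the model.

## Findings from the simulation studies worth knowing

These emerged from the package's own Monte-Carlo suites (sizes below) and
are properties of the stacked-dyad design, not implementation defects:

* **Duplicated receiver rows.** In triads and quads every receiver row
  appears once per sender. The perfectly correlated duplicates mimic
  person-by-time random effects: random slopes are "adopted" in most
  replicates even when the generative truth has none. Structure-recovery
  checks therefore use pair groups, where each receiver appears once per
  occasion.
* **Size of the sender tests.** Under the null (gamma = eta = 0, flat
  trajectory, study-default variances) the sequential-F size of the sender
  tests is parameter-dependent: the concurrent test runs conservative
  (about 1.4% at nominal 5% over 500 replicates) while the lagged test is
  close to nominal (about 5.8%). When residual variance dominates the mix
  the concurrent test instead inflates (reciprocal rows share
  `E[e_At * y_At] = sigma_e^2`). The acceptance suite records both rates.
* **Growth-curve terms absorb dynamics.** With only seven occasions,
  person-specific random time slopes largely absorb AR(1)-like deviation
  dynamics; after slopes are adopted, stability and moderate coupling
  (gamma = 0.3) add little to the likelihood. Coupling-recovery checks
  therefore run on flat-trajectory panels where the dynamics are
  identified.

Simulation sizes used by the test and acceptance suites: 500 null
replicates for test size, 200 replicates per gamma in {0, 0.2, 0.4, 0.6}
for coupling recovery, 100 strong-coupling and 200 null replicates for
stepwise adoption, 100 replicates for the moderation direction, 200 panels
for CCF null calibration, and 501 participants for ICC recovery -- each on
48 triads (or the stated size), chosen to keep Monte-Carlo error well below
the asserted margins.

## Known limitations

* Dyad rows are modelled as conditionally independent given the receiver's
  random effects; no dyad-level random effect is fitted by default, so
  standard errors of concurrent-influence terms inherit the calibration
  caveats above.
* Containment df reproduce the two-level reporting convention, not
  Satterthwaite/Kenward-Roger small-sample corrections.
* Lags k >= 2 are supported by the API but untested against ground truth;
  the default pipeline uses k = 1 (and k = 0 implicitly via the concurrent
  sender term).
* Whether level-1 centering should be done within condition is an open
  design question; grand-mean centering is the default and a flag.
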