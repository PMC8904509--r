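---
title: "Models and methods: exploration under time pressure in four-armed bandits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: exploration under time pressure in four-armed bandits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`banditrt` implements a complete simulation-and-analysis pipeline for a
four-armed bandit task with a within-subject time-pressure manipulation: the
task itself, a Bayesian learner of per-option reward beliefs, a hierarchical
softmax choice model with an uncertainty-directed exploration bonus, a Linear
Ballistic Accumulator (LBA) for joint choice and response-time data, and
hierarchical regressions linking belief-derived predictors to response times
and drift rates. This vignette explains each model, its assumptions, the
tunable parameters, and the numerical and design choices the package makes.

## The task

Participants play 40 rounds of 20 trials. Each round pairs one of four
payoff conditions (`igt`, `low_var`, `high_var`, `equal_means`; see
`payoff_conditions()`) with one of two time conditions, in a crossed design
with exactly 5 repetitions per cell, order randomized per session. Rewards
are drawn from the option's normal distribution, plus a per-round uniform
shift on [30, 60] so displayed rewards are positive and round-relative. In
*limited* rounds a response slower than 400 ms forfeits the reward (the
crossed-out value is still shown). A round's performance bonus is
`(total / (best * 20))^4 * $4.00`.

Two details the task description leaves open, and what the package does:

* **Reward positivity.** Rewards are "always larger than zero" after
  shifting, but the mechanism is unspecified. The package redraws the normal
  sample until the shifted value is positive, rather than clipping, because
  redrawing preserves the distribution's shape. The redraw probability is at
  most `pnorm(-2)` (high-variance arm at the minimal shift of 30) and below
  `3e-4` at typical shifts, so the generative means/variances are
  effectively unchanged — except exactly at the worst-case corner, which the
  tests avoid when checking moment convergence.
* **Timeouts for simulated agents.** Only agents that emit an RT (e.g. via
  the LBA race) can time out; an agent without a response-time model has
  `rt_ms = NA` and never times out.

## The Bayesian mean tracker

Each option j carries an independent normal posterior over its mean reward,
updated only when chosen, by the delta rule with Kalman gain
`G = v / (v + error_variance)`:

```
m' = m + G (y - m)        v' = (1 - G) v
```

This is exactly the conjugate normal–normal posterior (the package's oracle
test checks agreement to 1e-10), and the static-mean special case of the
Kalman filter — appropriate because the reward distributions do not drift.
Defaults: prior mean 0 and prior variance 1100 (= 55 × 20) on the unshifted
reward scale; the error variance is the true generative variance of the
chosen option (a fitted scalar can be substituted for sensitivity analyses,
off by default). Learning uses **unshifted** rewards.

Replaying a participant's choices and rewards yields, per trial, the
*prior-predictive* beliefs (the posterior after trials 1..t-1), from which
three predictors are computed:

* **relative reward** — chosen option's posterior mean minus the average of
  the unchosen options';
* **relative uncertainty** — the same contrast on posterior standard
  deviations;
* **total uncertainty** — the summed posterior standard deviation.

Two open points and the package's choices: (1) the sum-vs-average reading of
total uncertainty — the package computes the sum as the canonical regressor
and exposes `total_uncertainty_avg = sum/4` for trajectory plots; after
z-standardization the two are identical as regressors. (2) Whether timed-out
trials update beliefs — the forfeited payoff was displayed, so by default
they do (`bmt_config(include_timeouts = FALSE)` switches this off; the
choice likelihood, by contrast, excludes timed-out trials by default since
no reward was earned).

## The hierarchical softmax choice model

Choice probabilities are a softmax over decision values

```
Q_j = alpha * (m_j + beta * sd_j) + gamma * 1[j = previous choice]
```

with posterior means and standard deviations min–max scaled to [0, 1]
(globally over the dataset, constants stored for reuse and inversion;
per-participant scaling would make `alpha` incomparable across
participants). `alpha` indexes value-directed choice (its inverse, random
exploration), `beta` the uncertainty bonus (directed exploration), `gamma`
stickiness. The stickiness term is omitted on trial 1, where no previous
choice exists. Each of the three parameters has a limited-time baseline and
an unlimited-time offset per participant, drawn independently from normal
group distributions — six group means and six group standard deviations.

**Priors.** The package uses weakly informative group priors on the natural
scale of the parameters: `mu0 ~ N(0, 10^2)` for group means and a
half-normal `N(0, 5^2)` on group standard deviations. A unit-normal prior
on the group means — occasionally quoted for models of this family — cannot
be reconciled with group-level `alpha` estimates near 9 under [0, 1]-scaled
predictors: with realistic between-participant spread it would shrink the
posterior mean by 10–30%. The half-normal is placed on the standard
deviation rather than the variance for the usual reasons (interpretable
scale, no pile-up at 0).

**Sampler.** Estimation is Metropolis-within-Gibbs: componentwise adaptive
random-walk updates of each participant's six-parameter block (step sizes
tuned to a 0.44 acceptance rate during warmup), exact conjugate updates of
the group means, and adaptive Metropolis on the log of each group standard
deviation. Defaults are 4 chains × 4000 iterations with 1000 warmup;
reduced settings (2 × 1500) are used in the smoke-scale recovery studies.
Convergence is summarized by split-Rhat and an autocorrelation-based
effective sample size; fits with any split-Rhat at or above 1.01 are flagged
`converged = FALSE` but retained.

**Parameter recovery and the scaling pitfall.** A generator cannot know the
dataset's min–max before generating the choices that produce the dataset,
so `simulate_cohort()` scales beliefs with fixed task-derived limits —
posterior means over [-30, 30], standard deviations over [0, sqrt(1100)] —
and stores them in the ground truth. Recovery studies fit with these stored
constants. Re-deriving min–max from the generated data would multiply
`alpha` and `beta` by the ratio of ranges (typically 10–20%), a
preprocessing mismatch rather than an estimation failure; with matched
constants the posterior intervals are approximately calibrated, which is
what the recovery suite checks (group-mean intervals covering the
generating values, which default to the reported human estimates:
alpha 7.31/9.21, beta 0.16/0.26, gamma 1.91/1.58 for limited/unlimited).

## The Linear Ballistic Accumulator

Evidence for each option accumulates linearly from a uniform start point on
[0, A] at a trial-level drift drawn from `N(v_j, s^2)`, until threshold
`b = A + k`; the winner sets the choice and RT = finishing time + tau. The
defective density of (choice j, RT t) is the winner's first-passage density
times the survival of the other accumulators. The drift scale is fixed at
`s = 1` — the conventional identifiability constraint; it is configurable.
Priors follow the standard Bayesian LBA parameterization: drifts
`N(2,1)` truncated positive, `A` and `k` `N(0.5,1)` truncated positive,
`tau ~ U(0,1)`. Trial-level drifts are *not* truncated, and the
all-negative-drift normalization term is omitted (its mass is below 1e-6 in
fitted regimes; the simulator counts redraws so this is monitored).

Numerical contracts: RTs at or below `tau` get zero density by contract
(a floored log-density of `log(1e-10)`, counted, never an exception); RTs
above 5000 ms are excluded before fitting, with the exclusion count kept;
timed-out trials in limited rounds are included by default (a late key was
still pressed).

Fitting is per participant-round (the task's unit of stationarity for
thresholds) by differential-evolution MCMC — the field's standard sampler
for LBA posteriors — with a population of 24 chains proposing jumps along
scaled difference vectors of two other chains; parameters are sampled on
log/logit scales with the exact Jacobian. At 200 trials, posterior means of
drifts and threshold recover generating values within 15%. At the task's
20-trial rounds, recovery is intentionally noisy: rarely-chosen options'
drift posteriors sit close to the common prior, which compresses the lower
ranks of the posterior-mean drifts. In the package's rank-preservation
study (equally spaced generating drifts [3.5, 2.75, 2.0, 1.25] spanning the
prior's ±1.5 sd), the exact four-way ordering is preserved in roughly 70%
of rounds — a known limitation of per-round fitting at this trial count,
reported as measured rather than idealized.

## Linking beliefs to RTs and drift rates

Two Bayesian hierarchical Gaussian regressions share one engine
(`fit_bhlm()`), an exact conjugate Gibbs sampler: fixed effects with
`N(0, 1)` priors (all variables standardized), independent random
intercepts and slopes per participant with inverse-gamma variance priors
(`IG(1.5, 0.25)`, weakly informative while allowing collapse to zero when
there is no group structure), and `IG(1, 0.5)` on the residual variance.

* **RT regression:** log(RT + 1 ms), clipped at 5000 ms, z-standardized,
  regressed on relative reward, relative uncertainty, total uncertainty,
  and round number, each interacting with time condition, plus pairwise
  interactions among the belief predictors.
* **Drift regression:** per-option posterior-mean drifts regressed on the
  same belief predictors computed *for each option* (its mean/sd minus the
  average of the others') and averaged over the round's trials, because the
  LBA is fitted per round.

On pure-noise outcomes the fixed-effect intervals cover zero at their
nominal rate; with generating weights set to the reported effects
(RT: -0.08, +0.15, +0.22; drift: +0.35, -0.35, -0.05) the signs are
recovered and the total-uncertainty effect is correctly the weakest.

## The synthetic-cohort generator

`simulate_cohort()` composes the pieces into a generative model: softmax
parameters per participant from the group distributions; beliefs evolving
with each simulated choice; choices from the softmax; and RTs from an LBA
race whose four drift rates are an affine function of the current
(standardized) belief predictors — intercept 2.5, weights +0.35 (relative
reward), -0.35 (relative uncertainty), -0.05 (total uncertainty), floored
at 0.05. The race's structure parameters differ by time condition
(limited: A = 0.30, k = 0.35, tau = 0.15 s; unlimited: A = 0.80, k = 0.60,
tau = 0.25 s), giving limited-round RTs around 250 ms with a realistic
minority of deadline misses, and unlimited RTs around 600 ms. The
generator inverts the analysis pipeline's direction (the analysis estimates
drifts, then regresses them on predictors; the generator constructs drifts
from predictors) — the simplest generative model consistent with the
regression structure. One master seed fans out to per-participant streams,
so cohorts are reproducible and participants independent.

Between-participant standard deviations of the softmax parameters are not
reported for the human cohort; the generator defaults to 20% of each group
mean — enough heterogeneity to exercise the hierarchy without degenerate
participants.

What the generator does *not* emulate: reward-magnitude effects on motor
vigor, practice/fatigue drifts across rounds, lapses, and any dependence of
learning itself on time pressure. Passing recovery tests therefore show
that the estimation machinery is correct and calibrated under the model's
own assumptions, not that the model is true of human data.

## Problem sizes used by the test suite

The package's checks run at deliberately reduced scale, chosen to keep the
full suite in the tens of minutes while leaving each property detectable:
recovery cohorts of 16 participants × 40 rounds with 2 × 1500 MCMC
(3 replicates in the smoke suite), 30–50 replicates for the 20-trial LBA
rank study, 10^6 races for the Monte-Carlo density comparison, and
full-scale (99 × 40 × 20) cohorts only for cheap descriptive statistics.
The multi-replicate coverage study at publication scale (20+ cohorts,
full-length chains) is a scheduled run of the same functions.

## Known limitations

* The six softmax parameter blocks are modeled as independent normals; the
  correlation structure across blocks (and the multivariate formulation) is
  an extension, not implemented.
* Random effects in the regressions are independent (no intercept–slope
  correlations), a deliberate simplification of the maximal structure.
* DE-MCMC split-Rhat for the LBA's A/k/tau often sits above 1.1 at
  realistic iteration counts because of the threshold/non-decision-time
  ridge; drift posteriors converge much faster, and only drifts feed the
  downstream regression.
* `fit_choice_mle()` is a convenience for validation, not a substitute for
  the hierarchical fit; at single-round scale its estimates are unstable.
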