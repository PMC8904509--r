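# banditrt

Simulation and model-based analysis of four-armed bandit tasks with a
within-subject **time-pressure** manipulation, for researchers studying the
exploration–exploitation trade-off with behavioral, reaction-time (RT), and
evidence-accumulation analyses.

The task crosses four payoff conditions (each a set of four normal reward
distributions, Table below) with limited (400 ms deadline) vs. unlimited
decision time, over 40 rounds × 20 trials. The package provides every stage
of the analysis as composable, pipe-friendly functions over tibbles:

1. **Task engine** — session plans with exactly 5 rounds per design cell,
   reward sampling with uniform shifting on [30, 60] and guaranteed
   positivity, the `(total / (best × 20))⁴ × $4` performance bonus, and
   simulation of arbitrary choice policies.
2. **Bayesian mean tracker (BMT)** — per-option conjugate normal beliefs
   `m′ = m + G(y − m)`, `v′ = (1 − G)v` with Kalman gain
   `G = v/(v + θ²ε)`; trial-wise predictors *relative reward*, *relative
   uncertainty*, *total uncertainty*.
3. **Hierarchical softmax choice model** —
   `Q_j = α(m_j + β√v_j) + γ·1[j = prev]`, `P(C = j) ∝ exp(Q_j)`, with
   per-participant limited-time baselines plus unlimited-time offsets for
   α (value-directedness), β (uncertainty-directed exploration bonus), and
   γ (stickiness), fitted by Metropolis-within-Gibbs MCMC.
4. **Linear Ballistic Accumulator** — defective first-passage likelihood,
   forward simulation, and per-participant-per-round Bayesian fits by
   differential-evolution MCMC with truncated-normal priors
   (v ~ N(2,1)⁺, A, k ~ N(0.5,1)⁺, τ ~ U(0,1); threshold b = A + k).
5. **Hierarchical regressions** — log-RTs and per-option drift rates on the
   BMT predictors (× time condition, with pairwise interactions and random
   intercepts/slopes per participant), via an exact conjugate Gibbs sampler.
6. **Synthetic cohorts** — a full generative model (BMT + softmax choices,
   LBA-race RTs with belief-linked drifts) with stored ground truth for
   parameter-recovery studies, plus descriptive statistics (learning
   curves, choice entropy, repeat choices, chance-normalized choice
   proportions).

| condition | means | variances |
|---|---|---|
| `igt` | −10, −10, 10, 10 | 10, 100, 10, 100 |
| `low_var` | −10, −1/3, 1/3, 10 | 10, 10, 10, 10 |
| `high_var` | −10, −1/3, 1/3, 10 | 100, 100, 100, 100 |
| `equal_means` | 0, 0, 0, 0 | 10, 40, 70, 100 |

## Worked example

```r
library(banditrt)
library(dplyr)

# simulate a small cohort with known parameters
cohort <- simulate_cohort(cohort_spec(n_participants = 6, n_reps = 2),
                          seed = 404)
pred <- bmt_predictors(cohort$trials)

round_summaries(cohort$trials) |>
  group_by(time_condition) |>
  summarise(entropy = mean(entropy), repeats = mean(repeat_proportion))
#> # A tibble: 2 × 3
#>   time_condition entropy repeats
#>   <chr>            <dbl>   <dbl>
#> 1 limited          0.991   0.695
#> 2 unlimited        1.02    0.598
```

Time pressure (here induced by the generator's higher limited-time
stickiness, γ 1.91 vs 1.58) lowers the Shannon entropy of round choices
(chance level ln 4 ≈ 1.386) and raises the proportion of repeat choices —
the behavioral signature of perseveration under deadline.

```r
fit <- fit_choice_model(pred, scaling = cohort$truth$scaling,
                        chains = 2, iter = 1500, warmup = 500, seed = 1)
tidy(fit)            # posterior means + 95% intervals for the six
                     # effective group parameters
recovery_report(fit, cohort)$group   # coverage of the generating values
autoplot(fit)        # interval plot

# LBA on one round's choices and RTs
one <- cohort$trials |> filter(participant_id == "p001", round == 1)
lba <- fit_lba(one$rt_ms / 1000, one$choice, seed = 2)
tidy(lba)
```

`plot_learning_curves()`, `plot_bmt_trajectories()`, and
`plot_choice_proportions()` reproduce the standard descriptive views;
`fit_rt_regression()` and `build_drift_design() |> fit_drift_regression()`
give the RT and evidence-accumulation analyses; `run_pipeline()` writes all
stage outputs with a checksummed manifest.

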