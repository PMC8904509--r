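# Shared fixtures, built in code at test time.

# A small cohort reused by several test files (generated once per run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(cohort_spec(n_participants = 6, n_reps = 2),
                                seed = 404)
    }
    cache
  }
})

# Closed-form conjugate normal-normal posterior after one observation:
# the independent oracle for the Bayesian mean tracker update.
conjugate_posterior <- function(m0, v0, y, err_var) {
  v1 <- 1 / (1 / v0 + 1 / err_var)
  m1 <- v1 * (m0 / v0 + y / err_var)
  list(m = m1, v = v1)
}

# Deterministic trial table for metric tests.
toy_round <- function(choices, rewards = seq_along(choices),
                      participant = "p1", round = 1,
                      time_condition = "unlimited", payoff = "low_var") {
  tibble::tibble(
    participant_id = participant, round = round,
    time_condition = time_condition, payoff_name = payoff,
    trial = seq_along(choices), choice = choices,
    reward_unshifted = rewards, reward_shifted = rewards + 45,
    rt_ms = 500, timeout = FALSE
  )
}
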