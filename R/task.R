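#' Payoff conditions of the four-armed bandit task
#'
#' Returns the four within-subject payoff conditions. Each condition defines a
#' normal reward distribution \eqn{N(\mu_j, \sigma^2_j)} for each of the four
#' options, on the unshifted scale (a per-round uniform shift on \[30, 60\] is
#' added before display so that experienced rewards are always positive).
#'
#' * `igt`: two low-mean and two high-mean options, each pair with a low- and
#'   a high-variance member (inspired by the Iowa Gambling Task).
#' * `low_var`: equally spaced means, uniformly low variance.
#' * `high_var`: the same means, uniformly high variance.
#' * `equal_means`: identical means, gradually increasing variance, isolating
#'   the influence of uncertainty from reward.
#'
#' @return A tibble with columns `payoff_name`, `option` (canonical index
#'   1..4), `mean`, and `variance`.
#' @export
#' @examples
#' payoff_conditions()
payoff_conditions <- function() {
  tibble::tibble(
    payoff_name = rep(c("igt", "low_var", "high_var", "equal_means"), each = 4L),
    option      = rep(1:4, times = 4L),
    mean        = c(-10, -10, 10, 10,
                    -10, -1 / 3, 1 / 3, 10,
                    -10, -1 / 3, 1 / 3, 10,
                    0, 0, 0, 0),
    variance    = c(10, 100, 10, 100,
                    10, 10, 10, 10,
                    100, 100, 100, 100,
                    10, 40, 70, 100)
  )
}

payoff_names <- function() c("igt", "low_var", "high_var", "equal_means")

payoff_lookup <- function(payoff_name) {
  tab <- payoff_conditions()
  if (!payoff_name %in% payoff_names()) {
    stop("unknown payoff condition: ", payoff_name, call. = FALSE)
  }
  tab[tab$payoff_name == payoff_name, ]
}

#' Sample rewards for one option of a payoff condition
#'
#' Draws unshifted rewards from the option's normal distribution and adds the
#' round's uniform shift. Rewards experienced by participants are always
#' positive: draws whose shifted value would be non-positive are redrawn
#' (rather than clipped), which preserves the distribution's shape; with a
#' shift of at least 30 and standard deviations of at most 10 the redraw
#' probability is negligible.
#'
#' @param payoff_name One of `"igt"`, `"low_var"`, `"high_var"`,
#'   `"equal_means"`.
#' @param option Canonical option index (1..4).
#' @param shift The round's reward shift, on \[30, 60\].
#' @param n Number of draws.
#' @return A tibble with columns `reward_unshifted` and `reward_shifted`
#'   (`reward_shifted = reward_unshifted + shift > 0`).
#' @export
#' @examples
#' set.seed(1)
#' sample_reward("low_var", option = 4, shift = 45, n = 3)
sample_reward <- function(payoff_name, option, shift, n = 1L) {
  if (!(length(option) == 1L && option %in% 1:4)) {
    stop("`option` must be a single index in 1..4", call. = FALSE)
  }
  if (shift < 30 || shift > 60) {
    stop("`shift` must lie in [30, 60]", call. = FALSE)
  }
  row <- payoff_lookup(payoff_name)[option, ]
  y <- stats::rnorm(n, row$mean, sqrt(row$variance))
  bad <- which(y + shift <= 0)
  while (length(bad) > 0L) {
    y[bad] <- stats::rnorm(length(bad), row$mean, sqrt(row$variance))
    bad <- bad[y[bad] + shift <= 0]
  }
  tibble::tibble(reward_unshifted = y, reward_shifted = y + shift)
}

#' Build the round plan of one session
#'
#' Constructs the 40-round session of the task: a 2 (time pressure: limited
#' vs. unlimited) x 4 (payoff condition) within-subject design with each cell
#' repeated exactly 5 times, in randomized order (sampling without replacement
#' from the full crossed list). Each round gets a fresh random key mapping
#' (the permutation of canonical options onto display keys) and a fresh reward
#' shift drawn uniformly on \[30, 60\].
#'
#' @param participant_id Identifier stored with the plan.
#' @param n_reps Repetitions per design cell (default 5, giving 40 rounds).
#' @param n_trials Trials per round (default 20).
#' @return A tibble with one row per round: `participant_id`, `round`,
#'   `time_condition`, `payoff_name`, `reward_shift`, and `key_mapping`
#'   (a list column of permutations of 1:4).
#' @export
#' @examples
#' set.seed(1)
#' plan <- build_session("p01")
#' dplyr::count(plan, time_condition, payoff_name)
build_session <- function(participant_id, n_reps = 5L, n_trials = 20L) {
  cells <- tidyr::expand_grid(
    time_condition = c("limited", "unlimited"),
    payoff_name = payoff_names(),
    rep = seq_len(n_reps)
  )
  n_rounds <- nrow(cells)
  ord <- sample.int(n_rounds)
  plan <- cells[ord, c("time_condition", "payoff_name")]
  plan$participant_id <- as.character(participant_id)
  plan$round <- seq_len(n_rounds)
  plan$n_trials <- as.integer(n_trials)
  plan$reward_shift <- stats::runif(n_rounds, 30, 60)
  plan$key_mapping <- purrr::map(seq_len(n_rounds), ~ sample.int(4L))
  dplyr::select(
    plan, "participant_id", "round", "time_condition", "payoff_name",
    "n_trials", "reward_shift", "key_mapping"
  )
}

#' Performance bonus for one round
#'
#' The round bonus is the fraction of the best attainable total reward,
#' raised to the fourth power (accentuating the upper performance range) and
#' scaled to a maximum of $4.00:
#' \deqn{bonus = (total / (best \times n))^4 \times 4}
#'
#' @param total_reward Total shifted reward gained in the round.
#' @param best_option_mean Mean shifted reward of the best option (must be
#'   positive).
#' @param n_trials Trials per round (default 20).
#' @param max_bonus Maximum bonus in dollars (default 4).
#' @return The bonus in dollars, clipped to \[0, `max_bonus`\].
#' @export
#' @examples
#' compute_bonus(20 * 50, 50)        # perfect play: $4.00
#' compute_bonus(10 * 50, 50)        # half: 0.5^4 * 4 = $0.25
compute_bonus <- function(total_reward, best_option_mean, n_trials = 20L,
                          max_bonus = 4) {
  if (any(best_option_mean <= 0)) {
    stop("`best_option_mean` must be positive (shifted scale)", call. = FALSE)
  }
  ratio <- total_reward / (best_option_mean * n_trials)
  pmin(pmax(ratio, 0)^4 * max_bonus, max_bonus)
}

#' Run a choice policy through a session plan
#'
#' Plays an agent (an R function) through each round of a session plan,
#' sampling rewards from the round's payoff condition. The agent is called
#' once per trial with a context list and must return the canonical index of
#' the chosen option, or a list with elements `choice` and (optionally)
#' `rt_ms`. In limited-time rounds a returned RT above the deadline marks the
#' trial as a timeout (reward forfeited); the sampled reward is still
#' recorded, since its (crossed-out) value was displayed. Agents that emit no
#' RT get `rt_ms = NA` and can never time out.
#'
#' The context passed to the agent has elements `round` (the plan row),
#' `trial`, `prev_choice` (NA on trial 1), and `history` (tibble of the
#' round's previous choices and unshifted rewards).
#'
#' @param agent Function of one argument (the context) returning a choice.
#' @param plan A session plan from [build_session()].
#' @param deadline_ms Response deadline in limited-time rounds (default 400).
#' @return A tibble of trial records: `participant_id`, `round`,
#'   `time_condition`, `payoff_name`, `trial`, `choice`, `reward_unshifted`,
#'   `reward_shifted`, `rt_ms`, `timeout`.
#' @export
#' @examples
#' set.seed(1)
#' uniform_agent <- function(ctx) sample.int(4L, 1L)
#' trials <- run_agent_session(uniform_agent, build_session("p01"))
#' nrow(trials)  # 800
run_agent_session <- function(agent, plan, deadline_ms = 400) {
  rounds <- purrr::map(seq_len(nrow(plan)), function(r) {
    row <- plan[r, ]
    n_t <- row$n_trials
    choice <- integer(n_t)
    y <- numeric(n_t)
    ys <- numeric(n_t)
    rt <- rep(NA_real_, n_t)
    for (t in seq_len(n_t)) {
      ctx <- list(
        round = row,
        trial = t,
        prev_choice = if (t > 1L) choice[t - 1L] else NA_integer_,
        history = tibble::tibble(
          trial = seq_len(t - 1L),
          choice = choice[seq_len(t - 1L)],
          reward_unshifted = y[seq_len(t - 1L)]
        )
      )
      out <- agent(ctx)
      if (is.list(out)) {
        ch <- out$choice
        if (!is.null(out$rt_ms)) rt[t] <- out$rt_ms
      } else {
        ch <- out
      }
      if (!(length(ch) == 1L && !is.na(ch) && ch %in% 1:4)) {
        stop("agent returned an invalid option index", call. = FALSE)
      }
      choice[t] <- as.integer(ch)
      rw <- sample_reward(row$payoff_name, choice[t], row$reward_shift)
      y[t] <- rw$reward_unshifted
      ys[t] <- rw$reward_shifted
    }
    tibble::tibble(
      participant_id = row$participant_id,
      round = row$round,
      time_condition = row$time_condition,
      payoff_name = row$payoff_name,
      trial = seq_len(n_t),
      choice = choice,
      reward_unshifted = y,
      reward_shifted = ys,
      rt_ms = rt,
      timeout = row$time_condition == "limited" & !is.na(rt) & rt > deadline_ms
    )
  })
  dplyr::bind_rows(rounds)
}
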