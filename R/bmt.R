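#' Bayesian mean tracker configuration
#'
#' The Bayesian mean tracker (BMT) maintains, for each option, an independent
#' normal posterior over its mean reward, assuming normally distributed
#' rewards with known variance. It is the static-mean special case of the
#' Kalman filter and a Bayesian analogue of the Rescorla-Wagner delta rule.
#'
#' Defaults follow the task's unshifted reward scale: prior mean 0 (the
#' expectation across payoff conditions) and prior variance 55 * 20 = 1100
#' (the cross-condition expected variance scaled by the round length). The
#' error variance — the assumed observation noise around an option's mean —
#' defaults to the true generative variance of the chosen option; a single
#' fixed scalar can be supplied instead for sensitivity analyses.
#'
#' @param prior_mean Prior mean \eqn{m_0} for each option.
#' @param prior_variance Prior variance \eqn{v_0} (> 0) for each option.
#' @param error_variance `NULL` to use the true payoff-condition variance of
#'   the chosen option, or a single positive scalar.
#' @param include_timeouts Should timed-out trials update beliefs? The
#'   forfeited payoff was displayed (crossed out), so by default the
#'   information still enters learning.
#' @return An object of class `bmt_config`.
#' @export
bmt_config <- function(prior_mean = 0, prior_variance = 55 * 20,
                       error_variance = NULL, include_timeouts = TRUE) {
  stopifnot(prior_variance > 0, is.null(error_variance) || error_variance > 0)
  structure(
    list(
      prior_mean = prior_mean,
      prior_variance = prior_variance,
      error_variance = error_variance,
      include_timeouts = include_timeouts
    ),
    class = "bmt_config"
  )
}

#' One Bayesian mean tracker update
#'
#' Updates the posterior of the chosen option after observing an unshifted
#' reward `y`, by the delta rule with Kalman gain
#' \eqn{G = v/(v + \theta^2_\epsilon)}:
#' \eqn{m' = m + G (y - m)}, \eqn{v' = (1 - G) v}.
#' Unchosen options are untouched. This is exactly the conjugate
#' normal-normal posterior update.
#'
#' @param m Numeric vector of posterior means (one per option).
#' @param v Numeric vector of posterior variances (> 0).
#' @param choice Index of the chosen option.
#' @param reward Observed unshifted reward.
#' @param error_variance Observation noise variance \eqn{\theta^2_\epsilon}
#'   of the chosen option.
#' @return A list with updated vectors `m` and `v`.
#' @export
#' @examples
#' bmt_update(m = rep(0, 4), v = rep(1100, 4), choice = 2,
#'            reward = 12, error_variance = 100)
bmt_update <- function(m, v, choice, reward, error_variance) {
  if (!(length(choice) == 1L && choice %in% seq_along(m))) {
    stop("`choice` must index an option", call. = FALSE)
  }
  if (!is.finite(reward)) stop("`reward` must be finite", call. = FALSE)
  stopifnot(error_variance > 0, all(v > 0))
  g <- v[choice] / (v[choice] + error_variance)
  m[choice] <- m[choice] + g * (reward - m[choice])
  v[choice] <- (1 - g) * v[choice]
  list(m = m, v = v)
}

# Belief trajectory and predictors for the trials of a single round.
# Beliefs reset to the prior at each round start; the predictors reported for
# trial t are computed from the PRIOR (pre-update) belief at t, i.e. the
# prior predictive distribution given trials 1..t-1.
replay_round_beliefs <- function(choice, reward_unshifted, timeout,
                                 err_var_by_option, config) {
  n_t <- length(choice)
  if (anyDuplicated(seq_len(n_t)) > 0L) stop("duplicate trials", call. = FALSE)
  m <- rep(config$prior_mean, 4L)
  v <- rep(config$prior_variance, 4L)
  M <- matrix(NA_real_, n_t, 4L)
  V <- matrix(NA_real_, n_t, 4L)
  for (t in seq_len(n_t)) {
    M[t, ] <- m
    V[t, ] <- v
    if (config$include_timeouts || !isTRUE(timeout[t])) {
      ev <- if (is.null(config$error_variance)) {
        err_var_by_option[choice[t]]
      } else {
        config$error_variance
      }
      upd <- bmt_update(m, v, choice[t], reward_unshifted[t], ev)
      m <- upd$m
      v <- upd$v
    }
  }
  list(m = M, v = V)
}

#' Belief trajectories and trial-wise predictors for a cohort
#'
#' Replays the Bayesian mean tracker over every (participant, round) of a
#' trial table, using the observed choices and unshifted rewards, and returns
#' for each trial the prior-predictive beliefs (`m1..m4`, `v1..v4`) together
#' with the three derived predictors:
#'
#' * `relative_reward`: posterior mean of the chosen option minus the average
#'   posterior mean of the unchosen options;
#' * `relative_uncertainty`: posterior standard deviation of the chosen
#'   option minus the average over the unchosen options;
#' * `total_uncertainty`: sum of the posterior standard deviations over all
#'   four options (`total_uncertainty_avg = total_uncertainty / 4` is also
#'   returned for trajectory plots; after standardization the two are
#'   interchangeable as regressors).
#'
#' Beliefs reset to the prior at the start of each round; rounds are
#' independent.
#'
#' @param trials A trial table (as produced by [simulate_cohort()] or
#'   [run_agent_session()]), with columns `participant_id`, `round`,
#'   `payoff_name`, `trial`, `choice`, `reward_unshifted`, and optionally
#'   `timeout`.
#' @param config A [bmt_config()].
#' @return The input table with belief and predictor columns appended.
#' @export
bmt_predictors <- function(trials, config = bmt_config()) {
  required <- c("participant_id", "round", "payoff_name", "trial",
                "choice", "reward_unshifted")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0L) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  pay <- payoff_conditions()
  err_var <- split(pay$variance, pay$payoff_name)

  trials <- dplyr::arrange(trials, .data$participant_id, .data$round, .data$trial)
  has_timeout <- "timeout" %in% names(trials)

  out <- trials |>
    dplyr::group_by(.data$participant_id, .data$round) |>
    dplyr::group_modify(function(df, key) {
      if (anyDuplicated(df$trial) > 0L) {
        stop("duplicate trial indices within a round", call. = FALSE)
      }
      to <- if (has_timeout) df$timeout else rep(FALSE, nrow(df))
      bel <- replay_round_beliefs(
        df$choice, df$reward_unshifted, to,
        err_var[[df$payoff_name[1L]]], config
      )
      sd_mat <- sqrt(bel$v)
      idx <- cbind(seq_len(nrow(df)), df$choice)
      m_ch <- bel$m[idx]
      sd_ch <- sd_mat[idx]
      m_un <- (rowSums(bel$m) - m_ch) / 3
      sd_un <- (rowSums(sd_mat) - sd_ch) / 3
      colnames(bel$m) <- paste0("m", 1:4)
      colnames(bel$v) <- paste0("v", 1:4)
      dplyr::bind_cols(
        df,
        tibble::as_tibble(bel$m),
        tibble::as_tibble(bel$v),
        tibble::tibble(
          relative_reward = m_ch - m_un,
          relative_uncertainty = sd_ch - sd_un,
          total_uncertainty = rowSums(sd_mat),
          total_uncertainty_avg = rowSums(sd_mat) / 4
        )
      )
    }) |>
    dplyr::ungroup()
  dplyr::relocate(out, dplyr::all_of(setdiff(names(trials), c("participant_id", "round"))),
                  .after = "round")
}
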