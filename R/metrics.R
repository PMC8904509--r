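#' Shannon entropy of a round's choices
#'
#' Plug-in Shannon entropy of the empirical choice distribution within a
#' round, \eqn{H = -\sum_j \hat p_j \log \hat p_j} with \eqn{0 \log 0 = 0}.
#' Uniform play over four options gives the chance level \eqn{\ln 4}
#' (2 bits); constant choices give 0.
#'
#' @param choices Vector of option indices.
#' @param base `"nats"` (natural log, default) or `"bits"`.
#' @return The entropy.
#' @export
#' @examples
#' choice_entropy(rep(1:4, each = 5))  # log(4)
#' choice_entropy(rep(2, 20))          # 0
choice_entropy <- function(choices, base = c("nats", "bits")) {
  base <- match.arg(base)
  if (length(choices) == 0L) stop("empty choice vector", call. = FALSE)
  stopifnot(all(choices %in% 1:4))
  p <- tabulate(choices, nbins = 4L) / length(choices)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (base == "bits") h / log(2) else h
}

#' Repeat-choice statistics for one round
#'
#' A trial is a repeat when its choice equals the previous trial's choice;
#' the first trial cannot be a repeat by definition. With the previous
#' trial's unshifted reward attached, the per-trial indicators feed the
#' repeat-probability regression.
#'
#' @param choices Vector of option indices (>= 2).
#' @param prev_rewards Optional vector of unshifted rewards, aligned with
#'   `choices`; the covariate attached to trial t is the reward at t - 1.
#' @return A list with `n_repeats`, `n_transitions`, `repeat_proportion`,
#'   and a tibble `trials` (`trial`, `is_repeat`, `prev_reward`).
#' @export
#' @examples
#' repeat_stats(c(1, 1, 2, 2, 2))
repeat_stats <- function(choices, prev_rewards = NULL) {
  n <- length(choices)
  if (n < 2L) stop("need at least 2 choices", call. = FALSE)
  if (!is.null(prev_rewards) && length(prev_rewards) != n) {
    stop("`prev_rewards` must align with `choices`", call. = FALSE)
  }
  is_rep <- choices[-1L] == choices[-n]
  list(
    n_repeats = sum(is_rep),
    n_transitions = n - 1L,
    repeat_proportion = mean(is_rep),
    trials = tibble::tibble(
      trial = 2:n,
      is_repeat = is_rep,
      prev_reward = if (is.null(prev_rewards)) NA_real_ else prev_rewards[-n]
    )
  )
}

#' Per-round behavioral summaries
#'
#' One row per (participant, round): mean unshifted reward, choice entropy,
#' and repeat counts. Timed-out trials count as choices (a key was pressed);
#' set `include_timeouts = FALSE` to drop them first.
#'
#' @param trials A trial table.
#' @param include_timeouts Keep timed-out trials (default `TRUE`).
#' @return A tibble of round summaries.
#' @export
round_summaries <- function(trials, include_timeouts = TRUE) {
  if (!include_timeouts && "timeout" %in% names(trials)) {
    trials <- trials[!trials$timeout, ]
  }
  trials |>
    dplyr::arrange(.data$participant_id, .data$round, .data$trial) |>
    dplyr::group_by(.data$participant_id, .data$round,
                    .data$time_condition, .data$payoff_name) |>
    dplyr::summarise(
      mean_reward = mean(.data$reward_unshifted),
      entropy = choice_entropy(.data$choice),
      n_repeats = sum(.data$choice[-1L] == .data$choice[-length(.data$choice)]),
      n_transitions = dplyr::n() - 1L,
      repeat_proportion = .data$n_repeats / .data$n_transitions,
      .groups = "drop"
    )
}

#' Chance-normalized choice proportions
#'
#' Per-option choice proportions minus the chance level 0.25, aggregated
#' within groups (by default payoff condition x time condition), with
#' bootstrap confidence intervals over participants. Options are in the
#' canonical payoff-table order, so deviations can be read against the
#' generative means/variances. Deviations sum to zero within each group.
#'
#' @param trials A trial table.
#' @param n_boot Bootstrap resamples of participants (default 500; 0 skips
#'   the intervals).
#' @param conf_level Interval coverage (default 0.95).
#' @return A tibble with `payoff_name`, `time_condition`, `option`,
#'   `proportion`, `deviation`, and interval bounds.
#' @export
choice_proportions <- function(trials, n_boot = 500, conf_level = 0.95) {
  props_of <- function(df) {
    df |>
      dplyr::group_by(.data$payoff_name, .data$time_condition) |>
      dplyr::reframe(
        option = 1:4,
        proportion = tabulate(.data$choice, 4L) / length(.data$choice)
      )
  }
  base <- props_of(trials)
  base$deviation <- base$proportion - 0.25
  if (n_boot > 0) {
    ids <- unique(trials$participant_id)
    by_id <- split(trials, trials$participant_id)
    alpha <- (1 - conf_level) / 2
    boots <- purrr::map(seq_len(n_boot), function(b) {
      res <- dplyr::bind_rows(by_id[sample(length(ids), replace = TRUE)])
      props_of(res)
    })
    boot_all <- dplyr::bind_rows(boots) |>
      dplyr::group_by(.data$payoff_name, .data$time_condition, .data$option) |>
      dplyr::summarise(
        conf.low = stats::quantile(.data$proportion, alpha) - 0.25,
        conf.high = stats::quantile(.data$proportion, 1 - alpha) - 0.25,
        .groups = "drop"
      )
    base <- dplyr::left_join(
      base, boot_all, by = c("payoff_name", "time_condition", "option")
    )
  }
  base
}

#' Prepare RTs for regression
#'
#' RTs are clipped at 5000 ms, then log-transformed after adding 1 ms to
#' avoid \eqn{\log(0)}. Monotone on \[0, 5000\].
#'
#' @param rt_ms RTs in milliseconds (non-negative).
#' @return `log(pmin(rt, 5000) + 1)`.
#' @export
#' @examples
#' prepare_rt(c(0, 350, 6000))
prepare_rt <- function(rt_ms) {
  if (any(rt_ms < 0, na.rm = TRUE)) stop("negative RT", call. = FALSE)
  log(pmin(rt_ms, 5000) + 1)
}

#' Hierarchical regression of log-RTs on belief predictors
#'
#' Regresses log-transformed RTs on relative reward, relative uncertainty,
#' total uncertainty, and round number, each interacting with time
#' condition, plus the pairwise interactions among the three belief
#' predictors; random intercepts and random slopes (for the belief
#' predictors) per participant. Dependent and independent variables are
#' z-standardized before fitting, and fixed effects get N(0, 1) priors
#' (see [fit_bhlm()]).
#'
#' @param predictors A predictor table from [bmt_predictors()] that also
#'   carries `rt_ms`, `round`, and `time_condition`.
#' @param ... Sampler settings passed to [fit_bhlm()].
#' @return A `bhlm_fit`. Term names use `u` for the unlimited-time dummy, so
#'   e.g. `relative_uncertainty` is the limited-time slope and
#'   `relative_uncertainty:u` the unlimited-time offset.
#' @export
fit_rt_regression <- function(predictors, ...) {
  df <- predictors[!is.na(predictors$rt_ms), ]
  dat <- tibble::tibble(
    participant_id = df$participant_id,
    y = zstandardize(prepare_rt(df$rt_ms)),
    rr = zstandardize(df$relative_reward),
    ru = zstandardize(df$relative_uncertainty),
    tu = zstandardize(df$total_uncertainty),
    round_z = zstandardize(df$round),
    u = as.numeric(df$time_condition == "unlimited")
  )
  dat <- dplyr::mutate(
    dat,
    `rr:u` = .data$rr * .data$u, `ru:u` = .data$ru * .data$u,
    `tu:u` = .data$tu * .data$u, `round_z:u` = .data$round_z * .data$u,
    `rr:ru` = .data$rr * .data$ru, `rr:tu` = .data$rr * .data$tu,
    `ru:tu` = .data$ru * .data$tu
  )
  fit <- fit_bhlm(
    dat, response = "y",
    fixed = c("rr", "ru", "tu", "round_z", "u", "rr:u", "ru:u", "tu:u",
              "round_z:u", "rr:ru", "rr:tu", "ru:tu"),
    random = c("rr", "ru", "tu"),
    group = "participant_id", ...
  )
  fit$model <- "rt_regression"
  fit
}
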