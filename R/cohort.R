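#' Specification of a synthetic cohort
#'
#' Defines the generative model for a full synthetic dataset with the same
#' statistical structure the analysis pipeline assumes: the crossed task
#' design, Bayesian-mean-tracker learning from each simulated choice,
#' softmax choices with value, uncertainty-bonus, and stickiness terms, and
#' RTs from an LBA race whose drift rates are linked to the current belief
#' predictors.
#'
#' Defaults are anchored to the hierarchical group-level point estimates
#' reported for the human cohort (alpha 7.31 limited / 9.21 unlimited, beta
#' 0.16 / 0.26, gamma 1.91 / 1.58); between-participant standard deviations
#' are not reported and default to 20% of the group mean. The \[0, 1\]
#' scaling the generator applies to beliefs uses fixed task-derived limits
#' (posterior means over \[-30, 30\], posterior standard deviations over
#' \[0, sqrt(1100)\]), which are stored in the ground truth so that fits for
#' recovery studies can reuse them.
#'
#' @param n_participants Number of participants (default 99).
#' @param n_reps Repetitions per design cell (default 5, i.e. 40 rounds).
#' @param n_trials Trials per round (default 20).
#' @param choice_means Named list of group means per time condition for
#'   `alpha`, `beta`, `gamma` (each `c(limited, unlimited)`).
#' @param choice_sds Between-participant sds, same shape; `NULL` = 20% of
#'   the absolute group means.
#' @param m_limits,sd_limits Fixed scaling limits for posterior means / sds.
#' @param drift_link Linkage of drift rates to z-scored belief predictors:
#'   intercept and weights for relative reward, relative uncertainty, and
#'   total uncertainty, plus centering/scaling constants of the z-maps.
#' @param lba Per-time-condition LBA structure parameters `A`, `k`, `tau`
#'   (time-pressured rounds get lower thresholds and faster non-decision
#'   times, matching the direction observed empirically).
#' @param deadline_ms Response deadline in limited rounds (default 400).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 99L, n_reps = 5L, n_trials = 20L,
                        choice_means = list(
                          alpha = c(limited = 7.31, unlimited = 9.21),
                          beta = c(limited = 0.16, unlimited = 0.26),
                          gamma = c(limited = 1.91, unlimited = 1.58)
                        ),
                        choice_sds = NULL,
                        m_limits = c(-30, 30),
                        sd_limits = c(0, sqrt(1100)),
                        drift_link = list(
                          intercept = 2.5,
                          w_reward = 0.35, w_rel_unc = -0.35, w_total_unc = -0.05,
                          rr_center = 0, rr_scale = 0.1,
                          ru_center = 0, ru_scale = 0.12,
                          tu_center = 2.8, tu_scale = 0.6
                        ),
                        lba = list(
                          limited = c(A = 0.30, k = 0.35, tau = 0.15),
                          unlimited = c(A = 0.80, k = 0.60, tau = 0.25)
                        ),
                        deadline_ms = 400) {
  if (is.null(choice_sds)) {
    choice_sds <- purrr::map(choice_means, ~ pmax(abs(.x) * 0.2, 0.02))
  }
  stopifnot(n_participants >= 2, all(unlist(choice_sds) > 0))
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_reps = as.integer(n_reps), n_trials = as.integer(n_trials),
      choice_means = choice_means, choice_sds = choice_sds,
      m_limits = m_limits, sd_limits = sd_limits,
      drift_link = drift_link, lba = lba, deadline_ms = deadline_ms
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates every participant of a [cohort_spec()]: per-participant softmax
#' parameters drawn from the group distributions, a randomized session plan,
#' belief-dependent softmax choices, rewards from the round's payoff
#' condition, and RTs from an LBA race with belief-linked drift rates.
#' Timed-out trials (limited rounds, RT above the deadline) forfeit the
#' reward but still update beliefs, since the payoff value was displayed.
#'
#' One master seed fans out to independent per-participant RNG streams, so
#' cohorts are reproducible and participants independent.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master seed.
#' @return An object of class `bandit_cohort`: a list with `trials` (the
#'   session table), `truth` (per-participant generating parameters, the
#'   scaling constants, the per-trial generating drifts, and the spec), and
#'   `seed`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_participants = 2, n_reps = 1), seed = 1)
#' nrow(cohort$trials)  # 2 * 8 * 20
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  part_seeds <- sample.int(2^31 - 2, spec$n_participants)

  # participant-level generating parameters
  draw_block <- function(name) {
    mu <- spec$choice_means[[name]]
    sd <- spec$choice_sds[[name]]
    lim <- stats::rnorm(spec$n_participants, mu["limited"], sd["limited"])
    unl <- stats::rnorm(spec$n_participants, mu["unlimited"], sd["unlimited"])
    tibble::tibble(lim = lim, unl = unl)
  }
  a <- draw_block("alpha"); b <- draw_block("beta"); g <- draw_block("gamma")
  ids <- sprintf("p%03d", seq_len(spec$n_participants))
  params <- tibble::tibble(
    participant_id = ids,
    alpha_limited = a$lim, alpha_unlimited = a$unl,
    beta_limited = b$lim, beta_unlimited = b$unl,
    gamma_limited = g$lim, gamma_unlimited = g$unl
  )

  pay <- payoff_conditions()
  err_var <- split(pay$variance, pay$payoff_name)
  link <- spec$drift_link
  m_lo <- spec$m_limits[1]; m_rg <- diff(spec$m_limits)
  s_lo <- spec$sd_limits[1]; s_rg <- diff(spec$sd_limits)

  sim_participant <- function(i) {
    set.seed(part_seeds[i])
    plan <- build_session(ids[i], n_reps = spec$n_reps,
                          n_trials = spec$n_trials)
    al <- c(params$alpha_limited[i], params$alpha_unlimited[i])
    be <- c(params$beta_limited[i], params$beta_unlimited[i])
    ga <- c(params$gamma_limited[i], params$gamma_unlimited[i])
    rounds <- purrr::map(seq_len(nrow(plan)), function(r) {
      row <- plan[r, ]
      cond <- if (row$time_condition == "unlimited") 2L else 1L
      lba_str <- spec$lba[[row$time_condition]]
      A_r <- lba_str[["A"]]; b_r <- A_r + lba_str[["k"]]
      tau_r <- lba_str[["tau"]]
      ev <- err_var[[row$payoff_name]]
      pay_row <- payoff_lookup(row$payoff_name)
      mu_pay <- pay_row$mean; sd_pay <- sqrt(pay_row$variance)
      n_t <- row$n_trials
      m <- rep(0, 4); v <- rep(55 * 20, 4)
      choice <- integer(n_t); y <- numeric(n_t); ys <- numeric(n_t)
      rt <- numeric(n_t); drift_mat <- matrix(NA_real_, n_t, 4)
      for (t in seq_len(n_t)) {
        ms <- (m - m_lo) / m_rg
        ss <- (sqrt(v) - s_lo) / s_rg
        prev <- if (t > 1L) choice[t - 1L] else NA_integer_
        q <- decision_value(ms, ss, prev, al[cond], be[cond], ga[cond])
        choice[t] <- sample.int(4L, 1L, prob = choice_probabilities(q))
        # drift rates linked to the current belief predictors
        rr <- ms - (sum(ms) - ms) / 3
        ru <- ss - (sum(ss) - ss) / 3
        tu <- sum(ss)
        vdrift <- pmax(
          link$intercept +
            link$w_reward * (rr - link$rr_center) / link$rr_scale +
            link$w_rel_unc * (ru - link$ru_center) / link$ru_scale +
            link$w_total_unc * (tu - link$tu_center) / link$tu_scale,
          0.05
        )
        drift_mat[t, ] <- vdrift
        # LBA race (inlined for speed; same math as simulate_lba)
        repeat {
          dr <- stats::rnorm(4L, vdrift, 1)
          fin <- (b_r - stats::runif(4L, 0, A_r)) / dr
          fin[dr <= 0] <- Inf
          tmin <- min(fin)
          if (is.finite(tmin)) break
        }
        rt[t] <- tmin + tau_r
        # reward draw with positivity-preserving redraw (as sample_reward)
        repeat {
          yy <- stats::rnorm(1L, mu_pay[choice[t]], sd_pay[choice[t]])
          if (yy + row$reward_shift > 0) break
        }
        y[t] <- yy
        ys[t] <- yy + row$reward_shift
        g_bmt <- v[choice[t]] / (v[choice[t]] + ev[choice[t]])
        m[choice[t]] <- m[choice[t]] + g_bmt * (yy - m[choice[t]])
        v[choice[t]] <- (1 - g_bmt) * v[choice[t]]
      }
      rt_ms <- rt * 1000
      tibble::tibble(
        participant_id = ids[i], round = row$round,
        time_condition = row$time_condition, payoff_name = row$payoff_name,
        trial = seq_len(n_t), choice = choice,
        reward_unshifted = y, reward_shifted = ys,
        rt_ms = rt_ms,
        timeout = row$time_condition == "limited" & rt_ms > spec$deadline_ms,
        gen_drift_chosen = drift_mat[cbind(seq_len(n_t), choice)],
        gen_drift1 = drift_mat[, 1], gen_drift2 = drift_mat[, 2],
        gen_drift3 = drift_mat[, 3], gen_drift4 = drift_mat[, 4]
      )
    })
    dplyr::bind_rows(rounds)
  }

  trials <- dplyr::bind_rows(purrr::map(seq_len(spec$n_participants),
                                        sim_participant))
  structure(
    list(
      trials = trials,
      truth = list(
        params = params,
        group_means = spec$choice_means,
        scaling = predictor_scaling(m_limits = spec$m_limits,
                                    sd_limits = spec$sd_limits),
        drift_link = spec$drift_link,
        lba = spec$lba,
        spec = spec
      ),
      seed = seed
    ),
    class = "bandit_cohort"
  )
}

#' @export
print.bandit_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic bandit cohort: %d participants, %d rounds x %d trials (seed %s)\n",
    x$truth$spec$n_participants, 8L * x$truth$spec$n_reps,
    x$truth$spec$n_trials, format(x$seed)
  ))
  invisible(x)
}

#' Parameter-recovery report for a choice-model fit
#'
#' Compares the posterior of a hierarchical choice fit against the ground
#' truth of the cohort it was fitted to: per effective group mean (limited
#' and unlimited alpha, beta, gamma), the generating value, posterior mean,
#' 95% interval, interval coverage, and bias; plus participant-level bias
#' and RMSE of the posterior-mean parameters.
#'
#' @param fit A `choice_fit` from [fit_choice_model()].
#' @param truth The `truth` element of a [simulate_cohort()] result (or the
#'   cohort itself).
#' @return A list with tibbles `group` and `participant`.
#' @export
recovery_report <- function(fit, truth) {
  stopifnot(inherits(fit, "choice_fit"))
  if (inherits(truth, "bandit_cohort")) truth <- truth$truth
  fit_ids <- fit$participant_means$participant_id
  truth_ids <- truth$params$participant_id
  if (length(intersect(fit_ids, truth_ids)) == 0L) {
    stop("no overlapping participant ids between fit and truth", call. = FALSE)
  }
  gm <- truth$group_means
  gen <- c(
    alpha_limited = unname(gm$alpha["limited"]),
    alpha_unlimited = unname(gm$alpha["unlimited"]),
    beta_limited = unname(gm$beta["limited"]),
    beta_unlimited = unname(gm$beta["unlimited"]),
    gamma_limited = unname(gm$gamma["limited"]),
    gamma_unlimited = unname(gm$gamma["unlimited"])
  )
  group <- fit$summary[match(names(gen), fit$summary$term), ]
  group$generating <- gen
  group$covered <- group$conf.low <= gen & gen <= group$conf.high
  group$bias <- group$estimate - gen
  group <- group[, c("term", "generating", "estimate", "conf.low",
                     "conf.high", "covered", "bias", "rhat")]

  pm <- fit$participant_means
  tp <- truth$params
  common <- intersect(fit_ids, truth_ids)
  pm <- pm[match(common, pm$participant_id), ]
  tp <- tp[match(common, tp$participant_id), ]
  est_unl <- function(base, off) pm[[base]] + pm[[off]]
  participant <- tibble::tibble(
    term = rep(names(gen), each = length(common)),
    participant_id = rep(common, times = length(gen)),
    estimate = c(pm$alpha_limited, est_unl("alpha_limited", "alpha_offset"),
                 pm$beta_limited, est_unl("beta_limited", "beta_offset"),
                 pm$gamma_limited, est_unl("gamma_limited", "gamma_offset")),
    generating = c(tp$alpha_limited, tp$alpha_unlimited,
                   tp$beta_limited, tp$beta_unlimited,
                   tp$gamma_limited, tp$gamma_unlimited)
  ) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      bias = mean(.data$estimate - .data$generating),
      rmse = sqrt(mean((.data$estimate - .data$generating)^2)),
      .groups = "drop"
    )
  list(group = group, participant = participant)
}
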