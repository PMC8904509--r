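#' Decision values of the softmax choice policy
#'
#' The decision value of option j combines its scaled posterior mean and
#' uncertainty with a perseveration bonus:
#' \deqn{Q_j = \alpha (m_j + \beta \sqrt{v_j}) + \gamma 1[j = prev]}
#' where \eqn{\alpha} is the value-directed component (its inverse indexes
#' random exploration), \eqn{\beta} the uncertainty-directed exploration
#' bonus, and \eqn{\gamma} the stickiness bonus for the option chosen on the
#' previous trial. On the first trial of a round there is no previous choice
#' and the stickiness term is omitted.
#'
#' @param m_scaled Scaled (\[0, 1\]) posterior means, one per option.
#' @param sd_scaled Scaled posterior standard deviations, one per option.
#' @param prev_choice Index of the previous choice, or `NA` on trial 1.
#' @param alpha,beta,gamma Effective parameters for the round's time
#'   condition.
#' @return Numeric vector of decision values.
#' @export
#' @examples
#' decision_value(rep(0.5, 4), rep(0.3, 4), prev_choice = 2,
#'                alpha = 9.21, beta = 0.26, gamma = 1.58)
decision_value <- function(m_scaled, sd_scaled, prev_choice, alpha, beta, gamma) {
  q <- alpha * (m_scaled + beta * sd_scaled)
  if (!is.na(prev_choice)) q[prev_choice] <- q[prev_choice] + gamma
  q
}

#' Softmax choice probabilities
#'
#' \eqn{p_j = \exp(Q_j) / \sum_k \exp(Q_k)}, computed with max-subtraction
#' for overflow safety. Invariant to adding a constant to all decision
#' values.
#'
#' @param q Numeric vector of decision values.
#' @return Probabilities summing to 1.
#' @export
#' @examples
#' choice_probabilities(c(1, 0, 0, 0))
choice_probabilities <- function(q) {
  stopifnot(all(is.finite(q)))
  e <- exp(q - max(q))
  e / sum(e)
}

# ---- likelihood machinery ----------------------------------------------

# Per-participant design for the vectorized likelihood: matrices over the
# participant's (non-excluded) trials.
prepare_choice_data <- function(pred, exclude_timeouts = TRUE) {
  needed <- c("participant_id", "round", "trial", "choice", "time_condition",
              paste0("ms", 1:4), paste0("ss", 1:4))
  missing <- setdiff(needed, names(pred))
  if (length(missing) > 0L) {
    stop("predictors must be scaled first; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pred <- dplyr::arrange(pred, .data$participant_id, .data$round, .data$trial)
  pred <- pred |>
    dplyr::group_by(.data$participant_id, .data$round) |>
    dplyr::mutate(prev_choice = dplyr::lag(.data$choice)) |>
    dplyr::ungroup()
  if (exclude_timeouts && "timeout" %in% names(pred)) {
    pred <- pred[!pred$timeout, ]
  }
  split(pred, pred$participant_id) |>
    purrr::map(function(df) {
      n <- nrow(df)
      st <- matrix(0, n, 4L)
      ok <- which(!is.na(df$prev_choice))
      st[cbind(ok, df$prev_choice[ok])] <- 1
      list(
        M = as.matrix(df[paste0("ms", 1:4)]),
        S = as.matrix(df[paste0("ss", 1:4)]),
        St = st,
        choice = df$choice,
        unlimited = as.numeric(df$time_condition == "unlimited"),
        n = n
      )
    })
}

# theta = c(alpha_lim, alpha_off, beta_lim, beta_off, gamma_lim, gamma_off)
choice_loglik_one <- function(d, theta) {
  a <- theta[1] + d$unlimited * theta[2]
  b <- theta[3] + d$unlimited * theta[4]
  g <- theta[5] + d$unlimited * theta[6]
  q <- (d$M + d$S * b) * a + d$St * g
  qmax <- pmax(q[, 1], q[, 2], q[, 3], q[, 4])
  denom <- qmax + log(exp(q[, 1] - qmax) + exp(q[, 2] - qmax) +
                        exp(q[, 3] - qmax) + exp(q[, 4] - qmax))
  sum(q[cbind(seq_len(d$n), d$choice)] - denom)
}

#' Log-likelihood of the softmax choice model for a cohort
#'
#' Sums, over all (non-excluded) trials, the log softmax probability of the
#' chosen option under each participant's parameters.
#'
#' @param predictors A scaled predictor table (see [scale_predictors()]).
#' @param params A tibble with one row per participant: `participant_id`,
#'   `alpha_limited`, `alpha_offset`, `beta_limited`, `beta_offset`,
#'   `gamma_limited`, `gamma_offset`. Effective unlimited-time parameters are
#'   limited + offset.
#' @param exclude_timeouts Drop timed-out trials from the likelihood
#'   (default `TRUE`; no reward was earned).
#' @return The summed log-likelihood (a single number, always <= 0).
#' @export
choice_log_likelihood <- function(predictors, params, exclude_timeouts = TRUE) {
  data <- prepare_choice_data(predictors, exclude_timeouts)
  ids <- names(data)
  missing <- setdiff(ids, as.character(params$participant_id))
  if (length(missing) > 0L) {
    stop("params missing participants: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pk <- c("alpha_limited", "alpha_offset", "beta_limited", "beta_offset",
          "gamma_limited", "gamma_offset")
  sum(vapply(ids, function(id) {
    th <- as.numeric(params[match(id, as.character(params$participant_id)), pk])
    choice_loglik_one(data[[id]], th)
  }, numeric(1)))
}

#' Maximum-likelihood softmax parameters for a single participant
#'
#' Non-hierarchical point estimation, mainly used to validate the
#' hierarchical sampler (shrinkage checks, large-data recovery).
#'
#' @param predictors Scaled predictor table for one participant.
#' @param exclude_timeouts Drop timed-out trials (default `TRUE`).
#' @return Named vector of the six parameters at the optimum.
#' @export
fit_choice_mle <- function(predictors, exclude_timeouts = TRUE) {
  data <- prepare_choice_data(predictors, exclude_timeouts)
  if (length(data) != 1L) {
    stop("`fit_choice_mle` expects exactly one participant", call. = FALSE)
  }
  d <- data[[1L]]
  both <- length(unique(d$unlimited)) == 2L
  nll <- function(th6) -choice_loglik_one(d, th6)
  if (both) {
    start <- c(5, 0, 0.2, 0, 1, 0)
    fit <- stats::optim(start, nll, method = "BFGS",
                        control = list(maxit = 500))
    est <- fit$par
  } else {
    # single condition: offsets unidentified, fixed at 0
    start <- c(5, 0.2, 1)
    fit <- stats::optim(start, function(p) nll(c(p[1], 0, p[2], 0, p[3], 0)),
                        method = "BFGS", control = list(maxit = 500))
    est <- c(fit$par[1], 0, fit$par[2], 0, fit$par[3], 0)
  }
  names(est) <- c("alpha_limited", "alpha_offset", "beta_limited",
                  "beta_offset", "gamma_limited", "gamma_offset")
  est
}

# ---- hierarchical fit ---------------------------------------------------

choice_param_names <- c("alpha_limited", "alpha_offset", "beta_limited",
                        "beta_offset", "gamma_limited", "gamma_offset")

#' Fit the hierarchical softmax choice model
#'
#' Per-participant parameters (limited-time baseline plus unlimited-time
#' offset for each of \eqn{\alpha}, \eqn{\beta}, \eqn{\gamma}) are modeled
#' as independent normals around group-level means with group-level
#' standard deviations, and estimated jointly by Metropolis-within-Gibbs
#' MCMC: adaptive random-walk updates of each participant's six-parameter
#' block, conjugate updates of the group means, and Metropolis updates of
#' the group standard deviations on the log scale.
#'
#' Group-level priors are weakly informative on the natural scale of the
#' softmax parameters under \[0, 1\]-scaled predictors: means
#' \eqn{\mu_0 \sim N(0, 10^2)} and standard deviations
#' \eqn{\sigma_0 \sim N(0, 5^2)} truncated to \eqn{(0, \infty)}.
#'
#' @param predictors A predictor table from [bmt_predictors()]; scaled with
#'   [scale_predictors()] first, or pass `scaling` to have it done here.
#' @param scaling Optional [predictor_scaling()] (e.g. the constants a
#'   synthetic generator used). Defaults to global data-derived min-max.
#' @param chains,iter,warmup MCMC settings (post-warmup draws per chain are
#'   `iter - warmup`).
#' @param exclude_timeouts Drop timed-out trials from the likelihood.
#' @param seed Optional RNG seed.
#' @param progress Print progress lines.
#' @return An object of class `choice_fit` with posterior draws for group
#'   parameters and effective limited/unlimited group means, per-participant
#'   posterior means, and convergence diagnostics. Fits with any
#'   split-\eqn{\hat{R}} of 1.01 or more are flagged (`converged = FALSE`).
#' @export
fit_choice_model <- function(predictors, scaling = NULL, chains = 4,
                             iter = 4000, warmup = 1000,
                             exclude_timeouts = TRUE, seed = NULL,
                             progress = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(paste0("ms", 1:4) %in% names(predictors))) {
    predictors <- scale_predictors(predictors, scaling)
    scaling <- attr(predictors, "scaling")
  }
  data <- prepare_choice_data(predictors, exclude_timeouts)
  n_p <- length(data)
  if (n_p < 2L) stop("hierarchical fit needs at least 2 participants", call. = FALSE)
  if (length(unique(unlist(purrr::map(data, "unlimited")))) < 2L) {
    stop("both time conditions must be present", call. = FALSE)
  }
  stopifnot(warmup < iter)

  mu_prior_sd <- 10
  sigma_prior_sd <- 5
  n_par <- 6L
  group_names <- c(paste0("mu_", choice_param_names),
                   paste0("sigma_", choice_param_names),
                   "alpha_limited", "alpha_unlimited",
                   "beta_limited", "beta_unlimited",
                   "gamma_limited", "gamma_unlimited")

  run_chain <- function(chain_id) {
    theta <- matrix(rep(c(5, 1, 0.2, 0.05, 1, 0.2), each = n_p), n_p, n_par) +
      matrix(stats::rnorm(n_p * n_par, 0, 0.2), n_p, n_par)
    mu <- colMeans(theta)
    sigma <- rep(1, n_par)
    step_theta <- matrix(0.15, n_p, n_par)
    step_sigma <- rep(0.3, n_par)
    ll <- vapply(seq_len(n_p), function(i) choice_loglik_one(data[[i]], theta[i, ]),
                 numeric(1))
    n_keep <- iter - warmup
    draws <- matrix(NA_real_, n_keep, length(group_names))
    colnames(draws) <- group_names
    theta_sum <- matrix(0, n_p, n_par)

    for (it in seq_len(iter)) {
      # participant blocks: componentwise random walk
      for (i in seq_len(n_p)) {
        for (k in seq_len(n_par)) {
          prop <- theta[i, ]
          prop[k] <- prop[k] + stats::rnorm(1, 0, step_theta[i, k])
          ll_prop <- choice_loglik_one(data[[i]], prop)
          lr <- ll_prop - ll[i] +
            stats::dnorm(prop[k], mu[k], sigma[k], log = TRUE) -
            stats::dnorm(theta[i, k], mu[k], sigma[k], log = TRUE)
          acc <- is.finite(lr) && log(stats::runif(1)) < lr
          if (acc) {
            theta[i, ] <- prop
            ll[i] <- ll_prop
          }
          if (it <= warmup) {
            step_theta[i, k] <- exp(log(step_theta[i, k]) +
                                      (as.numeric(acc) - 0.44) / sqrt(it))
          }
        }
      }
      # group means: conjugate normal update
      for (k in seq_len(n_par)) {
        prec <- 1 / mu_prior_sd^2 + n_p / sigma[k]^2
        mean_k <- sum(theta[, k]) / sigma[k]^2 / prec
        mu[k] <- stats::rnorm(1, mean_k, sqrt(1 / prec))
      }
      # group sds: Metropolis on log scale, half-normal prior
      for (k in seq_len(n_par)) {
        prop <- sigma[k] * exp(stats::rnorm(1, 0, step_sigma[k]))
        lr <- sum(stats::dnorm(theta[, k], mu[k], prop, log = TRUE)) -
          sum(stats::dnorm(theta[, k], mu[k], sigma[k], log = TRUE)) +
          stats::dnorm(prop, 0, sigma_prior_sd, log = TRUE) -
          stats::dnorm(sigma[k], 0, sigma_prior_sd, log = TRUE) +
          log(prop) - log(sigma[k])   # Jacobian of the log transform
        acc <- is.finite(lr) && log(stats::runif(1)) < lr
        if (acc) sigma[k] <- prop
        if (it <= warmup) {
          step_sigma[k] <- exp(log(step_sigma[k]) +
                                 (as.numeric(acc) - 0.44) / sqrt(it))
        }
      }
      if (it > warmup) {
        j <- it - warmup
        draws[j, ] <- c(mu, sigma,
                        mu[1], mu[1] + mu[2],
                        mu[3], mu[3] + mu[4],
                        mu[5], mu[5] + mu[6])
        theta_sum <- theta_sum + theta
      }
      if (progress && it %% 500 == 0) {
        message(sprintf("chain %d: iteration %d/%d", chain_id, it, iter))
      }
    }
    list(draws = draws, theta_mean = theta_sum / n_keep)
  }

  chains_out <- purrr::map(seq_len(chains), run_chain)
  n_keep <- iter - warmup
  draws <- array(
    NA_real_, c(n_keep, chains, length(group_names)),
    dimnames = list(NULL, paste0("chain", seq_len(chains)), group_names)
  )
  for (c in seq_len(chains)) draws[, c, ] <- chains_out[[c]]$draws
  theta_mean <- Reduce(`+`, purrr::map(chains_out, "theta_mean")) / chains

  colnames(theta_mean) <- choice_param_names
  participant_means <- tibble::as_tibble(theta_mean)
  participant_means <- dplyr::mutate(
    participant_means,
    participant_id = names(data), .before = 1
  )

  summary <- summarize_draws_matrix(draws)
  structure(
    list(
      draws = draws,
      summary = summary,
      participant_means = participant_means,
      scaling = scaling,
      settings = list(chains = chains, iter = iter, warmup = warmup,
                      exclude_timeouts = exclude_timeouts),
      converged = all(summary$rhat < 1.01, na.rm = TRUE),
      n_participants = n_p
    ),
    class = "choice_fit"
  )
}

#' @export
print.choice_fit <- function(x, ...) {
  cat("Hierarchical softmax choice model fit\n")
  cat(sprintf("  participants: %d | chains: %d | draws/chain: %d\n",
              x$n_participants, x$settings$chains,
              x$settings$iter - x$settings$warmup))
  cat(sprintf("  converged (all split-Rhat < 1.01): %s\n", x$converged))
  eff <- x$summary[x$summary$term %in% c("alpha_limited", "alpha_unlimited",
                                         "beta_limited", "beta_unlimited",
                                         "gamma_limited", "gamma_unlimited"), ]
  print(as.data.frame(eff[, c("term", "estimate", "conf.low", "conf.high")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}
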