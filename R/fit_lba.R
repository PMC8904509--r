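# Differential-evolution MCMC (DE-MCMC), the standard sampler for LBA-type
# likelihoods: a population of chains proposes jumps along difference vectors
# of two other randomly chosen chains, which self-tunes to the posterior's
# scale and correlation structure.
demcmc <- function(log_post_mat, d, n_chains = 3 * d, iter = 600, burn = 300,
                   init = NULL, gamma = 2.38 / sqrt(2 * d), jitter = 1e-4) {
  theta <- if (is.null(init)) matrix(stats::rnorm(n_chains * d), n_chains, d) else init
  lp <- log_post_mat(theta)
  bad <- !is.finite(lp)
  tries <- 0
  while (any(bad) && tries < 50) {
    theta[bad, ] <- theta[bad, , drop = FALSE] +
      matrix(stats::rnorm(sum(bad) * d, 0, 0.1), sum(bad), d)
    lp <- log_post_mat(theta)
    bad <- !is.finite(lp)
    tries <- tries + 1
  }
  if (any(bad)) stop("could not initialize sampler at finite density", call. = FALSE)
  keep <- array(NA_real_, c(iter - burn, n_chains, d))
  ii <- seq_len(n_chains)
  for (it in seq_len(iter)) {
    g <- if (stats::runif(1) < 0.1) 1 else gamma
    # synchronous generation update: partners from the previous generation
    a <- sample.int(n_chains - 1L, n_chains, replace = TRUE)
    a <- a + (a >= ii)
    b <- sample.int(n_chains - 1L, n_chains, replace = TRUE)
    b <- b + (b >= ii)
    eps <- matrix(stats::runif(n_chains * d, -jitter, jitter), n_chains, d)
    props <- theta + g * (theta[a, , drop = FALSE] - theta[b, , drop = FALSE]) + eps
    lp_prop <- log_post_mat(props)
    acc <- is.finite(lp_prop) & log(stats::runif(n_chains)) < lp_prop - lp
    theta[acc, ] <- props[acc, , drop = FALSE]
    lp[acc] <- lp_prop[acc]
    if (it > burn) keep[it - burn, , ] <- theta
  }
  keep
}

lba_transform <- function(psi) {
  # psi: c(log v1..v4, log A, log k, logit tau)
  list(v = exp(psi[1:4]), A = exp(psi[5]), k = exp(psi[6]),
       tau = stats::plogis(psi[7]))
}

lba_log_posterior <- function(psi, rt, choice, s = 1, tau_max = 1) {
  as.numeric(lba_log_posterior_mat(matrix(psi, 1), rt, choice, s, tau_max))
}

# Vectorized over a population of parameter vectors (rows of psi_mat):
# evaluates every chain's defective log-likelihood in one fused set of
# matrix operations over trials x (options x chains).
lba_log_posterior_mat <- function(psi_mat, rt, choice, s = 1, tau_max = 1) {
  C <- nrow(psi_mat)
  n <- length(rt)
  v <- exp(psi_mat[, 1:4, drop = FALSE])          # C x 4
  A <- exp(psi_mat[, 5])
  k <- exp(psi_mat[, 6])
  ptau <- stats::plogis(psi_mat[, 7])
  tau <- ptau * tau_max
  b <- A + k
  ok <- is.finite(A) & is.finite(k) & apply(is.finite(v), 1, all) &
    A > 0 & k > 0 & ptau > 0 & ptau < 1
  C4 <- 4L * C
  TD <- outer(rt, tau, "-")                        # n x C
  TDb <- TD[, rep(seq_len(C), each = 4L), drop = FALSE]
  Vb <- matrix(rep(as.vector(t(v)), each = n), n, C4)
  cA <- matrix(rep(A, each = 4L), n, C4, byrow = TRUE)
  cbm <- matrix(rep(b, each = 4L), n, C4, byrow = TRUE)
  sTD <- s * TDb
  U1 <- cbm - cA - Vb * TDb
  U2 <- cbm - Vb * TDb
  z1 <- U1 / sTD
  z2 <- U2 / sTD
  P1 <- stats::pnorm(z1); D1 <- stats::dnorm(z1)
  P2 <- stats::pnorm(z2); D2 <- stats::dnorm(z2)
  pdf <- pmax((-Vb * P1 + s * D1 + Vb * P2 - s * D2) / cA, 0)
  cdf <- pmin(pmax(1 + (U1 * P1 - U2 * P2 + sTD * (D1 - D2)) / cA, 0), 1)
  neg <- TDb <= 0
  pdf[neg] <- 0
  cdf[neg] <- 0
  logsurv <- log(pmax(1 - cdf, 1e-300))
  dim(logsurv) <- c(n, 4L, C)
  tls <- logsurv[, 1, ] + logsurv[, 2, ] + logsurv[, 3, ] + logsurv[, 4, ]
  tls <- matrix(tls, n, C)
  flat <- rep((seq_len(C) - 1L) * 4L * n, each = n) +
    (choice - 1L) * n + seq_len(n)
  pdf_ch <- matrix(pdf[flat], n, C)
  ls_ch <- matrix(logsurv[flat], n, C)
  dens <- pdf_ch * exp(tls - ls_ch)
  ll <- colSums(log(pmax(dens, 1e-10)))
  lprior <- rowSums(stats::dnorm(v, 2, 1, log = TRUE)) +
    stats::dnorm(A, 0.5, 1, log = TRUE) +
    stats::dnorm(k, 0.5, 1, log = TRUE)
  ljac <- rowSums(psi_mat[, 1:6, drop = FALSE]) + log(ptau) + log1p(-ptau)
  out <- ll + lprior + ljac
  out[!ok] <- -Inf
  out
}

#' Fit an LBA to the trials of one participant-round
#'
#' Bayesian estimation of the four drift rates, maximum starting evidence A,
#' relative threshold k (threshold b = A + k), and non-decision time tau by
#' differential-evolution MCMC. Priors: drifts \eqn{v_j \sim N(2,1)}
#' truncated to \eqn{(0,\infty)}; \eqn{A, k \sim N(0.5, 1)} truncated to
#' \eqn{(0,\infty)}; \eqn{\tau \sim U(0, 1)}. The drift scale `s` is fixed
#' (default 1).
#'
#' @param rt RTs in seconds, truncated at 5 s.
#' @param choice Chosen option indices (1..4).
#' @param n_chains,iter,burn Sampler population size and iteration counts.
#' @param s Fixed drift standard deviation.
#' @param seed Optional RNG seed.
#' @return An object of class `lba_fit`: posterior means/sds on the natural
#'   scale, split-\eqn{\hat{R}} per parameter, and the post-burn draws.
#' @export
fit_lba <- function(rt, choice, n_chains = 24, iter = 2000, burn = 1000,
                    s = 1, seed = NULL) {
  if (length(rt) < 5L) stop("need at least 5 usable trials", call. = FALSE)
  stopifnot(length(rt) == length(choice), all(rt > 0), all(rt <= 5))
  if (!is.null(seed)) set.seed(seed)
  tau_max <- min(1, min(rt))
  d <- 7L
  init <- cbind(
    matrix(log(pmax(stats::rnorm(n_chains * 4, 2, 0.5), 0.3)), n_chains, 4),
    log(pmax(stats::rnorm(n_chains, 0.5, 0.2), 0.1)),
    log(pmax(stats::rnorm(n_chains, 0.5, 0.2), 0.1)),
    stats::qlogis(stats::runif(n_chains, 0.2, 0.8))
  )
  draws_psi <- demcmc(
    function(psi) lba_log_posterior_mat(psi, rt, choice, s, tau_max),
    d = d, n_chains = n_chains, iter = iter, burn = burn, init = init
  )
  n_keep <- dim(draws_psi)[1]
  nat <- array(NA_real_, dim(draws_psi),
               dimnames = list(NULL, NULL,
                               c("v1", "v2", "v3", "v4", "A", "k", "tau")))
  nat[, , 1:6] <- exp(draws_psi[, , 1:6])
  nat[, , 7] <- stats::plogis(draws_psi[, , 7]) * tau_max
  est <- apply(nat, 3, mean)
  sds <- apply(nat, 3, stats::sd)
  rhat <- vapply(1:7, function(p) split_rhat(nat[, , p]), numeric(1))
  structure(
    list(
      estimate = c(est, b = unname(est["A"] + est["k"])),
      std.error = sds,
      rhat = rhat,
      draws = nat,
      n_trials = length(rt),
      s = s,
      converged = all(rhat < 1.1, na.rm = TRUE)
    ),
    class = "lba_fit"
  )
}

#' @export
print.lba_fit <- function(x, ...) {
  cat(sprintf("LBA fit (%d trials, %s)\n", x$n_trials,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$estimate, 3))
  invisible(x)
}

#' Fit LBAs to every participant-round of a trial table
#'
#' Applies [fit_lba()] separately to each (participant, round), as in
#' per-round evidence-accumulation analyses: RTs are converted to seconds,
#' trials slower than 5000 ms are excluded (the exclusion count is
#' recorded), and timed-out trials in limited-time rounds are included by
#' default since a (late) key was pressed.
#'
#' @param trials Trial table with `participant_id`, `round`,
#'   `time_condition`, `trial`, `choice`, `rt_ms` (and optionally `timeout`).
#' @param include_timeouts Keep timed-out trials (default `TRUE`).
#' @param min_trials Minimum usable trials per round (default 5).
#' @param ... Passed to [fit_lba()].
#' @return A tibble with one row per fitted participant-round: posterior
#'   means `v1..v4`, `A`, `k`, `b`, `tau`, the worst split-\eqn{\hat{R}},
#'   and bookkeeping columns `n_used` and `n_excluded`.
#' @export
fit_lba_rounds <- function(trials, include_timeouts = TRUE, min_trials = 5L,
                           ...) {
  stopifnot(all(c("participant_id", "round", "rt_ms", "choice") %in% names(trials)))
  trials |>
    dplyr::group_by(.data$participant_id, .data$round) |>
    dplyr::group_modify(function(df, key) {
      keep <- !is.na(df$rt_ms) & df$rt_ms > 0 & df$rt_ms <= 5000
      if (!include_timeouts && "timeout" %in% names(df)) keep <- keep & !df$timeout
      n_excluded <- sum(!keep)
      df <- df[keep, ]
      if (nrow(df) < min_trials) {
        return(tibble::tibble(
          time_condition = df$time_condition[1] %||% NA_character_,
          v1 = NA_real_, v2 = NA_real_, v3 = NA_real_, v4 = NA_real_,
          A = NA_real_, k = NA_real_, b = NA_real_, tau = NA_real_,
          max_rhat = NA_real_, n_used = nrow(df), n_excluded = n_excluded
        ))
      }
      fit <- fit_lba(df$rt_ms / 1000, df$choice, ...)
      e <- fit$estimate
      tibble::tibble(
        time_condition = df$time_condition[1],
        v1 = e[["v1"]], v2 = e[["v2"]], v3 = e[["v3"]], v4 = e[["v4"]],
        A = e[["A"]], k = e[["k"]], b = e[["b"]], tau = e[["tau"]],
        max_rhat = max(fit$rhat, na.rm = TRUE),
        n_used = nrow(df), n_excluded = n_excluded
      )
    }) |>
    dplyr::ungroup()
}
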