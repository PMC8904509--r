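#' Linear Ballistic Accumulator parameter container
#'
#' In the LBA race, evidence for each option j accumulates linearly from a
#' starting point drawn uniformly on \[0, A\] at a drift rate drawn (per
#' trial) from \eqn{N(v_j, s^2)}, until the threshold \eqn{b = A + k} is
#' reached; the first accumulator to finish determines the choice, and
#' RT = finishing time + non-decision time \eqn{\tau}. The drift scale `s`
#' is a fixed constant (1 by default), the conventional identifiability
#' constraint.
#'
#' @param v Mean drift rates, one per option (evidence units / s).
#' @param A Maximum starting evidence (> 0).
#' @param k Relative threshold (> 0); the threshold is `b = A + k`.
#' @param tau Non-decision time in seconds.
#' @param s Trial-level drift standard deviation (fixed, default 1).
#' @return An object of class `lba_params`.
#' @export
#' @examples
#' lba_params(v = c(3.2, 2.1, 2.0, 1.9), A = 0.8, k = 0.6, tau = 0.2)
lba_params <- function(v, A, k, tau, s = 1) {
  stopifnot(length(v) >= 2, A > 0, k > 0, tau >= 0, s > 0)
  structure(list(v = v, A = A, k = k, b = A + k, tau = tau, s = s),
            class = "lba_params")
}

# First-passage density and CDF of all accumulators at decision times td
# (RT minus non-decision time), sharing the normal pdf/cdf evaluations.
# td: n-vector; v: vector of mean drifts. Returns n x n_opt matrices.
lba_joint <- function(td, v, A, b, s) {
  n <- length(td)
  n_opt <- length(v)
  TD <- matrix(td, n, n_opt)
  V <- matrix(v, n, n_opt, byrow = TRUE)
  sTD <- s * TD
  u1 <- b - A - V * TD
  u2 <- b - V * TD
  z1 <- u1 / sTD
  z2 <- u2 / sTD
  P1 <- stats::pnorm(z1); D1 <- stats::dnorm(z1)
  P2 <- stats::pnorm(z2); D2 <- stats::dnorm(z2)
  pdf <- (-V * P1 + s * D1 + V * P2 - s * D2) / A
  cdf <- 1 + (u1 * P1 - u2 * P2 + sTD * (D1 - D2)) / A
  bad <- td <= 0
  pdf[bad, ] <- 0
  cdf[bad, ] <- 0
  list(pdf = pmax(pdf, 0), cdf = pmin(pmax(cdf, 0), 1))
}

# First-passage density of a single accumulator at decision time td.
lba_pdf_acc <- function(td, v, A, b, s) {
  lba_joint(td, v, A, b, s)$pdf[, 1]
}

# First-passage CDF of a single accumulator at decision time td.
lba_cdf_acc <- function(td, v, A, b, s) {
  lba_joint(td, v, A, b, s)$cdf[, 1]
}

# Fast defective log-likelihood used by the sampler: no class checks.
lba_loglik_fast <- function(rt, choice, v, A, b, tau, s) {
  td <- rt - tau
  jt <- lba_joint(td, v, A, b, s)
  n <- length(rt)
  idx <- cbind(seq_len(n), choice)
  surv <- 1 - jt$cdf
  dens <- jt$pdf[idx] * exp(rowSums(log(pmax(surv, 1e-300))) -
                              log(pmax(surv[idx], 1e-300)))
  dens[td <= 0] <- 0
  sum(log(pmax(dens, 1e-10)))
}

#' Defective density of an LBA choice-RT pair
#'
#' Joint density of observing choice `j` at RT `t` (seconds): the winning
#' accumulator's first-passage density times the probability that every
#' other accumulator is still unfinished,
#' \eqn{f_j(t) \prod_{k \ne j} (1 - F_k(t))}. RTs at or below the
#' non-decision time have density zero (not an error). Summed over choices
#' and integrated over time the defective densities have total mass 1, up to
#' the (negligible, for the fitted regimes) probability that all trial-level
#' drifts are negative.
#'
#' @param t RT in seconds (vectorized).
#' @param choice Chosen option index (vectorized, recycled against `t`).
#' @param params An [lba_params()].
#' @return Density values.
#' @export
lba_density <- function(t, choice, params) {
  stopifnot(inherits(params, "lba_params"))
  n_opt <- length(params$v)
  stopifnot(all(choice %in% seq_len(n_opt)))
  td <- t - params$tau
  n <- max(length(td), length(choice))
  td <- rep_len(td, n)
  choice <- rep_len(choice, n)
  jt <- lba_joint(td, params$v, params$A, params$b, params$s)
  surv <- 1 - jt$cdf
  idx <- cbind(seq_len(n), choice)
  prod_surv <- rep(1, n)
  for (j in seq_len(n_opt)) {
    use <- choice != j
    prod_surv[use] <- prod_surv[use] * surv[use, j]
  }
  res <- jt$pdf[idx] * prod_surv
  res[td <= 0] <- 0
  res
}

#' Log-likelihood of choices and RTs under an LBA
#'
#' Sum of log defective densities over the trials of one participant-round,
#' with a finite floor (density `1e-10`) replacing zero densities so the
#' sampler never sees `-Inf`; trials that hit the floor are counted in the
#' `"n_floored"` attribute.
#'
#' @param rt RTs in seconds (already truncated at 5 s upstream).
#' @param choice Chosen option indices.
#' @param params An [lba_params()].
#' @return The log-likelihood, with attribute `n_floored`.
#' @export
lba_loglik <- function(rt, choice, params) {
  if (length(rt) == 0L) stop("empty trial list", call. = FALSE)
  d <- lba_density(rt, choice, params)
  floored <- d < 1e-10
  d[floored] <- 1e-10
  structure(sum(log(d)), n_floored = sum(floored))
}

#' Simulate choices and RTs from an LBA race
#'
#' Per trial and accumulator, a start point is drawn uniformly on \[0, A\]
#' and a drift from \eqn{N(v_j, s^2)}; accumulators with positive drift
#' finish at `(b - start) / drift`, the earliest finisher wins, and
#' RT = finishing time + tau. Trials on which every drift is negative (no
#' accumulator ever finishes) are redrawn and counted in the `"n_redrawn"`
#' attribute.
#'
#' @param n Number of trials.
#' @param params An [lba_params()].
#' @return A tibble with columns `choice` and `rt` (seconds), with attribute
#'   `n_redrawn`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_lba(5, lba_params(c(3, 2, 2, 2), A = 0.8, k = 0.6, tau = 0.2))
simulate_lba <- function(n, params) {
  stopifnot(inherits(params, "lba_params"))
  n_opt <- length(params$v)
  choice <- integer(n)
  rt <- numeric(n)
  todo <- seq_len(n)
  n_redrawn <- 0L
  while (length(todo) > 0L) {
    m <- length(todo)
    drift <- matrix(stats::rnorm(m * n_opt, rep(params$v, each = m), params$s),
                    m, n_opt)
    start <- matrix(stats::runif(m * n_opt, 0, params$A), m, n_opt)
    finish <- (params$b - start) / drift
    finish[drift <= 0] <- Inf
    winner <- max.col(-finish, ties.method = "first")
    tmin <- finish[cbind(seq_len(m), winner)]
    done <- is.finite(tmin)
    choice[todo[done]] <- winner[done]
    rt[todo[done]] <- tmin[done] + params$tau
    n_redrawn <- n_redrawn + sum(!done)
    todo <- todo[!done]
  }
  structure(tibble::tibble(choice = choice, rt = rt), n_redrawn = n_redrawn)
}
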