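# MCMC convergence diagnostics for the package's samplers.

#' Split-\eqn{\hat{R}} for one parameter
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also registers as non-convergence.
#'
#' @param draws A matrix of posterior draws, iterations x chains.
#' @return The split-\eqn{\hat{R}} statistic (1 at perfect mixing).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  if (m < 2 || half < 2) return(NA_real_)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Effective sample size for one parameter
#'
#' Autocorrelation-based effective sample size, summing paired
#' autocorrelations (Geyer's initial positive sequence) per chain.
#'
#' @param draws A matrix of posterior draws, iterations x chains.
#' @return Estimated effective number of independent draws.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4) return(NA_real_)
  rho_sum <- vapply(seq_len(m), function(j) {
    x <- draws[, j]
    if (stats::sd(x) == 0) return(0)
    ac <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
    s <- 0
    k <- 1
    while (k < length(ac)) {
      pair <- ac[k] + ac[k + 1]
      if (is.na(pair) || pair <= 0) break
      s <- s + pair
      k <- k + 2
    }
    s
  }, numeric(1))
  n * m / (1 + 2 * mean(rho_sum))
}

summarize_draws_matrix <- function(draws_3d) {
  # draws_3d: iterations x chains x parameters (named)
  params <- dimnames(draws_3d)[[3]]
  purrr::map_dfr(seq_along(params), function(p) {
    mat <- draws_3d[, , p, drop = TRUE]
    mat <- as.matrix(mat)
    x <- as.vector(mat)
    tibble::tibble(
      term = params[p],
      estimate = mean(x),
      std.error = stats::sd(x),
      conf.low = unname(stats::quantile(x, 0.025)),
      conf.high = unname(stats::quantile(x, 0.975)),
      rhat = split_rhat(mat),
      ess = ess_basic(mat)
    )
  })
}
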