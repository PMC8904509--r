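#' Bayesian hierarchical linear regression by Gibbs sampling
#'
#' Gaussian mixed-effects model \eqn{y = X\beta + Z_g b_g + \epsilon} with
#' independent random effects per group (random intercept plus random
#' slopes), fitted by an exact conjugate Gibbs sampler. Priors: fixed
#' effects \eqn{\beta_p \sim N(0, 1)} (both response and predictors are
#' expected to be standardized), residual variance
#' \eqn{\sigma^2 \sim IG(1, 0.5)}, and random-effect variances
#' \eqn{\tau^2_q \sim IG(1.5, 0.25)} — weakly informative while letting
#' variances collapse toward zero when the data carry no group structure.
#'
#' @param data A data frame holding the (already standardized) response,
#'   predictor columns, and the grouping column.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect columns (precomputed,
#'   including any interaction columns); an intercept is always added.
#' @param random Character vector of random-slope columns (subset of
#'   `fixed`); a random intercept is always added.
#' @param group Name of the grouping column (participants).
#' @param chains,iter,warmup Sampler settings.
#' @param prior_sd Prior standard deviation of the fixed effects.
#' @param seed Optional RNG seed.
#' @return An object of class `bhlm_fit` with posterior draws for the fixed
#'   effects and variance components, a tidy summary, and convergence
#'   diagnostics.
#' @export
fit_bhlm <- function(data, response, fixed, random = character(), group,
                     chains = 2, iter = 2000, warmup = 500, prior_sd = 1,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(warmup < iter)
  y <- data[[response]]
  X <- cbind(`(Intercept)` = 1, as.matrix(data[fixed]))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effect design", call. = FALSE)
  Z <- cbind(`(Intercept)` = 1, as.matrix(data[random]))
  g <- as.factor(data[[group]])
  groups <- levels(g)
  G <- length(groups)
  p <- ncol(X)
  q <- ncol(Z)
  n <- length(y)
  idx <- split(seq_len(n), g)

  XtX <- crossprod(X)
  a_sigma <- 1; b_sigma <- 0.5
  a_tau <- 1.5; b_tau <- 0.25

  run_chain <- function(chain_id) {
    beta <- stats::rnorm(p, 0, 0.1)
    b <- matrix(0, G, q)
    sigma2 <- 1
    tau2 <- rep(0.25, q)
    n_keep <- iter - warmup
    keep_beta <- matrix(NA_real_, n_keep, p)
    keep_var <- matrix(NA_real_, n_keep, 1 + q)
    for (it in seq_len(iter)) {
      # fixed effects
      resid_rand <- y
      for (gi in seq_len(G)) {
        ii <- idx[[gi]]
        resid_rand[ii] <- resid_rand[ii] - Z[ii, , drop = FALSE] %*% b[gi, ]
      }
      V <- chol2inv(chol(XtX / sigma2 + diag(1 / prior_sd^2, p)))
      mu_b <- V %*% crossprod(X, resid_rand) / sigma2
      beta <- as.vector(mu_b + t(chol(V)) %*% stats::rnorm(p))
      # random effects
      resid_fix <- y - as.vector(X %*% beta)
      for (gi in seq_len(G)) {
        ii <- idx[[gi]]
        Zg <- Z[ii, , drop = FALSE]
        Vg <- chol2inv(chol(crossprod(Zg) / sigma2 + diag(1 / tau2, q)))
        mg <- Vg %*% crossprod(Zg, resid_fix[ii]) / sigma2
        b[gi, ] <- as.vector(mg + t(chol(Vg)) %*% stats::rnorm(q))
      }
      # residual variance
      resid <- resid_fix
      for (gi in seq_len(G)) {
        ii <- idx[[gi]]
        resid[ii] <- resid[ii] - Z[ii, , drop = FALSE] %*% b[gi, ]
      }
      sigma2 <- 1 / stats::rgamma(1, a_sigma + n / 2,
                                  b_sigma + sum(resid^2) / 2)
      # random-effect variances
      for (qi in seq_len(q)) {
        tau2[qi] <- 1 / stats::rgamma(1, a_tau + G / 2,
                                      b_tau + sum(b[, qi]^2) / 2)
      }
      if (it > warmup) {
        keep_beta[it - warmup, ] <- beta
        keep_var[it - warmup, ] <- c(sigma2, tau2)
      }
    }
    list(beta = keep_beta, var = keep_var)
  }

  out <- purrr::map(seq_len(chains), run_chain)
  n_keep <- iter - warmup
  par_names <- c(colnames(X), "sigma2", paste0("tau2_", colnames(Z)))
  draws <- array(NA_real_, c(n_keep, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (c in seq_len(chains)) {
    draws[, c, seq_len(p)] <- out[[c]]$beta
    draws[, c, p + seq_len(1 + q)] <- out[[c]]$var
  }
  summary <- summarize_draws_matrix(draws)
  structure(
    list(
      draws = draws,
      summary = summary,
      fixed = colnames(X),
      random = colnames(Z),
      n_obs = n,
      n_groups = G,
      settings = list(chains = chains, iter = iter, warmup = warmup),
      converged = all(summary$rhat[seq_len(p)] < 1.01, na.rm = TRUE)
    ),
    class = "bhlm_fit"
  )
}

#' @export
print.bhlm_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian hierarchical linear model (%d obs, %d groups, %s)\n",
    x$n_obs, x$n_groups, if (x$converged) "converged" else "NOT converged"
  ))
  fx <- x$summary[x$summary$term %in% x$fixed, ]
  print(as.data.frame(fx[, c("term", "estimate", "conf.low", "conf.high")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}
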