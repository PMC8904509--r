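#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hierarchical choice-model fit
#'
#' @param x A `choice_fit`.
#' @param effective Return the effective limited/unlimited group parameters
#'   (default) rather than the raw group means/sds.
#' @param ... Unused.
#' @return A tibble with one row per term: posterior mean, sd, 95% interval,
#'   split-\eqn{\hat{R}}, and effective sample size.
#' @export
tidy.choice_fit <- function(x, effective = TRUE, ...) {
  terms <- if (effective) {
    c("alpha_limited", "alpha_unlimited", "beta_limited", "beta_unlimited",
      "gamma_limited", "gamma_unlimited")
  } else {
    grep("^(mu|sigma)_", x$summary$term, value = TRUE)
  }
  x$summary[x$summary$term %in% terms, ]
}

#' @rdname tidy.choice_fit
#' @export
glance.choice_fit <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants,
    chains = x$settings$chains,
    draws_per_chain = x$settings$iter - x$settings$warmup,
    max_rhat = max(x$summary$rhat, na.rm = TRUE),
    min_ess = min(x$summary$ess, na.rm = TRUE),
    converged = x$converged
  )
}

#' Tidy a Bayesian hierarchical linear model fit
#'
#' @param x A `bhlm_fit`.
#' @param effects `"fixed"` (default) or `"all"` (includes variance
#'   components).
#' @param ... Unused.
#' @return A tibble of posterior summaries.
#' @export
tidy.bhlm_fit <- function(x, effects = c("fixed", "all"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$summary[x$summary$term %in% x$fixed, ] else x$summary
}

#' @rdname tidy.bhlm_fit
#' @export
glance.bhlm_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_groups = x$n_groups,
    chains = x$settings$chains,
    draws_per_chain = x$settings$iter - x$settings$warmup,
    max_rhat = max(x$summary$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' Tidy an LBA fit
#'
#' @param x An `lba_fit`.
#' @param ... Unused.
#' @return A tibble with posterior mean, sd, and split-\eqn{\hat{R}} per
#'   parameter (plus the derived threshold `b`).
#' @export
tidy.lba_fit <- function(x, ...) {
  nm <- c("v1", "v2", "v3", "v4", "A", "k", "tau")
  tibble::tibble(
    term = c(nm, "b"),
    estimate = unname(x$estimate[c(nm, "b")]),
    std.error = c(unname(x$std.error[nm]), NA_real_),
    rhat = c(unname(x$rhat), NA_real_)
  )
}
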