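#' Min-max scaling constants for belief predictors
#'
#' The choice model enters posterior means and posterior standard deviations
#' scaled to \[0, 1\]. Constants are computed once, globally over the whole
#' dataset (separately for means and standard deviations), and stored so the
#' transform can be reapplied or inverted. Fixed limits can also be supplied,
#' e.g. the task-derived limits a synthetic generator used, so that fitted
#' parameters live on the generating scale.
#'
#' @param predictors A predictor table from [bmt_predictors()].
#' @param m_limits,sd_limits Optional fixed `c(min, max)` limits overriding
#'   the data-derived ones.
#' @return An object of class `predictor_scaling`: a list with elements `m`
#'   and `sd`, each `c(min, max)`.
#' @export
predictor_scaling <- function(predictors = NULL, m_limits = NULL,
                              sd_limits = NULL) {
  if (is.null(m_limits) || is.null(sd_limits)) {
    stopifnot(!is.null(predictors))
    m_cols <- as.matrix(predictors[paste0("m", 1:4)])
    sd_cols <- sqrt(as.matrix(predictors[paste0("v", 1:4)]))
    if (is.null(m_limits)) m_limits <- range(m_cols)
    if (is.null(sd_limits)) sd_limits <- range(sd_cols)
  }
  if (diff(m_limits) <= 0 || diff(sd_limits) <= 0) {
    stop("degenerate scaling: max must exceed min", call. = FALSE)
  }
  structure(list(m = m_limits, sd = sd_limits), class = "predictor_scaling")
}

#' Min-max scale a vector to \[0, 1\]
#'
#' @param x Numeric vector.
#' @param limits `c(min, max)`; defaults to `range(x)`.
#' @return Scaled vector with attribute `"limits"`.
#' @export
#' @examples
#' minmax_scale(c(0, 5, 10))
minmax_scale <- function(x, limits = range(x, na.rm = TRUE)) {
  if (!all(is.finite(limits)) || diff(limits) <= 0) {
    stop("degenerate scaling: max must exceed min", call. = FALSE)
  }
  structure((x - limits[1]) / (limits[2] - limits[1]), limits = limits)
}

#' Invert a min-max scaling
#'
#' @param x Scaled vector.
#' @param limits The `c(min, max)` used for scaling.
#' @return Vector on the original scale.
#' @export
minmax_unscale <- function(x, limits) {
  x * (limits[2] - limits[1]) + limits[1]
}

#' Apply \[0, 1\] scaling to belief predictors
#'
#' Adds `ms1..ms4` (scaled posterior means) and `ss1..ss4` (scaled posterior
#' standard deviations) to a predictor table.
#'
#' @param predictors A predictor table from [bmt_predictors()].
#' @param scaling A [predictor_scaling()]; computed from the data when `NULL`.
#' @return The table with scaled columns appended and the scaling stored in
#'   attribute `"scaling"`.
#' @export
scale_predictors <- function(predictors, scaling = NULL) {
  if (is.null(scaling)) scaling <- predictor_scaling(predictors)
  for (j in 1:4) {
    predictors[[paste0("ms", j)]] <-
      (predictors[[paste0("m", j)]] - scaling$m[1]) / diff(scaling$m)
    predictors[[paste0("ss", j)]] <-
      (sqrt(predictors[[paste0("v", j)]]) - scaling$sd[1]) / diff(scaling$sd)
  }
  attr(predictors, "scaling") <- scaling
  predictors
}

# z-standardize columns; returns centred/scaled data plus the constants.
# Constant columns error by default; with allow_constant they map to zeros
# (a constant predictor carries no signal — downstream rank checks catch it
# if it ends up in a design).
zstandardize <- function(x, allow_constant = FALSE) {
  mu <- mean(x, na.rm = TRUE)
  sd <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(sd) || sd == 0) {
    if (allow_constant) return(structure(x * 0, center = mu, scale = 1))
    stop("degenerate column (zero variance)", call. = FALSE)
  }
  structure((x - mu) / sd, center = mu, scale = sd)
}
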