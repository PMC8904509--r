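# ggplot2 views of the main result types.

#' Learning curves by payoff condition and time pressure
#'
#' Mean unshifted reward per trial (cohort average with standard-error
#' ribbons), faceted by payoff condition.
#'
#' @param trials A trial table.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(trials) {
  df <- trials |>
    dplyr::group_by(.data$payoff_name, .data$time_condition, .data$trial) |>
    dplyr::summarise(
      mean = mean(.data$reward_unshifted),
      se = stats::sd(.data$reward_unshifted) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$trial, .data$mean,
                                   color = .data$time_condition,
                                   fill = .data$time_condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~payoff_name) +
    ggplot2::labs(x = "Trial", y = "Mean unshifted reward",
                  color = "Time", fill = "Time") +
    ggplot2::theme_minimal()
}

#' Belief-predictor trajectories of the chosen option
#'
#' Cohort-mean trajectories over trials of relative reward, relative
#' uncertainty, and average total uncertainty of the chosen option, split by
#' time condition. An early positive bump in relative uncertainty is the
#' signature of uncertainty-directed exploration; total uncertainty decays
#' as beliefs sharpen.
#'
#' @param predictors A predictor table from [bmt_predictors()].
#' @return A ggplot object.
#' @export
plot_bmt_trajectories <- function(predictors) {
  df <- predictors |>
    dplyr::group_by(.data$time_condition, .data$trial) |>
    dplyr::summarise(
      `Relative reward` = mean(.data$relative_reward),
      `Relative uncertainty` = mean(.data$relative_uncertainty),
      `Total uncertainty (avg sd)` = mean(.data$total_uncertainty_avg),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-c("time_condition", "trial"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$trial, .data$value,
                                   color = .data$time_condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Trial", y = NULL, color = "Time") +
    ggplot2::theme_minimal()
}

#' Chance-normalized choice proportions
#'
#' Bars of per-option deviations from chance (0.25) by payoff and time
#' condition, with bootstrap intervals when present.
#'
#' @param proportions Output of [choice_proportions()].
#' @return A ggplot object.
#' @export
plot_choice_proportions <- function(proportions) {
  p <- ggplot2::ggplot(
    proportions,
    ggplot2::aes(factor(.data$option), .data$deviation,
                 fill = .data$time_condition)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~payoff_name) +
    ggplot2::labs(x = "Option (canonical order)",
                  y = "Choice proportion - chance", fill = "Time") +
    ggplot2::theme_minimal()
  if (all(c("conf.low", "conf.high") %in% names(proportions))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    )
  }
  p
}

posterior_interval_plot <- function(summary, terms) {
  df <- summary[summary$term %in% terms, ]
  df$term <- factor(df$term, levels = rev(terms))
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Posterior estimate (95% interval)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Posterior intervals of a choice-model fit
#'
#' @param object A `choice_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the effective group-level parameters.
#' @export
autoplot.choice_fit <- function(object, ...) {
  posterior_interval_plot(
    object$summary,
    c("alpha_limited", "alpha_unlimited", "beta_limited", "beta_unlimited",
      "gamma_limited", "gamma_unlimited")
  )
}

#' Posterior intervals of a hierarchical regression fit
#'
#' @param object A `bhlm_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the fixed effects.
#' @export
autoplot.bhlm_fit <- function(object, ...) {
  posterior_interval_plot(object$summary, setdiff(object$fixed, "(Intercept)"))
}
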