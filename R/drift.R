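#' Build the drift-rate regression design
#'
#' Joins per-round LBA drift estimates with round-averaged belief
#' predictors, one row per (participant, round, option). For each option j
#' and trial, the predictors are computed for that option — its posterior
#' mean minus the average of the other options' means (relative reward), its
#' posterior standard deviation minus the average of the others' (relative
#' uncertainty), and the summed standard deviation over all options (total
#' uncertainty) — then averaged over the round's trials, since the LBA is
#' fitted per round. All columns entering the regression are z-standardized.
#'
#' @param lba_fits Output of [fit_lba_rounds()] (posterior-mean drifts
#'   `v1..v4` per participant-round).
#' @param predictors A predictor table from [bmt_predictors()].
#' @return A tibble with `participant_id`, `round`, `time_condition`,
#'   `option`, `drift`, `rel_reward`, `rel_uncertainty`, `total_uncertainty`
#'   and their z-scored versions (`drift_z`, `rr_z`, `ru_z`, `tu_z`).
#' @export
build_drift_design <- function(lba_fits, predictors) {
  m_cols <- as.matrix(predictors[paste0("m", 1:4)])
  sd_cols <- sqrt(as.matrix(predictors[paste0("v", 1:4)]))
  per_option <- purrr::map_dfr(1:4, function(j) {
    tibble::tibble(
      participant_id = predictors$participant_id,
      round = predictors$round,
      option = j,
      rel_reward = m_cols[, j] - rowMeans(m_cols[, -j, drop = FALSE]),
      rel_uncertainty = sd_cols[, j] - rowMeans(sd_cols[, -j, drop = FALSE]),
      total_uncertainty = rowSums(sd_cols)
    )
  }) |>
    dplyr::group_by(.data$participant_id, .data$round, .data$option) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop")

  drifts <- lba_fits |>
    dplyr::filter(!is.na(.data$v1)) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("v", 1:4)),
                        names_to = "option", values_to = "drift") |>
    dplyr::mutate(option = as.integer(sub("^v", "", .data$option))) |>
    dplyr::select("participant_id", "round", "time_condition",
                  "option", "drift")

  design <- dplyr::inner_join(
    drifts, per_option, by = c("participant_id", "round", "option")
  )
  if (nrow(design) == 0L) {
    stop("no overlap between LBA fits and predictors", call. = FALSE)
  }
  n_fit <- nrow(dplyr::distinct(drifts, .data$participant_id, .data$round))
  if (nrow(design) != 4L * n_fit) {
    stop("predictors do not cover every fitted participant-round", call. = FALSE)
  }
  design$drift_z <- zstandardize(design$drift, allow_constant = TRUE)
  design$rr_z <- zstandardize(design$rel_reward, allow_constant = TRUE)
  design$ru_z <- zstandardize(design$rel_uncertainty, allow_constant = TRUE)
  design$tu_z <- zstandardize(design$total_uncertainty, allow_constant = TRUE)
  design
}

#' Hierarchical regression of drift rates on belief predictors
#'
#' Regresses the per-option estimated drift rate on relative reward,
#' relative uncertainty, and total uncertainty, each interacting with time
#' condition, plus the pairwise interactions among the predictors; random
#' intercepts and slopes per participant; N(0, 1) priors on the fixed
#' effects (see [fit_bhlm()]).
#'
#' @param design A design tibble from [build_drift_design()].
#' @param ... Sampler settings passed to [fit_bhlm()].
#' @return A `bhlm_fit`; `u` in term names is the unlimited-time dummy.
#' @export
fit_drift_regression <- function(design, ...) {
  dat <- tibble::tibble(
    participant_id = design$participant_id,
    y = design$drift_z,
    rr = design$rr_z,
    ru = design$ru_z,
    tu = design$tu_z,
    u = as.numeric(design$time_condition == "unlimited")
  )
  dat <- dplyr::mutate(
    dat,
    `rr:u` = .data$rr * .data$u, `ru:u` = .data$ru * .data$u,
    `tu:u` = .data$tu * .data$u,
    `rr:ru` = .data$rr * .data$ru, `rr:tu` = .data$rr * .data$tu,
    `ru:tu` = .data$ru * .data$tu
  )
  fit <- fit_bhlm(
    dat, response = "y",
    fixed = c("rr", "ru", "tu", "u", "rr:u", "ru:u", "tu:u",
              "rr:ru", "rr:tu", "ru:tu"),
    random = c("rr", "ru", "tu"),
    group = "participant_id", ...
  )
  fit$model <- "drift_regression"
  fit
}
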