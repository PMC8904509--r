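session_columns <- c("participant_id", "round", "time_condition",
                     "payoff_name", "trial", "choice", "reward_unshifted",
                     "reward_shifted", "rt_ms", "timeout")

#' Write a session table to CSV
#'
#' One row per trial, header included, RTs in milliseconds, UTF-8, "."
#' decimal separator.
#'
#' @param trials A trial table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(trials, path) {
  cols <- intersect(session_columns, names(trials))
  readr::write_csv(trials[cols], path)
  invisible(path)
}

#' Read and validate a session table
#'
#' Reads a trial CSV, optionally renaming columns from another deposit
#' layout via `col_map`, coerces types, and validates every trial-record
#' invariant: required columns, trial indices within the round length,
#' canonical option indices 1..4, positive shifted rewards, known condition
#' labels, no duplicate trials within a round, at most the round length of
#' trials per round, and timeouts only on limited-time trials above the
#' deadline. In strict mode any violation is an error; in lenient mode
#' offending rows are dropped and logged in the report.
#'
#' @param path CSV file.
#' @param strict Fail on any violation (default `TRUE`).
#' @param col_map Optional named character vector mapping source column
#'   names to canonical ones, e.g. `c(id = "participant_id")`.
#' @param n_trials Round length (default 20).
#' @param deadline_ms Response deadline (default 400).
#' @return The validated tibble, with a `validation_report` attribute (see
#'   [validation_report()]).
#' @export
read_sessions <- function(path, strict = TRUE, col_map = NULL,
                          n_trials = 20L, deadline_ms = 400) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    pos <- match(names(col_map), names(df))
    names(df)[pos[!is.na(pos)]] <- unname(col_map[!is.na(pos)])
  }
  required <- c("participant_id", "round", "trial", "choice")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  df$round <- as.integer(df$round)
  df$trial <- as.integer(df$trial)
  df$choice <- as.integer(df$choice)
  if ("timeout" %in% names(df)) df$timeout <- as.logical(df$timeout)

  checks <- list(
    trial_range = df$trial >= 1L & df$trial <= n_trials,
    choice_range = df$choice %in% 1:4
  )
  if ("payoff_name" %in% names(df)) {
    checks$payoff_known <- df$payoff_name %in% payoff_names()
  }
  if ("time_condition" %in% names(df)) {
    checks$time_known <- df$time_condition %in% c("limited", "unlimited")
  }
  if ("reward_shifted" %in% names(df)) {
    checks$reward_positive <- is.na(df$reward_shifted) | df$reward_shifted > 0
  }
  if (all(c("timeout", "time_condition", "rt_ms") %in% names(df))) {
    checks$timeout_consistent <- !df$timeout |
      (df$time_condition == "limited" & (is.na(df$rt_ms) | df$rt_ms > deadline_ms))
  }
  key <- paste(df$participant_id, df$round, df$trial)
  checks$no_duplicate_trials <- !duplicated(key)

  report <- purrr::imap(checks, function(ok, name) {
    bad <- which(!ok)
    list(check = name, pass = length(bad) == 0L,
         n_bad = length(bad), rows = utils::head(bad, 20L))
  })
  bad_rows <- sort(unique(unlist(purrr::map(report, "rows"))))
  any_bad <- any(!purrr::map_lgl(report, "pass"))
  if (any_bad && strict) {
    failing <- names(checks)[!purrr::map_lgl(report, "pass")]
    stop("session table failed validation: ",
         paste(failing, collapse = ", "), call. = FALSE)
  }
  all_bad <- which(!Reduce(`&`, checks))
  if (any_bad) df <- df[-all_bad, ]
  attr(df, "validation_report") <- list(
    n_rows_read = length(key), n_rows_kept = nrow(df),
    n_rows_dropped = length(all_bad), checks = report
  )
  df
}

#' Validation report of a read session table
#'
#' @param x A table returned by [read_sessions()].
#' @return The stored validation report (row counts and per-check results).
#' @export
validation_report <- function(x) attr(x, "validation_report")

#' Run the simulation-and-analysis pipeline
#'
#' Runs the deterministic-given-seed stages end to end: simulate a cohort,
#' compute belief predictors, round summaries and choice proportions, and
#' (optionally) fit the hierarchical choice model with reduced MCMC; writes
#' every output as CSV into `out_dir` together with a `manifest.json`
#' recording inputs, seed, package version, and an MD5 checksum per output,
#' sufficient to re-run bit-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [cohort_spec()] (or `NULL` to read `spec_json`).
#' @param seed Master seed for all stochastic stages.
#' @param fit_choice Also fit the choice model (default `FALSE`; slow).
#' @param chains,iter,warmup MCMC settings when `fit_choice = TRUE`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, spec = cohort_spec(), seed = 1L,
                         fit_choice = FALSE, chains = 2, iter = 1000,
                         warmup = 500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()

  cohort <- simulate_cohort(spec, seed = seed)
  p_sessions <- file.path(out_dir, "sessions.csv")
  write_sessions(cohort$trials, p_sessions)
  p_truth <- file.path(out_dir, "truth_params.csv")
  readr::write_csv(cohort$truth$params, p_truth)
  outputs <- c(outputs, p_sessions, p_truth)

  pred <- bmt_predictors(cohort$trials)
  p_pred <- file.path(out_dir, "bmt_predictors.csv")
  readr::write_csv(
    pred[c(session_columns[session_columns %in% names(pred)],
           paste0("m", 1:4), paste0("v", 1:4),
           "relative_reward", "relative_uncertainty", "total_uncertainty")],
    p_pred
  )
  outputs <- c(outputs, p_pred)

  p_summ <- file.path(out_dir, "round_summaries.csv")
  readr::write_csv(round_summaries(cohort$trials), p_summ)
  p_prop <- file.path(out_dir, "choice_proportions.csv")
  set.seed(seed + 1L)
  readr::write_csv(choice_proportions(cohort$trials, n_boot = 200), p_prop)
  outputs <- c(outputs, p_summ, p_prop)

  if (fit_choice) {
    fit <- fit_choice_model(pred, scaling = cohort$truth$scaling,
                            chains = chains, iter = iter, warmup = warmup,
                            seed = seed + 2L)
    p_fit <- file.path(out_dir, "choice_fit_summary.csv")
    readr::write_csv(fit$summary, p_fit)
    outputs <- c(outputs, p_fit)
  }

  manifest <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("banditrt")),
    seed = seed,
    spec = list(
      n_participants = spec$n_participants, n_reps = spec$n_reps,
      n_trials = spec$n_trials
    ),
    outputs = purrr::map(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
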