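test_that("the Gibbs sampler recovers a known linear model", {
  withr::with_seed(31, {
    n_g <- 12; n_per <- 60
    g <- rep(sprintf("g%02d", 1:n_g), each = n_per)
    x1 <- rnorm(n_g * n_per); x2 <- rnorm(n_g * n_per)
    u0 <- rep(rnorm(n_g, 0, 0.4), each = n_per)
    y <- 0.5 * x1 - 0.3 * x2 + u0 + rnorm(n_g * n_per, 0, 0.6)
    dat <- tibble::tibble(g = g, y = y, x1 = x1, x2 = x2)
    fit <- fit_bhlm(dat, "y", fixed = c("x1", "x2"), random = "x1",
                    group = "g", chains = 2, iter = 1200, warmup = 400,
                    seed = 32)
    td <- tidy(fit)
    b1 <- td[td$term == "x1", ]
    b2 <- td[td$term == "x2", ]
    expect_gt(b1$conf.high, 0.5 - 0.15)
    expect_lt(b1$conf.low, 0.5 + 0.15)
    expect_lt(abs(b1$estimate - 0.5), 0.1)
    expect_lt(abs(b2$estimate + 0.3), 0.1)
    expect_true(b2$conf.low < -0.3 & b2$conf.high > -0.3 - 0.2)
    expect_true(all(td$rhat < 1.05, na.rm = TRUE))
  })
  expect_error(
    fit_bhlm(tibble::tibble(g = c("a", "b"), y = 1:2, x = c(1, 1)),
             "y", fixed = "x", group = "g", chains = 1, iter = 20,
             warmup = 10),
    "rank-deficient"
  )
})

test_that("rt regression recovers generating weights' signs and ranks", {
  withr::with_seed(33, {
    co <- simulate_cohort(cohort_spec(n_participants = 10, n_reps = 3),
                          seed = 34)
    pred <- bmt_predictors(co$trials)
    rr <- as.numeric(scale(pred$relative_reward))
    ru <- as.numeric(scale(pred$relative_uncertainty))
    tu <- as.numeric(scale(pred$total_uncertainty))
    # weights on the scale of the reported RT effects
    eta <- -0.08 * rr + 0.15 * ru + 0.22 * tu + rnorm(nrow(pred), 0, 0.5)
    pred$rt_ms <- exp(6 + 0.4 * eta)
    fit <- fit_rt_regression(pred, chains = 2, iter = 1200, warmup = 400,
                             seed = 35)
    td <- tidy(fit)
    est <- td$estimate[match(c("rr", "ru", "tu"), td$term)]
    expect_lt(est[1], 0)
    expect_gt(est[2], 0)
    expect_gt(est[3], 0)
    expect_gt(est[3], est[2])          # total > relative uncertainty
    expect_gt(abs(est[2]), abs(est[1]))
  })
})

test_that("drift design has one row per option and zero-symmetry on trial 1", {
  co <- small_cohort()
  pred <- bmt_predictors(co$trials)
  # fake per-round drift estimates, to exercise the design bookkeeping
  fits <- dplyr::distinct(co$trials, participant_id, round, time_condition) |>
    dplyr::mutate(v1 = 2, v2 = 2.1, v3 = 1.9, v4 = 2.2)
  design <- build_drift_design(fits, pred)
  expect_equal(nrow(design), 4L * nrow(fits))
  # first-trial-only predictors are symmetric across options
  pred1 <- pred[pred$trial == 1, ]
  d1 <- build_drift_design(fits, pred1)
  expect_equal(d1$rel_reward, rep(0, nrow(d1)))
  expect_equal(d1$rel_uncertainty, rep(0, nrow(d1)))
  expect_error(build_drift_design(fits, pred[pred$participant_id == "none", ]),
               "overlap")
})

test_that("drift regression: null calibration and weight recovery", {
  withr::with_seed(36, {
    co <- simulate_cohort(cohort_spec(n_participants = 10, n_reps = 3),
                          seed = 37)
    pred <- bmt_predictors(co$trials)
    base <- dplyr::distinct(co$trials, participant_id, round, time_condition)
    # (a) pure-noise drifts: intervals should cover zero
    fits0 <- dplyr::mutate(base,
                           v1 = rnorm(dplyr::n(), 2, 0.5),
                           v2 = rnorm(dplyr::n(), 2, 0.5),
                           v3 = rnorm(dplyr::n(), 2, 0.5),
                           v4 = rnorm(dplyr::n(), 2, 0.5))
    f0 <- fit_drift_regression(build_drift_design(fits0, pred),
                               chains = 2, iter = 1000, warmup = 300,
                               seed = 38)
    td0 <- tidy(f0)
    main <- td0[td0$term %in% c("rr", "ru", "tu"), ]
    expect_true(all(main$conf.low < 0 & main$conf.high > 0))
    # (b) drifts built from the predictors: signs recovered, total
    # uncertainty weakest
    des <- build_drift_design(fits0, pred)
    drift_gen <- 2 + 0.35 * des$rr_z - 0.35 * des$ru_z - 0.05 * des$tu_z +
      rnorm(nrow(des), 0, 0.3)
    des$drift <- drift_gen
    des$drift_z <- as.numeric(scale(drift_gen))
    f1 <- fit_drift_regression(des, chains = 2, iter = 1000, warmup = 300,
                               seed = 39)
    td1 <- tidy(f1)
    est <- td1$estimate[match(c("rr", "ru", "tu"), td1$term)]
    expect_gt(est[1], 0)
    expect_lt(est[2], 0)
    expect_lt(abs(est[3]), min(abs(est[1]), abs(est[2])))
  })
})
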