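test_that("min-max scaling hits [0, 1], round-trips, and rejects constants", {
  x <- c(0, 5, 10)
  s <- minmax_scale(x)
  expect_equal(as.numeric(s), c(0, 0.5, 1))
  y <- rnorm(50)
  sy <- minmax_scale(y)
  expect_equal(min(sy), 0)
  expect_equal(max(sy), 1)
  expect_equal(minmax_unscale(as.numeric(sy), attr(sy, "limits")), y,
               tolerance = 1e-12)
  expect_error(minmax_scale(rep(2, 5)), "degenerate")
})

test_that("decision values follow the softmax policy's algebra", {
  # group-mean parameters of the unlimited-time condition
  q <- decision_value(rep(0.5, 4), rep(0.3, 4), prev_choice = 2,
                      alpha = 9.21, beta = 0.26, gamma = 1.58)
  expect_equal(q[2], 9.21 * (0.5 + 0.26 * 0.3) + 1.58, tolerance = 1e-12)
  expect_equal(q[1], 9.21 * (0.5 + 0.26 * 0.3), tolerance = 1e-12)
  expect_equal(decision_value(rep(0.2, 4), rep(0.1, 4), NA, 0, 5, 0),
               rep(0, 4))
  # beta = 0: ranking follows means among non-previous options
  q2 <- decision_value(c(0.1, 0.4, 0.2, 0.9), rep(0.3, 4), NA, 3, 0, 1)
  expect_equal(order(q2), order(c(0.1, 0.4, 0.2, 0.9)))
})

test_that("softmax probabilities normalize, respect symmetry and shift", {
  expect_equal(choice_probabilities(rep(0, 4)), rep(0.25, 4))
  p <- choice_probabilities(c(1, 0, 0, 0))
  expect_equal(p[1], exp(1) / (exp(1) + 3), tolerance = 1e-12)
  withr::with_seed(5, {
    for (i in 1:50) {
      q <- rnorm(4, 0, 5)
      p1 <- choice_probabilities(q)
      expect_equal(sum(p1), 1, tolerance = 1e-12)
      expect_equal(choice_probabilities(q + rnorm(1, 0, 100)), p1,
                   tolerance = 1e-9)
    }
  })
  # overflow safety
  expect_equal(choice_probabilities(c(2000, 0, 0, 0)), c(1, 0, 0, 0))
})

test_that("zero parameters give the uniform-model log-likelihood exactly", {
  co <- small_cohort()
  pred <- scale_predictors(bmt_predictors(co$trials), co$truth$scaling)
  null_params <- dplyr::distinct(co$trials, participant_id) |>
    dplyr::mutate(alpha_limited = 0, alpha_offset = 0, beta_limited = 0,
                  beta_offset = 0, gamma_limited = 0, gamma_offset = 0)
  ll <- choice_log_likelihood(pred, null_params)
  n_used <- sum(!co$trials$timeout)
  expect_equal(ll, n_used * log(1 / 4), tolerance = 1e-9)
  # generating parameters beat the null on generated data
  gen_params <- co$truth$params |>
    dplyr::transmute(participant_id,
                     alpha_limited, alpha_offset = alpha_unlimited - alpha_limited,
                     beta_limited, beta_offset = beta_unlimited - beta_limited,
                     gamma_limited, gamma_offset = gamma_unlimited - gamma_limited)
  expect_gt(choice_log_likelihood(pred, gen_params), ll)
})

test_that("single-participant likelihood optimization recovers parameters", {
  # one participant at many rounds, pinned at the group means
  sp <- cohort_spec(n_participants = 2, n_reps = 50)
  sp$choice_sds <- purrr::map(sp$choice_means, ~ .x * 0 + 1e-6)
  co <- simulate_cohort(sp, seed = 71)
  pred <- scale_predictors(bmt_predictors(co$trials), co$truth$scaling)
  mle <- fit_choice_mle(pred[pred$participant_id == "p001", ])
  expect_lt(abs(mle[["alpha_limited"]] - 7.31) / 7.31, 0.10)
  expect_lt(abs(mle[["gamma_limited"]] - 1.91) / 1.91, 0.10)
  expect_lt(abs(mle[["beta_limited"]] - 0.16), 0.05)
  expect_lt(abs((mle[["alpha_limited"]] + mle[["alpha_offset"]]) - 9.21) / 9.21,
            0.10)
})

test_that("hierarchical fit validates its inputs", {
  co <- small_cohort()
  pred <- scale_predictors(bmt_predictors(co$trials), co$truth$scaling)
  one <- pred[pred$participant_id == "p001", ]
  expect_error(fit_choice_model(one, chains = 1, iter = 20, warmup = 10),
               "2 participants")
  lim <- pred[pred$time_condition == "limited", ]
  expect_error(fit_choice_model(lim, chains = 1, iter = 20, warmup = 10),
               "time conditions")
})

test_that("hierarchical estimates shrink individual MLEs toward the group", {
  co <- small_cohort()
  pred <- scale_predictors(bmt_predictors(co$trials), co$truth$scaling)
  fit <- fit_choice_model(pred, chains = 2, iter = 500, warmup = 250,
                          seed = 8)
  mles <- purrr::map_dbl(
    unique(pred$participant_id),
    ~ fit_choice_mle(pred[pred$participant_id == .x, ])[["alpha_limited"]]
  )
  post <- fit$participant_means$alpha_limited
  mu_hat <- fit$summary$estimate[fit$summary$term == "mu_alpha_limited"]
  # posterior means lie within the mle-to-group-mean segment (with slack
  # for sampling noise)
  inside <- (post >= pmin(mles, mu_hat) - 0.5) & (post <= pmax(mles, mu_hat) + 0.5)
  expect_gt(mean(inside), 0.8)
  # shrinkage reduces spread
  expect_lt(sd(post), sd(mles) + 0.2)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 6L)
  expect_true(all(c("max_rhat", "converged") %in% names(glance(fit))))
})
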