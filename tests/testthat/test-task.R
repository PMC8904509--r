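test_that("payoff table matches the task's four conditions", {
  tab <- payoff_conditions()
  expect_equal(nrow(tab), 16L)
  igt <- tab[tab$payoff_name == "igt", ]
  expect_equal(igt$mean, c(-10, -10, 10, 10))
  expect_equal(igt$variance, c(10, 100, 10, 100))
  hv <- tab[tab$payoff_name == "high_var", ]
  expect_equal(hv$mean, c(-10, -1 / 3, 1 / 3, 10))
  expect_equal(hv$variance, rep(100, 4))
  em <- tab[tab$payoff_name == "equal_means", ]
  expect_equal(em$mean, rep(0, 4))
  expect_equal(em$variance, c(10, 40, 70, 100))
})

test_that("sampled rewards follow the condition's distribution and shifting", {
  withr::with_seed(11, {
    rw <- sample_reward("low_var", option = 4, shift = 45, n = 1e5)
    # option 4 of low_var has mean 10, variance 10
    expect_lt(abs(mean(rw$reward_unshifted) - 10), 3 * sqrt(10 / 1e5))
    expect_equal(rw$reward_shifted, rw$reward_unshifted + 45)
    # mid-range shift: the positivity redraw is then rare enough (< 3e-4)
    # that the sample variance matches the generative one
    rw2 <- sample_reward("high_var", option = 1, shift = 45, n = 1e5)
    expect_lt(abs(var(rw2$reward_unshifted) - 100) / 100, 0.03)
    expect_true(all(rw2$reward_shifted > 0))
    rw3 <- sample_reward("high_var", option = 1, shift = 30, n = 1e5)
    expect_true(all(rw3$reward_shifted > 0))
  })
  expect_error(sample_reward("low_var", option = 5, shift = 45), "option")
  expect_error(sample_reward("low_var", option = 1, shift = 10), "shift")
})

test_that("session plans have exactly five rounds per design cell", {
  withr::with_seed(21, {
    plan <- build_session("p1")
    expect_equal(nrow(plan), 40L)
    counts <- dplyr::count(plan, time_condition, payoff_name)
    expect_equal(nrow(counts), 8L)
    expect_true(all(counts$n == 5L))
    expect_true(all(plan$reward_shift >= 30 & plan$reward_shift <= 60))
    expect_true(all(purrr::map_lgl(plan$key_mapping, ~ setequal(.x, 1:4))))
    plan2 <- build_session("p1")
    expect_false(identical(plan$payoff_name, plan2$payoff_name) &&
                   identical(plan$time_condition, plan2$time_condition))
  })
})

test_that("bonus formula reproduces its worked values and is monotone", {
  expect_equal(compute_bonus(20 * 50, 50), 4.00)
  expect_equal(compute_bonus(10 * 50, 50), 0.5^4 * 4)
  expect_equal(compute_bonus(0, 50), 0)
  x <- seq(0, 1500, by = 50)
  b <- compute_bonus(x, 50)
  expect_true(all(diff(b) >= 0))
  expect_true(all(b <= 4))
  expect_error(compute_bonus(100, 0), "positive")
})

test_that("agent sessions record choices, rewards, and timeouts correctly", {
  withr::with_seed(31, {
    plan <- build_session("p9", n_reps = 1L)
    constant <- run_agent_session(function(ctx) 1L, plan)
    expect_equal(nrow(constant), 8L * 20L)
    expect_true(all(constant$choice == 1L))
    # constant policy: every transition is a repeat
    reps <- round_summaries(constant)
    expect_true(all(reps$repeat_proportion == 1))
    # greedy on true means in low_var earns ~10 per trial
    greedy <- run_agent_session(function(ctx) 4L, plan)
    lv <- greedy[greedy$payoff_name == "low_var", ]
    expect_lt(abs(mean(lv$reward_unshifted) - 10), 1)
    # agents that emit RTs can time out only in limited rounds
    slow <- run_agent_session(function(ctx) list(choice = 2L, rt_ms = 900),
                              plan)
    expect_true(all(slow$timeout == (slow$time_condition == "limited")))
    expect_error(run_agent_session(function(ctx) 7L, plan), "invalid")
  })
})

test_that("uniform agents produce near-chance entropy", {
  withr::with_seed(41, {
    plan <- build_session("p2", n_reps = 2L)
    tr <- run_agent_session(function(ctx) sample.int(4L, 1L), plan)
    ent <- round_summaries(tr)$entropy
    expect_gt(mean(ent), log(4) - 0.15)  # plug-in entropy is biased low
    expect_true(all(ent <= log(4) + 1e-12))
  })
})
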