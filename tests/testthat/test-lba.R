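random_lba_params <- function(v_min = 0) {
  repeat {
    v <- rnorm(4, 2, 1)
    if (all(v > max(v_min, 0.1))) break
  }
  A <- abs(rnorm(1, 0.5, 0.4)) + 0.05
  k <- abs(rnorm(1, 0.5, 0.4)) + 0.05
  lba_params(v, A, k, tau = runif(1, 0.05, 0.5))
}

test_that("accumulator CDF approaches one and density integrates to it", {
  p <- lba_params(c(2.5, 2, 2, 2), A = 0.7, k = 0.5, tau = 0.1)
  far <- lba_cdf_acc(1000, p$v[1], p$A, p$b, p$s)
  expect_gt(far, 0.98)  # mass 1 minus the all-negative-drift probability
  # pdf integrates to cdf
  for (tt in c(0.5, 1, 2)) {
    quad <- integrate(function(x) lba_pdf_acc(x, p$v[1], p$A, p$b, p$s),
                      0, tt, rel.tol = 1e-9)$value
    expect_equal(quad, lba_cdf_acc(tt, p$v[1], p$A, p$b, p$s),
                 tolerance = 1e-6)
  }
})

test_that("defective densities sum to total mass one over choices and time", {
  withr::with_seed(13, {
    for (r in 1:5) {
      p <- random_lba_params(v_min = 1.5)
      mass <- sum(vapply(1:4, function(j) {
        integrate(function(t) lba_density(t, j, p), p$tau, p$tau + 50,
                  rel.tol = 1e-8)$value
      }, numeric(1)))
      expect_equal(mass, 1, tolerance = 1e-4)
    }
  })
})

test_that("density agrees with the brute-force race simulator", {
  withr::with_seed(14, {
    p <- random_lba_params(v_min = 1)
    sim <- simulate_lba(2e5, p)
    shares <- tabulate(sim$choice, 4) / nrow(sim)
    analytic <- vapply(1:4, function(j) {
      integrate(function(t) lba_density(t, j, p), p$tau, p$tau + 50,
                rel.tol = 1e-7)$value
    }, numeric(1))
    expect_equal(shares, analytic, tolerance = 0.02)
    expect_true(all(sim$rt >= p$tau))
    # dominance: one huge drift wins essentially always
    dom <- simulate_lba(1e4, lba_params(c(10, 0.01, 0.01, 0.01),
                                        A = 0.5, k = 0.5, tau = 0.1))
    expect_gt(mean(dom$choice == 1), 0.99)
  })
})

test_that("log-likelihood is floor-safe and monotone in the chosen drift", {
  p <- lba_params(c(2, 2, 2, 2), A = 0.5, k = 0.5, tau = 0.2)
  # t = tau exactly: contract floor, no crash
  ll <- lba_loglik(c(0.2, 0.6), c(1, 2), p)
  expect_true(is.finite(ll))
  expect_equal(attr(ll, "n_floored"), 1L)
  expect_error(lba_loglik(numeric(0), integer(0), p), "empty")
  # a fast correct response becomes likelier as its drift grows (on the
  # rising side of the first-passage density, i.e. drifts below b / td)
  lls <- vapply(seq(1, 3.5, by = 0.5), function(v1) {
    as.numeric(lba_loglik(0.4, 1L, lba_params(c(v1, 2, 2, 2), 0.5, 0.5, 0.2)))
  }, numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("two-accumulator reduction approaches the single-accumulator density", {
  # with vanishing competitor mean drifts and A -> 0, the defective density
  # of accumulator 1 approaches its first-passage density alone at early
  # times (trial-level drift noise s = 1 lets competitors finish at later
  # times, so the reduction is exact only where b / td is large)
  A_small <- 1e-4
  p <- lba_params(c(2.5, 1e-6, 1e-6, 1e-6), A = A_small, k = 0.8, tau = 0.2)
  tt <- seq(0.25, 0.45, by = 0.05)
  defective <- lba_density(tt, 1L, p)
  single <- lba_pdf_acc(tt - p$tau, 2.5, A_small, p$b, 1)
  expect_equal(defective, single, tolerance = 0.01)
})

test_that("posterior means recover generating parameters at 200 trials", {
  withr::with_seed(15, {
    p <- lba_params(c(3.2, 2.1, 2.0, 1.9), A = 0.8, k = 0.6, tau = 0.2)
    sim <- simulate_lba(200, p)
    fit <- fit_lba(sim$rt, sim$choice, seed = 16)
    expect_true(all(abs(fit$estimate[1:4] - p$v) / p$v < 0.15))
    expect_lt(abs(fit$estimate[["b"]] - p$b) / p$b, 0.15)
    expect_s3_class(tidy(fit), "tbl_df")
  })
  expect_error(fit_lba(rep(0.5, 3), c(1, 2, 3)), "5 usable")
})

test_that("lower thresholds speed responses and hurt accuracy", {
  withr::with_seed(17, {
    v <- c(3, 2.2, 1.8, 1.4)
    stats <- purrr::map_dfr(c(0.2, 0.6, 1.2), function(k) {
      sim <- simulate_lba(5000, lba_params(v, A = 0.5, k = k, tau = 0.2))
      tibble::tibble(k = k, mean_rt = mean(sim$rt),
                     accuracy = mean(sim$choice == 1))
    })
    expect_true(all(diff(stats$mean_rt) > 0))
    expect_true(all(diff(stats$accuracy) > 0))
  })
})

test_that("per-round fitting handles truncation, timeouts, and short rounds", {
  withr::with_seed(18, {
    co <- small_cohort()
    tr <- co$trials[co$trials$participant_id == "p001" &
                      co$trials$round <= 2, ]
    tr$rt_ms[1] <- 6000  # beyond the 5000 ms truncation
    fits <- fit_lba_rounds(tr, n_chains = 14, iter = 300, burn = 150)
    expect_equal(nrow(fits), 2L)
    expect_equal(sum(fits$n_excluded), 1L)
    expect_true(all(fits$n_used + fits$n_excluded == 20L))
    # too few usable trials: row kept but unfitted
    short <- tr[tr$round == 1 & tr$trial <= 3, ]
    out <- fit_lba_rounds(short)
    expect_true(is.na(out$v1))
  })
})
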