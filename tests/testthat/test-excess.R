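# Stage-2 excess inference: closed forms, bootstrap mechanics, degenerate and
# normal-residual behaviour, draw-sharing between daily and cumulative
# estimates, and weekend CI width.

test_that("excess closed forms hold exactly", {
  expect_equal(excess_visits(c(50, 50), c(50, 50)),
               list(excess = 0, pct_excess = 0))
  e <- excess_visits(c(70, 70), c(50, 50))  # totals 140 vs 100
  expect_equal(e$excess, 40, tolerance = 1e-15)
  expect_equal(e$pct_excess, 40, tolerance = 1e-15)
  expect_warning(e0 <- excess_visits(c(1, 2), c(0, 0)), "undefined")
  expect_equal(e0$excess, 3)
  expect_true(is.na(e0$pct_excess))
})

test_that("all-zero residuals give a degenerate CI at the point estimate", {
  obs <- c(12, 14, 13, 12, 15, 11, 13)
  pred <- rep(10, 7)
  expect_warning(
    est <- monte_carlo_excess(pred, obs, residuals = rep(0, 100),
                              n_iter = 200, seed = 1),
    "degenerate"
  )
  expect_equal(est$ci_low, est$pct_excess)
  expect_equal(est$ci_high, est$pct_excess)
  expect_true(est$degenerate)
})

test_that("constant residual blocks shift every draw by a known amount", {
  # residuals all +5 with block length = window length: every iteration's
  # counterfactual is pred + 5, so the CI collapses to a computable value
  pred <- rep(100, 7); obs <- rep(110, 7)
  est <- monte_carlo_excess(pred, obs, residuals = rep(5, 50),
                            n_iter = 100, block_len = 7, seed = 2)
  expect_equal(est$pct_excess, 10)                      # point uses pred
  expect_equal(est$ci_low, 100 * (770 - 735) / 735)     # draws use pred + 5
  expect_equal(est$ci_high, est$ci_low)
  expect_equal(est$excess_ci_low, 35)
})

test_that("iid normal residuals under the null give a symmetric CI around 0", {
  set.seed(41)
  resid <- rnorm(800, 0, 10)
  pred <- rep(100, 28)
  est <- monte_carlo_excess(pred, pred, resid, n_iter = 2000, block_len = 1,
                            seed = 42)
  expect_lt(est$ci_low, 0)
  expect_gt(est$ci_high, 0)
  half <- (est$ci_high - est$ci_low) / 2
  expect_lt(abs(est$ci_high + est$ci_low) / half, 0.35)
  # same seed twice: identical bounds
  est2 <- monte_carlo_excess(pred, pred, resid, n_iter = 2000, block_len = 1,
                             seed = 42)
  expect_identical(est, est2)
})

test_that("daily profile shares draws with the cumulative estimate", {
  sc <- one_stratum_scenario(43, multiplier = 1.4)
  covs <- generate_covariates(sc)
  visits <- generate_visits(sc, covs)
  fit <- fit_counterfactual(visits, covs, pre_end = sc$event_date,
                            configs = fast_configs()[1], seed = 7)
  win <- c(sc$event_date, sc$event_date + 6)
  prof <- daily_excess_profile(fit, visits, covs, win, n_iter = 300, seed = 9)
  cum <- monte_carlo_ci(fit, visits, covs, win, n_iter = 300, seed = 9)
  expect_equal(nrow(prof$daily), 7)
  expect_identical(prof$cumulative, cum)
  # additivity: daily excess sums exactly to the window excess
  expect_equal(sum(prof$daily$excess), prof$cumulative$excess)
  expect_equal(sum(prof$daily$observed), prof$cumulative$observed)
})

test_that("percent CIs are wider on weekends in a low-count outpatient series", {
  sc <- synthetic_scenario(n_tracts_per_zone = c(high = 1L), baseline_rate = 25,
                           settings = "outpatient", causes = "respiratory",
                           seed = 44)
  covs <- generate_covariates(sc)
  visits <- generate_visits(sc, covs)
  fit <- fit_counterfactual(visits, covs, pre_end = sc$event_date,
                            configs = fast_configs()[1], seed = 8)
  prof <- daily_excess_profile(fit, visits, covs,
                               c(sc$event_date, sc$event_date + 6),
                               n_iter = 500, seed = 10)
  wd <- as.POSIXlt(prof$daily$date)$wday
  width <- prof$daily$ci_high - prof$daily$ci_low
  expect_gt(mean(width[wd %in% c(0, 6)]), mean(width[!wd %in% c(0, 6)]))
})

test_that("refit mode produces a finite CI bracketing plausible excess", {
  sc <- one_stratum_scenario(45, multiplier = 1.4)
  covs <- generate_covariates(sc)
  visits <- generate_visits(sc, covs)
  fit <- fit_counterfactual(visits, covs, pre_end = sc$event_date,
                            configs = fast_configs()[1], seed = 11)
  est <- monte_carlo_ci(fit, visits, covs, c(sc$event_date, sc$event_date + 6),
                        n_iter = 25, seed = 12, mode = "refit")
  expect_true(is.finite(est$ci_low) && is.finite(est$ci_high))
  expect_lte(est$ci_low, est$ci_high)
  expect_equal(est$n_iterations, 25L)
})
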