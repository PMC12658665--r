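# Stage-1 counterfactual: RMSE, rolling-origin folds, model selection,
# tie-breaking, leakage protection, and seasonal model sanity.

test_that("rmse matches hand computations", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3), tolerance = 1e-15)
  expect_equal(rmse(0, 5), 5)
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("rolling-origin folds cover the tail of the pre-period disjointly", {
  dates <- seq(as.Date("2022-11-01"), by = "day", length.out = 800)
  sch <- cv_scheme(n_folds = 5, validation_days = 28, gap_days = 0)
  folds <- make_folds(dates, sch)
  expect_length(folds, 5)
  expect_equal(max(folds[[5]]$validation), max(dates))
  for (f in folds) {
    expect_length(f$validation, 28)
    expect_length(intersect(f$train, f$validation), 0)
    # gap 0: training ends the day before validation starts
    expect_equal(max(f$train), min(f$validation) - 1)
    expect_true(all(f$train < min(f$validation)))
  }
  # consecutive validation windows tile the tail without overlap
  all_val <- do.call(c, lapply(folds, `[[`, "validation"))
  expect_equal(anyDuplicated(all_val), 0)

  g <- make_folds(dates, cv_scheme(gap_days = 3))
  expect_equal(max(g[[1]]$train), min(g[[1]]$validation) - 4)

  expect_error(make_folds(dates[1:400], sch), "at least 505")
})

test_that("a constant series is predicted within 1% on held-out days", {
  dates <- seq(as.Date("2022-11-01"), by = "day", length.out = 780)
  series <- tibble::tibble(date = dates, count = 100)
  covs <- tibble::tibble(date = dates)
  cfg <- model_config(fourier_order_annual = 0, trend_flexibility = 0,
                      use_holidays = FALSE)
  fit <- fit_counterfactual(series, covs, pre_end = max(dates) - 27,
                            configs = list(cfg), seed = 3)
  expect_equal(fit$selected_index, 1)  # singleton argmin
  pred <- predict(fit, tail(dates, 28), covs)
  expect_true(all(abs(pred - 100) / 100 < 0.01))
  expect_equal(fit$n_clipped, 0)
})

test_that("RMSE ties resolve to the earlier config in the list", {
  sc <- one_stratum_scenario(31)
  covs <- generate_covariates(sc)
  visits <- generate_visits(sc, covs)
  cfg_a <- model_config(fourier_order_annual = 3)
  cfg_b <- model_config(fourier_order_annual = 3,
                        residual_learner = "gradient_boosting", gb_rounds = 0)
  fit <- fit_counterfactual(visits, covs[, !(names(covs) == "zone")],
                            pre_end = sc$event_date,
                            configs = list(cfg_a, cfg_b), seed = 3)
  expect_equal(fit$cv_results$mean_cv_rmse[1], fit$cv_results$mean_cv_rmse[2])
  expect_equal(fit$selected_index, 1)
})

test_that("post-period counts never leak into fit, selection, or prediction", {
  sc <- one_stratum_scenario(32, multiplier = 1.4)
  covs <- generate_covariates(sc)
  visits <- generate_visits(sc, covs)
  covs1 <- covs[, !(names(covs) == "zone")]
  window <- seq(sc$event_date, sc$event_date + 6, by = "day")

  fit1 <- fit_counterfactual(visits, covs1, pre_end = sc$event_date,
                             configs = fast_configs(), seed = 5)
  mutated <- visits
  post <- mutated$date >= sc$event_date
  mutated$count[post] <- mutated$count[post] * 10L + 17L
  fit2 <- fit_counterfactual(mutated, covs1, pre_end = sc$event_date,
                             configs = fast_configs(), seed = 5)

  expect_identical(fit1$config, fit2$config)
  expect_identical(fit1$cv_results, fit2$cv_results)
  expect_identical(fit1$fitted_pre, fit2$fitted_pre)
  expect_identical(predict(fit1, window, covs1), predict(fit2, window, covs1))
})

test_that("annual harmonics beat a seasonality-free model on seasonal data", {
  sc <- one_stratum_scenario(33, annual_amplitude = 0.4, baseline = 120)
  covs <- generate_covariates(sc)
  visits <- generate_visits(sc, covs)
  fit <- fit_counterfactual(
    visits, covs[, !(names(covs) == "zone")], pre_end = sc$event_date,
    configs = list(model_config(fourier_order_annual = 0),
                   model_config(fourier_order_annual = 3)),
    seed = 6
  )
  expect_lt(fit$cv_results$mean_cv_rmse[2], fit$cv_results$mean_cv_rmse[1])
  expect_equal(fit$selected_index, 2)
})

test_that("non-finite covariates are rejected with date and column", {
  sc <- one_stratum_scenario(34)
  covs <- generate_covariates(sc)
  visits <- generate_visits(sc, covs)
  covs$ww_flu[100] <- NaN
  expect_error(
    fit_counterfactual(visits, covs[, !(names(covs) == "zone")],
                       pre_end = sc$event_date,
                       configs = fast_configs(), seed = 1),
    "ww_flu.*2023-02-08"
  )
})
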