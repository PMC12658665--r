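# Synthetic EHR generator: determinism, marginal structure, closed-form mean
# recovery, and locality of injected effects.

test_that("member generation matches the requested demographic mix", {
  sc <- synthetic_scenario(seed = 11)
  expect_equal(nrow(generate_members(sc, 0)), 0)

  n <- 10000
  m <- generate_members(sc, n)
  expect_equal(nrow(m), n)
  expect_equal(anyDuplicated(m$member_id), 0)
  p <- default_demographic_mix()$sex[["female"]]
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(m$sex == "female") - p), 3 * se)

  # deterministic given the scenario seed
  expect_identical(m, generate_members(sc, n))

  bad_mix <- list(sex = c(female = 0.6, male = 0.6),
                  race_ethnicity = default_demographic_mix()$race_ethnicity)
  expect_error(generate_members(sc, 5, demographic_mix = bad_mix), "sex")
})

test_that("covariate panel satisfies its physical invariants", {
  sc <- synthetic_scenario(n_tracts_per_zone = c(high = 1L, moderate = 1L),
                           seed = 12)
  cv <- generate_covariates(sc)
  n_days <- as.integer(sc$study_end - sc$study_start) + 1L
  expect_equal(nrow(cv), 2 * n_days)
  expect_true(all(cv$tmin_c <= cv$tmax_c))
  expect_true(all(cv$rhmin_pct <= cv$rhmax_pct))
  expect_true(all(cv$rhmax_pct <= 100 & cv$rhmin_pct >= 0))
  expect_true(all(cv$wind_ms >= 0 & cv$srad_wm2 >= 0))
  expect_true(all(cv$ww_flu > 0))

  # wastewater constant within each ISO week
  wk <- format(cv$date, "%G-W%V")
  per_week <- tapply(cv$ww_flu, paste(cv$zone, wk), function(x) length(unique(x)))
  expect_true(all(per_week == 1))

  # noise scale 0 removes all stochasticity: two seeds give identical curves
  a <- generate_covariates(synthetic_scenario(covariate_noise = 0, seed = 1))
  b <- generate_covariates(synthetic_scenario(covariate_noise = 0, seed = 2))
  expect_identical(a, b)
})

test_that("visit counts recover the closed-form Poisson mean", {
  sc <- one_stratum_scenario(13, baseline = 100, trend_slope = 0,
                             weekly_amplitude = 0, annual_amplitude = 0,
                             holiday_effect = 1, covariate_betas = numeric(0),
                             dispersion = Inf)
  v <- generate_visits(sc, generate_covariates(sc))
  n <- nrow(v)
  expect_lt(abs(mean(v$count) - 100), 3 * sqrt(100 / n))

  sc0 <- one_stratum_scenario(13, baseline = 0)
  v0 <- generate_visits(sc0, generate_covariates(sc0))
  expect_true(all(v0$count == 0))
})

test_that("injected multiplier scales the post-event mean as configured", {
  sc <- one_stratum_scenario(14, multiplier = 1.4, baseline = 100,
                             trend_slope = 0, weekly_amplitude = 0,
                             annual_amplitude = 0, holiday_effect = 1,
                             covariate_betas = numeric(0), dispersion = Inf)
  v <- generate_visits(sc, generate_covariates(sc))
  win <- v$date >= as.Date("2025-01-07") & v$date <= as.Date("2025-01-13")
  expect_lt(abs(mean(v$count[win]) - 140), 3 * sqrt(140 / 7))
  expect_equal(attr(v, "mu")[win], rep(140, 7))
})

test_that("generation is deterministic and injections are local", {
  sc <- synthetic_scenario(n_tracts_per_zone = c(high = 1L, moderate = 1L),
                           settings = "virtual",
                           causes = c("respiratory", "cardiovascular"),
                           seed = 15)
  covs <- generate_covariates(sc)
  v1 <- generate_visits(sc, covs)
  expect_identical(v1, generate_visits(sc, covs))

  sc_inj <- synthetic_scenario(n_tracts_per_zone = c(high = 1L, moderate = 1L),
                               settings = "virtual",
                               causes = c("respiratory", "cardiovascular"),
                               injected_effects = list(list(
                                 zone = "high", setting = "virtual",
                                 cause = "respiratory", start = "2025-01-07",
                                 end = "2025-01-13", multiplier = 2)),
                               seed = 15)
  v2 <- generate_visits(sc_inj, covs)
  hit <- v2$zone == "high" & v2$cause == "respiratory" &
    v2$date >= as.Date("2025-01-07") & v2$date <= as.Date("2025-01-13")
  expect_identical(v1$count[!hit], v2$count[!hit])
  expect_gt(sum(v2$count[hit]), sum(v1$count[hit]))
})

test_that("visit generation rejects covariate gaps, naming missing dates", {
  sc <- one_stratum_scenario(16)
  covs <- generate_covariates(sc)
  expect_error(generate_visits(sc, covs[-c(5, 6), ]),
               "missing for zone 'high'.*2022-11-05")
})

test_that("scenario validation enforces window and effect invariants", {
  expect_error(synthetic_scenario(event_date = "2022-10-01"), "study_start")
  expect_error(synthetic_scenario(baseline_rate = -1), "baseline")
  expect_error(
    synthetic_scenario(injected_effects = list(list(
      zone = "high", setting = "virtual", cause = "respiratory",
      start = "2024-01-01", end = "2024-01-07", multiplier = 1.4))),
    "within \\[event_date, study_end\\]"
  )
})

test_that("scenario YAML round-trips every generative parameter", {
  sc <- one_stratum_scenario(17, multiplier = 1.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2, sc)
})
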