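# Stage 2 of the two-stage interrupted time series: excess visits over a
# post-event window with 95% empirical confidence intervals from a circular
# moving-block bootstrap of pre-period residuals around the stage-1
# counterfactual (1000 Monte Carlo iterations by default).

#' Excess visits and percent excess over a window
#'
#' @param observed,predicted Equal-length numeric vectors over the window.
#' @return List with `excess = sum(observed - predicted)` and
#'   `pct_excess = 100 * excess / sum(predicted)` (`NA` with a warning when
#'   the predicted total is 0).
#' @examples
#' excess_visits(c(50, 45, 45), c(40, 40, 20))  # 40 excess, 40%
#' @export
excess_visits <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  exc <- sum(observed - predicted)
  tot <- sum(predicted)
  if (tot <= 0) {
    warning("predicted total is 0; percent excess undefined", call. = FALSE)
    return(list(excess = exc, pct_excess = NA_real_))
  }
  list(excess = exc, pct_excess = 100 * exc / tot)
}

# circular moving-block bootstrap: n_iter x n_days matrix of resampled
# residuals (blocks of block_len wrap around the residual vector); block
# starts can be restricted to a subset of positions (seasonal sampling)
block_bootstrap_matrix <- function(residuals, n_days, n_iter, block_len, seed,
                                   eligible_starts = NULL) {
  n_res <- length(residuals)
  stopifnot(n_res >= 1, block_len >= 1)
  if (is.null(eligible_starts) || length(eligible_starts) < 30) {
    eligible_starts <- seq_len(n_res)
  }
  n_blocks <- ceiling(n_days / block_len)
  with_seed(seed, {
    starts <- matrix(sample(eligible_starts, n_iter * n_blocks, replace = TRUE),
                     nrow = n_iter)
    offs <- rep(seq_len(block_len) - 1L, n_blocks)[seq_len(n_days)]
    blk <- rep(seq_len(n_blocks), each = block_len)[seq_len(n_days)]
    t(apply(starts, 1, function(s) {
      residuals[((s[blk] + offs - 1L) %% n_res) + 1L]
    }))
  })
}

# block-start positions whose day-of-year lies within half_width days of the
# window's mean day-of-year (wrapping across the year boundary); residual
# variance of daily counts is strongly seasonal, so resampling within the
# matching season keeps the interval honest for winter windows
seasonal_starts <- function(residual_dates, window_dates, half_width) {
  if (is.null(residual_dates) || is.null(half_width) || !is.finite(half_width)) {
    return(NULL)
  }
  doy <- as.POSIXlt(residual_dates)$yday
  target <- mean(as.POSIXlt(window_dates)$yday)
  delta <- abs(doy - target)
  delta <- pmin(delta, 365.25 - delta)
  which(delta <= half_width)
}

# moment estimate of the negative-binomial dispersion k from residuals
# around fitted means (variance = m + m^2/k); Inf means Poisson-or-less
estimate_dispersion <- function(residuals, fitted) {
  num <- sum(residuals^2 - fitted)
  if (num <= 0) return(Inf)
  sum(fitted^2) / num
}

# shared Monte Carlo machinery: one set of draws yields both the cumulative
# and the per-day estimates, so daily excess sums to cumulative excess within
# every iteration. When `pool_sd`/`target_sd` are given, residual blocks are
# standardized by the fitted-scale standard deviation of their source day and
# rescaled to the predicted window day (a heteroscedastic residual bootstrap:
# count variance grows with the predicted level, and the post-event window
# sits at the seasonal peak); `inflation` stretches draws to the
# out-of-sample error scale estimated by cross-validation.
mc_core <- function(predicted, observed, residuals, dates,
                    n_iter, block_len, seed,
                    residual_dates = NULL, season_half_width = 45,
                    pool_sd = NULL, target_sd = NULL, inflation = 1) {
  stopifnot(n_iter >= 2, length(observed) == length(predicted))
  n_days <- length(predicted)
  if (!is.null(pool_sd)) residuals <- residuals / pmax(pool_sd, 1e-8)
  pert <- block_bootstrap_matrix(
    residuals, n_days, n_iter, block_len, seed,
    eligible_starts = seasonal_starts(residual_dates, dates, season_half_width)
  )
  if (!is.null(target_sd)) {
    pert <- pert * matrix(inflation * target_sd, n_iter, n_days, byrow = TRUE)
  }
  pred_mat <- pmax(matrix(predicted, n_iter, n_days, byrow = TRUE) + pert, 0)
  degenerate <- all(residuals == 0)
  # iterations whose perturbed prediction is floored to 0 have no defined
  # percent excess and drop out of the percent quantiles
  ci <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    unname(quantile(x, c(0.025, 0.975), type = 7, names = FALSE))
  }
  cum_pred <- rowSums(pred_mat)
  cum_exc <- sum(observed) - cum_pred
  cum_pct <- ifelse(cum_pred > 0, 100 * cum_exc / cum_pred, NA_real_)
  point <- excess_visits(observed, predicted)
  pct_ci <- ci(cum_pct)
  exc_ci <- ci(cum_exc)
  cumulative <- tibble::tibble(
    window_start = min(dates), window_end = max(dates),
    observed = sum(observed), predicted = sum(predicted),
    excess = point$excess, pct_excess = point$pct_excess,
    ci_low = pct_ci[1], ci_high = pct_ci[2],
    excess_ci_low = exc_ci[1], excess_ci_high = exc_ci[2],
    n_iterations = as.integer(n_iter), degenerate = degenerate
  )
  day_exc <- matrix(observed, n_iter, n_days, byrow = TRUE) - pred_mat
  day_pct <- ifelse(pred_mat > 0, 100 * day_exc / pred_mat, NA_real_)
  daily <- tibble::tibble(
    date = dates, observed = observed, predicted = predicted,
    excess = observed - predicted,
    pct_excess = ifelse(predicted > 0, 100 * (observed - predicted) / predicted,
                        NA_real_),
    ci_low = apply(day_pct, 2, function(x) ci(x)[1]),
    ci_high = apply(day_pct, 2, function(x) ci(x)[2]),
    excess_ci_low = apply(day_exc, 2, function(x) ci(x)[1]),
    excess_ci_high = apply(day_exc, 2, function(x) ci(x)[2]),
    n_iterations = as.integer(n_iter)
  )
  if (degenerate) {
    warning("all residuals are zero: empirical CI is degenerate", call. = FALSE)
  }
  list(cumulative = cumulative, daily = daily,
       draws = list(cum_excess = cum_exc, cum_pct = cum_pct))
}

#' Monte Carlo empirical confidence interval for excess visits
#'
#' Around the selected counterfactual's point predictions over the window,
#' each iteration adds a circular moving-block bootstrap sample of the
#' pre-period residuals, floors the perturbed counterfactual at 0, and
#' recomputes cumulative percent excess; the 95% empirical CI is the
#' 2.5th/97.5th percentile of the iterations. The point estimate always uses
#' the unperturbed predictions.
#'
#' `monte_carlo_excess()` is the series-level core (explicit predictions and
#' residuals, added to the predictions as-is); `monte_carlo_ci()` derives
#' predictions from a [fit_counterfactual()] object and additionally (i)
#' standardizes each resampled residual by the negative-binomial standard
#' deviation of its source day and rescales it to the predicted window day,
#' so the interval reflects the window's own variance level, and (ii)
#' inflates draws by the ratio of cross-validated to in-sample RMSE (floored
#' at 1), the honest out-of-sample error scale. Both are deterministic given
#' `seed`.
#'
#' @param predicted,observed Numeric vectors over the window.
#' @param residuals Pre-period residuals (observed - fitted) of the selected
#'   model.
#' @param dates Window dates (same length as `observed`).
#' @param n_iter Monte Carlo iterations (default 1000).
#' @param block_len Bootstrap block length in days (default 7, one weekly
#'   cycle).
#' @param seed Integer seed.
#' @param residual_dates Optional dates of the residual vector. When given,
#'   block starts are restricted to pre-period days whose day-of-year lies
#'   within `season_half_width` days of the window (seasonal moving-block
#'   bootstrap); daily count residuals are strongly heteroscedastic across
#'   the year, so season-matched resampling keeps winter intervals honest.
#' @param season_half_width Seasonal matching half-width in days (default
#'   45; `Inf` restores whole-year sampling). Ignored when fewer than 30
#'   eligible block starts remain.
#' @return One-row tibble (the cumulative `ExcessEstimate`): `observed`,
#'   `predicted`, `excess`, `pct_excess`, percent CI (`ci_low`, `ci_high`),
#'   count CI (`excess_ci_low`, `excess_ci_high`), `n_iterations`, and a
#'   `degenerate` flag (all-zero residuals).
#' @export
monte_carlo_excess <- function(predicted, observed, residuals, dates = NULL,
                               n_iter = 1000, block_len = 7, seed = 1L,
                               residual_dates = NULL, season_half_width = 45) {
  dates <- as.Date(dates %||% (as.Date("1970-01-01") + seq_along(observed)))
  res <- mc_core(predicted, observed, residuals, dates, n_iter, block_len, seed,
                 residual_dates = residual_dates,
                 season_half_width = season_half_width)
  res$cumulative
}

#' @rdname monte_carlo_excess
#' @param fit A `counterfactual_fit`.
#' @param series Observed visit series (data frame with `date`, `count`)
#'   covering the window.
#' @param covariates Covariate panel covering the window (for the residual
#'   booster's features).
#' @param window Two dates `c(start, end)` or a vector of dates.
#' @param mode `"resample"` (default: residual bootstrap around one fit) or
#'   `"refit"` (slow mode: each iteration refits the selected configuration
#'   on a bootstrap-perturbed pre-period series and re-predicts).
#' @export
monte_carlo_ci <- function(fit, series, covariates, window, n_iter = 1000,
                           block_len = 7, seed = 1L,
                           mode = c("resample", "refit"),
                           season_half_width = 45) {
  mode <- match.arg(mode)
  prep <- mc_prepare(fit, series, covariates, window)
  if (mode == "refit") {
    return(mc_refit(fit, prep, covariates, n_iter, block_len, seed))
  }
  sc <- mc_fit_scales(fit, prep$predicted)
  mc_core(prep$predicted, prep$observed, fit$residuals, prep$dates,
          n_iter, block_len, seed, residual_dates = fit$pre_dates,
          season_half_width = season_half_width,
          pool_sd = sc$pool_sd, target_sd = sc$target_sd,
          inflation = sc$inflation)$cumulative
}

#' Daily excess profile with a consistent cumulative estimate
#'
#' Applies the Monte Carlo machinery of [monte_carlo_ci()] per day, using the
#' same iteration draws for the daily and the cumulative estimates, so
#' per-iteration daily excesses sum exactly to that iteration's cumulative
#' excess.
#'
#' @inheritParams monte_carlo_ci
#' @return List with `daily` (one `ExcessEstimate` row per window day) and
#'   `cumulative` (identical to the [monte_carlo_ci()] result at the same
#'   seed).
#' @export
daily_excess_profile <- function(fit, series, covariates, window,
                                 n_iter = 1000, block_len = 7, seed = 1L,
                                 season_half_width = 45) {
  prep <- mc_prepare(fit, series, covariates, window)
  sc <- mc_fit_scales(fit, prep$predicted)
  res <- mc_core(prep$predicted, prep$observed, fit$residuals, prep$dates,
                 n_iter, block_len, seed, residual_dates = fit$pre_dates,
                 season_half_width = season_half_width,
                 pool_sd = sc$pool_sd, target_sd = sc$target_sd,
                 inflation = sc$inflation)
  res[c("daily", "cumulative")]
}

# heteroscedastic scales for the fit-level bootstrap: per-day residual sd on
# the pre-period (pool) and prediction window (target) under the estimated
# negative-binomial variance, plus an out-of-sample inflation factor (the
# ratio of cross-validated to in-sample RMSE, floored at 1: a model cannot
# honestly predict new days better than it fits its training days)
mc_fit_scales <- function(fit, predicted) {
  k <- estimate_dispersion(fit$residuals, fit$fitted_pre)
  v <- function(m) { m <- pmax(m, 1); if (is.finite(k)) m + m^2 / k else m }
  in_rmse <- sqrt(mean(fit$residuals^2))
  list(pool_sd = sqrt(v(fit$fitted_pre)),
       target_sd = sqrt(v(predicted)),
       inflation = if (in_rmse > 0) max(1, fit$cv_rmse / in_rmse) else 1)
}

mc_prepare <- function(fit, series, covariates, window) {
  window <- as.Date(window)
  dates <- if (length(window) == 2) seq(window[1], window[2], by = "day") else window
  idx <- match(dates, as.Date(series$date))
  if (anyNA(idx)) {
    stop("observed series missing window dates: ",
         paste(format(dates[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  list(dates = dates, observed = series$count[idx],
       predicted = predict(fit, dates, covariates))
}

# slow mode: refit the selected configuration per iteration on a
# block-bootstrap-perturbed pre-period and re-predict the window
mc_refit <- function(fit, prep, covariates, n_iter, block_len, seed) {
  n_pre <- length(fit$pre_dates)
  pert <- block_bootstrap_matrix(fit$residuals, n_pre, n_iter, block_len, seed)
  preds <- matrix(NA_real_, n_iter, length(prep$dates))
  for (i in seq_len(n_iter)) {
    tr <- tibble::tibble(date = fit$pre_dates,
                         count = pmax(fit$fitted_pre + pert[i, ], 0))
    m <- fit_hybrid(tr, covariates, fit$config, fit$model$cov_names, fit$seed)
    preds[i, ] <- pmax(predict_hybrid(m, prep$dates, covariates), 0)
  }
  ci <- function(x) unname(quantile(x, c(0.025, 0.975), type = 7, names = FALSE))
  cum_pred <- rowSums(preds)
  cum_exc <- sum(prep$observed) - cum_pred
  cum_pct <- ifelse(cum_pred > 0, 100 * cum_exc / cum_pred, NA_real_)
  point <- excess_visits(prep$observed, prep$predicted)
  pct_ci <- ci(cum_pct)
  exc_ci <- ci(cum_exc)
  tibble::tibble(
    window_start = min(prep$dates), window_end = max(prep$dates),
    observed = sum(prep$observed), predicted = sum(prep$predicted),
    excess = point$excess, pct_excess = point$pct_excess,
    ci_low = pct_ci[1], ci_high = pct_ci[2],
    excess_ci_low = exc_ci[1], excess_ci_high = exc_ci[2],
    n_iterations = as.integer(n_iter), degenerate = FALSE
  )
}
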