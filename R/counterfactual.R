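# Stage 1 of the two-stage interrupted time series: a hybrid counterfactual
# model fit on pre-event data only. The base learner is a structural
# seasonal-trend regression (piecewise-linear trend, annual Fourier
# harmonics, day-of-week and holiday terms); an optional gradient-boosted
# residual corrector learns what the structural part misses from exogenous
# covariates and calendar features. The corrector never sees lagged observed
# counts: post-event prediction must not depend on post-event outcomes, which
# embed the very effect stage 2 estimates.

#' Model configuration for the hybrid counterfactual
#'
#' @param base_learner `"structural_seasonal"` (piecewise-linear trend) or
#'   `"seasonal_regression"` (strictly linear trend).
#' @param fourier_order_annual Number of annual sine/cosine harmonic pairs
#'   (>= 0; 0 disables annual seasonality).
#' @param trend_flexibility Number of trend changepoints (>= 0; only used by
#'   `structural_seasonal`). 0 is a single linear trend.
#' @param use_holidays Include a holiday indicator ([us_holidays()] plus the
#'   late-December block)?
#' @param residual_learner `"none"` or `"gradient_boosting"`.
#' @param gb_depth,gb_learning_rate,gb_rounds Gradient-boosting tree depth,
#'   learning rate in (0, 1], and boosting rounds (>= 0; 0 rounds makes the
#'   corrector a no-op). Ignored when `residual_learner = "none"`.
#' @param gb_min_child_weight,gb_lambda Regularization for the corrector:
#'   minimum hessian per leaf and L2 penalty. The corrector sees a weak,
#'   season-concentrated signal under heavy count noise, so it is strongly
#'   regularized by default.
#' @param covariate_names Covariate columns fed to the residual learner;
#'   `NULL` means every numeric covariate available at fit time.
#' @return A `model_config` list.
#' @export
model_config <- function(base_learner = c("structural_seasonal", "seasonal_regression"),
                         fourier_order_annual = 3,
                         trend_flexibility = 0,
                         use_holidays = TRUE,
                         residual_learner = c("none", "gradient_boosting"),
                         gb_depth = 2, gb_learning_rate = 0.05, gb_rounds = 200,
                         gb_min_child_weight = 30, gb_lambda = 10,
                         covariate_names = NULL) {
  base_learner <- match.arg(base_learner)
  residual_learner <- match.arg(residual_learner)
  stopifnot(fourier_order_annual >= 0, trend_flexibility >= 0,
            gb_depth >= 1, gb_learning_rate > 0, gb_learning_rate <= 1,
            gb_rounds >= 0, gb_min_child_weight >= 0, gb_lambda >= 0)
  structure(list(base_learner = base_learner,
                 fourier_order_annual = as.integer(fourier_order_annual),
                 trend_flexibility = as.integer(trend_flexibility),
                 use_holidays = isTRUE(use_holidays),
                 residual_learner = residual_learner,
                 gb_depth = as.integer(gb_depth),
                 gb_learning_rate = gb_learning_rate,
                 gb_rounds = as.integer(gb_rounds),
                 gb_min_child_weight = gb_min_child_weight,
                 gb_lambda = gb_lambda,
                 covariate_names = covariate_names),
            class = "model_config")
}

config_label <- function(cfg) {
  sprintf("%s/K%d/cp%d%s/%s", cfg$base_learner, cfg$fourier_order_annual,
          cfg$trend_flexibility, if (cfg$use_holidays) "/hol" else "",
          if (cfg$residual_learner == "none") "none"
          else sprintf("gb(d%d,eta%g,n%d)", cfg$gb_depth, cfg$gb_learning_rate,
                       cfg$gb_rounds))
}

#' Default candidate-model grid
#'
#' A small grid suited to desk-scale cross-validation: structural seasonal
#' base learner with annual Fourier order 3 or 8 and residual learner none
#' or gradient boosting at depth 2 or 4. Within each base-learner shape the
#' no-corrector config precedes the boosted ones, so RMSE ties resolve to
#' the simpler model. Trend changepoints are deliberately absent: they
#' improve in-sample fit but destabilize the boundary extrapolation that a
#' short post-event forecast depends on (the last trend segment is estimated
#' from a sliver of data); `trend_flexibility` remains available through
#' [model_config()] for users who want it in a custom grid.
#'
#' @return List of [model_config()] objects.
#' @export
default_config_grid <- function() {
  out <- list()
  for (K in c(3L, 8L)) {
    out <- c(out, list(model_config(fourier_order_annual = K)))
    for (d in c(2L, 4L)) {
      out <- c(out, list(model_config(fourier_order_annual = K,
                                      residual_learner = "gradient_boosting",
                                      gb_depth = d)))
    }
  }
  out
}

#' Rolling-origin cross-validation scheme
#'
#' The default (10 folds of 7 days, no gap) matches the validation horizon to
#' the 7-day post-event prediction task and concentrates the validation
#' windows on the weeks leading up to the event, where the counterfactual
#' will be deployed.
#'
#' @param n_folds Number of folds (default 10).
#' @param validation_days Length of each validation window in days
#'   (default 7).
#' @param gap_days Days left out between a fold's training data and its
#'   validation window (default 0).
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(n_folds = 10, validation_days = 7, gap_days = 0) {
  stopifnot(n_folds >= 1, validation_days >= 1, gap_days >= 0)
  structure(list(n_folds = as.integer(n_folds),
                 validation_days = as.integer(validation_days),
                 gap_days = as.integer(gap_days)),
            class = "cv_scheme")
}

#' Root-mean-square error
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 1).
#' @return `sqrt(mean((observed - predicted)^2))`, in visits/day.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  stopifnot(length(observed) >= 1)
  sqrt(mean((observed - predicted)^2))
}

MIN_TRAIN_DAYS <- 365L

#' Build rolling-origin cross-validation folds
#'
#' The validation windows are the last `n_folds` non-overlapping blocks of
#' `validation_days` in the pre-period; each fold trains only on dates ending
#' at least `gap_days` before its validation window, preserving temporal
#' order. A minimum of 365 training days is required ahead of the earliest
#' window so every fold sees a full annual cycle.
#'
#' @param pre_dates Sorted vector of pre-period dates.
#' @param scheme A [cv_scheme()].
#' @return List of `n_folds` elements (chronological), each
#'   `list(train = <dates>, validation = <dates>)`.
#' @export
make_folds <- function(pre_dates, scheme) {
  pre_dates <- sort(unique(as.Date(pre_dates)))
  n <- length(pre_dates)
  need <- scheme$n_folds * scheme$validation_days + MIN_TRAIN_DAYS + scheme$gap_days
  if (n < need) {
    stop("pre-period has ", n, " days but the CV scheme needs at least ",
         need, call. = FALSE)
  }
  lapply(seq_len(scheme$n_folds), function(i) {
    v_end <- n - (scheme$n_folds - i) * scheme$validation_days
    v_start <- v_end - scheme$validation_days + 1
    validation <- pre_dates[v_start:v_end]
    train <- pre_dates[pre_dates <= validation[1] - 1 - scheme$gap_days]
    list(train = train, validation = validation)
  })
}

# ---- feature construction -------------------------------------------------

TIME_EPOCH <- as.Date("2020-01-01")

base_features <- function(dates, cfg, changepoints) {
  t_yr <- as.numeric(dates - TIME_EPOCH) / 365.25
  df <- data.frame(t = t_yr)
  for (j in seq_along(changepoints)) {
    df[[paste0("cp", j)]] <- pmax(t_yr - changepoints[j], 0)
  }
  for (k in seq_len(cfg$fourier_order_annual)) {
    df[[paste0("s", k)]] <- sin(2 * pi * k * t_yr)
    df[[paste0("c", k)]] <- cos(2 * pi * k * t_yr)
  }
  df$dow <- factor(as.POSIXlt(dates)$wday, levels = 0:6)
  if (cfg$use_holidays) df$holiday <- as.numeric(is_holiday(dates))
  df
}

gb_features <- function(dates, covariates, cov_names, scale_stats) {
  idx <- match(dates, covariates$date)
  mats <- list()
  if (length(cov_names) > 0) {
    m <- as.matrix(covariates[idx, cov_names, drop = FALSE])
    m <- sweep(sweep(m, 2, scale_stats$mean, "-"), 2, scale_stats$sd, "/")
    mats$cov <- m
  }
  wd <- as.POSIXlt(dates)$wday
  dow <- matrix(0, length(dates), 7, dimnames = list(NULL, paste0("dow", 0:6)))
  dow[cbind(seq_along(dates), wd + 1)] <- 1
  mats$dow <- dow
  mats$holiday <- matrix(as.numeric(is_holiday(dates)), ncol = 1,
                         dimnames = list(NULL, "holiday"))
  do.call(cbind, mats)
}

# fit the hybrid model (base + optional residual booster) on training rows
fit_hybrid <- function(train, covariates, cfg, cov_names, seed) {
  changepoints <- numeric(0)
  if (cfg$base_learner == "structural_seasonal" && cfg$trend_flexibility > 0) {
    t_yr <- as.numeric(train$date - TIME_EPOCH) / 365.25
    qs <- seq_len(cfg$trend_flexibility) / (cfg$trend_flexibility + 1)
    changepoints <- unname(quantile(t_yr, qs, type = 7))
  }
  bf <- base_features(train$date, cfg, changepoints)
  bf$count <- train$count
  # log-link count regression: trend, seasonality and the holiday dip act
  # multiplicatively on the visit rate (quasipoisson tolerates the
  # non-integer outcomes of the bootstrap-refit mode)
  base_fit <- stats::glm(count ~ ., data = bf,
                         family = stats::quasipoisson(link = "log"))
  base_pred <- unname(predict(base_fit, newdata = bf, type = "response"))
  booster <- NULL
  scale_stats <- NULL
  if (cfg$residual_learner == "gradient_boosting" && cfg$gb_rounds > 0) {
    m <- as.matrix(covariates[match(train$date, covariates$date), cov_names,
                              drop = FALSE])
    scale_stats <- list(mean = colMeans(m), sd = apply(m, 2, sd))
    scale_stats$sd[!is.finite(scale_stats$sd) | scale_stats$sd == 0] <- 1
    X <- gb_features(train$date, covariates, cov_names, scale_stats)
    # the corrector learns relative residuals: covariate effects act
    # multiplicatively on the rate, so (obs - base)/base is approximately
    # linear in the covariates and not swamped by count-level noise
    rel_resid <- (train$count - base_pred) / pmax(base_pred, 1)
    with_seed(seed, {
      booster <- xgboost::xgb.train(
        params = list(max_depth = cfg$gb_depth, eta = cfg$gb_learning_rate,
                      min_child_weight = cfg$gb_min_child_weight,
                      lambda = cfg$gb_lambda,
                      objective = "reg:squarederror", nthread = 1,
                      seed = seed),
        data = xgboost::xgb.DMatrix(X, label = rel_resid),
        nrounds = cfg$gb_rounds, verbose = 0
      )
    })
  }
  structure(list(config = cfg, base_fit = base_fit, changepoints = changepoints,
                 booster = booster, scale_stats = scale_stats,
                 cov_names = cov_names),
            class = "hybrid_model")
}

predict_hybrid <- function(model, dates, covariates) {
  bf <- base_features(dates, model$config, model$changepoints)
  pred <- unname(predict(model$base_fit, newdata = bf, type = "response"))
  if (!is.null(model$booster)) {
    X <- gb_features(dates, covariates, model$cov_names, model$scale_stats)
    pred <- pred * (1 + predict(model$booster, xgboost::xgb.DMatrix(X)))
  }
  pred
}

check_covariates <- function(covariates, dates, cov_names) {
  if (anyDuplicated(covariates$date) > 0) {
    stop("covariates must have one row per date (filter to one zone first)",
         call. = FALSE)
  }
  miss <- dates[!dates %in% covariates$date]
  if (length(miss) > 0) {
    stop("covariates missing for dates: ",
         paste(utils::head(format(miss), 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(dates, covariates$date)
  for (nm in cov_names) {
    bad <- !is.finite(covariates[[nm]][idx])
    if (any(bad)) {
      stop("non-finite covariate '", nm, "' on date ",
           format(covariates$date[idx][which(bad)[1]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Fit the stage-1 counterfactual model for one stratum
#'
#' For every candidate configuration the mean RMSE over rolling-origin
#' cross-validation folds is computed on pre-period data only; the candidate
#' with the smallest mean RMSE (ties resolving to the earlier entry in
#' `configs`) is refit on the full pre-period. Hybrid fitting is sequential:
#' the structural base learner is fit to counts, then gradient boosting
#' learns the base learner's residuals from covariates, day-of-week and
#' holiday features. Nothing after `pre_end` is ever touched, so post-event
#' predictions are genuine counterfactuals.
#'
#' @param series Visit series for one stratum: data frame with `date` and
#'   `count` (any additional stratum columns are carried as metadata).
#' @param covariates Covariate panel filtered to the stratum's zone: one row
#'   per date, numeric covariate columns.
#' @param pre_end First post-period date; only `date < pre_end` rows are used.
#' @param configs Non-empty list of [model_config()] candidates.
#' @param scheme A [cv_scheme()].
#' @param seed Integer seed for the residual booster.
#' @return A `counterfactual_fit` with elements `config` (selected),
#'   `cv_results` (mean CV RMSE per candidate), `cv_rmse`, `fitted_pre`,
#'   `residuals` (observed - fitted over the pre-period), `n_clipped`
#'   (negative predictions floored at 0), `stratum`, and `predict` via
#'   [predict.counterfactual_fit()].
#' @export
fit_counterfactual <- function(series, covariates, pre_end,
                               configs = default_config_grid(),
                               scheme = cv_scheme(), seed = 1L) {
  stopifnot(length(configs) >= 1)
  pre_end <- as.Date(pre_end)
  series <- dplyr::arrange(series[series$date < pre_end, , drop = FALSE], .data$date)
  if (anyDuplicated(series$date) > 0) {
    stop("series must have one row per date (one stratum)", call. = FALSE)
  }
  all_cov <- setdiff(names(covariates)[vapply(covariates, is.numeric, logical(1))],
                     c("lon", "lat"))
  cov_names_for <- function(cfg) {
    nm <- cfg$covariate_names %||% all_cov
    bad <- setdiff(nm, names(covariates))
    if (length(bad) > 0) stop("unknown covariate(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    nm
  }
  needs_cov <- any(vapply(configs, function(cfg)
    cfg$residual_learner == "gradient_boosting", logical(1)))
  if (needs_cov) {
    check_covariates(covariates, series$date,
                     unique(unlist(lapply(configs, cov_names_for))))
  }
  folds <- make_folds(series$date, scheme)
  cv_mean <- vapply(seq_along(configs), function(ci) {
    cfg <- configs[[ci]]
    cov_names <- cov_names_for(cfg)
    fold_rmse <- vapply(folds, function(f) {
      tr <- series[series$date %in% f$train, , drop = FALSE]
      m <- fit_hybrid(tr, covariates, cfg, cov_names, seed)
      pred <- pmax(predict_hybrid(m, f$validation, covariates), 0)
      rmse(series$count[match(f$validation, series$date)], pred)
    }, numeric(1))
    mean(fold_rmse)
  }, numeric(1))
  best <- which.min(cv_mean)  # first minimum wins ties
  cfg <- configs[[best]]
  model <- fit_hybrid(series, covariates, cfg, cov_names_for(cfg), seed)
  fitted_raw <- predict_hybrid(model, series$date, covariates)
  fitted_pre <- pmax(fitted_raw, 0)
  stratum_cols <- intersect(c("zone", "setting", "cause"), names(series))
  structure(list(
    config = cfg, selected_index = best,
    cv_results = tibble::tibble(
      config = vapply(configs, config_label, character(1)),
      mean_cv_rmse = cv_mean, selected = seq_along(configs) == best),
    cv_rmse = cv_mean[best],
    model = model,
    pre_dates = series$date, fitted_pre = fitted_pre,
    residuals = series$count - fitted_pre,
    n_clipped = sum(fitted_raw < 0),
    stratum = if (length(stratum_cols) > 0)
      as.list(series[1, stratum_cols, drop = FALSE]) else NULL,
    seed = seed
  ), class = "counterfactual_fit")
}

#' Predict counterfactual visit counts
#'
#' Predictions for any date range use only calendar features and exogenous
#' covariates — never observed counts — and are floored at 0.
#'
#' @param object A `counterfactual_fit`.
#' @param dates Dates to predict.
#' @param covariates Covariate panel covering `dates` (one row per date).
#' @param ... Unused.
#' @return Numeric vector of non-negative predicted visits/day.
#' @export
predict.counterfactual_fit <- function(object, dates, covariates, ...) {
  dates <- as.Date(dates)
  if (!is.null(object$model$booster)) {
    check_covariates(covariates, dates, object$model$cov_names)
  }
  pmax(predict_hybrid(object$model, dates, covariates), 0)
}

#' @export
print.counterfactual_fit <- function(x, ...) {
  cat("<counterfactual_fit>",
      if (!is.null(x$stratum)) paste0(unlist(x$stratum), collapse = "/") else "",
      "\n  selected:", config_label(x$config),
      sprintf("\n  mean CV RMSE: %.3f visits/day over %d candidate(s)",
              x$cv_rmse, nrow(x$cv_results)),
      sprintf("\n  pre-period: %s .. %s (%d days, %d clipped predictions)\n",
              format(min(x$pre_dates)), format(max(x$pre_dates)),
              length(x$pre_dates), x$n_clipped))
  invisible(x)
}
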