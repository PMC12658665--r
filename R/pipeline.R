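#' Run both stages of the interrupted time series for one stratum
#'
#' Filters the visit and covariate tables to one zone x setting x cause
#' stratum, fits the stage-1 counterfactual on pre-event data with
#' cross-validated model selection, and computes the stage-2 daily and
#' cumulative excess estimates with Monte Carlo empirical CIs over the
#' post-event window.
#'
#' @param visits `VisitSeries` tibble (`date`, `zone`, `setting`, `cause`,
#'   `count`).
#' @param covariates Covariate panel with a `zone` column.
#' @param zone,setting,cause The stratum to analyze.
#' @param pre_end First post-period date (the event date).
#' @param window Post-event evaluation window, `c(start, end)`; defaults to
#'   the week starting at `pre_end`.
#' @param configs,scheme,n_iter,block_len,seed,mode Passed to
#'   [fit_counterfactual()] and [monte_carlo_ci()].
#' @return List with `fit` (`counterfactual_fit`), `cumulative` (one-row
#'   excess estimate, with `zone`, `setting`, `cause` columns prepended) and
#'   `daily`.
#' @export
estimate_stratum_excess <- function(visits, covariates, zone, setting, cause,
                                    pre_end,
                                    window = c(as.Date(pre_end),
                                               as.Date(pre_end) + 6),
                                    configs = default_config_grid(),
                                    scheme = cv_scheme(),
                                    n_iter = 1000, block_len = 7, seed = 1L,
                                    mode = c("resample", "refit")) {
  mode <- match.arg(mode)
  series <- visits[visits$zone == zone & visits$setting == setting &
                     visits$cause == cause, , drop = FALSE]
  if (nrow(series) == 0) {
    stop("no visit rows for stratum ", zone, "/", setting, "/", cause,
         call. = FALSE)
  }
  cov_z <- covariates[covariates$zone == zone, , drop = FALSE]
  fit <- fit_counterfactual(series, cov_z, pre_end = pre_end,
                            configs = configs, scheme = scheme, seed = seed)
  if (mode == "refit") {
    cumulative <- monte_carlo_ci(fit, series, cov_z, window, n_iter = n_iter,
                                 block_len = block_len, seed = seed,
                                 mode = "refit")
    daily <- NULL
  } else {
    prof <- daily_excess_profile(fit, series, cov_z, window, n_iter = n_iter,
                                 block_len = block_len, seed = seed)
    cumulative <- prof$cumulative
    daily <- dplyr::bind_cols(
      tibble::tibble(zone = zone, setting = setting, cause = cause),
      prof$daily
    )
  }
  cumulative <- dplyr::bind_cols(
    tibble::tibble(zone = zone, setting = setting, cause = cause), cumulative
  )
  list(fit = fit, cumulative = cumulative, daily = daily)
}
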