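#' Define a synthetic study scenario
#'
#' A scenario is the full generative parameter set for the synthetic EHR
#' module: study window, event date, tract counts per exposure zone, baseline
#' visit rates, trend, weekly/annual/holiday seasonality, covariate effects,
#' count dispersion, and a list of injected post-event effects. Because every
#' parameter is known, pipelines run on scenario data support
#' parameter-recovery tests: the injected multiplier is the truth the
#' two-stage estimator should recover.
#'
#' Defaults mirror the study conditions the package targets: a 26-month
#' membership window from 2022-11-01 through 2025-01-21 with an abrupt event
#' on 2025-01-07.
#'
#' @param study_start,study_end,event_date Dates (or strings) with
#'   `study_start < event_date <= study_end`.
#' @param n_tracts_per_zone Named integer vector over
#'   `c("high", "moderate", "minimal")`; zones with 0 tracts are dropped from
#'   generated tables.
#' @param baseline_rate Expected visits/day for one zone x setting x cause
#'   cell. Either a single non-negative number applied to every cell or a
#'   named vector over cause categories.
#' @param trend_slope Long-term change in visits/day per year (additive on the
#'   baseline level).
#' @param weekly_amplitude Scale (>= 0) on the day-of-week pattern; 0 switches
#'   weekly seasonality off, 1 is the full default pattern in which weekends
#'   fall well below weekdays (outpatient more so than virtual care).
#' @param annual_amplitude Relative amplitude (>= 0) of a winter-peaking
#'   annual cycle in the visit rate.
#' @param holiday_effect Multiplier in (0, 2] applied on
#'   [us_holidays()] dates; values < 1 are dips.
#' @param covariate_betas Named numeric vector of log-rate coefficients per
#'   standardized (pre-period z-scored) covariate unit. Names must be
#'   covariate columns of [generate_covariates()].
#' @param dispersion Negative-binomial dispersion `k` (> 0), with
#'   `variance = mu + mu^2 / k`; `Inf` gives Poisson counts.
#' @param injected_effects List of effects, each a list with elements
#'   `zone`, `setting`, `cause`, `start`, `end`, `multiplier` (> 0). Every
#'   window must lie within `[event_date, study_end]`.
#' @param covariate_noise Scale (>= 0) on all covariate noise terms; 0 yields
#'   the deterministic seasonal curves.
#' @param settings,causes Character subsets of the care settings and cause
#'   categories to generate (defaults: all).
#' @param seed Master integer seed; per-stream child seeds (members, tracts,
#'   covariates, visits) are derived from it deterministically.
#' @return An object of class `fire_scenario` (a validated list).
#' @examples
#' sc <- synthetic_scenario(baseline_rate = 80, seed = 1)
#' sc$event_date
#' @seealso [generate_visits()], [generate_covariates()], [simulate_study()]
#' @export
synthetic_scenario <- function(study_start = "2022-11-01",
                               study_end = "2025-01-21",
                               event_date = "2025-01-07",
                               n_tracts_per_zone = c(high = 8L, moderate = 12L, minimal = 10L),
                               baseline_rate = c(all_cause = 400, cardiovascular = 40,
                                                 injury = 30, neuropsychiatric = 50,
                                                 respiratory = 80),
                               trend_slope = 2,
                               weekly_amplitude = 1,
                               annual_amplitude = 0.10,
                               holiday_effect = 0.6,
                               covariate_betas = c(tmax_c = 0.02, rhmin_pct = -0.01,
                                                   ww_flu = 0.08, ww_rsv = 0.04,
                                                   ww_cov = 0.05),
                               dispersion = 50,
                               injected_effects = list(),
                               covariate_noise = 1,
                               settings = setting_levels(),
                               causes = cause_levels(),
                               seed = 20250107L) {
  sc <- list(
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    event_date = as.Date(event_date),
    n_tracts_per_zone = n_tracts_per_zone,
    baseline_rate = baseline_rate, trend_slope = trend_slope,
    weekly_amplitude = weekly_amplitude, annual_amplitude = annual_amplitude,
    holiday_effect = holiday_effect, covariate_betas = covariate_betas,
    dispersion = dispersion,
    injected_effects = lapply(injected_effects, function(e) {
      e$start <- as.Date(e$start); e$end <- as.Date(e$end); e
    }),
    covariate_noise = covariate_noise,
    settings = settings, causes = causes, seed = as.integer(seed)
  )
  class(sc) <- "fire_scenario"
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "fire_scenario"))
  if (!(sc$study_start < sc$event_date && sc$event_date <= sc$study_end)) {
    stop("scenario requires study_start < event_date <= study_end", call. = FALSE)
  }
  if (!all(names(sc$n_tracts_per_zone) %in% exposure_levels())) {
    stop("n_tracts_per_zone names must be among: ",
         paste(exposure_levels(), collapse = ", "), call. = FALSE)
  }
  if (any(sc$n_tracts_per_zone < 0)) stop("tract counts must be >= 0", call. = FALSE)
  br <- sc$baseline_rate
  if (any(br < 0)) stop("all baseline rates must be >= 0", call. = FALSE)
  if (length(br) > 1 && !all(sc$causes %in% names(br))) {
    stop("baseline_rate must be scalar or named for every generated cause",
         call. = FALSE)
  }
  stopifnot(sc$weekly_amplitude >= 0, sc$annual_amplitude >= 0,
            sc$holiday_effect > 0, sc$holiday_effect <= 2,
            sc$dispersion > 0, sc$covariate_noise >= 0)
  if (!all(sc$settings %in% setting_levels())) stop("unknown setting", call. = FALSE)
  if (!all(sc$causes %in% cause_levels())) stop("unknown cause", call. = FALSE)
  for (e in sc$injected_effects) {
    need <- c("zone", "setting", "cause", "start", "end", "multiplier")
    if (!all(need %in% names(e))) {
      stop("each injected effect needs fields: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (e$multiplier <= 0) stop("injected multiplier must be > 0", call. = FALSE)
    if (e$start < sc$event_date || e$end > sc$study_end || e$start > e$end) {
      stop("injected-effect window [", e$start, ", ", e$end,
           "] must lie within [event_date, study_end]", call. = FALSE)
    }
  }
  invisible(sc)
}

scenario_zones <- function(sc) {
  names(sc$n_tracts_per_zone)[sc$n_tracts_per_zone > 0]
}

scenario_dates <- function(sc) seq(sc$study_start, sc$study_end, by = "day")

# baseline for a given cause, honoring scalar or per-cause vectors
scenario_baseline <- function(sc, cause) {
  if (length(sc$baseline_rate) == 1) unname(sc$baseline_rate)
  else unname(sc$baseline_rate[[cause]])
}

#' Read / write a scenario as YAML
#'
#' Round-trips every generative parameter so a scenario file fully determines
#' a synthetic dataset (together with the seed stored inside it).
#'
#' @param sc A `fire_scenario`.
#' @param path File path.
#' @return `read_scenario()` returns a `fire_scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(sc, path) {
  validate_scenario(sc)
  x <- unclass(sc)
  # yaml serializes named atomic vectors as plain sequences; lists keep names
  for (nm in c("n_tracts_per_zone", "baseline_rate", "covariate_betas")) {
    if (!is.null(names(x[[nm]]))) x[[nm]] <- as.list(x[[nm]])
  }
  x$study_start <- format(x$study_start)
  x$study_end <- format(x$study_end)
  x$event_date <- format(x$event_date)
  x$injected_effects <- lapply(x$injected_effects, function(e) {
    e$start <- format(e$start); e$end <- format(e$end); e
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  synthetic_scenario(
    study_start = x$study_start, study_end = x$study_end,
    event_date = x$event_date,
    n_tracts_per_zone = unlist(x$n_tracts_per_zone),
    baseline_rate = unlist(x$baseline_rate),
    trend_slope = x$trend_slope, weekly_amplitude = x$weekly_amplitude,
    annual_amplitude = x$annual_amplitude, holiday_effect = x$holiday_effect,
    covariate_betas = unlist(x$covariate_betas), dispersion = x$dispersion,
    injected_effects = x$injected_effects, covariate_noise = x$covariate_noise,
    settings = x$settings, causes = x$causes, seed = x$seed
  )
}
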