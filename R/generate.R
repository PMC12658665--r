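# Synthetic EHR generator: members, tracts, burn zones, covariates, visits.
# All randomness flows through per-stream child seeds of scenario$seed, so a
# scenario is a complete, reproducible description of a dataset.

default_demographic_mix <- function() {
  # Marginals of a large integrated-care membership in Southern California.
  list(
    sex = c(female = 1941970, male = 1774871, other = 167, unknown = 202) / 3717210,
    race_ethnicity = c(hispanic = 1627406, nh_asian = 426054, nh_black = 290701,
                       nh_white = 1078707, other = 120964, unknown = 173378) / 3717210
  )
}

#' Generate synthetic member records
#'
#' Draws member demographics i.i.d. from the supplied marginal mix and assigns
#' each member uniformly to a census tract. Ages at the scenario event date
#' follow a piecewise-linear quantile curve with median 42 and IQR 21-62
#' years, the shape of a general insured population.
#'
#' @param scenario A [synthetic_scenario()].
#' @param n_members Number of members to generate (0 gives an empty table).
#' @param demographic_mix List with named probability vectors `sex` and
#'   `race_ethnicity`; each must sum to 1 within 1e-9. Defaults to a large
#'   Southern California membership mix.
#' @param tracts Optional tract table (from [generate_tracts()]); when absent,
#'   tract ids are synthesized from `scenario$n_tracts_per_zone`.
#' @return Tibble with columns `member_id`, `tract_id`, `birth_date`, `sex`,
#'   `race_ethnicity`; deterministic given the scenario seed.
#' @export
generate_members <- function(scenario, n_members,
                             demographic_mix = default_demographic_mix(),
                             tracts = NULL) {
  validate_scenario(scenario)
  stopifnot(n_members >= 0)
  for (attr_name in c("sex", "race_ethnicity")) {
    p <- demographic_mix[[attr_name]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9) {
      stop("demographic_mix probabilities for '", attr_name,
           "' must sum to 1 (within 1e-9)", call. = FALSE)
    }
  }
  tract_ids <- if (!is.null(tracts)) tracts$tract_id else {
    nz <- scenario$n_tracts_per_zone[scenario$n_tracts_per_zone > 0]
    unlist(lapply(names(nz), function(z) sprintf("T-%s-%03d", z, seq_len(nz[[z]]))))
  }
  if (n_members == 0) {
    return(tibble::tibble(member_id = character(), tract_id = character(),
                          birth_date = as.Date(character()), sex = character(),
                          race_ethnicity = character()))
  }
  with_seed(child_seed(scenario$seed, "members"), {
    age_q <- stats::approxfun(c(0, 0.25, 0.5, 0.75, 1), c(0, 21, 42, 62, 95))
    age <- age_q(runif(n_members))
    tibble::tibble(
      member_id = sprintf("M%07d", seq_len(n_members)),
      tract_id = sample(tract_ids, n_members, replace = TRUE),
      birth_date = scenario$event_date - round(age * 365.25),
      sex = sample(names(demographic_mix$sex), n_members, replace = TRUE,
                   prob = demographic_mix$sex),
      race_ethnicity = sample(names(demographic_mix$race_ethnicity), n_members,
                              replace = TRUE, prob = demographic_mix$race_ethnicity)
    )
  })
}

#' Synthetic burn-zone polygons
#'
#' Two small labelled synthetic fire footprints (a few km across) in the Los
#' Angeles basin, used as stand-ins for real burn perimeters when exercising
#' the zoning pipeline end to end.
#'
#' @return A `burn_zones` object (see [burn_zones()]).
#' @export
synthetic_burn_zones <- function() {
  ring <- function(lon0, lat0, half_km) {
    # square ring ~2*half_km across, closed
    dlat <- half_km / 111.32
    dlon <- half_km / (111.32 * cos(lat0 * pi / 180))
    cbind(lon = lon0 + dlon * c(-1, 1, 1, -1, -1),
          lat = lat0 + dlat * c(-1, -1, 1, 1, -1))
  }
  burn_zones(list(
    list(fire_name = "synthetic_fire_alpha", coords = ring(-118.53, 34.05, 1.8)),
    list(fire_name = "synthetic_fire_beta", coords = ring(-118.48, 34.09, 1.2))
  ))
}

#' Generate synthetic census tracts around the burn zones
#'
#' Places tract representative points at distances consistent with the three
#' exposure zones: high within a few km of a burn-zone footprint, moderate
#' tens of km away inside the impacted county, minimal far away in the other
#' catchment counties. Distance ranges keep every tract well clear of the
#' 20 km buffer boundary so the intended zone equals the classified zone.
#'
#' @param scenario A [synthetic_scenario()].
#' @param zones Burn zones to anchor distances on (default
#'   [synthetic_burn_zones()]).
#' @return Tibble with `tract_id`, `lon`, `lat`, `county`, `in_la_county`,
#'   `zone_intended`.
#' @export
generate_tracts <- function(scenario, zones = synthetic_burn_zones()) {
  validate_scenario(scenario)
  cent <- colMeans(do.call(rbind, lapply(zones, function(z) z$coords[-1, , drop = FALSE])))
  other_counties <- c("Imperial", "Kern", "Orange", "Riverside", "San Bernardino",
                      "San Diego", "San Luis Obispo", "Santa Barbara", "Ventura")
  with_seed(child_seed(scenario$seed, "tracts"), {
    one_zone <- function(zone, n) {
      if (n == 0) return(NULL)
      rng <- switch(zone, high = c(1, 13), moderate = c(30, 70), minimal = c(40, 150))
      d_km <- runif(n, rng[1], rng[2])
      brg <- runif(n, 0, 360)
      pts <- dest_point_sphere(cent[1], cent[2], brg, d_km)
      tibble::tibble(
        tract_id = sprintf("T-%s-%03d", zone, seq_len(n)),
        lon = pts[, 1], lat = pts[, 2],
        county = if (zone == "minimal") sample(other_counties, n, replace = TRUE)
                 else "Los Angeles",
        in_la_county = zone != "minimal",
        zone_intended = zone
      )
    }
    nz <- scenario$n_tracts_per_zone
    dplyr::bind_rows(lapply(names(nz), function(z) one_zone(z, nz[[z]])))
  })
}

#' Generate daily meteorological and weekly wastewater covariates
#'
#' One row per date x zone: daily maximum/minimum temperature (degrees C),
#' maximum/minimum relative humidity (%), wind velocity (m/s) and downward
#' shortwave radiation (W/m2) follow sinusoidal annual cycles (summer-peaking
#' temperature and radiation, winter-peaking humidity) with additive Gaussian
#' noise; wastewater concentrations for influenza, RSV and SARS-CoV-2 follow a
#' winter-peaking log-scale cycle and are constant across the 7 days of each
#' ISO week, shared by all zones (a county-level surveillance signal). Setting
#' `scenario$covariate_noise = 0` yields the deterministic curves.
#'
#' @param scenario A [synthetic_scenario()].
#' @return Tibble with columns `date`, `zone`, `tmax_c`, `tmin_c`,
#'   `rhmax_pct`, `rhmin_pct`, `wind_ms`, `srad_wm2`, `ww_flu`, `ww_rsv`,
#'   `ww_cov`. Invariants: `tmin_c <= tmax_c`, humidity within \[0, 100\],
#'   wind and radiation non-negative.
#' @export
generate_covariates <- function(scenario) {
  validate_scenario(scenario)
  dates <- scenario_dates(scenario)
  zones <- scenario_zones(scenario)
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1
  ann_summer <- cos(2 * pi * (doy - 196) / 365.25)  # peaks mid-July
  ann_winter <- cos(2 * pi * (doy - 15) / 365.25)   # peaks mid-January
  ns <- scenario$covariate_noise
  with_seed(child_seed(scenario$seed, "covariates"), {
    # weekly wastewater signal, shared across zones, piecewise-constant by ISO week
    wk <- iso_week(dates)
    uw <- unique(wk)
    mid_doy <- vapply(uw, function(w) mean(doy[wk == w]), numeric(1))
    ww_curve <- function(lvl, amp, sdlog) {
      exp(lvl + amp * cos(2 * pi * (mid_doy - 20) / 365.25) + rnorm(length(uw), 0, sdlog * ns))
    }
    ww <- tibble::tibble(
      week = uw,
      ww_flu = ww_curve(3.0, 1.2, 0.25),
      ww_rsv = ww_curve(2.5, 1.0, 0.25),
      ww_cov = ww_curve(3.5, 0.6, 0.25)
    )
    zone_offset <- setNames(c(0, 0.5, 1.0), exposure_levels())
    out <- lapply(zones, function(z) {
      tmax <- 21 + zone_offset[[z]] + 6 * ann_summer + rnorm(n, 0, 1.8 * ns)
      spread <- pmax(9 - 1.5 * ann_winter + abs(rnorm(n, 0, 1.2 * ns)), 0)
      rhmax <- pmin(pmax(82 + 8 * ann_winter + rnorm(n, 0, 5 * ns), 0), 100)
      rhspread <- pmax(35 + rnorm(n, 0, 6 * ns), 0)
      tibble::tibble(
        date = dates, zone = z,
        tmax_c = tmax, tmin_c = tmax - spread,
        rhmax_pct = rhmax, rhmin_pct = pmax(rhmax - rhspread, 0),
        wind_ms = pmax(3.2 + 0.6 * ann_winter + rnorm(n, 0, 1.0 * ns), 0),
        srad_wm2 = pmax(235 + 105 * ann_summer + rnorm(n, 0, 15 * ns), 0),
        week = wk
      )
    })
    dplyr::select(dplyr::left_join(dplyr::bind_rows(out), ww, by = "week"), -"week")
  })
}

# day-of-week multipliers (Sun..Sat), mean exactly 1 within each setting;
# weekends are suppressed more for in-person clinics than for virtual care
dow_pattern <- function(setting) {
  if (setting == "outpatient") c(0.55, 1.25, 1.20, 1.15, 1.15, 1.10, 0.60)
  else c(0.80, 1.10, 1.10, 1.10, 1.05, 1.05, 0.80)
}

# closed-form expected count for every row; exported logic used by tests via
# attribute "mu" on generate_visits() output
visit_mean <- function(scenario, grid, cov_z) {
  years <- as.numeric(grid$date - scenario$study_start) / 365.25
  doy <- as.POSIXlt(grid$date)$yday + 1
  wday <- as.POSIXlt(grid$date)$wday + 1
  hol <- is_holiday(grid$date)
  base <- vapply(grid$cause, function(cs) scenario_baseline(scenario, cs),
                 numeric(1), USE.NAMES = FALSE)
  level <- ifelse(base > 0, pmax(base + scenario$trend_slope * years, 0), 0)
  wk_fac <- 1 + scenario$weekly_amplitude *
    (vapply(seq_len(nrow(grid)), function(i) dow_pattern(grid$setting[i])[wday[i]],
            numeric(1)) - 1)
  ann_fac <- 1 + scenario$annual_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  hol_fac <- ifelse(hol, scenario$holiday_effect, 1)
  mu <- level * pmax(wk_fac, 0) * pmax(ann_fac, 0) * hol_fac * exp(cov_z)
  for (e in scenario$injected_effects) {
    idx <- grid$zone == e$zone & grid$setting == e$setting & grid$cause == e$cause &
      grid$date >= e$start & grid$date <= e$end
    mu[idx] <- mu[idx] * e$multiplier
  }
  mu
}

#' Generate the daily visit-count series
#'
#' For each zone x setting x cause x date cell the count is drawn from a
#' negative binomial with mean
#' `baseline * trend * weekly * annual * holiday * exp(sum(beta * z))`
#' times any matching injected multiplier, and dispersion `k`
#' (`variance = mu + mu^2/k`; `k = Inf` gives Poisson). Covariates enter
#' through coefficients on their z-scores, standardized per zone over the
#' pre-event period. Counts are produced by inverting per-row uniform draws
#' through the negative-binomial quantile function, so editing the mean of
#' one cell (e.g. configuring an injected effect) never perturbs the draws of
#' any other cell.
#'
#' @param scenario A [synthetic_scenario()].
#' @param covariates Covariate panel from [generate_covariates()]; must cover
#'   every study date for every generated zone.
#' @return `VisitSeries` tibble with columns `date`, `zone`, `setting`,
#'   `cause`, `count` (non-negative integers), one row per cell, plus an
#'   attribute `"mu"` holding the closed-form expected counts (used for
#'   generative-oracle checks). Deterministic given the scenario seed.
#' @export
generate_visits <- function(scenario, covariates) {
  validate_scenario(scenario)
  dates <- scenario_dates(scenario)
  zones <- scenario_zones(scenario)
  for (z in zones) {
    have <- covariates$date[covariates$zone == z]
    miss <- dates[!dates %in% have]
    if (length(miss) > 0) {
      stop("covariates missing for zone '", z, "' on dates: ",
           paste(utils::head(format(miss), 5), collapse = ", "),
           if (length(miss) > 5) " ..." else "", call. = FALSE)
    }
  }
  grid <- tidyr::expand_grid(zone = zones, setting = scenario$settings,
                             cause = scenario$causes, date = dates)
  # covariate log-rate term: betas on pre-period z-scores, per zone
  betas <- scenario$covariate_betas
  cov_z <- numeric(nrow(grid))
  if (length(betas) > 0) {
    bad <- setdiff(names(betas), names(covariates))
    if (length(bad) > 0) stop("unknown covariates in betas: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    zterm <- covariates[, c("date", "zone")]
    zterm$lp <- 0
    for (z in zones) {
      idx <- covariates$zone == z
      pre <- idx & covariates$date < scenario$event_date
      for (nm in names(betas)) {
        v <- covariates[[nm]]
        mu0 <- mean(v[pre]); s0 <- stats::sd(v[pre])
        if (!is.finite(s0) || s0 == 0) s0 <- 1
        zterm$lp[idx] <- zterm$lp[idx] + betas[[nm]] * (v[idx] - mu0) / s0
      }
    }
    cov_z <- zterm$lp[match(paste(grid$date, grid$zone),
                            paste(zterm$date, zterm$zone))]
  }
  mu <- visit_mean(scenario, grid, cov_z)
  counts <- with_seed(child_seed(scenario$seed, "visits"), {
    u <- runif(nrow(grid))
    if (is.infinite(scenario$dispersion)) qpois(u, lambda = mu)
    else qnbinom(u, size = scenario$dispersion, mu = mu)
  })
  out <- tibble::tibble(date = grid$date, zone = grid$zone,
                        setting = grid$setting, cause = grid$cause,
                        count = as.integer(counts))
  out <- dplyr::arrange(out, .data$zone, .data$setting, .data$cause, .data$date)
  attr(out, "mu") <- mu[order(grid$zone, grid$setting, grid$cause, grid$date)]
  out
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper producing every table a pipeline run consumes: burn
#' zones, tracts, exposure zoning, covariates, visit counts and (optionally)
#' a member line list.
#'
#' @param scenario A [synthetic_scenario()].
#' @param n_members Members to generate for cohort summaries (0 skips).
#' @param buffer_km Buffer passed to [classify_tracts()].
#' @return List with elements `burn_zones`, `tracts`, `zoning`, `covariates`,
#'   `visits`, and `members` (NULL when `n_members = 0`).
#' @export
simulate_study <- function(scenario, n_members = 0, buffer_km = 20) {
  validate_scenario(scenario)
  bz <- synthetic_burn_zones()
  tracts <- generate_tracts(scenario, bz)
  zoning <- classify_tracts(tracts, bz, buffer_km = buffer_km)
  covariates <- generate_covariates(scenario)
  visits <- generate_visits(scenario, covariates)
  members <- if (n_members > 0) generate_members(scenario, n_members, tracts = tracts)
  list(burn_zones = bz, tracts = tracts, zoning = zoning,
       covariates = covariates, visits = visits, members = members)
}
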