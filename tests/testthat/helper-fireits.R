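# Shared fixtures: small single-stratum scenarios and a reduced candidate
# grid that keeps cross-validated fits fast while still exercising model
# selection (structural base with and without the boosted corrector).

one_stratum_scenario <- function(seed, multiplier = NULL, baseline = 80, ...) {
  inj <- list()
  if (!is.null(multiplier)) {
    inj <- list(list(zone = "high", setting = "virtual", cause = "respiratory",
                     start = "2025-01-07", end = "2025-01-13",
                     multiplier = multiplier))
  }
  synthetic_scenario(
    n_tracts_per_zone = c(high = 1L),
    baseline_rate = baseline,
    settings = "virtual", causes = "respiratory",
    injected_effects = inj, seed = seed, ...
  )
}

fast_configs <- function() {
  list(
    model_config(fourier_order_annual = 3),
    model_config(fourier_order_annual = 3, residual_learner = "gradient_boosting"),
    model_config(fourier_order_annual = 8),
    model_config(fourier_order_annual = 8, residual_learner = "gradient_boosting")
  )
}

# one full two-stage run (default candidate grid) on a fresh single-stratum
# synthetic dataset
run_replicate <- function(seed, multiplier = NULL, baseline = 80, n_iter = 500) {
  sc <- one_stratum_scenario(seed, multiplier, baseline)
  covs <- generate_covariates(sc)
  visits <- generate_visits(sc, covs)
  estimate_stratum_excess(visits, covs, "high", "virtual", "respiratory",
                          pre_end = sc$event_date,
                          configs = default_config_grid(), n_iter = n_iter,
                          seed = seed)$cumulative
}

square_ring <- function(lon0, lat0, half_deg) {
  cbind(lon = lon0 + half_deg * c(-1, 1, 1, -1, -1),
        lat = lat0 + half_deg * c(-1, -1, 1, 1, -1))
}

# independent distance oracle: minimum haversine distance to points densely
# sampled along each great-circle edge of each polygon
dense_boundary_distance <- function(lon, lat, zones, n_per_edge = 2000) {
  r_m <- 6371008.8
  dmin <- Inf
  for (z in zones) {
    cc <- z$coords
    for (i in seq_len(nrow(cc) - 1)) {
      pts <- rbind(cc[i, , drop = FALSE],
                   geosphere::gcIntermediate(cc[i, ], cc[i + 1, ], n = n_per_edge),
                   cc[i + 1, , drop = FALSE])
      d <- min(geosphere::distHaversine(c(lon, lat), pts, r = r_m)) / 1000
      if (d < dmin) dmin <- d
    }
  }
  dmin
}
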