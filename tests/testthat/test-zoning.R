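# Exposure zoning: great-circle distances against a dense-sampling oracle,
# zone partition/monotonicity, boundary-tie handling, GeoJSON round-trips.

test_that("distance to burn zones matches closed forms and decomposes", {
  bz <- burn_zones(list(list(fire_name = "a", coords = square_ring(0, 0, 0.5))))
  # inside the polygon
  expect_equal(distance_to_burn_zones(0, 0, bz), 0)
  # 1 degree of latitude due south of a southern-edge vertex on its meridian
  d <- distance_to_burn_zones(-0.5, -1.5, bz)
  expect_equal(d, pi / 180 * 6371.0088, tolerance = 1e-6)
  expect_equal(d, 111.19, tolerance = 1e-4)

  b2 <- burn_zones(list(list(fire_name = "b", coords = square_ring(3, 0, 0.5))))
  both <- burn_zones(c(unclass(bz), unclass(b2)))
  p <- c(1.7, 0.3)
  expect_equal(distance_to_burn_zones(p[1], p[2], both),
               min(distance_to_burn_zones(p[1], p[2], bz),
                   distance_to_burn_zones(p[1], p[2], b2)))

  expect_error(distance_to_burn_zones(0, 0, burn_zones(list())), "at least one")
})

test_that("distances agree with dense boundary sampling within 0.1%", {
  set.seed(501)
  polys <- lapply(1:3, function(i) {
    # irregular convex-ish ring with up to 20 vertices
    k <- sample(5:19, 1)
    th <- sort(runif(k, 0, 2 * pi))
    r <- runif(k, 0.1, 0.4)
    lon0 <- runif(1, -120, -117); lat0 <- runif(1, 33, 35)
    cc <- cbind(lon = lon0 + r * cos(th), lat = lat0 + r * sin(th))
    list(fire_name = paste0("f", i), coords = rbind(cc, cc[1, ]))
  })
  bz <- burn_zones(polys)
  for (j in 1:12) {
    lon <- runif(1, -122, -115); lat <- runif(1, 32, 36)
    d <- distance_to_burn_zones(lon, lat, bz)
    if (d == 0) next  # inside: oracle does not apply
    oracle <- dense_boundary_distance(lon, lat, bz)
    expect_lt(abs(d - oracle) / oracle, 0.001)
  }
})

test_that("tract classification partitions tracts and respects the buffer", {
  sc <- synthetic_scenario(seed = 21)
  bz <- synthetic_burn_zones()
  tracts <- generate_tracts(sc, bz)
  z <- classify_tracts(tracts, bz, buffer_km = 20)
  expect_equal(z$tract_id, tracts$tract_id)  # order preserved
  expect_true(all(z$zone %in% c("high", "moderate", "minimal")))
  # invariants tie zone to distance and county
  expect_true(all((z$zone == "high") == (z$distance_km < 20)))
  expect_true(all(z$zone[z$distance_km >= 20] ==
                    ifelse(tracts$in_la_county[z$distance_km >= 20],
                           "moderate", "minimal")))
  # distance ranges were chosen clear of the buffer, so intent is recovered
  expect_equal(z$zone, tracts$zone_intended)

  # a tract at exactly the buffer distance is not highly exposed
  d0 <- z$distance_km[z$zone == "moderate"][1]
  id0 <- z$tract_id[z$zone == "moderate"][1]
  z_tie <- classify_tracts(tracts[tracts$tract_id == id0, ], bz, buffer_km = d0)
  expect_equal(z_tie$zone, "moderate")

  bad <- tracts[1, ]; bad$lon <- 500
  expect_error(classify_tracts(bad, bz), bad$tract_id)
})

test_that("the high-exposure set grows monotonically with the buffer", {
  sc <- synthetic_scenario(seed = 22)
  bz <- synthetic_burn_zones()
  tracts <- generate_tracts(sc, bz)
  prev <- character(0)
  for (b in seq(5, 30, by = 5)) {
    z <- classify_tracts(tracts, bz, buffer_km = b)
    high <- z$tract_id[z$zone == "high"]
    expect_true(all(prev %in% high))
    prev <- high
  }
  # the 10 km sensitivity rule flips a ~14 km LA-county tract high -> moderate
  t15 <- tibble::tibble(tract_id = "t15",
                        lon = -118.48, lat = 34.09 + 15 / 111.195,
                        in_la_county = TRUE)
  z20 <- classify_tracts(t15, bz, buffer_km = 20)
  z10 <- classify_tracts(t15, bz, buffer_km = 10)
  expect_true(z20$distance_km[1] > 10 && z20$distance_km[1] < 20)
  expect_equal(z20$zone, "high")
  expect_equal(z10$zone, "moderate")
})

test_that("burn zones survive a GeoJSON round-trip", {
  bz <- synthetic_burn_zones()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_burn_zones(bz, path)
  bz2 <- read_burn_zones(path)
  expect_equal(length(bz2), length(bz))
  for (i in seq_along(bz)) {
    expect_equal(bz2[[i]]$fire_name, bz[[i]]$fire_name)
    expect_equal(unname(bz2[[i]]$coords), unname(bz[[i]]$coords))
  }
  expect_error(burn_zones(list(list(fire_name = "open",
                                    coords = square_ring(0, 0, 1)[1:4, ]))),
               "closed ring")
})
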