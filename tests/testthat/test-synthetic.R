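test_that("network generation spans the smallest and degenerate cases", {
  u <- generate_network(1, n_roots = 1, n_closed_basins = 0)
  expect_equal(nrow(u), 1)
  expect_equal(u$tohuc_id, "OCEAN")
  expect_false(u$closed_basin)
  expect_error(generate_network(2, n_roots = 3), "impossible")
  expect_error(generate_network(3, n_roots = 1, n_closed_basins = 3),
               "impossible|n_closed_basins")
})

test_that("every downstream walk terminates; no cycles; closed count exact", {
  u <- generate_network(200, n_roots = 3, n_closed_basins = 2, seed = 7)
  expect_equal(sum(u$closed_basin), 2)
  parent <- match(u$tohuc_id, u$unit_id)
  parent[u$tohuc_id == "OCEAN" | u$closed_basin] <- NA
  for (s in seq_len(nrow(u))) {
    v <- s
    steps <- 0
    while (!is.na(v)) {
      v <- parent[v]
      steps <- steps + 1
      expect_lte(steps, nrow(u))
    }
  }
  expect_s3_class(build_graph(u), "catchment_graph")  # validator agrees
})

test_that("same seed reproduces networks, placements and observations", {
  expect_identical(generate_network(120, seed = 5),
                   generate_network(120, seed = 5))
  u <- generate_network(120, seed = 5)
  expect_identical(place_stations(u, 10, seed = 6),
                   place_stations(u, 10, seed = 6))
  expect_identical(
    simulate_observations(4, c(8, 0.9, 0.3, 0.1), seed = 9),
    simulate_observations(4, c(8, 0.9, 0.3, 0.1), seed = 9))
  expect_identical(simulate_watershed(n_units = 60, n_stations = 4, seed = 3),
                   simulate_watershed(n_units = 60, n_stations = 4, seed = 3))
})

test_that("unit areas are lognormal at the hydrologic-unit scale", {
  u <- generate_network(20000, seed = 12)
  expect_true(all(u$area_km2 > 0))
  # default parameters target a mean unit area of about 104 km^2
  expect_equal(mean(u$area_km2), 104, tolerance = 0.05)
})

test_that("station placement respects eligibility and saturates", {
  u <- generate_network(50, n_roots = 1, n_closed_basins = 1, seed = 8)
  g <- build_graph(u)
  excl <- closed_basin_excluded_set(g)
  eligible <- setdiff(u$unit_id, excl)
  st <- place_stations(g, length(eligible), seed = 9)
  expect_setequal(st$unit_id, eligible)          # saturation
  expect_equal(anyDuplicated(st$unit_id), 0)     # one station per unit
  expect_equal(nrow(place_stations(g, 0)), 0)    # empty request
  expect_error(place_stations(g, length(eligible) + 1), "exceeds")
  # headwater placements carry a reported area strictly below the unit area
  hw <- vapply(st$unit_id, function(x) is.null(g$children[[x]]), logical(1))
  area <- u$area_km2[match(st$unit_id, u$unit_id)]
  expect_true(all(st$reported_area_km2[hw] < area[hw]))
  expect_true(all(is.na(st$reported_area_km2[!hw])))
})

test_that("constant-model observations are constant and sigma is validated", {
  sim <- simulate_observations(1, c(7, 0), sigma = 0, n_days = 200,
                               n_samples = 20, seed = 3)
  p <- pair_same_day(sim$flow, sim$samples)
  expect_equal(p$load, rep(exp(7), 20), tolerance = 1e-12)
  expect_error(simulate_observations(1, c(7, 0), sigma = -0.1), ">= 0")
  expect_error(simulate_observations(1, c(7, 0, 0)), "coefficients")
})

test_that("noiseless observations round-trip through every model's fitter", {
  for (m in 1:9) {
    k <- n_model_coefficients(m)
    a <- c(6, seq(0.8, by = -0.12, length.out = k - 1))
    sim <- simulate_observations(m, a, sigma = 0, n_days = 1825,
                                 n_samples = 80, seed = 100 + m)
    p <- pair_same_day(sim$flow, sim$samples)
    f <- fit_rating_model(p, compute_centers(p), m)
    expect_false(f$failed)
    expect_equal(unname(f$coefficients), a, tolerance = 1e-8)
  }
})

test_that("seasonal terms put an annual period into generated ln-loads", {
  sim <- simulate_observations(4, c(5, 0, 1, 0), sigma = 0,
                               flow_seasonal_amplitude = 0, n_days = 1460,
                               n_samples = 200, seed = 44)
  p <- pair_same_day(sim$flow, sim$samples)
  dtc <- p$dtime - sim$centers$dtime
  # ln-load (flow slope zero) must equal sin(2 pi dtime): exact annual cycle
  expect_equal(log(p$load), 5 + sin(2 * pi * dtc), tolerance = 1e-9)
  # shifting time by one year leaves the seasonal predictor unchanged
  expect_equal(sin(2 * pi * (dtc + 1)), sin(2 * pi * dtc), tolerance = 1e-9)
})

test_that("induced station loads equal the brute-force yield sum", {
  u <- generate_network(180, n_roots = 2, seed = 13)
  g <- build_graph(u)
  st <- place_stations(g, 12, seed = 14)
  y <- generate_yield_field(g, mean = 1000, sd = 400, seed = 15)
  tl <- induce_station_loads(g, st, y)
  oracle_up <- brute_force_upstream(u)
  for (k in seq_len(nrow(st))) {
    up <- oracle_up[[match(st$unit_id[k], u$unit_id)]]
    area <- u$area_km2[match(up, u$unit_id)]
    if (length(up) == 1 && !is.na(st$reported_area_km2[k]))
      area <- st$reported_area_km2[k]
    expect_equal(unname(tl[st$station_id[k]]), sum(y[up] * area),
                 tolerance = 1e-12)
  }
  # uniform yield over a station's drainage: load = y * A exactly
  y1 <- setNames(rep(50, nrow(u)), u$unit_id)
  st1 <- st; st1$reported_area_km2 <- NA_real_
  tl1 <- induce_station_loads(g, st1, y1)
  acc <- accumulate_drainage(g)
  expect_equal(unname(tl1), unname(50 * acc[st1$unit_id]), tolerance = 1e-12)
  # zero yield -> zero loads
  y0 <- setNames(rep(0, nrow(u)), u$unit_id)
  expect_equal(unname(induce_station_loads(g, st1, y0)), rep(0, nrow(st1)))
})

test_that("nested station loads are monotone under nonnegative yields", {
  u <- generate_network(150, seed = 17)
  g <- build_graph(u)
  st <- place_stations(g, 15, seed = 18)
  st$reported_area_km2 <- NA_real_
  y <- abs(generate_yield_field(g, mean = 500, sd = 400, seed = 19))
  tl <- induce_station_loads(g, st, y)
  for (k in seq_len(nrow(st))) {
    path <- downstream_station_path(g, st, st$unit_id[k])
    if (length(path) < 2) next
    expect_true(all(diff(unname(tl[path])) >= -1e-12))
  }
})

test_that("stations draining to closed basins are rejected for induction", {
  u <- make_units(c("a", "b"), c("b", "OCEAN"), closed = c(FALSE, TRUE))
  g <- build_graph(u)
  st <- data.frame(station_id = "S", unit_id = "a",
                   reported_area_km2 = NA_real_)
  y <- setNames(c(1, 1), u$unit_id)
  expect_error(induce_station_loads(g, st, y), "closed-basin")
})

test_that("calibrated observations hit the target annual load at sigma=0", {
  target <- 5e4
  sim <- simulate_calibrated_observations(4, c(0, 0.9, 0.3, 0.1),
                                          target_annual_load = target,
                                          sigma = 0, n_days = 730,
                                          n_samples = 30, seed = 21)
  p <- pair_same_day(sim$flow, sim$samples)
  rc <- rating_curve(p)
  daily <- predict(rc, sim$flow)
  expect_equal(mean(daily$load) * 365.25 / 1000, target,
               tolerance = 1e-6)
})

test_that("a full synthetic watershed passes its own validation round trip", {
  sw <- simulate_watershed(n_units = 80, n_stations = 5,
                           n_closed_basins = 1, sigma = 0.1, seed = 33)
  expect_s3_class(build_graph(sw$units), "catchment_graph")
  expect_true(all(sw$true_loads > 0))
  expect_setequal(unique(sw$observations$station_id), sw$stations$station_id)
  expect_true(all(sw$observations$flow > 0))
})
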