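#' Generate a synthetic catchment drainage network
#'
#' Builds a random forest of catchment units with the structure of a
#' hydrologic-unit (HUC12/ToHUC style) table: every unit carries one
#' downstream link that is another unit, or the [OCEAN] sentinel for
#' terminal outlets; closed-basin units are terminal sinks flagged on the
#' unit and root their own (excluded) subtrees. Unit areas are lognormal;
#' the defaults give a mean unit area of about 104 km^2, the scale of the
#' national HUC12 population.
#'
#' @param n_units total number of units (>= n_roots + n_closed_basins).
#' @param n_roots number of terminal ocean outlets (trees), default 1.
#' @param n_closed_basins number of closed-basin units (each roots an
#'   excluded subtree), default 0.
#' @param area_log_mean,area_log_sd lognormal parameters of unit area (km^2);
#'   defaults `log(104) - 0.5^2/2` and `0.5` give mean ~104 km^2.
#' @param max_children maximum upstream units draining into one unit.
#' @param seed optional integer seed; identical seeds give identical
#'   networks.
#' @return data.frame with columns `unit_id`, `tohuc_id`, `area_km2`,
#'   `closed_basin`, ready for [build_graph()].
#' @export
generate_network <- function(n_units, n_roots = 1, n_closed_basins = 0,
                             area_log_mean = log(104) - 0.5^2 / 2,
                             area_log_sd = 0.5,
                             max_children = 4, seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, generate_network(
      n_units, n_roots, n_closed_basins, area_log_mean, area_log_sd,
      max_children)))
  stopifnot(n_units >= 1, n_roots >= 1, n_closed_basins >= 0,
            max_children >= 1)
  n_trees <- n_roots + n_closed_basins
  if (n_trees > n_units)
    stop("impossible configuration: n_roots + n_closed_basins (", n_trees,
         ") exceeds n_units (", n_units, ")")
  if (n_closed_basins >= n_units)
    stop("impossible configuration: n_closed_basins must be < n_units")
  ids <- sprintf("U%05d", seq_len(n_units))
  tohuc <- rep(OCEAN, n_units)
  closed <- c(rep(FALSE, n_roots), rep(TRUE, n_closed_basins),
              rep(FALSE, n_units - n_trees))
  n_children <- integer(n_units)
  if (n_units > n_trees) {
    for (i in (n_trees + 1):n_units) {
      open <- which(n_children[seq_len(i - 1)] < max_children)
      p <- if (length(open) == 1) open else sample(open, 1)
      tohuc[i] <- ids[p]
      n_children[p] <- n_children[p] + 1L
    }
  }
  data.frame(unit_id = ids, tohuc_id = tohuc,
             area_km2 = stats::rlnorm(n_units, area_log_mean, area_log_sd),
             closed_basin = closed)
}

#' Place stations on a synthetic network
#'
#' Samples station hosting units (at most one station per unit) among units
#' not draining to a closed basin. Headwater placements get a reported
#' drainage area drawn strictly smaller than the unit area — gauges in
#' headwater units control only a fraction of the unit — which exercises the
#' headwater reported-area rule downstream; interior placements carry no
#' reported area unless `interior_reported = "exact"`, which sets it to the
#' true accumulated area (useful for derived-vs-reported validation).
#'
#' @param network data.frame from [generate_network()] (or a
#'   `"catchment_graph"`).
#' @param n_stations number of stations to place.
#' @param seed optional integer seed.
#' @param headwater_fraction_range range of the unit-area fraction a
#'   headwater gauge controls, default `c(0.2, 0.8)`.
#' @param interior_reported `"none"` (default) or `"exact"`.
#' @return data.frame `station_id`, `unit_id`, `reported_area_km2` (`NA`
#'   where no reported record exists).
#' @export
place_stations <- function(network, n_stations, seed = NULL,
                           headwater_fraction_range = c(0.2, 0.8),
                           interior_reported = c("none", "exact")) {
  interior_reported <- match.arg(interior_reported)
  if (!is.null(seed))
    return(withr::with_seed(seed, place_stations(
      network, n_stations, NULL, headwater_fraction_range, interior_reported)))
  graph <- if (inherits(network, "catchment_graph")) network
           else build_graph(network)
  eligible <- setdiff(graph$units$unit_id, closed_basin_excluded_set(graph))
  if (n_stations > length(eligible))
    stop("n_stations (", n_stations, ") exceeds the ", length(eligible),
         " eligible (non-closed-draining) units")
  if (n_stations == 0)
    return(data.frame(station_id = character(0), unit_id = character(0),
                      reported_area_km2 = numeric(0)))
  units <- sort(sample(eligible, n_stations))
  headwater <- vapply(units, function(u) is.null(graph$children[[u]]),
                      logical(1))
  area <- graph$units$area_km2[match(units, graph$units$unit_id)]
  reported <- rep(NA_real_, n_stations)
  if (any(headwater))
    reported[headwater] <- area[headwater] *
      stats::runif(sum(headwater), headwater_fraction_range[1],
                   headwater_fraction_range[2])
  if (interior_reported == "exact" && any(!headwater)) {
    acc <- accumulate_drainage(graph)
    reported[!headwater] <- unname(acc[units[!headwater]])
  }
  data.frame(station_id = sprintf("S%04d", seq_len(n_stations)),
             unit_id = units, reported_area_km2 = reported)
}

#' Generate a ground-truth per-unit yield field
#'
#' Independent Gaussian yields per unit (kgC km^-2 yr^-1); negative values
#' (net-removal units) are allowed and arise whenever `sd` is large relative
#' to `mean`.
#'
#' @param network data.frame or `"catchment_graph"`.
#' @param mean,sd Gaussian parameters, defaults 2000 and 500.
#' @param seed optional integer seed.
#' @return named numeric vector over all units.
#' @export
generate_yield_field <- function(network, mean = 2000, sd = 500, seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, generate_yield_field(network, mean, sd)))
  units <- if (inherits(network, "catchment_graph")) network$units else network
  stats::setNames(stats::rnorm(nrow(units), mean, sd), units$unit_id)
}

#' True station loads induced by a yield field
#'
#' The mass-balance inverse of the yield allocation: each station's true
#' load is the sum of `yield * area` over its upstream units. A headwater
#' station with a reported (partial-unit) area contributes only that
#' fraction of its hosting unit. Stations on units draining to a closed
#' basin are rejected.
#'
#' @param graph a `"catchment_graph"` (or unit table).
#' @param stations data.frame with `station_id`, `unit_id`,
#'   `reported_area_km2`.
#' @param yields named numeric vector from [generate_yield_field()].
#' @return named numeric vector of station loads, kgC yr^-1.
#' @export
induce_station_loads <- function(graph, stations, yields) {
  if (!inherits(graph, "catchment_graph")) graph <- build_graph(graph)
  excluded <- closed_basin_excluded_set(graph)
  bad <- stations$unit_id %in% excluded
  if (any(bad))
    stop("station(s) on closed-basin-draining unit(s): ",
         paste(stations$station_id[bad], collapse = ", "))
  loads <- vapply(seq_len(nrow(stations)), function(k) {
    u <- as.character(stations$unit_id[k])
    up <- upstream_units(graph, u)
    area <- graph$units$area_km2[match(up, graph$units$unit_id)]
    headwater <- length(up) == 1
    rep_a <- stations$reported_area_km2[k]
    if (headwater && !is.na(rep_a)) area <- rep_a
    sum(yields[up] * area)
  }, numeric(1))
  stats::setNames(loads, as.character(stations$station_id))
}

#' Simulate daily flows and sparse concentration samples
#'
#' Daily flows are lognormal with a sinusoidal annual component on the log
#' scale. On each of `n_samples` sampled days, ln(instantaneous load) is the
#' chosen rating-curve model's linear predictor — evaluated at that day's
#' covariates centered with the decorrelating centers of the sampled days —
#' plus Gaussian noise of standard deviation `sigma`; the concentration is
#' back-computed as `load / (86400 * flow)`, so the generating process is
#' exactly a rating-curve model on ln-load and a noiseless refit recovers
#' the coefficients.
#'
#' @param model_id rating-curve model id, 1..9.
#' @param coefficients numeric vector: intercept `a0` followed by the
#'   model's slope coefficients in the model's term order.
#' @param sigma residual SD on the ln-load scale, >= 0.
#' @param flow_log_mean,flow_log_sd lognormal flow parameters (ln m^3 s^-1).
#' @param flow_seasonal_amplitude amplitude of the annual ln-flow cycle.
#' @param n_days length of the daily flow record.
#' @param n_samples number of concentration sampling days (<= n_days).
#' @param start_date first day of the record.
#' @param seed optional integer seed.
#' @return list: `flow` (data.frame `date`, `flow`), `samples` (data.frame
#'   `date`, `concentration`), `centers`, `coefficients` (as used).
#' @export
simulate_observations <- function(model_id, coefficients, sigma = 0.2,
                                  flow_log_mean = 1, flow_log_sd = 0.6,
                                  flow_seasonal_amplitude = 0.5,
                                  n_days = 1095, n_samples = 36,
                                  start_date = as.Date("2000-01-01"),
                                  seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, simulate_observations(
      model_id, coefficients, sigma, flow_log_mean, flow_log_sd,
      flow_seasonal_amplitude, n_days, n_samples, start_date)))
  stopifnot(model_id %in% 1:9, n_samples <= n_days, n_samples >= 2)
  if (sigma < 0) stop("sigma must be >= 0")
  p <- n_model_coefficients(model_id)
  if (length(coefficients) != p)
    stop("model ", model_id, " needs ", p, " coefficients (a0..a",
         p - 1, "); got ", length(coefficients))
  dates <- start_date + seq_len(n_days) - 1
  dtime <- decimal_time(dates)
  lnQ <- flow_log_mean + flow_seasonal_amplitude * sin(2 * pi * dtime) +
    stats::rnorm(n_days, 0, flow_log_sd)
  flow <- data.frame(date = dates, flow = exp(lnQ))
  sampled <- sort(sample(n_days, n_samples))
  paired0 <- data.frame(flow = flow$flow[sampled], dtime = dtime[sampled])
  centers <- compute_centers(paired0)
  X <- .design(lnQ[sampled], dtime[sampled], centers, model_id)
  lnload <- drop(X %*% coefficients) + stats::rnorm(n_samples, 0, sigma)
  conc <- exp(lnload) / (86400 * flow$flow[sampled])
  list(flow = flow,
       samples = data.frame(date = dates[sampled], concentration = conc),
       centers = centers,
       coefficients = stats::setNames(coefficients, colnames(X)))
}

#' Calibrate an observation generator to a target annual load
#'
#' Shifts the intercept `a0` so that the generating process's expected mean
#' daily load over the full flow record — `mean(exp(linear predictor)) *
#' exp(sigma^2/2)` — corresponds to a target annual load (kgC yr^-1). With
#' `sigma = 0` the whole-record load estimated from the simulated
#' observations then equals the target exactly, which is how the generator
#' induces mass-balanced station loads.
#'
#' @inheritParams simulate_observations
#' @param target_annual_load kgC yr^-1, > 0.
#' @return as [simulate_observations()].
#' @export
simulate_calibrated_observations <- function(model_id, coefficients,
                                             target_annual_load,
                                             sigma = 0.2, ...,
                                             seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, simulate_calibrated_observations(
      model_id, coefficients, target_annual_load, sigma, ...)))
  stopifnot(target_annual_load > 0)
  # one uncalibrated draw fixes flows, sampling days and centers
  sim <- simulate_observations(model_id, coefficients, sigma = 0, ...)
  X <- .design(log(sim$flow$flow), decimal_time(sim$flow$date), sim$centers,
               model_id)
  mean_daily <- mean(exp(drop(X %*% coefficients))) *
    bias_correction_factor(sigma^2)
  annual0 <- mean_daily * 365.25 / 1000
  shift <- log(target_annual_load / annual0)
  coefficients[1] <- coefficients[1] + shift
  lnload <- drop(.design(log(sim$flow$flow[match(sim$samples$date, sim$flow$date)]),
                         decimal_time(sim$samples$date), sim$centers,
                         model_id) %*% coefficients) +
    stats::rnorm(nrow(sim$samples), 0, sigma)
  sim$samples$concentration <- exp(lnload) /
    (86400 * sim$flow$flow[match(sim$samples$date, sim$flow$date)])
  sim$coefficients <- stats::setNames(coefficients, names(sim$coefficients))
  sim
}

#' Simulate a complete synthetic watershed study
#'
#' One call produces everything the pipeline consumes with known answers: a
#' catchment network, station placements, a ground-truth yield field, the
#' mass-balanced true station loads it induces, and per-station observation
#' records (daily flows plus sparse concentrations) calibrated so that the
#' generating process's expected load is the induced truth. Flow magnitude
#' scales with drainage area (a fixed specific runoff), so nested stations
#' carry nested flows.
#'
#' @param n_units,n_roots,n_closed_basins,seed as [generate_network()].
#' @param n_stations number of stations.
#' @param yield_mean,yield_sd Gaussian yield-field parameters
#'   (kgC km^-2 yr^-1).
#' @param model_id,sigma,n_days,n_samples observation-generator settings.
#' @param constituent label attached to the observations, default `"DOC"`.
#' @return list: `units`, `graph`, `stations`, `yields`, `true_loads`,
#'   `observations` (long data.frame: `station_id`, `date`, `flow`,
#'   `flow_unit`, `concentration`, `constituent`; flow rows carry `NA`
#'   concentration on unsampled days).
#' @export
simulate_watershed <- function(n_units = 300, n_stations = 12, n_roots = 1,
                               n_closed_basins = 0,
                               yield_mean = 2000, yield_sd = 500,
                               model_id = 4, sigma = 0.2,
                               n_days = 1095, n_samples = 36,
                               constituent = "DOC", seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, simulate_watershed(
      n_units, n_stations, n_roots, n_closed_basins, yield_mean, yield_sd,
      model_id, sigma, n_days, n_samples, constituent)))
  units <- generate_network(n_units, n_roots, n_closed_basins)
  graph <- build_graph(units)
  stations <- place_stations(graph, n_stations)
  yields <- generate_yield_field(graph, yield_mean, yield_sd)
  true_loads <- induce_station_loads(graph, stations, yields)
  if (any(true_loads <= 0))
    stop("yield field induces nonpositive station load(s); ",
         "increase yield_mean relative to yield_sd")
  acc <- accumulate_drainage(graph)
  base_coef <- switch(as.character(model_id),
                      `1` = c(0, 0.9),
                      `4` = c(0, 0.9, 0.3, 0.15),
                      c(0, rep(0.1, n_model_coefficients(model_id) - 1)))
  obs <- lapply(seq_len(nrow(stations)), function(k) {
    a_km2 <- unname(acc[stations$unit_id[k]])
    sim <- simulate_calibrated_observations(
      model_id, base_coef, target_annual_load = unname(true_loads[k]),
      sigma = sigma, flow_log_mean = log(0.01 * a_km2),
      n_days = n_days, n_samples = n_samples)
    m <- merge(sim$flow, sim$samples, by = "date", all.x = TRUE)
    data.frame(station_id = stations$station_id[k], m,
               flow_unit = "m3s", constituent = constituent)
  })
  list(units = units, graph = graph, stations = stations, yields = yields,
       true_loads = true_loads, observations = do.call(rbind, obs))
}
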