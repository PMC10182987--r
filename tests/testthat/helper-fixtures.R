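# Shared fixtures and independent oracles.

# Minimal unit-table constructor.
make_units <- function(ids, tohuc, area = rep(10, length(ids)),
                       closed = rep(FALSE, length(ids))) {
  data.frame(unit_id = ids, tohuc_id = tohuc, area_km2 = area,
             closed_basin = closed)
}

# Independent brute-force oracle: walk every unit's downstream path over the
# raw table (closed-basin units are terminal) and invert to upstream sets.
brute_force_paths <- function(units) {
  n <- nrow(units)
  parent <- match(units$tohuc_id, units$unit_id)
  parent[units$tohuc_id == "OCEAN" | units$closed_basin] <- NA
  lapply(seq_len(n), function(u) {
    path <- integer(0)
    v <- u
    steps <- 0
    while (!is.na(v)) {
      path <- c(path, v)
      v <- parent[v]
      steps <- steps + 1
      if (steps > n) stop("path longer than n: cycle")
    }
    path
  })
}

brute_force_upstream <- function(units) {
  paths <- brute_force_paths(units)
  up <- vector("list", nrow(units))
  for (u in seq_along(paths))
    for (v in paths[[u]]) up[[v]] <- c(up[[v]], u)
  lapply(up, function(ix) units$unit_id[ix])
}

brute_force_drainage <- function(units) {
  up <- brute_force_upstream(units)
  vapply(up, function(ids)
    sum(units$area_km2[match(ids, units$unit_id)]), numeric(1))
}

# Nine-station nested-gauge fixture: S1 the outlet gauge; S11..S15 its
# immediate upstream gauges; S121 above S12; S131, S132 above S13; two
# ungauged units below S1 and one plain upstream unit above S11.
fig5_fixture <- function() {
  ids <- c("OUT1", "MID0", "U1", "U11", "U12", "U13", "U14", "U15",
           "U121", "U131", "U132", "U11A")
  tohuc <- c("OCEAN", "OUT1", "MID0", "U1", "U1", "U1", "U1", "U1",
             "U12", "U13", "U13", "U11")
  units <- make_units(ids, tohuc, area = seq(10, 120, by = 10))
  stations <- data.frame(
    station_id = c("S1", "S11", "S12", "S13", "S14", "S15",
                   "S121", "S131", "S132"),
    unit_id = c("U1", "U11", "U12", "U13", "U14", "U15",
                "U121", "U131", "U132"),
    reported_area_km2 = NA_real_)
  list(units = units, stations = stations, graph = build_graph(units))
}

# Chain watershed with gauges every `every` units: guarantees nesting, so
# upstream/downstream pair fixtures always exist.
chain_fixture <- function(n_units = 30, every = 3, area = 10) {
  ids <- sprintf("c%02d", seq_len(n_units))
  tohuc <- c(ids[-1], "OCEAN")
  units <- make_units(ids, tohuc, area = rep(area, n_units))
  pos <- seq(every, n_units, by = every)
  stations <- data.frame(station_id = sprintf("G%02d", pos),
                         unit_id = ids[pos],
                         reported_area_km2 = NA_real_)
  list(units = units, stations = stations, graph = build_graph(units),
       positions = pos)
}

# All stations strictly upstream of s (transitive closure).
upstream_station_closure <- function(graph, stations, s) {
  ids <- as.character(stations$station_id)
  keep <- vapply(seq_len(nrow(stations)), function(k) {
    ids[k] != s &&
      s %in% downstream_station_path(graph, stations, stations$unit_id[k])
  }, logical(1))
  ids[keep]
}

# Paired-observation table generated straight from a model, bypassing the
# flow/concentration plumbing, for fitter-level tests.
make_paired <- function(n = 50, seed = 1, sigma = 0) {
  withr::with_seed(seed, {
    dates <- as.Date("2005-03-01") + sort(sample(0:1500, n))
    flow <- exp(rnorm(n, 1, 0.7))
    dt <- decimal_time(dates)
    lnload <- 8 + 0.9 * (log(flow) - mean(log(flow))) + rnorm(n, 0, sigma)
    data.frame(date = dates, flow = flow,
               concentration = exp(lnload) / (86400 * flow),
               load = exp(lnload), dtime = dt)
  })
}
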