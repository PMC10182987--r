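#' Pipeline configuration
#'
#' Declarative settings for the end-to-end load/yield pipeline.
#'
#' @param min_obs minimum paired observations per station (default 12).
#' @param flow_unit `"m3s"` or `"cfs"` (cfs input is converted by 0.0283168).
#' @param days_per_year conversion year length, default 365.25.
#' @param yield_granularity `"per_region"` or `"per_level"`.
#' @param max_up_obs,min_down_obs validation pair thresholds (20 / 30).
#' @param pair_mode `"immediate"` or `"any"` upstream pairing.
#' @param seed optional integer seed for anything stochastic downstream.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(min_obs = 12, flow_unit = c("m3s", "cfs"),
                            days_per_year = 365.25,
                            yield_granularity = c("per_region", "per_level"),
                            max_up_obs = 20, min_down_obs = 30,
                            pair_mode = c("immediate", "any"),
                            seed = NULL) {
  stopifnot(min_obs >= 1, max_up_obs >= 1, min_down_obs >= 1,
            days_per_year > 0)
  structure(list(min_obs = min_obs, flow_unit = match.arg(flow_unit),
                 days_per_year = days_per_year,
                 yield_granularity = match.arg(yield_granularity),
                 max_up_obs = max_up_obs, min_down_obs = min_down_obs,
                 pair_mode = match.arg(pair_mode), seed = seed),
            class = "pipeline_config")
}

CFS_TO_M3S <- 0.0283168

#' Read catchment, station and observation CSV files
#'
#' Thin readers for the pipeline's CSV dialects. Observation files carry
#' `station_id, date, flow, flow_unit, concentration, constituent`; flows in
#' `cfs` are converted to m^3 s^-1 on read. Malformed files error naming the
#' missing column.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @name pipeline_io
NULL

.read_csv_req <- function(path, required) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss) > 0)
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  d
}

#' @rdname pipeline_io
#' @export
read_catchments_csv <- function(path)
  .read_csv_req(path, c("unit_id", "tohuc_id", "area_km2", "closed_basin"))

#' @rdname pipeline_io
#' @export
read_corrections_csv <- function(path)
  .read_csv_req(path, c("unit_id", "corrected_tohuc_id"))

#' @rdname pipeline_io
#' @export
read_stations_csv <- function(path)
  .read_csv_req(path, c("station_id", "unit_id"))

#' @rdname pipeline_io
#' @export
read_observations_csv <- function(path) {
  d <- .read_csv_req(path, c("station_id", "date", "flow", "flow_unit",
                             "concentration", "constituent"))
  d$date <- as.Date(d$date)
  cfs <- d$flow_unit == "cfs"
  d$flow[cfs] <- d$flow[cfs] * CFS_TO_M3S
  d$flow_unit[cfs] <- "m3s"
  d
}

#' Write the station-load table
#'
#' Column names mirror the station-load record schema: station id, derived
#' and reported drainage areas, a source flag (0 = no reported record),
#' carbon load (gC day^-1), observation count, data period, regression model
#' id and R-square (%).
#'
#' @param station_loads data.frame from [run_carbon_pipeline()].
#' @param path output CSV path.
#' @export
write_station_loads_csv <- function(station_loads, path) {
  out <- data.frame(
    `Station ID` = station_loads$station_id,
    `NHDplus derived drainage area` = station_loads$derived_area_km2,
    `USGS reported drainage area (km2)` =
      ifelse(is.na(station_loads$reported_area_km2), 0,
             station_loads$reported_area_km2),
    `Drainage area data source flag` =
      ifelse(is.na(station_loads$reported_area_km2), 0, 1),
    `Carbon load` = station_loads$mean_daily_load,
    `Number of observations` = station_loads$n_obs,
    `Data period` = ifelse(is.na(station_loads$period_start), "",
                           paste0(station_loads$period_start, "-",
                                  station_loads$period_end)),
    `Regression model` = station_loads$model_id,
    `R-square(%)` = station_loads$r_square_pct,
    Constituent = station_loads$constituent,
    `Exclusion reason` = ifelse(is.na(station_loads$reason), "",
                                station_loads$reason),
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the per-unit yield table
#'
#' Columns mirror the watershed-yield record schema: HUC12-style unit id,
#' downstream link, unit area, and one yield column per constituent
#' (kgC km^-2 yr^-1; blank = no data).
#'
#' @param yield_table data.frame from [build_yield_table()].
#' @param path output CSV path.
#' @export
write_yield_csv <- function(yield_table, path) {
  nm <- names(yield_table)
  nm[nm == "unit_id"] <- "HUC12 ID"
  nm[nm == "tohuc_id"] <- "ToHUC"
  nm[nm == "area_km2"] <- "Area"
  nm <- sub("^poc_yield$", "POC yield", nm)
  nm <- sub("^doc_yield$", "DOC yield", nm)
  out <- yield_table
  names(out) <- nm
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full load-and-yield pipeline
#'
#' End-to-end orchestration over in-memory tables: builds and validates the
#' drainage graph, derives station drainage areas (headwater rule applied),
#' pairs observations and fits the AIC-selected rating curve per station and
#' constituent, predicts and averages daily loads, levels stations, maps
#' units to inter-station regions, computes net regional yields by mass
#' balance, and runs both validation procedures. Stations failing the
#' minimum-observation filter (or with all fits failed) are carried through
#' with a `NA` load and a reason code, never dropped.
#'
#' @param units catchment table (see [build_graph()]).
#' @param stations station table (`station_id`, `unit_id`,
#'   `reported_area_km2` optional).
#' @param observations long observation table (`station_id`, `date`, `flow`,
#'   `flow_unit`, `concentration`, `constituent`; concentration `NA` on
#'   unsampled days).
#' @param corrections optional downstream-link corrections table.
#' @param config a [pipeline_config()].
#' @return list: `graph`, `station_loads` (one row per station x
#'   constituent), `station_areas`, `region_yields`, `yield_table`,
#'   `sign_summary`, `assignments`, `validation` (`area_comparison`,
#'   `pair_report`), `exclusions` (machine-readable ledger).
#' @export
run_carbon_pipeline <- function(units, stations, observations,
                                corrections = NULL,
                                config = pipeline_config()) {
  graph <- build_graph(units, corrections)
  excluded <- closed_basin_excluded_set(graph)
  stations$station_id <- as.character(stations$station_id)
  stations$unit_id <- as.character(stations$unit_id)
  if (is.null(stations$reported_area_km2))
    stations$reported_area_km2 <- NA_real_

  # station drainage areas (headwater rule)
  sa <- lapply(seq_len(nrow(stations)), function(k)
    station_drainage_area(graph, stations$unit_id[k],
                          stations$reported_area_km2[k]))
  station_areas <- data.frame(
    station_id = stations$station_id,
    unit_id = stations$unit_id,
    derived_area_km2 = vapply(stations$unit_id, function(u)
      drainage_area(graph, u), numeric(1), USE.NAMES = FALSE),
    reported_area_km2 = stations$reported_area_km2,
    area_km2 = vapply(sa, `[[`, numeric(1), "area_km2"),
    area_source = vapply(sa, `[[`, character(1), "source"))
  areas <- stats::setNames(station_areas$area_km2, station_areas$station_id)

  cfs <- observations$flow_unit == "cfs"
  observations$flow[cfs] <- observations$flow[cfs] * CFS_TO_M3S
  observations$date <- as.Date(observations$date)

  exclusions <- list()
  rows <- list()
  for (const in unique(observations$constituent)) {
    oc <- observations[observations$constituent == const, , drop = FALSE]
    for (s in stations$station_id) {
      os <- oc[oc$station_id == s, , drop = FALSE]
      flow <- unique(os[!is.na(os$flow), c("date", "flow")])
      samp <- os[!is.na(os$concentration), c("date", "concentration")]
      base <- data.frame(station_id = s, constituent = const,
                         mean_daily_load = NA_real_, annual_load = NA_real_,
                         n_obs = 0L, period_start = NA_real_,
                         period_end = NA_real_, model_id = NA_integer_,
                         r_square_pct = NA_real_, reason = NA_character_)
      if (nrow(flow) == 0 || nrow(samp) == 0) {
        base$reason <- "no_observations"
        exclusions[[length(exclusions) + 1]] <-
          data.frame(station_id = s, constituent = const,
                     reason = "no_observations")
        rows[[length(rows) + 1]] <- base
        next
      }
      paired <- pair_same_day(flow, samp)
      base$n_obs <- nrow(paired)
      if (!passes_min_obs(paired, config$min_obs)) {
        base$reason <- "too_few_observations"
        exclusions[[length(exclusions) + 1]] <-
          data.frame(station_id = s, constituent = const,
                     reason = "too_few_observations")
        rows[[length(rows) + 1]] <- base
        next
      }
      rc <- tryCatch(rating_curve(paired, min_obs = config$min_obs),
                     error = function(e) NULL)
      if (is.null(rc)) {
        base$reason <- "all_fits_failed"
        exclusions[[length(exclusions) + 1]] <-
          data.frame(station_id = s, constituent = const,
                     reason = "all_fits_failed")
        rows[[length(rows) + 1]] <- base
        next
      }
      daily <- predict(rc, flow)
      yrs <- as.POSIXlt(paired$date)$year + 1900
      sl <- summarize_station_load(daily, nrow(paired),
                                   c(min(yrs), max(yrs)), rc$fit,
                                   station_id = s)
      sl$annual_load <- sl$mean_daily_load * config$days_per_year / 1000
      base[c("mean_daily_load", "annual_load", "n_obs", "period_start",
             "period_end", "model_id", "r_square_pct")] <-
        sl[c("mean_daily_load", "annual_load", "n_obs", "period_start",
             "period_end", "model_id", "r_square_pct")]
      rows[[length(rows) + 1]] <- base
    }
  }
  station_loads <- do.call(rbind, rows)
  station_loads <- merge(station_loads,
                         station_areas[, c("station_id", "derived_area_km2",
                                           "reported_area_km2",
                                           "area_source")],
                         by = "station_id", sort = FALSE)

  # yields per constituent over the stations with loads
  assignments <- list()
  ry <- list()
  for (const in unique(station_loads$constituent)) {
    sl <- station_loads[station_loads$constituent == const, , drop = FALSE]
    st_c <- stations[stations$station_id %in%
                       sl$station_id[!is.na(sl$annual_load)], , drop = FALSE]
    if (nrow(st_c) == 0) {
      assignments[[const]] <- assign_regions(graph,
                                             stations[0, , drop = FALSE],
                                             excluded)
      ry[[const]] <- NULL
      next
    }
    loads_v <- stats::setNames(sl$annual_load, sl$station_id)
    assignments[[const]] <- assign_regions(graph, st_c, excluded)
    ry[[const]] <- region_yields(graph, st_c, loads_v, areas,
                                 granularity = config$yield_granularity)
  }
  have_ry <- !vapply(ry, is.null, logical(1))
  yield_table <- build_yield_table(graph, assignments[have_ry], ry[have_ry])
  sign_summary <- summarize_yield_sign(yield_table)

  # validation
  area_comparison <- tryCatch(
    compare_drainage_areas(data.frame(
      derived_km2 = station_areas$derived_area_km2,
      reported_km2 = station_areas$reported_area_km2)),
    error = function(e) list(skipped = conditionMessage(e)))
  pair_report <- lapply(split(station_loads, station_loads$constituent),
                        function(sl) {
    pairs <- select_validation_pairs(graph, stations, sl, areas,
                                     max_up_obs = config$max_up_obs,
                                     min_down_obs = config$min_down_obs,
                                     mode = config$pair_mode)
    tryCatch(pair_consistency_report(pairs),
             error = function(e) list(skipped = conditionMessage(e),
                                      pairs = pairs))
  })

  list(graph = graph, station_loads = station_loads,
       station_areas = station_areas,
       region_yields = ry, yield_table = yield_table,
       sign_summary = sign_summary, assignments = assignments,
       validation = list(area_comparison = area_comparison,
                         pair_report = pair_report),
       exclusions = if (length(exclusions)) do.call(rbind, exclusions)
                    else data.frame(station_id = character(0),
                                    constituent = character(0),
                                    reason = character(0)))
}
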