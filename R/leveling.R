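#' Sentinel region id for units not controlled by any station
#' @export
NO_DATA <- "NO_DATA"

.station_by_unit <- function(stations) {
  stations$station_id <- as.character(stations$station_id)
  stations$unit_id <- as.character(stations$unit_id)
  if (anyDuplicated(stations$unit_id))
    stop("more than one station on unit(s): ",
         paste(unique(stations$unit_id[duplicated(stations$unit_id)]),
               collapse = ", "),
         "; co-located gauges must be merged before leveling")
  stats::setNames(stations$station_id, stations$unit_id)
}

#' Stations on the downstream path of a unit
#'
#' Walks the unique downstream path starting at `unit_id` (a station hosted
#' on the unit itself comes first) and returns the stations encountered, in
#' downstream order.
#'
#' @param graph a `"catchment_graph"`.
#' @param stations data.frame with `station_id`, `unit_id`.
#' @param unit_id starting unit.
#' @return character vector of station ids (possibly empty).
#' @export
downstream_station_path <- function(graph, stations, unit_id) {
  by_unit <- .station_by_unit(stations)
  i <- .unit_index(graph, unit_id)
  out <- character(0)
  while (!is.na(i)) {
    u <- graph$units$unit_id[i]
    if (!is.na(by_unit[u])) out <- c(out, unname(by_unit[u]))
    i <- graph$parent_idx[i]
  }
  out
}

#' Assign hierarchical levels to stations
#'
#' A level-1 station has no station downstream on its drainage path; level
#' `n + 1` stations are immediately (or transitively) upstream of level-`n`
#' ones: `level = 1 + number of stations strictly downstream`.
#'
#' @param graph a `"catchment_graph"`.
#' @param stations data.frame with `station_id`, `unit_id`; at most one
#'   station per unit.
#' @return data.frame `station_id`, `unit_id`, `level`.
#' @export
assign_station_levels <- function(graph, stations) {
  .station_by_unit(stations)  # validates one-per-unit
  lv <- vapply(seq_len(nrow(stations)), function(k) {
    path <- downstream_station_path(graph, stations, stations$unit_id[k])
    length(path)  # includes the station itself first
  }, numeric(1))
  data.frame(station_id = as.character(stations$station_id),
             unit_id = as.character(stations$unit_id),
             level = as.integer(lv))
}

#' Map every unit to its controlling inter-station region
#'
#' Each unit belongs to the region of the nearest station on its downstream
#' path (the hosting unit of a station belongs to that station's own
#' region). Units with no station downstream, and units draining to a closed
#' basin, are `NO_DATA` with a reason code: `closed_basin`,
#' `downstream_of_outlet` (a station exists upstream but none downstream) or
#' `no_station` (no station controls or feeds the unit).
#'
#' @param graph a `"catchment_graph"`.
#' @param stations data.frame with `station_id`, `unit_id`.
#' @param excluded character vector of excluded unit ids, default
#'   [closed_basin_excluded_set()].
#' @return data.frame `unit_id`, `region_id`, `no_data_reason` (`NA` for
#'   assigned units).
#' @export
assign_regions <- function(graph, stations,
                           excluded = closed_basin_excluded_set(graph)) {
  ids <- graph$units$unit_id
  by_unit <- .station_by_unit(stations)
  pidx <- graph$parent_idx
  n <- length(ids)

  # nearest downstream station, memoized along parent pointers
  region <- rep(NA_character_, n)
  known <- logical(n)
  host <- unname(by_unit[ids])
  for (s in seq_len(n)) {
    if (known[s]) next
    path <- integer(0)
    v <- s
    r <- NA_character_
    while (!is.na(v) && !known[v]) {
      if (!is.na(host[v])) { r <- host[v]; known[v] <- TRUE; region[v] <- r; break }
      path <- c(path, v)
      v <- pidx[v]
    }
    if (is.na(r) && !is.na(v) && known[v]) r <- region[v]
    region[path] <- r
    known[path] <- TRUE
  }

  # any station strictly upstream? (for the no-data reason code)
  has_up_station <- !is.na(host)
  acc <- accumulate_drainage(graph)  # reuse root-first ordering logic cheaply
  # propagate hosting flags leaf-to-root via parent pointers on a reverse pass
  ord <- order(acc[ids])  # upstream units have smaller accumulated area than parents
  for (i in ord) {
    p <- pidx[i]
    if (!is.na(p) && has_up_station[i]) has_up_station[p] <- TRUE
  }

  out <- data.frame(unit_id = ids, region_id = region,
                    no_data_reason = NA_character_)
  nodata <- is.na(out$region_id)
  out$region_id[nodata] <- NO_DATA
  out$no_data_reason[nodata] <-
    ifelse(has_up_station[nodata], "downstream_of_outlet", "no_station")
  excl <- out$unit_id %in% excluded
  out$region_id[excl] <- NO_DATA
  out$no_data_reason[excl] <- "closed_basin"
  out
}
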