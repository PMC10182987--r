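#' Immediately upstream stations of a station
#'
#' Stations whose first strictly-downstream station is `station_id` (the
#' nested gauges that bound the incremental watershed from above).
#'
#' @param graph a `"catchment_graph"`.
#' @param stations data.frame with `station_id`, `unit_id`.
#' @param station_id downstream station.
#' @return character vector of station ids (possibly empty).
#' @export
immediate_upstream_stations <- function(graph, stations, station_id) {
  stations$station_id <- as.character(stations$station_id)
  if (!station_id %in% stations$station_id)
    stop("unknown station: ", station_id)
  up <- vapply(seq_len(nrow(stations)), function(k) {
    path <- downstream_station_path(graph, stations, stations$unit_id[k])
    # path[1] is the station itself; path[2] its first downstream station
    length(path) >= 2 && path[2] == station_id
  }, logical(1))
  stations$station_id[up]
}

#' Net carbon yield of one inter-station region
#'
#' The incremental watershed of a station is its drainage area minus the
#' drainage areas of its immediately upstream stations; its net yield is the
#' load difference over the area difference,
#' `Y = (F_down - sum F_up) / (A_down - sum A_up)` (kgC km^-2 yr^-1).
#' With no upstream stations `Y = F/A`. Negative `Y` (net removal) is a
#' valid result and is retained. A non-positive incremental area flags the
#' region invalid; a missing upstream load or area flags it incomplete.
#'
#' @param station_id downstream station id.
#' @param loads named numeric vector of station loads, kgC yr^-1.
#' @param areas named numeric vector of station drainage areas, km^2.
#' @param upstream_ids character vector of the immediately upstream stations.
#' @param level optional station level carried through.
#' @return one-row data.frame: `region_id`, `level`, `F_down`, `F_up_sum`,
#'   `A_down`, `A_up_sum`, `yield`, `status` (valid / invalid / incomplete).
#' @export
compute_region_yield <- function(station_id, loads, areas, upstream_ids,
                                 level = NA_integer_) {
  F_down <- unname(loads[station_id])
  A_down <- unname(areas[station_id])
  F_up <- loads[upstream_ids]
  A_up <- areas[upstream_ids]
  row <- data.frame(region_id = station_id, level = level,
                    F_down = F_down, F_up_sum = sum(F_up),
                    A_down = A_down, A_up_sum = sum(A_up),
                    yield = NA_real_, status = "valid")
  if (is.na(F_down) || is.na(A_down) || anyNA(F_up) || anyNA(A_up)) {
    row$status <- "incomplete"
    return(row)
  }
  dA <- A_down - sum(A_up)
  if (dA <= 0) {
    row$status <- "invalid"  # non-positive incremental area
    return(row)
  }
  row$yield <- (F_down - sum(F_up)) / dA
  row
}

#' Yields for every station region of one constituent
#'
#' Computes [compute_region_yield()] for every station that has a load and
#' area, using the immediate-upstream-station structure from the leveling.
#' With `granularity = "per_level"` regions of the same level within one
#' drainage tree are pooled: the pooled yield is the incremental-area-
#' weighted mean of the per-region yields, written back to each region.
#'
#' @param graph a `"catchment_graph"`.
#' @param stations data.frame with `station_id`, `unit_id`.
#' @param loads named numeric vector of station loads, kgC yr^-1 (`NA`
#'   allowed for stations without an estimate).
#' @param areas named numeric vector of station drainage areas, km^2.
#' @param granularity `"per_region"` (default, one yield per downstream
#'   station) or `"per_level"` (pooled within level and drainage tree).
#' @return data.frame of region records (see [compute_region_yield()]), plus
#'   a `tree_id` column identifying the drainage tree.
#' @export
region_yields <- function(graph, stations, loads, areas,
                          granularity = c("per_region", "per_level")) {
  granularity <- match.arg(granularity)
  levels <- assign_station_levels(graph, stations)
  tree <- .tree_roots(graph)
  rows <- lapply(seq_len(nrow(levels)), function(k) {
    s <- levels$station_id[k]
    up <- immediate_upstream_stations(graph, stations, s)
    r <- compute_region_yield(s, loads, areas, up, level = levels$level[k])
    r$tree_id <- unname(tree[levels$unit_id[k]])
    r
  })
  out <- do.call(rbind, rows)
  if (granularity == "per_level") {
    valid <- out$status == "valid"
    key <- paste(out$tree_id, out$level)
    for (g in unique(key[valid])) {
      sel <- valid & key == g
      dA <- out$A_down[sel] - out$A_up_sum[sel]
      out$yield[sel] <- sum(out$yield[sel] * dA) / sum(dA)
    }
  }
  out
}

# root unit id of every unit's drainage tree
.tree_roots <- function(graph) {
  ids <- graph$units$unit_id
  pidx <- graph$parent_idx
  root <- rep(NA_character_, length(ids))
  for (s in seq_along(ids)) {
    if (!is.na(root[s])) next
    path <- integer(0)
    v <- s
    while (!is.na(v) && is.na(root[v])) { path <- c(path, v); v <- pidx[v] }
    r <- if (is.na(v)) ids[path[length(path)]] else root[v]
    root[path] <- r
  }
  stats::setNames(root, ids)
}

#' Per-unit yield table
#'
#' One record per catchment unit carrying the (corrected) downstream link,
#' the unit area, and the yield of each constituent's controlling region —
#' blank (`NA`) where the unit is `NO_DATA` or its region is invalid or
#' incomplete. All units of one region carry the region's identical value.
#'
#' @param graph a `"catchment_graph"`.
#' @param assignments named list, one [assign_regions()] result per
#'   constituent (e.g. `list(POC = ..., DOC = ...)`).
#' @param yields named list, one [region_yields()] result per constituent,
#'   same names as `assignments`.
#' @return data.frame: `unit_id`, `tohuc_id`, `area_km2`, then one
#'   `<constituent>_yield` column per constituent (kgC km^-2 yr^-1).
#' @export
build_yield_table <- function(graph, assignments, yields) {
  stopifnot(identical(sort(names(assignments)), sort(names(yields))))
  out <- graph$units[, c("unit_id", "tohuc_id", "area_km2")]
  for (const in names(assignments)) {
    a <- assignments[[const]]
    y <- yields[[const]]
    lut <- stats::setNames(ifelse(y$status == "valid", y$yield, NA_real_),
                           y$region_id)
    col <- lut[a$region_id[match(out$unit_id, a$unit_id)]]
    out[[paste0(tolower(const), "_yield")]] <- unname(col)
  }
  rownames(out) <- NULL
  out
}

#' Tally units by yield sign
#'
#' Counts units and sums unit areas by yield sign per constituent. Exactly
#' zero yields form their own class (the gain/removal boundary is strict).
#'
#' @param yield_table data.frame from [build_yield_table()].
#' @return data.frame with one row per constituent: counts `n_positive`,
#'   `n_negative`, `n_zero`, `n_nodata` and the corresponding total areas
#'   (km^2).
#' @export
summarize_yield_sign <- function(yield_table) {
  ycols <- grep("_yield$", names(yield_table), value = TRUE)
  rows <- lapply(ycols, function(cn) {
    y <- yield_table[[cn]]
    a <- yield_table$area_km2
    data.frame(constituent = sub("_yield$", "", cn),
               n_positive = sum(!is.na(y) & y > 0),
               area_positive = sum(a[!is.na(y) & y > 0]),
               n_negative = sum(!is.na(y) & y < 0),
               area_negative = sum(a[!is.na(y) & y < 0]),
               n_zero = sum(!is.na(y) & y == 0),
               area_zero = sum(a[!is.na(y) & y == 0]),
               n_nodata = sum(is.na(y)),
               area_nodata = sum(a[is.na(y)]))
  })
  if (length(rows) == 0)
    return(data.frame(constituent = character(0), n_positive = integer(0),
                      area_positive = numeric(0), n_negative = integer(0),
                      area_negative = numeric(0), n_zero = integer(0),
                      area_zero = numeric(0), n_nodata = integer(0),
                      area_nodata = numeric(0)))
  do.call(rbind, rows)
}
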