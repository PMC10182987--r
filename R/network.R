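#' Terminal sentinel for units draining to the sea
#' @export
OCEAN <- "OCEAN"

#' Build and validate a catchment drainage graph
#'
#' Units form a forest through their downstream ("ToHUC"-style) links: every
#' unit points to exactly one downstream unit, or to the terminal sentinel
#' [OCEAN]. Closed-basin units are flagged on the unit and treated as
#' terminal sinks regardless of their link. An explicit corrections table
#' (analogous to manual repair of defective downstream links against the
#' flowline network) is applied before validation; every applied correction
#' is recorded in the report. Residual cycles or dangling links are hard
#' errors naming the offending units.
#'
#' @param units data.frame with columns `unit_id`, `tohuc_id`, `area_km2`,
#'   `closed_basin` (logical or 0/1).
#' @param corrections optional data.frame with columns `unit_id`,
#'   `corrected_tohuc_id` (and optionally `note`).
#' @return object of class `"catchment_graph"`: `units` (corrected table),
#'   `parent` (named character vector, `NA` for terminal units), `children`
#'   (named list), `report` (applied corrections and defects).
#' @export
build_graph <- function(units, corrections = NULL) {
  req <- c("unit_id", "tohuc_id", "area_km2", "closed_basin")
  stopifnot(all(req %in% names(units)))
  units$unit_id <- as.character(units$unit_id)
  units$tohuc_id <- as.character(units$tohuc_id)
  units$closed_basin <- as.logical(units$closed_basin)
  if (anyDuplicated(units$unit_id))
    stop("duplicate unit_id: ",
         paste(unique(units$unit_id[duplicated(units$unit_id)]), collapse = ", "))
  if (any(!(units$area_km2 > 0)))
    stop("nonpositive area for unit(s): ",
         paste(units$unit_id[!(units$area_km2 > 0)], collapse = ", "))

  applied <- NULL
  if (!is.null(corrections) && nrow(corrections) > 0) {
    stopifnot(all(c("unit_id", "corrected_tohuc_id") %in% names(corrections)))
    idx <- match(as.character(corrections$unit_id), units$unit_id)
    if (anyNA(idx))
      stop("corrections reference unknown unit(s): ",
           paste(corrections$unit_id[is.na(idx)], collapse = ", "))
    old <- units$tohuc_id[idx]
    units$tohuc_id[idx] <- as.character(corrections$corrected_tohuc_id)
    applied <- data.frame(unit_id = as.character(corrections$unit_id),
                          old_tohuc = old,
                          new_tohuc = units$tohuc_id[idx])
  }

  n <- nrow(units)
  parent <- units$tohuc_id
  parent[parent == OCEAN | units$closed_basin] <- NA_character_
  pidx <- match(parent, units$unit_id)
  dangling <- !is.na(parent) & is.na(pidx)
  if (any(dangling))
    stop("dangling downstream link(s): ",
         paste(sprintf("%s -> %s", units$unit_id[dangling], parent[dangling]),
               collapse = ", "))
  if (any(!is.na(pidx) & pidx == seq_len(n)))
    stop("self-loop at unit(s): ",
         paste(units$unit_id[which(!is.na(pidx) & pidx == seq_len(n))],
               collapse = ", "))

  # cycle detection by downstream walk with tricolor marking
  state <- integer(n)  # 0 unseen, 1 on current path, 2 done
  for (s in seq_len(n)) {
    if (state[s] != 0L) next
    path <- integer(0)
    v <- s
    while (!is.na(v) && state[v] == 0L) {
      state[v] <- 1L
      path <- c(path, v)
      v <- pidx[v]
    }
    if (!is.na(v) && state[v] == 1L) {
      cyc <- path[seq(match(v, path), length(path))]
      stop("cycle in drainage network: ",
           paste(units$unit_id[cyc], collapse = " -> "))
    }
    state[path] <- 2L
  }

  children <- split(units$unit_id[!is.na(pidx)], parent[!is.na(pidx)])
  structure(list(units = units,
                 parent = stats::setNames(parent, units$unit_id),
                 parent_idx = stats::setNames(pidx, units$unit_id),
                 children = children,
                 report = list(corrections_applied = applied,
                               n_corrections = if (is.null(applied)) 0L else nrow(applied))),
            class = "catchment_graph")
}

#' @export
print.catchment_graph <- function(x, ...) {
  cat(sprintf("Catchment drainage graph: %d units, %d terminal, %d closed-basin, %d corrections applied\n",
              nrow(x$units), sum(is.na(x$parent)), sum(x$units$closed_basin),
              x$report$n_corrections))
  invisible(x)
}

.unit_index <- function(graph, unit_id) {
  i <- match(as.character(unit_id), graph$units$unit_id)
  if (is.na(i)) stop("unknown unit: ", unit_id)
  i
}

#' Upstream set of a unit
#'
#' All units whose downstream walk passes through `unit_id`, plus the unit
#' itself.
#'
#' @param graph a `"catchment_graph"`.
#' @param unit_id unit identifier.
#' @return character vector of unit ids.
#' @export
upstream_units <- function(graph, unit_id) {
  .unit_index(graph, unit_id)
  out <- character(0)
  frontier <- as.character(unit_id)
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    frontier <- unlist(graph$children[frontier], use.names = FALSE)
  }
  out
}

#' Drainage area of one unit
#'
#' Sum of unit areas over the upstream set (the unit's own area included).
#'
#' @inheritParams upstream_units
#' @return drainage area in km^2.
#' @export
drainage_area <- function(graph, unit_id) {
  up <- upstream_units(graph, unit_id)
  sum(graph$units$area_km2[match(up, graph$units$unit_id)])
}

#' Accumulated drainage area for every unit
#'
#' One leaf-to-root pass: each unit's accumulated area is its own area plus
#' its children's accumulated areas.
#'
#' @param graph a `"catchment_graph"`.
#' @return named numeric vector of drainage areas (km^2) for all units.
#' @export
accumulate_drainage <- function(graph) {
  ids <- graph$units$unit_id
  n <- length(ids)
  pidx <- graph$parent_idx
  # order units root-first by walking down from roots, then accumulate in reverse
  kids_idx <- lapply(graph$children[ids], function(k) match(k, ids))
  names(kids_idx) <- ids
  order_rf <- integer(n)
  head <- 1L
  roots <- which(is.na(pidx))
  order_rf[seq_along(roots)] <- roots
  filled <- length(roots)
  while (head <= filled) {
    k <- kids_idx[[order_rf[head]]]
    if (length(k)) {
      order_rf[filled + seq_along(k)] <- k
      filled <- filled + length(k)
    }
    head <- head + 1L
  }
  acc <- graph$units$area_km2
  for (i in rev(order_rf)) {
    p <- pidx[i]
    if (!is.na(p)) acc[p] <- acc[p] + acc[i]
  }
  stats::setNames(acc, ids)
}

#' Station drainage area with the headwater rule
#'
#' Interior stations take the accumulated (derived) drainage area of their
#' hosting unit. Stations on headwater units (no upstream units) control only
#' part of the unit, so a reported drainage area, where available, replaces
#' the unit area; a headwater without a reported value falls back to the
#' derived area with an overestimation warning.
#'
#' @param graph a `"catchment_graph"`.
#' @param unit_id the station's hosting unit.
#' @param reported_area optional reported drainage area (km^2), `NA` if none.
#' @return list with `area_km2` and `source` ("derived" or "reported").
#' @export
station_drainage_area <- function(graph, unit_id, reported_area = NA) {
  i <- .unit_index(graph, unit_id)
  headwater <- is.null(graph$children[[graph$units$unit_id[i]]])
  if (headwater && !is.na(reported_area))
    return(list(area_km2 = as.numeric(reported_area), source = "reported"))
  if (headwater && is.na(reported_area))
    warning("headwater station on unit ", unit_id,
            " has no reported drainage area; unit area may overestimate")
  list(area_km2 = drainage_area(graph, unit_id), source = "derived")
}

#' Units excluded by closed basins
#'
#' Every closed-basin unit plus every unit whose downstream walk reaches one;
#' water and carbon of these endorheic watersheds are assumed not to interact
#' with the rest of the network, so they are excluded from yield accounting.
#'
#' @param graph a `"catchment_graph"`.
#' @return character vector of excluded unit ids (possibly empty).
#' @export
closed_basin_excluded_set <- function(graph) {
  closed <- graph$units$unit_id[graph$units$closed_basin]
  if (length(closed) == 0) return(character(0))
  unique(unlist(lapply(closed, function(u) upstream_units(graph, u)),
                use.names = FALSE))
}
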