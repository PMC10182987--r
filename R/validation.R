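#' Compare derived and reported drainage areas
#'
#' Least-squares regression of network-derived drainage area on the reported
#' value, for stations carrying both; slope, intercept and R-square are
#' reported for inspection against the 1:1 line.
#'
#' @param areas data.frame with columns `derived_km2` and `reported_km2`
#'   (rows with `NA` in either are dropped).
#' @return list: `slope`, `intercept`, `r_square`, `n`.
#' @export
compare_drainage_areas <- function(areas) {
  stopifnot(all(c("derived_km2", "reported_km2") %in% names(areas)))
  ok <- stats::complete.cases(areas[, c("derived_km2", "reported_km2")])
  d <- areas[ok, , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 stations with both derived and reported areas; got ",
         nrow(d))
  fit <- stats::lm(derived_km2 ~ reported_km2, data = d)
  tss <- sum((d$derived_km2 - mean(d$derived_km2))^2)
  rss <- sum(stats::residuals(fit)^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_square = if (tss > 0) 1 - rss / tss else NA_real_,
       n = nrow(d))
}

#' Select upstream/downstream station pairs for load cross-validation
#'
#' Pairs a sparsely observed upstream station with a well-observed
#' downstream station it drains into: upstream stations with `max_up_obs` or
#' fewer observations (default 20), downstream with `min_down_obs` or more
#' (default 30). `mode = "immediate"` (default) pairs only immediately
#' upstream stations; `mode = "any"` pairs any reachable upstream station. A
#' downstream station may appear in several pairs.
#'
#' @param graph a `"catchment_graph"`.
#' @param stations data.frame with `station_id`, `unit_id`.
#' @param loads data.frame with columns `station_id`, `annual_load`
#'   (kgC yr^-1), `n_obs`.
#' @param areas named numeric vector of station drainage areas (km^2).
#' @param max_up_obs,min_down_obs observation-count thresholds, defaults 20
#'   and 30.
#' @param mode `"immediate"` or `"any"`.
#' @return data.frame of station pairs with observation counts, areas, the
#'   estimated loads and the area-ratio inversed upstream load.
#' @export
select_validation_pairs <- function(graph, stations, loads, areas,
                                    max_up_obs = 20, min_down_obs = 30,
                                    mode = c("immediate", "any")) {
  mode <- match.arg(mode)
  stopifnot(max_up_obs >= 1, min_down_obs >= 1)
  loads$station_id <- as.character(loads$station_id)
  pairs <- list()
  for (k in seq_len(nrow(stations))) {
    s <- as.character(stations$station_id[k])
    path <- downstream_station_path(graph, stations, stations$unit_id[k])
    down <- setdiff(path, s)  # strictly downstream, nearest first
    if (mode == "immediate" && length(down) > 0) down <- down[1]
    for (d in down) {
      iu <- loads[loads$station_id == s, , drop = FALSE]
      id <- loads[loads$station_id == d, , drop = FALSE]
      if (nrow(iu) == 0 || nrow(id) == 0) next
      if (is.na(iu$annual_load) || is.na(id$annual_load)) next
      if (iu$n_obs > max_up_obs || id$n_obs < min_down_obs) next
      pairs[[length(pairs) + 1]] <- data.frame(
        upstream_station_id = s, downstream_station_id = d,
        n_obs_up = iu$n_obs, n_obs_down = id$n_obs,
        A_up = unname(areas[s]), A_down = unname(areas[d]),
        F_up_est = iu$annual_load, F_down_est = id$annual_load,
        F_up_inversed = inverse_upstream_load(id$annual_load,
                                              unname(areas[s]),
                                              unname(areas[d])))
    }
  }
  if (length(pairs) == 0)
    return(data.frame(upstream_station_id = character(0),
                      downstream_station_id = character(0),
                      n_obs_up = integer(0), n_obs_down = integer(0),
                      A_up = numeric(0), A_down = numeric(0),
                      F_up_est = numeric(0), F_down_est = numeric(0),
                      F_up_inversed = numeric(0)))
  do.call(rbind, pairs)
}

#' Area-ratio inversed upstream load
#'
#' Scales a (well-observed) downstream load by the drainage-area ratio to
#' predict the upstream load, assuming load is proportional to contributing
#' area: `F_down * A_up / A_down`.
#'
#' @param F_down downstream load (kgC yr^-1).
#' @param A_up upstream drainage area (km^2).
#' @param A_down downstream drainage area (km^2), > 0.
#' @return inversed upstream load (kgC yr^-1).
#' @export
inverse_upstream_load <- function(F_down, A_up, A_down) {
  if (any(A_down <= 0)) stop("A_down must be > 0")
  F_down * A_up / A_down
}

#' Consistency of estimated vs. inversed upstream loads
#'
#' Pearson correlation and regression slope of the rating-curve-estimated
#' upstream loads against the area-ratio inversed ones, over the selected
#' pairs; high correlation indicates that sparsely observed upstream
#' estimates are consistent with the well-observed downstream record.
#'
#' @param pairs data.frame from [select_validation_pairs()].
#' @param log_scale correlate on the log scale instead (default FALSE).
#' @return list: `pearson_r`, `slope`, `intercept`, `n`, `pairs` (the
#'   per-pair table for plotting). With degenerate variance `pearson_r` is
#'   `NA` and `note` says so.
#' @export
pair_consistency_report <- function(pairs, log_scale = FALSE) {
  if (nrow(pairs) < 3)
    stop("need at least 3 station pairs; got ", nrow(pairs))
  x <- pairs$F_up_inversed
  y <- pairs$F_up_est
  if (log_scale) { x <- log(x); y <- log(y) }
  note <- NULL
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_
    note <- "degenerate variance: correlation undefined"
  } else {
    r <- stats::cor(x, y)
  }
  fit <- stats::lm(y ~ x)
  list(pearson_r = r,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = nrow(pairs), pairs = pairs, note = note)
}
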