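#' Decimal time
#'
#' Convert calendar dates to decimal years, `year + (day_of_year - 0.5) /
#' days_in_year`, the conventional covariate for seasonal rating-curve terms.
#'
#' @param dates a `Date` vector (or something coercible by [as.Date()]).
#' @return numeric vector of decimal years.
#' @export
decimal_time <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  year <- lt$year + 1900L
  doy <- lt$yday + 1L
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  diy <- ifelse(leap, 366, 365)
  year + (doy - 0.5) / diy
}

#' Pair same-day streamflow and concentration records
#'
#' Matches a daily streamflow series with sparse concentration samples on
#' calendar date and computes the instantaneous load. Multiple concentration
#' samples on one day are averaged before the load is computed. Matched days
#' with nonpositive flow or concentration are dropped with a warning (the log
#' transform is undefined there).
#'
#' @param flow data.frame with columns `date` and `flow` (m^3 s^-1).
#' @param conc data.frame with columns `date` and `concentration` (mgC L^-1).
#' @return data.frame with columns `date`, `flow`, `concentration`, `load`
#'   (gC day^-1, equal to `86400 * flow * concentration`) and `dtime`
#'   (decimal years), one row per day present in both inputs.
#' @export
pair_same_day <- function(flow, conc) {
  stopifnot(all(c("date", "flow") %in% names(flow)),
            all(c("date", "concentration") %in% names(conc)))
  flow$date <- as.Date(flow$date)
  conc$date <- as.Date(conc$date)
  cm <- stats::aggregate(concentration ~ date, data = conc, FUN = mean)
  m <- merge(flow[, c("date", "flow")], cm, by = "date")
  m <- m[order(m$date), , drop = FALSE]
  bad <- !(m$flow > 0 & m$concentration > 0) | !is.finite(m$flow) |
    !is.finite(m$concentration)
  if (any(bad)) {
    warning(sum(bad), " matched day(s) dropped: nonpositive flow or concentration")
    m <- m[!bad, , drop = FALSE]
  }
  m$load <- 86400 * m$flow * m$concentration
  m$dtime <- decimal_time(m$date)
  rownames(m) <- NULL
  m
}

#' Minimum-observation filter
#'
#' Stations must carry at least `min_n` paired observations (default 12, the
#' smallest record accepted for rating-curve fitting) to be analysed.
#'
#' @param paired data.frame from [pair_same_day()] (or anything with rows).
#' @param min_n minimum count, default 12.
#' @return logical scalar.
#' @export
passes_min_obs <- function(paired, min_n = 12) {
  stopifnot(min_n >= 1)
  nrow(paired) >= min_n
}

#' Decorrelating centers for ln-flow and decimal time
#'
#' The center is `mean(x) + sum((x - mean)^3) / (2 * sum((x - mean)^2))`, the
#' LOADEST convention that makes the centered variable uncorrelated with its
#' own square. For constant input the cubic correction is 0/0 and is defined
#' as zero, so the center is the common value.
#'
#' @param paired data.frame with columns `flow` and `dtime`.
#' @return list with `lnQ` and `dtime` centers.
#' @export
compute_centers <- function(paired) {
  stopifnot(nrow(paired) >= 2)
  ctr <- function(x) {
    d <- x - mean(x)
    s2 <- sum(d^2)
    if (s2 == 0) return(mean(x))
    mean(x) + sum(d^3) / (2 * s2)
  }
  list(lnQ = ctr(log(paired$flow)), dtime = ctr(paired$dtime))
}

# Covariate sets of the nine rating-curve models, in coefficient order
# (a1, a2, ... after the intercept a0).
.model_terms <- list(
  `1` = c("lnQ"),
  `2` = c("lnQ", "lnQ2"),
  `3` = c("lnQ", "dtime"),
  `4` = c("lnQ", "sin2pt", "cos2pt"),
  `5` = c("lnQ", "lnQ2", "dtime"),
  `6` = c("lnQ", "lnQ2", "sin2pt", "cos2pt"),
  `7` = c("lnQ", "sin2pt", "cos2pt", "dtime"),
  `8` = c("lnQ", "lnQ2", "sin2pt", "cos2pt", "dtime"),
  `9` = c("lnQ", "lnQ2", "sin2pt", "cos2pt", "dtime", "dtime2")
)

#' Number of regression coefficients (including intercept) per model
#' @param model_id integer 1..9
#' @return integer count
#' @export
n_model_coefficients <- function(model_id) {
  length(.model_terms[[as.character(model_id)]]) + 1L
}

# Full design matrix columns from centered covariates.
.covariates <- function(lnQ, dtime, centers) {
  q <- lnQ - centers$lnQ
  t <- dtime - centers$dtime
  cbind(lnQ = q, lnQ2 = q^2,
        sin2pt = sin(2 * pi * t), cos2pt = cos(2 * pi * t),
        dtime = t, dtime2 = t^2)
}

.design <- function(lnQ, dtime, centers, model_id) {
  cov <- .covariates(lnQ, dtime, centers)
  cbind(`(Intercept)` = 1, cov[, .model_terms[[as.character(model_id)]],
                               drop = FALSE])
}

#' Fit one rating-curve model
#'
#' Maximum-likelihood fit of ln(load) on the covariate set of one of the nine
#' models (for uncensored observations this is ordinary least squares; the
#' residual variance `s2` is the ML estimate RSS/n). The AIC counts the
#' variance parameter: `AIC = -2*logLik + 2*(p + 1)` with `p` regression
#' coefficients. `r_square_pct` is the percent of ln-load variance explained.
#'
#' @param paired data.frame from [pair_same_day()].
#' @param centers list from [compute_centers()].
#' @param model_id integer in 1..9.
#' @return list of class `"rating_fit"`: `model_id`, `coefficients` (named,
#'   intercept first), `s2`, `log_likelihood`, `aic`, `r_square_pct`,
#'   `n_obs`, `failed`, `residuals`, `fitted_lnload`.
#' @export
fit_rating_model <- function(paired, centers, model_id) {
  stopifnot(model_id %in% 1:9)
  n <- nrow(paired)
  p <- n_model_coefficients(model_id)
  fail <- function(reason) {
    structure(list(model_id = model_id, coefficients = NULL, s2 = NA_real_,
                   log_likelihood = NA_real_, aic = NA_real_,
                   r_square_pct = NA_real_, n_obs = n, failed = TRUE,
                   failure = reason, centers = centers),
              class = "rating_fit")
  }
  if (n < p + 2) return(fail("too few observations for model order"))
  X <- .design(log(paired$flow), paired$dtime, centers, model_id)
  y <- log(paired$load)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X) || anyNA(fit$coefficients))
    return(fail("rank-deficient design"))
  res <- fit$residuals
  rss <- sum(res^2)
  s2 <- rss / n
  tss <- sum((y - mean(y))^2)
  # log-density of N(Xb, s2) at the data; s2 -> 0 only when rss == 0 exactly,
  # where the likelihood is unbounded: report +Inf so the fit wins selection.
  ll <- if (s2 > 0) -n / 2 * (log(2 * pi * s2) + 1) else Inf
  aic <- -2 * ll + 2 * (p + 1)
  r2 <- if (tss > 0) (1 - rss / tss) * 100 else if (rss <= 1e-300) 100 else -Inf
  structure(list(model_id = model_id, coefficients = fit$coefficients,
                 s2 = s2, log_likelihood = ll, aic = aic,
                 r_square_pct = r2, n_obs = n, failed = FALSE,
                 failure = NULL, centers = centers),
            class = "rating_fit")
}

#' Select the best rating-curve model by AIC
#'
#' Returns the non-failed candidate with the smallest AIC; ties are broken
#' toward the smaller model id (the model list is ordered by complexity).
#'
#' @param fits list of `"rating_fit"` objects.
#' @return the selected `"rating_fit"`, or `NULL` if all candidates failed.
#' @export
select_best_model <- function(fits) {
  ok <- Filter(function(f) !f$failed, fits)
  if (length(ok) == 0) return(NULL)
  aics <- vapply(ok, function(f) f$aic, numeric(1))
  ids <- vapply(ok, function(f) f$model_id, numeric(1))
  best <- order(aics, ids)[1]
  ok[[best]]
}

#' Retransformation bias-correction factor
#'
#' Predictions of load on the natural scale from a ln-scale regression are
#' multiplied by `exp(s2 / 2)`, the lognormal mean correction with the ML
#' residual variance. Isolated here so an alternative small-sample (AMLE
#' g-function) correction can be swapped in.
#'
#' @param s2 ML residual variance on the ln-load scale.
#' @return multiplicative correction factor.
#' @export
bias_correction_factor <- function(s2) exp(s2 / 2)

#' Fit a station rating curve with AIC model selection
#'
#' Fits all nine candidate log-linear rating-curve models of ln(load) on
#' centered ln-flow and decimal-time covariates and selects the one with the
#' least AIC. This is the package's central estimator: the returned object
#' supports `print`, `summary`, `coef`, `predict` (daily loads on a flow
#' series, with retransformation bias correction), `fitted`, `residuals`,
#' `logLik`, `AIC`, `plot` and `simulate`.
#'
#' @param paired data.frame from [pair_same_day()] (columns `flow`, `load`,
#'   `dtime`; `date` kept if present).
#' @param models integer vector of candidate model ids, default `1:9`.
#' @param min_obs minimum paired-observation count, default 12.
#' @return object of class `"rating_curve"`: elements `fit` (selected
#'   `"rating_fit"`), `fits` (all candidates), `centers`, `data`, `call`.
#' @examples
#' d <- simulate_observations(model_id = 4, coefficients = c(8, 0.9, 0.4, 0.2),
#'                            sigma = 0.2, n_days = 730, n_samples = 40,
#'                            seed = 1)
#' rc <- rating_curve(pair_same_day(d$flow, d$samples))
#' rc
#' head(predict(rc, d$flow))
#' @export
rating_curve <- function(paired, models = 1:9, min_obs = 12) {
  stopifnot(all(models %in% 1:9), nrow(paired) >= 1)
  if (!passes_min_obs(paired, min_obs))
    stop("station has ", nrow(paired), " paired observations; at least ",
         min_obs, " are required")
  centers <- compute_centers(paired)
  fits <- lapply(models, function(m) fit_rating_model(paired, centers, m))
  best <- select_best_model(fits)
  if (is.null(best)) stop("all candidate rating-curve fits failed")
  structure(list(fit = best, fits = fits, centers = centers, data = paired,
                 call = match.call()),
            class = "rating_curve")
}

#' @export
print.rating_curve <- function(x, ...) {
  f <- x$fit
  cat("Rating curve (ln-load regression, AIC-selected)\n")
  cat(sprintf("  model %d of 9, n = %d paired observations\n",
              f$model_id, f$n_obs))
  cat(sprintf("  AIC = %.2f, R-square = %.1f%%, s2 = %.4g\n",
              f$aic, f$r_square_pct, f$s2))
  cat("  coefficients:\n")
  print(round(f$coefficients, 4))
  invisible(x)
}

#' @export
coef.rating_curve <- function(object, all_terms = FALSE, ...) {
  cf <- object$fit$coefficients
  if (!all_terms) return(cf)
  full <- c("(Intercept)", "lnQ", "lnQ2", "sin2pt", "cos2pt", "dtime", "dtime2")
  out <- stats::setNames(numeric(length(full)), full)
  out[names(cf)] <- cf
  out
}

#' @export
logLik.rating_curve <- function(object, ...) {
  f <- object$fit
  structure(f$log_likelihood, df = n_model_coefficients(f$model_id) + 1L,
            nobs = f$n_obs, class = "logLik")
}

#' @export
AIC.rating_curve <- function(object, ...) object$fit$aic

#' @export
fitted.rating_curve <- function(object, ...) {
  f <- object$fit
  X <- .design(log(object$data$flow), object$data$dtime, object$centers,
               f$model_id)
  drop(X %*% f$coefficients)
}

#' @export
residuals.rating_curve <- function(object, ...) {
  log(object$data$load) - fitted(object)
}

#' Predict daily loads from a fitted rating curve
#'
#' Evaluates the selected model at each day's centered covariates and
#' retransforms with the `exp(s2/2)` lognormal bias correction. Days with
#' nonpositive flow are skipped with a warning.
#'
#' @param object a `"rating_curve"`.
#' @param newdata data.frame with columns `date` and `flow` (m^3 s^-1).
#' @param bias_correction apply the retransformation correction (default TRUE).
#' @param ... unused.
#' @return data.frame with columns `date` and `load` (gC day^-1).
#' @export
predict.rating_curve <- function(object, newdata, bias_correction = TRUE, ...) {
  stopifnot(all(c("date", "flow") %in% names(newdata)))
  bad <- !(newdata$flow > 0) | !is.finite(newdata$flow)
  if (any(bad)) {
    warning(sum(bad), " day(s) with nonpositive flow skipped in prediction")
    newdata <- newdata[!bad, , drop = FALSE]
  }
  f <- object$fit
  X <- .design(log(newdata$flow), decimal_time(newdata$date), object$centers,
               f$model_id)
  corr <- if (bias_correction) bias_correction_factor(f$s2) else 1
  data.frame(date = as.Date(newdata$date),
             load = exp(drop(X %*% f$coefficients)) * corr)
}

#' Simulate ln-load observations from a fitted rating curve
#' @param object a `"rating_curve"`.
#' @param nsim number of replicate sample sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns of loads at the observed covariates.
#' @export
simulate.rating_curve <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) return(withr::with_seed(seed, simulate(object, nsim)))
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, exp(mu + stats::rnorm(length(mu),
                                                             sd = sqrt(object$fit$s2)))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.rating_curve <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$fits, function(f) {
    data.frame(model_id = f$model_id,
               p = n_model_coefficients(f$model_id),
               failed = f$failed,
               aic = f$aic, r_square_pct = f$r_square_pct)
  }))
  structure(list(candidates = tab, selected = object$fit,
                 centers = object$centers), class = "summary.rating_curve")
}

#' @export
print.summary.rating_curve <- function(x, ...) {
  cat("Candidate rating-curve models:\n")
  print(x$candidates, row.names = FALSE, digits = 5)
  cat(sprintf("\nSelected: model %d (AIC %.2f)\n", x$selected$model_id,
              x$selected$aic))
  cat(sprintf("Centers: ln Q = %.4f, dtime = %.4f\n",
              x$centers$lnQ, x$centers$dtime))
  invisible(x)
}

#' @export
plot.rating_curve <- function(x, ...) {
  obs <- x$data
  graphics::plot(log(obs$flow), log(obs$load),
                 xlab = "ln streamflow (m3/s)", ylab = "ln load (gC/day)",
                 main = sprintf("Rating curve, model %d", x$fit$model_id), ...)
  o <- order(obs$flow)
  graphics::lines(log(obs$flow)[o], fitted(x)[o], col = "steelblue", lwd = 2)
  invisible(x)
}

#' Summarize a station's mean and annual load
#'
#' The station load is the arithmetic mean of the predicted daily loads over
#' all days with flow data (whole-record mean); the annual load converts
#' gC day^-1 to kgC yr^-1 with a 365.25-day year.
#'
#' @param daily_loads data.frame from [predict.rating_curve()].
#' @param n_obs number of paired observations behind the fit.
#' @param period numeric length-2, start and end year of the record.
#' @param fit the selected `"rating_fit"` (for model id and R-square).
#' @param station_id optional identifier carried through.
#' @return one-row data.frame: `station_id`, `mean_daily_load` (gC day^-1),
#'   `annual_load` (kgC yr^-1), `n_obs`, `period_start`, `period_end`,
#'   `model_id`, `r_square_pct`.
#' @export
summarize_station_load <- function(daily_loads, n_obs, period, fit,
                                   station_id = NA_character_) {
  stopifnot(nrow(daily_loads) >= 1)
  mdl <- mean(daily_loads$load)
  data.frame(station_id = station_id,
             mean_daily_load = mdl,
             annual_load = mdl * 365.25 / 1000,
             n_obs = n_obs,
             period_start = period[1], period_end = period[2],
             model_id = fit$model_id,
             r_square_pct = fit$r_square_pct)
}
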