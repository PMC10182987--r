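test_that("same-day pairing averages duplicates and computes loads", {
  flow <- data.frame(date = as.Date("2010-01-01") + 0:29,
                     flow = rep(1, 30))
  conc <- data.frame(date = as.Date("2010-01-01") + c(2, 2, 9),
                     concentration = c(2, 4, 5))
  p <- pair_same_day(flow, conc)
  expect_equal(nrow(p), 2)
  expect_equal(p$concentration, c(3, 5))  # day-3 samples averaged
  # unit identity: Q = 1 m3/s, C = 1 mg/L -> 86,400 gC/day
  p1 <- pair_same_day(data.frame(date = as.Date("2010-01-01"), flow = 1),
                      data.frame(date = as.Date("2010-01-01"),
                                 concentration = 1))
  expect_equal(p1$load, 86400)
  # disjoint ranges
  expect_equal(nrow(pair_same_day(
    flow, data.frame(date = as.Date("2012-01-01"), concentration = 1))), 0)
  # nonpositive values dropped with warning
  expect_warning(
    p2 <- pair_same_day(data.frame(date = as.Date("2010-01-01") + 0:1,
                                   flow = c(1, -2)),
                        data.frame(date = as.Date("2010-01-01") + 0:1,
                                   concentration = c(1, 1))),
    "dropped")
  expect_equal(nrow(p2), 1)
})

test_that("minimum-observation filter is a strict count threshold", {
  mk <- function(n) data.frame(x = seq_len(n))
  expect_false(passes_min_obs(mk(11), 12))
  expect_true(passes_min_obs(mk(12), 12))
  expect_false(passes_min_obs(mk(0), 12))
})

test_that("decorrelating centers match hand arithmetic and kill cov(x, x^2)", {
  # lnQ = {0, 0, 3}: mean 1, sum d^2 = 6, sum d^3 = 6 -> center 1.5
  p <- data.frame(flow = exp(c(0, 0, 3)), dtime = c(-1, 0, 1))
  ctr <- compute_centers(p)
  expect_equal(ctr$lnQ, 1.5)
  # symmetric values: odd moment vanishes, center = mean
  expect_equal(ctr$dtime, 0)
  # centered variable uncorrelated with its square
  q <- c(0, 0, 3) - ctr$lnQ
  expect_lt(abs(sum((q - mean(q)) * (q^2 - mean(q^2)))), 1e-9)
  # constant input: 0/0 cubic term defined as zero
  pc <- data.frame(flow = exp(c(2, 2, 2)), dtime = c(1, 1, 1))
  expect_equal(compute_centers(pc)$lnQ, 2)
})

test_that("noiseless data from a model are recovered exactly by that model", {
  for (m in c(1, 2, 3, 4, 9)) {
    k <- n_model_coefficients(m)
    a <- c(8, seq(0.9, by = -0.15, length.out = k - 1))
    sim <- simulate_observations(m, a, sigma = 0, n_days = 1460,
                                 n_samples = 60, seed = 10 + m)
    p <- pair_same_day(sim$flow, sim$samples)
    f <- fit_rating_model(p, compute_centers(p), m)
    expect_false(f$failed)
    expect_equal(unname(f$coefficients), a, tolerance = 1e-8)
    expect_equal(f$r_square_pct, 100)
  }
})

test_that("log-likelihood and AIC agree with a direct log-density oracle", {
  p <- make_paired(n = 60, seed = 3, sigma = 0.4)
  ctr <- compute_centers(p)
  for (m in 1:9) {
    f <- fit_rating_model(p, ctr, m)
    expect_false(f$failed)
    n <- f$n_obs
    k <- n_model_coefficients(m)
    # oracle: sum the normal log-density at the fitted values directly
    X <- cbind(1, rivercarb:::.covariates(log(p$flow), p$dtime, ctr)[
      , rivercarb:::.model_terms[[as.character(m)]], drop = FALSE])
    mu <- drop(X %*% f$coefficients)
    ll_direct <- sum(dnorm(log(p$load), mu, sqrt(f$s2), log = TRUE))
    expect_equal(f$log_likelihood, ll_direct, tolerance = 1e-10)
    expect_equal(f$aic, -2 * ll_direct + 2 * (k + 1), tolerance = 1e-10)
    expect_equal(f$aic, n * log(2 * pi * f$s2) + n + 2 * (k + 1),
                 tolerance = 1e-10)
  }
})

test_that("model 9 has seven coefficients and nesting never loses likelihood", {
  p <- make_paired(n = 80, seed = 4, sigma = 0.5)
  ctr <- compute_centers(p)
  expect_equal(n_model_coefficients(9), 7)
  f <- lapply(1:9, function(m) fit_rating_model(p, ctr, m))
  expect_length(f[[9]]$coefficients, 7)
  for (pair in list(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(2, 6), c(3, 5),
                    c(4, 6), c(4, 7), c(6, 8), c(7, 8), c(8, 9))) {
    expect_gte(f[[pair[2]]]$log_likelihood + 1e-9,
               f[[pair[1]]]$log_likelihood)
  }
})

test_that("AIC selection takes the minimum and breaks ties toward simplicity", {
  p <- make_paired(n = 60, seed = 5, sigma = 0.3)
  ctr <- compute_centers(p)
  fits <- lapply(1:9, function(m) fit_rating_model(p, ctr, m))
  best <- select_best_model(fits)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  expect_equal(best$aic, min(aics))
  expect_false(any(aics < best$aic))
  # tie broken toward lower model id
  f1 <- fits[[3]]; f2 <- fits[[5]]
  f2$aic <- f1$aic
  expect_equal(select_best_model(list(f2, f1))$model_id, 3)
  # single non-failed candidate wins by default
  failed <- fits[[1]]; failed$failed <- TRUE
  expect_equal(select_best_model(list(failed, fits[[2]]))$model_id, 2)
  expect_null(select_best_model(list(failed)))
})

test_that("seasonal models fail gracefully without temporal spread", {
  # all observations on one calendar day of consecutive years is fine, but a
  # single date gives constant seasonal covariates -> rank-deficient
  p <- make_paired(n = 30, seed = 6, sigma = 0.2)
  p$dtime <- p$dtime[1]
  f <- fit_rating_model(p, compute_centers(p), 4)
  expect_true(f$failed)
})

test_that("retransformation correction is exp(s2/2) and switches off at s2=0", {
  expect_equal(bias_correction_factor(0), 1)
  expect_equal(bias_correction_factor(0.5), exp(0.25))
  sim <- simulate_observations(1, c(8, 0.8), sigma = 0, n_days = 400,
                               n_samples = 30, seed = 7)
  p <- pair_same_day(sim$flow, sim$samples)
  rc <- rating_curve(p, models = 1)
  pred <- predict(rc, sim$flow)
  # s2 = 0: prediction is exactly exp(linear predictor) at observed days
  ix <- match(p$date, pred$date)
  expect_equal(pred$load[ix], p$load, tolerance = 1e-8)
})

test_that("lognormal mean is recovered within 2% by the corrected estimator", {
  # Monte-Carlo oracle: true mean of exp(a0 + eps), eps ~ N(0, s^2),
  # is exp(a0 + s^2/2) in closed form.
  sigma <- 0.6
  a0 <- 5
  est <- withr::with_seed(42, {
    replicate(10, {
      y <- a0 + rnorm(500, 0, sigma)
      p <- data.frame(date = as.Date("2000-01-01") + seq_len(500) * 3,
                      flow = exp(rnorm(500, 0, 0.5)), load = exp(y))
      p$concentration <- p$load / 86400
      p$dtime <- decimal_time(p$date)
      f <- fit_rating_model(p, compute_centers(p), 1)
      unname(exp(f$coefficients[1]) * bias_correction_factor(f$s2))
    })
  })
  # each replicate fits n = 500 draws; the replicate mean pins the bias down
  expect_equal(mean(est), exp(a0 + sigma^2 / 2), tolerance = 0.02)
})

test_that("R-square is invariant to rescaling flow units", {
  p <- make_paired(n = 50, seed = 8, sigma = 0.4)
  rc1 <- rating_curve(p)
  p2 <- p
  p2$flow <- p$flow / 0.0283168   # report the same flows in cfs
  rc2 <- rating_curve(p2)
  expect_equal(rc2$fit$r_square_pct, rc1$fit$r_square_pct, tolerance = 1e-8)
  expect_equal(rc2$fit$model_id, rc1$fit$model_id)
})

test_that("rating_curve methods are coherent", {
  p <- make_paired(n = 40, seed = 9, sigma = 0.3)
  rc <- rating_curve(p)
  expect_s3_class(rc, "rating_curve")
  expect_output(print(rc), "AIC-selected")
  expect_equal(AIC(rc), rc$fit$aic)
  expect_equal(as.numeric(logLik(rc)), rc$fit$log_likelihood)
  expect_equal(length(residuals(rc)), nrow(p))
  expect_equal(residuals(rc), log(p$load) - fitted(rc))
  cf <- coef(rc, all_terms = TRUE)
  expect_length(cf, 7)
  s <- summary(rc)
  expect_equal(nrow(s$candidates), 9)
  sims <- simulate(rc, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(p), 2))
  expect_error(rating_curve(p[1:5, ]), "at least 12")
})

test_that("station load summary converts units correctly", {
  daily <- data.frame(date = as.Date("2001-01-01") + 0:9,
                      load = rep(1000, 10))
  fit <- list(model_id = 1L, r_square_pct = 95)
  sl <- summarize_station_load(daily, 20, c(2001, 2001), fit, "X")
  expect_equal(sl$mean_daily_load, 1000)
  expect_equal(sl$annual_load, 365.25)  # kgC/yr from 1000 gC/day
  one <- summarize_station_load(daily[1, ], 20, c(2001, 2001), fit)
  expect_equal(one$mean_daily_load, 1000)
})
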