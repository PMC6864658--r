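test_that("count-to-mass retrieval and its inverse", {
  expect_equal(count_to_mass(0), 0.518)
  expect_equal(count_to_mass(1000), 3.258)
  x <- c(0, 10, 5000, 123456)
  expect_equal(mass_to_count(count_to_mass(x)), x)
  expect_error(count_to_mass(-1), ">= 0")
  expect_error(retrieval_coefficients(slope = 0), "> 0")
})

test_that("network mean averages reporting sensors above the threshold", {
  h <- rbind(make_hourly(rep(8, 5), "A"), make_hourly(rep(12, 5), "B"))
  nm <- network_mean(h, min_sensors = 2)
  expect_equal(nm$pm25, rep(10, 5))

  # an hour below threshold is excluded
  h$pm25[h$sensor_id == "B" & h$hour_start == h$hour_start[3]] <- NA
  nm <- network_mean(h, min_sensors = 2)
  expect_equal(nrow(nm), 4L)

  expect_error(network_mean(make_hourly(rep(NA_real_, 3)), min_sensors = 1),
               "insufficient data")
})

test_that("sensor-vs-mean regression reproduces hand-computed OLS", {
  mean_series <- make_hourly(rep(c(2, 4, 6), 10))
  sensor <- make_hourly(rep(c(3, 5, 7), 10))
  f <- fit_sensor_vs_mean(sensor, mean_series, min_hours = 10)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  expect_equal(f$rmse, 1)   # raw differences, not regression residuals
  expect_equal(f$n_hours, 30L)

  ident <- fit_sensor_vs_mean(mean_series, mean_series, min_hours = 10)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$rmse, 0)

  flat <- make_hourly(rep(5, 30))
  expect_error(fit_sensor_vs_mean(sensor, flat), "zero variance")
})

test_that("correction factors average pre and post, with pre-only fallback", {
  mk <- function(slope, intercept, valid = TRUE)
    structure(list(sensor_id = "X", slope = slope, intercept = intercept,
                   valid = valid), class = "sensor_fit")
  cf <- derive_correction(mk(0.91, 0.03), mk(0.96, -0.19))
  expect_equal(round(cf$slope, 2), 0.94)
  expect_equal(round(cf$intercept, 2), -0.08)
  expect_identical(cf$source, "averaged")

  cf <- derive_correction(mk(0.80, 2.64), mk(0.87, 1.37))
  expect_equal(cf$slope, 0.835)
  expect_equal(cf$intercept, 2.005)

  cf <- derive_correction(mk(1.0, 0), NULL)
  expect_identical(cf$source, "pre_only")
  expect_equal(cf$slope, 1)

  # invalid post falls back to pre
  cf <- derive_correction(mk(1.1, 0.5), mk(1.3, 0.1, valid = FALSE))
  expect_identical(cf$source, "pre_only")
  expect_equal(cf$slope, 1.1)

  expect_error(derive_correction(mk(1, 0, valid = FALSE)), "valid pre")
})

test_that("applying a correction inverts the fitted linear map", {
  cf <- list(slope = 1, intercept = 0)
  expect_equal(as.numeric(apply_correction(10, cf)), 10)
  cf <- list(slope = 0.94, intercept = -0.08)
  expect_equal(as.numeric(apply_correction(10, cf)), (10 + 0.08) / 0.94)
  expect_equal(as.numeric(apply_correction(10, cf)), 10.723, tolerance = 1e-3)
  expect_error(apply_correction(10, list(slope = -1, intercept = 0)), "> 0")
  # missing propagates, negatives retained and flagged
  out <- apply_correction(c(NA, -5), list(slope = 1, intercept = 0))
  expect_true(is.na(out[1]) && out[2] == -5)
  expect_equal(attr(out, "n_negative"), 1L)
})

test_that("fit-then-correct recovers an affine-transformed series exactly", {
  set.seed(11)
  x <- runif(200, 3, 40)
  mean_series <- make_hourly(x)
  for (ab in list(c(1.3, -2), c(0.8, 1.5), c(1, 0))) {
    sensor <- make_hourly(ab[1] * x + ab[2])
    f <- fit_sensor_vs_mean(sensor, mean_series)
    cf <- derive_correction(f)
    expect_equal(as.numeric(apply_correction(sensor$pm25, cf)), x,
                 tolerance = 1e-10)
  }
})

test_that("R2 is invariant under correction but RMSE is not", {
  set.seed(12)
  x <- runif(300, 3, 40)
  raw <- 1.25 * x + 1.1 + rnorm(300, 0, 1)
  mean_series <- make_hourly(x)
  f <- fit_sensor_vs_mean(make_hourly(raw), mean_series)
  cf <- derive_correction(f)
  corrected <- as.numeric(apply_correction(raw, cf))
  expect_equal(cor(raw, x)^2, cor(corrected, x)^2, tolerance = 1e-12)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(corrected, x), rmse(raw, x))
})

test_that("calibrating a simulated collocation reduces inter-sensor RMSE", {
  camp <- simulate_campaign(test_config(), seed = 5, resolution = "hour")
  h <- camp$hourly
  coll <- h[h$phase %in% c("pre", "post"), ]
  cal <- calibrate_sensors(coll[, c("sensor_id", "hour_start", "pm25")],
                           camp$config$periods[c("pre", "post")])
  expect_s3_class(cal, "sensor_calibration")
  expect_equal(nrow(cal$corrections), camp$config$n_sensors)

  # corrected pairwise RMSE strictly decreases (injected biases nonzero)
  pair <- c("S01", "S02")
  a <- coll[coll$sensor_id == pair[1], ]
  b <- coll[coll$sensor_id == pair[2], ]
  al <- align_pairwise(a, b)
  raw_rmse <- sqrt(mean((al$x - al$y)^2))
  a$pm25 <- predict(cal, a); b$pm25 <- predict(cal, b)
  al <- align_pairwise(a, b)
  cor_rmse <- sqrt(mean((al$x - al$y)^2))
  expect_lt(cor_rmse, raw_rmse)

  # coef/predict method contract
  cm <- coef(cal)
  expect_identical(colnames(cm), c("slope", "intercept"))
  expect_equal(predict(cal, data.frame(sensor_id = "S01", pm25 = 10)),
               (10 - cm["S01", "intercept"]) / cm["S01", "slope"])
})

test_that("coefficient of variation follows the SD/mean convention", {
  h <- rbind(make_hourly(rep(8, 6), "A"), make_hourly(rep(12, 6), "B"))
  cv <- hourly_cv(h)
  expect_equal(cv$mean, sd(c(8, 12)) / 10, tolerance = 1e-12)
  expect_equal(cv$sd, 0)

  ident <- rbind(make_hourly(rep(9, 6), "A"), make_hourly(rep(9, 6), "B"))
  expect_equal(hourly_cv(ident)$mean, 0)
})

test_that("drift at fixed levels reproduces hand-computed changes", {
  mk <- function(slope, intercept)
    structure(list(slope = slope, intercept = intercept, valid = TRUE),
              class = "sensor_fit")
  # identical fits: no drift at any level
  d <- drift_table(mk(1.1, -0.5), mk(1.1, -0.5))
  expect_true(all(d$change_abs == 0) && all(d$change_pct == 0))

  d <- drift_table(mk(0.91, 0.03), mk(0.96, -0.19))
  at50 <- d[d$level == 50, ]
  expect_equal(at50$reading_pre, 45.53)
  expect_equal(at50$reading_post, 47.81)
  expect_equal(at50$change_abs, 2.28)
  expect_equal(at50$change_pct, 100 * 2.28 / 45.53, tolerance = 1e-6)

  d <- drift_table(mk(1.55, -1.17), mk(1.73, -0.51))
  at5 <- d[d$level == 5, ]
  expect_equal(at5$reading_pre, 6.58)
  expect_equal(at5$reading_post, 8.14)
  expect_equal(at5$change_pct, 100 * 1.56 / 6.58, tolerance = 1e-6)

  # alternative denominator: percentage of the nominal level
  d2 <- drift_table(mk(1.55, -1.17), mk(1.73, -0.51), denominator = "level")
  expect_equal(d2$change_pct[d2$level == 5], 100 * 1.56 / 5, tolerance = 1e-6)
})
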