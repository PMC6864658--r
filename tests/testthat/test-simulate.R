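test_that("the same seed reproduces the campaign exactly", {
  a <- simulate_campaign(test_config(), seed = 9, resolution = "hour")
  b <- simulate_campaign(test_config(), seed = 9, resolution = "hour")
  expect_identical(a$hourly, b$hourly)
  expect_identical(a$truth$field, b$truth$field)
  expect_identical(a$ei_grid, b$ei_grid)
  expect_identical(a$bam, b$bam)
  d <- simulate_campaign(test_config(), seed = 10, resolution = "hour")
  expect_false(identical(a$truth$field, d$truth$field))
})

test_that("the truth field peaks at night at every site", {
  camp <- default_campaign(seed = 1, resolution = "hour")
  hrs <- camp$truth$hour_start
  lt <- as.POSIXlt(hrs, tz = camp$config$tz)
  dep <- camp$config$periods$deployment
  in_dep <- hrs >= dep[1] & hrs < dep[2]
  night <- in_dep & (lt$hour >= 22 | lt$hour <= 4)
  afternoon <- in_dep & lt$hour >= 12 & lt$hour <= 16
  nf <- colMeans(camp$truth$field[night, ])
  af <- colMeans(camp$truth$field[afternoon, ])
  expect_true(all(nf > af))
  expect_true(all(camp$truth$field >= 0))
})

test_that("the growth factor follows the configured dew-point ramp", {
  cfg <- test_config(noise_sd = 0, missing_rate = 0)
  hours <- as.POSIXct(c("2016-12-01 00:00:00", "2016-12-01 01:00:00"),
                      tz = cfg$tz)
  met <- data.frame(hour_start = hours, dew_point_c = c(4, 14),
                    rh_pct = c(90, 95))
  obs <- sensor_forward_model(c(10, 10), hours, met,
                              list(slope = 1, intercept = 0), cfg,
                              resolution = "hour")
  expect_equal(obs$pm25, c(10, 30))   # growth 1.0 at onset, 3.0 at +10 C

  # noiseless identity: growth off, unit response
  cfg0 <- test_config(noise_sd = 0, missing_rate = 0, growth_slope = 0)
  obs0 <- sensor_forward_model(c(10, 10), hours, met,
                               list(slope = 1, intercept = 0), cfg0,
                               resolution = "hour")
  expect_equal(obs0$pm25, c(10, 10))
  expect_error(sensor_forward_model(c(10, 10), hours, met,
                                    list(slope = 0, intercept = 0), cfg0),
               "> 0")
})

test_that("minute records respect counts/mass linkage and missingness", {
  cfg <- test_config(missing_rate = 0.2)
  hours <- seq(as.POSIXct("2016-12-01 00:00:00", tz = cfg$tz),
               by = 3600, length.out = 100)
  met <- data.frame(hour_start = hours, dew_point_c = rep(5, 100),
                    rh_pct = rep(90, 100))
  set.seed(1)
  obs <- sensor_forward_model(runif(100, 5, 30), hours, met,
                              list(slope = 1.1, intercept = 0.3), cfg,
                              resolution = "minute")
  # counts are the exact retrieval inverse of the reported mass
  expect_equal(count_to_mass(obs$particle_count), obs$pm25,
               tolerance = 1e-12)
  expect_true(all(obs$pm25 >= 0) && all(obs$particle_count >= 0))
  expect_equal(nrow(obs) / (100 * 60), 0.8, tolerance = 0.03)
  expect_true(all(diff(as.numeric(obs$timestamp)) > 0))
})

test_that("every sensor accrues ample valid collocation hours", {
  camp <- default_campaign(seed = 1, resolution = "hour")
  h <- camp$hourly
  coll <- h[h$phase %in% c("pre", "post") & !is.na(h$pm25), ]
  per_sensor <- table(coll$sensor_id)
  expect_length(per_sensor, 19L)
  expect_true(all(per_sensor >= 100))
})

test_that("infinite correlation length collapses sites to one series", {
  cfg <- test_config(spatial_corr_length = Inf, spike_prob = 0,
                     site_effect_sd = 0, ej_effect = 0)
  truth <- local({set.seed(3); simulate_regional_pm(cfg)})
  expect_true(all(abs(truth$field - truth$field[, 1]) < 1e-9))
  expect_error(test_config(spatial_corr_length = 0), "positive")
})

test_that("noiseless reference limit gives near-perfect sensor-BAM R2", {
  cfg <- test_config(noise_sd = 0.01, growth_slope = 0,
                     bam_noise_fraction = 0, missing_rate = 0)
  camp <- simulate_campaign(cfg, seed = 6, resolution = "hour")
  dep <- camp$hourly[camp$hourly$phase == "deployment", ]
  sens <- dep[dep$site_id == "DPM" & dep$sensor_id == "S01", ]
  bam <- camp$bam[camp$bam$site_id == "DPM", ]
  al <- align_pairwise(sens, bam)
  expect_gt(cor(al$x, al$y)^2, 0.999)
})

test_that("null EJ construction keeps community group means close", {
  camp <- default_campaign(seed = 1, resolution = "hour")
  dep <- camp$hourly[camp$hourly$phase == "deployment" &
                       !is.na(camp$hourly$pm25), ]
  ej_sites <- camp$sites$site_id[camp$sites$ej_flag]
  ga <- dep$pm25[dep$site_id %in% ej_sites]
  gb <- dep$pm25[!dep$site_id %in% ej_sites]
  se <- sqrt(var(ga) / length(ga) + var(gb) / length(gb))
  # group means differ by a small multiple of the naive SE: the shared
  # regional baseline dominates the variance, so this is conservative
  expect_lt(abs(mean(ga) - mean(gb)), 4 * se)
})

test_that("emissions grid is nonnegative and exact at zero distortion", {
  camp <- simulate_campaign(test_config(ei_distortion = 0), seed = 7,
                            resolution = "hour")
  g <- camp$ei_grid
  expect_true(all(g$weekday_tons_per_day >= 0))
  expect_true(all(g$weekend_tons_per_day >= 0))
  expect_gte(nrow(g), 3L)

  # zero distortion: emissions are an exact affine map of the truth-field
  # cell increments, so regressing those increments on emissions is exact
  hours <- camp$truth$hour_start
  dep <- camp$config$periods$deployment
  sel <- hours >= dep[1] & hours < dep[2]
  dt <- day_type(hours[sel], tz = camp$config$tz)
  cx <- floor(camp$sites$x_km / 4); cy <- floor(camp$sites$y_km / 4)
  cid <- paste0("c", cx, "_", cy)
  for (d in c("weekday", "weekend")) {
    cm <- vapply(g$cell_id, function(cc) {
      mean(camp$truth$field[sel, camp$sites$site_id[cid == cc],
                            drop = FALSE][dt == d, ])
    }, numeric(1))
    inc <- cm - min(cm)
    r2 <- summary(lm(inc ~ g[[paste0(d, "_tons_per_day")]]))$r.squared
    expect_equal(r2, 1, tolerance = 1e-9)
  }
})

test_that("default-construction EI linkage is strong but imperfect", {
  # average measured-increment vs inventory R2 over a few replicates
  r2s <- c()
  for (s in 1:5) {
    camp <- default_campaign(seed = s, resolution = "hour")
    cd <- corrected_deployment(camp)
    cm <- assign_sites_to_cells(camp$sites, camp$ei_grid)
    names(cm) <- camp$sites$site_id
    inc <- cell_average(cd$deployment, cm, tz = camp$config$tz)
    reg <- regress_increment_vs_ei(inc, camp$ei_grid)
    r2s <- c(r2s, reg$weekday$r2, reg$weekend$r2)
  }
  expect_gt(mean(r2s), 0.4)
  expect_lt(mean(r2s), 0.9)
})

test_that("generated series satisfy the core data-model invariants", {
  camp <- simulate_campaign(test_config(), seed = 8, resolution = "minute")
  m <- camp$minutes
  expect_true(all(m$pm25 >= 0))
  expect_true(all(m$particle_count >= 0))
  for (s in unique(m$sensor_id)[1:3]) {
    ts <- m$timestamp[m$sensor_id == s]
    expect_true(all(diff(as.numeric(ts)) > 0))
  }
  h <- camp$hourly
  expect_true(all(is.na(h$pm25) | h$n_minutes >= 45))
  expect_true(all(h$n_minutes >= 0 & h$n_minutes <= 60))
  p <- camp$sensor_params
  expect_true(all(p$slope >= camp$config$sensor_slope_range[1] &
                    p$slope <= camp$config$sensor_slope_range[2]))
})
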