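#' Default site layout for a synthetic campaign
#'
#' Fifteen sites clustered into six communities (three flagged as
#' environmental-justice communities) inside a roughly 14 x 16 km urban
#' domain, two of them hosting reference monitors (role
#' \code{"reference-collocated"}). Coordinates are given both as local
#' projected km (used by the truth field and the emissions grid) and as
#' lat/lon.
#'
#' @return data.frame with \code{site_id}, \code{name}, \code{community},
#'   \code{ej_flag}, \code{x_km}, \code{y_km}, \code{lat}, \code{lon},
#'   \code{role}.
#' @export
default_site_layout <- function() {
  df <- data.frame(
    site_id = c("CRV", "SOC", "DAR", "ALD", "DPM", "WYM", "RTS", "TT3",
                "A24", "HEN", "HER", "TRI", "A13", "S64", "S79"),
    name = c("Coroval", "Socorro", "Darwin", "Alder", "Del Paso Manor",
             "Wyman", "Riverside T St", "T St Tier 3", "24th Ave",
             "Henrietta", "Hermosa", "Tristan", "13th Ave", "64th St",
             "79th St"),
    community = c("South Natomas", "South Natomas", "Arden", "Del Paso",
                  "Del Paso", "Del Paso", "T St", "T St",
                  "South Sacramento", "South Sacramento",
                  "South Sacramento", "South Sacramento", "Tahoe Park",
                  "Tahoe Park", "Tahoe Park"),
    ej_flag = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    x_km = c(1.2, 3.4, 7.8, 11.6, 11.0, 11.5, 5.8, 4.9,
             7.2, 9.0, 10.2, 11.0, 9.6, 10.6, 11.8),
    y_km = c(8.0, 8.8, 11.2, 13.6, 13.0, 12.0, 5.0, 4.6,
             4.0, 0.8, 2.0, 1.2, 5.6, 5.0, 4.6),
    role = c("community", "community", "community", "community",
             "reference-collocated", "community", "reference-collocated",
             "community", "community", "community", "community",
             "community", "community", "community", "community"),
    stringsAsFactors = FALSE
  )
  lat0 <- 38.45; lon0 <- -121.55
  df$lat <- lat0 + df$y_km / 110.574
  df$lon <- lon0 + df$x_km / (111.320 * cos(df$lat * pi / 180))
  df
}

#' Default study periods
#'
#' Three phases: a 7-day pre-study collocation, a 2-month deployment and a
#' 32-day post-study collocation, with short gaps between phases.
#'
#' @param tz local time zone.
#' @return named list of \code{c(start, end)} POSIXct windows (half-open).
#' @export
default_study_periods <- function(tz = .default_tz) {
  w <- function(a, b) as.POSIXct(c(a, b), tz = tz)
  list(pre = w("2016-11-10", "2016-11-17"),
       deployment = w("2016-12-01", "2017-02-01"),
       post = w("2017-02-04", "2017-03-08"))
}

#' Configuration for the synthetic sensor-network generator
#'
#' Defaults describe the emulated campaign: 19 sensors over 15 sites in six
#' communities, per-sensor linear biases spanning the observed collocation
#' range (slopes 0.78-1.64, intercepts -3.2 to 2.6 ug/m3), hourly sensor
#' noise of 1 ug/m3, a dew-point-driven hygroscopic growth bias switching on
#' at 4 degrees C and reaching a factor of 3 at 14 degrees C, multiplicative
#' reference-monitor noise of 22 percent (SD half that), a diurnal cycle
#' rising from 16:00 to a nocturnal peak, exponentially distance-correlated
#' site noise, nocturnal spike events, and random missing minutes.
#'
#' @param n_sensors number of sensors.
#' @param sites site layout data.frame (see [default_site_layout()]).
#' @param periods study periods (see [default_study_periods()]).
#' @param tz local time zone.
#' @param sensor_slope_range,sensor_intercept_range uniform ranges the
#'   per-sensor biases are drawn from.
#' @param noise_sd SD (ug/m3) of the noise added to each observation.
#' @param growth_model \code{"dewpoint_linear"} (default) or
#'   \code{"rh_power"}.
#' @param growth_onset_dewpoint dew point (degrees C) where optical growth
#'   bias begins.
#' @param growth_slope growth factor increase per degree C of dew point
#'   above onset; 0 disables the bias.
#' @param rh_growth_coef,rh_growth_power parameters of the alternative
#'   RH-power-law growth \code{1 + coef * (RH/100)^power}.
#' @param bam_noise_fraction relative precision of the hourly reference
#'   monitor; its multiplicative noise SD is half this value.
#' @param frm_noise_sd additive SD (ug/m3) of the daily filter reference.
#' @param evening_rise_hour local hour when concentrations start rising.
#' @param spike_prob per site-hour probability of a nocturnal spike.
#' @param spike_mean mean spike magnitude (ug/m3, exponential).
#' @param spatial_corr_length e-folding length (km) of inter-site
#'   correlation of the log-scale site noise; \code{Inf} makes sites share
#'   one noise series.
#' @param spatial_noise_sd log-scale SD of the transient site noise.
#' @param site_effect_sd log-scale SD of the persistent per-site
#'   source-strength factor (drawn once per campaign, independent across
#'   sites); gives grid cells genuinely different long-run means for the
#'   emissions-inventory linkage while staying small enough that community
#'   group means remain exchangeable under \code{ej_effect = 0}.
#' @param baseline_median median (ug/m3) of the regional baseline.
#' @param daily_log_sd,daily_log_ar,hourly_log_sd,hourly_log_ar AR(1)
#'   parameters of the day-scale and hour-scale log-baseline processes.
#' @param ej_effect additive mean shift (ug/m3) applied to
#'   environmental-justice sites (0 = null construction).
#' @param missing_rate fraction of minute records dropped at random.
#' @param ei_distortion relative SD of the distortion applied when deriving
#'   emissions-inventory values from the truth field.
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_sensors = 19L,
                             sites = default_site_layout(),
                             periods = default_study_periods(tz),
                             tz = .default_tz,
                             sensor_slope_range = c(0.78, 1.64),
                             sensor_intercept_range = c(-3.2, 2.6),
                             noise_sd = 1.0,
                             growth_model = c("dewpoint_linear", "rh_power"),
                             growth_onset_dewpoint = 4,
                             growth_slope = 0.2,
                             rh_growth_coef = 1.2,
                             rh_growth_power = 4,
                             bam_noise_fraction = 0.22,
                             frm_noise_sd = 0.3,
                             evening_rise_hour = 16L,
                             spike_prob = 0.05,
                             spike_mean = 8,
                             spatial_corr_length = 8,
                             spatial_noise_sd = 0.15,
                             site_effect_sd = 0.025,
                             baseline_median = 9,
                             daily_log_sd = 0.4,
                             daily_log_ar = 0.6,
                             hourly_log_sd = 0.1,
                             hourly_log_ar = 0.95,
                             ej_effect = 0,
                             missing_rate = 0.05,
                             ei_distortion = 0.4) {
  growth_model <- match.arg(growth_model)
  stopifnot(length(sensor_slope_range) == 2L,
            all(sensor_slope_range > 0),
            missing_rate >= 0, missing_rate < 1,
            bam_noise_fraction >= 0,
            noise_sd >= 0)
  if (spatial_corr_length <= 0)
    stop("spatial correlation length must be positive (use Inf for a ",
         "single shared noise series)")
  starts <- vapply(periods, function(p) as.numeric(p[1]), numeric(1))
  ends <- vapply(periods, function(p) as.numeric(p[2]), numeric(1))
  o <- order(starts)
  if (any(ends[o][-length(o)] > starts[o][-1L]))
    stop("study periods must be ordered and non-overlapping")
  cfg <- list(n_sensors = as.integer(n_sensors), sites = sites,
              periods = periods, tz = tz,
              sensor_slope_range = sensor_slope_range,
              sensor_intercept_range = sensor_intercept_range,
              noise_sd = noise_sd, growth_model = growth_model,
              growth_onset_dewpoint = growth_onset_dewpoint,
              growth_slope = growth_slope,
              rh_growth_coef = rh_growth_coef,
              rh_growth_power = rh_growth_power,
              bam_noise_fraction = bam_noise_fraction,
              frm_noise_sd = frm_noise_sd,
              evening_rise_hour = as.integer(evening_rise_hour),
              spike_prob = spike_prob, spike_mean = spike_mean,
              spatial_corr_length = spatial_corr_length,
              spatial_noise_sd = spatial_noise_sd,
              site_effect_sd = site_effect_sd,
              baseline_median = baseline_median,
              daily_log_sd = daily_log_sd, daily_log_ar = daily_log_ar,
              hourly_log_sd = hourly_log_sd, hourly_log_ar = hourly_log_ar,
              ej_effect = ej_effect, missing_rate = missing_rate,
              ei_distortion = ei_distortion)
  structure(cfg, class = "generator_config")
}

# AR(1) series with stationary-ish start, via recursive filter.
.ar1 <- function(n, phi, sd) {
  as.numeric(stats::filter(rnorm(n, 0, sd), phi, method = "recursive"))
}

#' Simulate hourly winter meteorology
#'
#' Smooth seasonal and diurnal harmonics plus AR(1) noise: cool humid
#' winter conditions with high nocturnal relative humidity (most night
#' hours above 85 percent), a mid-afternoon temperature peak, light winds.
#' Dew point and vapor pressure are derived via [enrich_met()].
#'
#' @param hours POSIXct vector of hour starts.
#' @param tz local time zone.
#' @return meteorology data.frame (\code{hour_start}, \code{temp_c},
#'   \code{rh_pct}, \code{ws_ms}, \code{wd_deg}, \code{vp_hpa},
#'   \code{dew_point_c}).
#' @export
simulate_met <- function(hours, tz = .default_tz) {
  n <- length(hours)
  lt <- as.POSIXlt(hours, tz = tz)
  h <- lt$hour
  doy <- lt$yday + 1
  seasonal <- 9 + 2 * sin(2 * pi * (doy - 60) / 365)
  diurnal <- 4 * sin(2 * pi * (h - 9) / 24)
  temp <- seasonal + diurnal + .ar1(n, 0.8, 0.8)
  daylight <- pmax(0, sin(pi * (h - 7) / 11))
  rh <- 96 - 16 * daylight + .ar1(n, 0.7, 3)
  rh <- pmin(100, pmax(35, rh))
  ws <- pmax(0.1, 0.3 + 0.8 * abs(.ar1(n, 0.85, 1)))
  wd <- (230 + cumsum(rnorm(n, 0, 25))) %% 360
  enrich_met(data.frame(hour_start = hours, temp_c = temp, rh_pct = rh,
                        ws_ms = ws, wd_deg = wd))
}

# Diurnal concentration factor: afternoon minimum, rise starting at the
# configured evening hour, nocturnal peak near 22:00-02:00.
.diurnal_factor <- function(hour, evening_rise_hour = 16L) {
  e <- evening_rise_hour
  stopifnot(e > 12, e + 3 < 22)
  x <- c(0, 4, 7, 10, 12, e, e + 3, 22, 24)
  y <- c(1.70, 1.50, 1.00, 0.70, 0.58, 0.55, 1.30, 1.85, 1.70)
  stats::approx(x, y, xout = hour, rule = 2)$y
}

#' Simulate the regional PM2.5 truth field
#'
#' Nonnegative site-by-hour field: a shared regional log-normal baseline
#' (day-scale and hour-scale AR(1) processes) times a diurnal factor
#' (afternoon minimum, evening rise, nocturnal peak), times site-level
#' log-normal noise with exponential spatial correlation over distance,
#' plus site-specific nocturnal spike events, plus the configured additive
#' EJ-community shift.
#'
#' @param config a [generator_config()].
#' @param hours POSIXct hour starts; defaults to all hours of all
#'   configured periods.
#' @return list with \code{hour_start}, \code{sites} and \code{field}
#'   (hours x sites matrix, ug/m3).
#' @export
simulate_regional_pm <- function(config, hours = NULL) {
  if (is.null(hours)) hours <- campaign_hours(config)
  n <- length(hours)
  sites <- config$sites
  k <- nrow(sites)
  lt <- as.POSIXlt(hours, tz = config$tz)
  h <- lt$hour
  day_id <- as.integer(factor(format(lt, "%Y-%m-%d")))

  u_d <- .ar1(max(day_id), config$daily_log_ar, config$daily_log_sd)
  v_h <- .ar1(n, config$hourly_log_ar, config$hourly_log_sd)
  baseline <- config$baseline_median * exp(u_d[day_id] + v_h)
  diurnal <- .diurnal_factor(h, config$evening_rise_hour)

  # spatially correlated log-scale site noise, iid over hours
  sdl <- config$spatial_noise_sd
  if (is.infinite(config$spatial_corr_length)) {
    eps <- matrix(rnorm(n, 0, sdl), n, k)
  } else {
    d <- as.matrix(dist(sites[, c("x_km", "y_km")]))
    sigma <- sdl^2 * exp(-d / config$spatial_corr_length)
    ch <- chol(sigma + diag(1e-10, k))
    eps <- matrix(rnorm(n * k), n, k) %*% ch
  }
  site_noise <- exp(eps - sdl^2 / 2)

  # persistent per-site source strength (mean-one log-normal, iid)
  se <- config$site_effect_sd
  site_effect <- exp(rnorm(k, 0, se) - se^2 / 2)

  night <- h >= 20 | h <= 4
  spikes <- matrix(0, n, k)
  if (config$spike_prob > 0) {
    hit <- matrix(runif(n * k) < config$spike_prob, n, k) & night
    spikes[hit] <- rexp(sum(hit), rate = 1 / config$spike_mean)
  }

  field <- baseline * diurnal * site_noise *
    matrix(site_effect, n, k, byrow = TRUE) + spikes
  if (config$ej_effect != 0)
    field[, sites$ej_flag] <- field[, sites$ej_flag] + config$ej_effect
  field <- pmax(field, 0)
  colnames(field) <- sites$site_id
  list(hour_start = hours, sites = sites, field = field,
       site_effect = setNames(site_effect, sites$site_id))
}

#' All hours of the configured study periods
#' @param config a [generator_config()].
#' @return POSIXct vector of hour starts across all phases.
#' @export
campaign_hours <- function(config) {
  do.call(c, lapply(unname(config$periods), function(p)
    seq(p[1], p[2] - 3600, by = 3600)))
}

# Optical growth factor from humidity: hygroscopic particle growth inflates
# the optical mass estimate once the air is moist enough.
.growth_factor <- function(config, met) {
  if (config$growth_model == "dewpoint_linear") {
    1 + config$growth_slope *
      pmax(0, met$dew_point_c - config$growth_onset_dewpoint)
  } else {
    1 + config$rh_growth_coef * (met$rh_pct / 100)^config$rh_growth_power
  }
}

#' Forward-model sensor observations from a truth series
#'
#' The aerosol the optical sensor sees is the true concentration inflated
#' by the humidity growth factor (shared by all sensors); the sensor then
#' applies its own linear response: \code{m = slope * (g * true) +
#' intercept + noise}, floored at zero. Particle counts are emitted as the
#' inverse of the count-to-mass retrieval, floored at zero. Minutes are
#' dropped independently at the configured missing rate.
#'
#' @param true_pm numeric vector of true hourly concentrations (ug/m3).
#' @param hours POSIXct hour starts matching \code{true_pm}.
#' @param met meteorology rows matching \code{hours} (needs
#'   \code{dew_point_c} or \code{rh_pct} depending on the growth model).
#' @param params list or vector with \code{slope} (> 0) and
#'   \code{intercept}.
#' @param config a [generator_config()].
#' @param sensor_id identifier stamped on the records.
#' @param resolution \code{"minute"} (emit one-minute records) or
#'   \code{"hour"} (emit hourly records directly, with a simulated
#'   valid-minute count).
#' @return minute resolution: data.frame \code{sensor_id}, \code{timestamp},
#'   \code{particle_count}, \code{pm25}. Hour resolution: data.frame
#'   \code{sensor_id}, \code{hour_start}, \code{pm25}, \code{n_minutes}
#'   (pm25 NA below 45 valid minutes).
#' @export
sensor_forward_model <- function(true_pm, hours, met, params, config,
                                 sensor_id = "S01",
                                 resolution = c("minute", "hour")) {
  resolution <- match.arg(resolution)
  slope <- params[["slope"]]; intercept <- params[["intercept"]]
  if (slope <= 0) stop("sensor slope must be > 0")
  stopifnot(length(true_pm) == length(hours), nrow(met) == length(hours))
  g <- .growth_factor(config, met)
  aerosol <- g * true_pm
  coeffs <- retrieval_coefficients()
  if (resolution == "minute") {
    n <- length(hours)
    ts <- rep(hours, each = 60L) + rep(0:59 * 60, times = n)
    m <- slope * rep(aerosol, each = 60L) + intercept +
      rnorm(n * 60L, 0, config$noise_sd)
    m <- pmax(0, m)
    keep <- runif(n * 60L) >= config$missing_rate
    data.frame(sensor_id = sensor_id, timestamp = ts[keep],
               particle_count = pmax(0, mass_to_count(m[keep], coeffs)),
               pm25 = m[keep], stringsAsFactors = FALSE)
  } else {
    n <- length(hours)
    n_minutes <- rbinom(n, 60L, 1 - config$missing_rate)
    m <- pmax(0, slope * aerosol + intercept +
                rnorm(n, 0, config$noise_sd))
    data.frame(sensor_id = sensor_id, hour_start = hours,
               pm25 = ifelse(n_minutes >= 45L, m, NA_real_),
               n_minutes = n_minutes, stringsAsFactors = FALSE)
  }
}

#' Simulate a full synthetic sensor-network campaign
#'
#' Generates meteorology, the truth field, per-sensor biases, the phase
#' assignments (pre/post: all sensors collocated at the first reference
#' site; deployment: three sensors at each of the two reference sites and
#' one at every other community site), sensor observations, hourly
#' reference-monitor (multiplicative-noise) and daily filter-sampler
#' (near-truth) series at the reference sites, and a derived emissions
#' grid. The same seed reproduces the campaign exactly.
#'
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @param resolution \code{"minute"} (emit minute records and aggregate
#'   them) or \code{"hour"} (emit hourly records directly; faster, used for
#'   replicated experiments).
#' @return object of class \code{pm_campaign}: list with \code{config},
#'   \code{seed}, \code{sites}, \code{met}, \code{truth} (hour_start +
#'   field), \code{sensor_params}, \code{assignments} (sensor x phase x
#'   site), \code{minutes} (minute resolution only), \code{hourly} (long,
#'   with phase and site columns), \code{bam}, \code{frm} and
#'   \code{ei_grid}.
#' @export
simulate_campaign <- function(config = generator_config(), seed = 1L,
                              resolution = c("minute", "hour")) {
  resolution <- match.arg(resolution)
  set.seed(seed)
  sites <- config$sites
  refs <- sites$site_id[sites$role == "reference-collocated"]
  if (length(refs) < 2L) stop("site layout needs two reference sites")
  community <- setdiff(sites$site_id, refs[1:2])
  need <- 6L + length(sites$site_id) - 2L
  if (config$n_sensors < need)
    stop("too few sensors to collocate 3 at each reference site and ",
         "cover every community site (need ", need, ")")

  hours <- campaign_hours(config)
  met <- simulate_met(hours, config$tz)
  truth <- simulate_regional_pm(config, hours)

  ids <- sprintf("S%02d", seq_len(config$n_sensors))
  params <- data.frame(
    sensor_id = ids,
    slope = runif(config$n_sensors, config$sensor_slope_range[1],
                  config$sensor_slope_range[2]),
    intercept = runif(config$n_sensors, config$sensor_intercept_range[1],
                      config$sensor_intercept_range[2]),
    stringsAsFactors = FALSE)

  deployment_site <- c(rep(refs[1L], 3L), rep(refs[2L], 3L),
                       community,
                       rep(refs[1L], max(0L, config$n_sensors - need)))
  assignments <- rbind(
    data.frame(phase = "pre", sensor_id = ids, site_id = refs[1L]),
    data.frame(phase = "deployment", sensor_id = ids,
               site_id = deployment_site[seq_along(ids)]),
    data.frame(phase = "post", sensor_id = ids, site_id = refs[1L]))

  phase_of <- rep(NA_character_, length(hours))
  for (p in names(config$periods)) {
    w <- config$periods[[p]]
    phase_of[hours >= w[1] & hours < w[2]] <- p
  }

  obs <- list()
  for (i in seq_along(ids)) {
    for (p in names(config$periods)) {
      sel <- phase_of == p
      site <- assignments$site_id[assignments$phase == p &
                                    assignments$sensor_id == ids[i]]
      rec <- sensor_forward_model(
        truth$field[sel, site], hours[sel], met[sel, , drop = FALSE],
        list(slope = params$slope[i], intercept = params$intercept[i]),
        config, sensor_id = ids[i], resolution = resolution)
      rec$phase <- p
      rec$site_id <- site
      obs[[paste(ids[i], p)]] <- rec
    }
  }
  obs <- do.call(rbind, obs)
  rownames(obs) <- NULL

  if (resolution == "minute") {
    minutes <- obs[, c("sensor_id", "timestamp", "particle_count", "pm25")]
    hourly <- aggregate_to_hours(minutes)
  } else {
    minutes <- NULL
    hourly <- obs[, c("sensor_id", "hour_start", "pm25", "n_minutes")]
  }
  hidx <- match(paste(hourly$sensor_id,
                      phase_of[match(hourly$hour_start, hours)]),
                paste(assignments$sensor_id, assignments$phase))
  hourly$phase <- assignments$phase[hidx]
  hourly$site_id <- assignments$site_id[hidx]

  bam <- do.call(rbind, lapply(refs[1:2], function(r) {
    v <- truth$field[, r] *
      (1 + rnorm(length(hours), 0, config$bam_noise_fraction / 2))
    data.frame(site_id = r, hour_start = hours, pm25 = pmax(0, v))
  }))
  frm <- do.call(rbind, lapply(refs[1:2], function(r) {
    d <- as.Date(hours, tz = config$tz)
    mu <- tapply(truth$field[, r], d, mean)
    full <- tapply(rep(1, length(d)), d, sum) == 24
    data.frame(site_id = r, date = as.Date(names(mu)),
               pm25 = pmax(0, as.numeric(mu) +
                             rnorm(length(mu), 0, config$frm_noise_sd)))[full, ]
  }))

  camp <- structure(list(
    config = config, seed = seed, resolution = resolution,
    sites = sites, met = met, truth = truth, sensor_params = params,
    assignments = assignments, minutes = minutes, hourly = hourly,
    bam = bam, frm = frm), class = "pm_campaign")
  camp$ei_grid <- simulate_ei_grid(camp)
  camp
}

#' @export
print.pm_campaign <- function(x, ...) {
  cat(sprintf(
    "synthetic campaign: %d sensors, %d sites, %d hours (%s resolution), seed %d\n",
    x$config$n_sensors, nrow(x$sites), length(x$truth$hour_start),
    x$resolution, x$seed))
  invisible(x)
}

#' Derive a synthetic gridded emissions inventory from the truth field
#'
#' Cells of \code{cell_size_km} tiling the site domain; per day type, each
#' cell's emissions are an affine function of the cell's long-run mean
#' truth-concentration increment above the lowest cell, distorted by
#' multiplicative noise of relative SD \code{distortion} (zero distortion
#' makes the increment-vs-emissions regression exact). Emissions are in
#' tons/day and never negative. Only cells containing sites are returned.
#'
#' @param campaign a \code{pm_campaign} (or list with \code{truth},
#'   \code{sites}, \code{config}).
#' @param cell_size_km cell edge length in km.
#' @param distortion relative SD of the distortion; defaults to the
#'   config's \code{ei_distortion}.
#' @return data.frame with \code{cell_id}, \code{min_x}, \code{min_y},
#'   \code{max_x}, \code{max_y}, \code{weekday_tons_per_day},
#'   \code{weekend_tons_per_day}.
#' @export
simulate_ei_grid <- function(campaign, cell_size_km = 4,
                             distortion = NULL) {
  config <- campaign$config
  if (is.null(distortion)) distortion <- config$ei_distortion
  sites <- campaign$sites
  cx <- floor(sites$x_km / cell_size_km)
  cy <- floor(sites$y_km / cell_size_km)
  cell_id <- paste0("c", cx, "_", cy)
  cells <- unique(data.frame(cell_id = cell_id,
                             min_x = cx * cell_size_km,
                             min_y = cy * cell_size_km,
                             max_x = (cx + 1) * cell_size_km,
                             max_y = (cy + 1) * cell_size_km,
                             stringsAsFactors = FALSE))

  hours <- campaign$truth$hour_start
  dep <- config$periods$deployment
  sel <- hours >= dep[1] & hours < dep[2]
  dt <- day_type(hours[sel], tz = config$tz)
  for (d in c("weekday", "weekend")) {
    cell_mean <- vapply(cells$cell_id, function(cid) {
      ss <- sites$site_id[cell_id == cid]
      mean(campaign$truth$field[sel, ss, drop = FALSE][dt == d, ])
    }, numeric(1))
    inc <- cell_mean - min(cell_mean)
    e <- 0.05 + 0.3 * inc * (1 + rnorm(length(inc), 0, distortion))
    cells[[paste0(d, "_tons_per_day")]] <- pmax(0.02, e)
  }
  rownames(cells) <- NULL
  cells
}
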