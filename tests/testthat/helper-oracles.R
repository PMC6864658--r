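# Independent brute-force oracles (loop-based, no shared code with the
# package implementations) and small data builders.

# COD by explicit loop over pairs
cod_oracle <- function(x, y) {
  total <- 0
  p <- 0
  for (i in seq_along(x)) {
    if (is.na(x[i]) || is.na(y[i])) next
    s <- x[i] + y[i]
    if (s == 0) next
    total <- total + ((x[i] - y[i]) / s)^2
    p <- p + 1
  }
  sqrt(total / p)
}

# Moran's I by explicit double loop, row-standardising the weights itself
morans_oracle <- function(values, weights) {
  n <- length(values)
  w <- matrix(0, n, n)
  for (i in 1:n) {
    rs <- sum(weights[i, -i])
    for (j in 1:n) if (i != j) w[i, j] <- weights[i, j] / rs
  }
  z <- values - mean(values)
  num <- 0
  s0 <- 0
  for (i in 1:n) for (j in 1:n) {
    num <- num + w[i, j] * z[i] * z[j]
    s0 <- s0 + w[i, j]
  }
  (n / s0) * num / sum(z^2)
}

# hourly records for one sensor: a POSIXct sequence with given values
make_hourly <- function(values, sensor_id = "S1",
                        start = "2016-12-01 00:00:00", tz = "Etc/GMT+8") {
  t0 <- as.POSIXct(start, tz = tz)
  data.frame(sensor_id = sensor_id,
             hour_start = t0 + 3600 * (seq_along(values) - 1),
             pm25 = values, stringsAsFactors = FALSE)
}

# minute records within one hour
make_minutes <- function(values, sensor_id = "S1",
                         start = "2016-12-01 05:00:00", tz = "Etc/GMT+8") {
  t0 <- as.POSIXct(start, tz = tz)
  data.frame(sensor_id = sensor_id,
             timestamp = t0 + 60 * (seq_along(values) - 1),
             pm25 = values, stringsAsFactors = FALSE)
}

# a reduced-length generator config for module tests (the statistical
# structure is unchanged; only the phase lengths shrink)
test_config <- function(...) {
  tz <- "Etc/GMT+8"
  w <- function(a, b) as.POSIXct(c(a, b), tz = tz)
  generator_config(
    periods = list(pre = w("2016-11-10", "2016-11-14"),
                   deployment = w("2016-12-01", "2016-12-15"),
                   post = w("2017-02-04", "2017-02-11")),
    ...)
}

# cache for default-config campaigns shared across test files
.camp_cache <- new.env(parent = emptyenv())
default_campaign <- function(seed = 1L, resolution = "hour") {
  key <- paste0(seed, "_", resolution)
  if (is.null(.camp_cache[[key]]))
    .camp_cache[[key]] <- simulate_campaign(generator_config(), seed = seed,
                                            resolution = resolution)
  .camp_cache[[key]]
}

# calibrate + correct the deployment period of a campaign
corrected_deployment <- function(camp) {
  h <- camp$hourly
  coll <- h[h$phase %in% c("pre", "post"), ]
  cal <- calibrate_sensors(coll[, c("sensor_id", "hour_start", "pm25")],
                           camp$config$periods[c("pre", "post")])
  dep <- h[h$phase == "deployment", ]
  dep$pm25 <- predict(cal, dep)
  list(calibration = cal, deployment = dep)
}

# one representative sensor series per site
site_series <- function(dep) {
  lapply(split(dep, dep$site_id), function(d) {
    d[d$sensor_id == sort(unique(d$sensor_id))[1L], ]
  })
}
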