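#' Count-to-mass retrieval coefficients
#'
#' The optical sensor reports raw particle counts in hundreds of particles
#' per cubic foot (hppcf); the manufacturer's default retrieval converts
#' counts to mass as \code{PM2.5 = 0.518 + 0.00274 * count}, assuming a fixed
#' size distribution and particle density.
#'
#' @param intercept retrieval intercept in ug/m3.
#' @param slope retrieval slope in ug/m3 per hppcf (> 0).
#' @return an object of class \code{retrieval_coefficients}.
#' @export
retrieval_coefficients <- function(intercept = 0.518, slope = 0.00274) {
  if (!is.numeric(slope) || slope <= 0) stop("retrieval slope must be > 0")
  structure(list(intercept = intercept, slope = slope),
            class = "retrieval_coefficients")
}

#' Convert particle counts to PM2.5 mass concentration
#'
#' @param count particle count in hppcf (>= 0).
#' @param coeffs [retrieval_coefficients()].
#' @return PM2.5 in ug/m3.
#' @export
count_to_mass <- function(count, coeffs = retrieval_coefficients()) {
  if (any(!is.na(count) & count < 0)) stop("particle counts must be >= 0")
  coeffs$intercept + coeffs$slope * count
}

#' Invert the count-to-mass retrieval
#'
#' @param mass PM2.5 in ug/m3.
#' @param coeffs [retrieval_coefficients()].
#' @return particle count in hppcf; exact inverse of [count_to_mass()].
#' @export
mass_to_count <- function(mass, coeffs = retrieval_coefficients()) {
  (mass - coeffs$intercept) / coeffs$slope
}

#' Hourly network-mean series across collocated sensors
#'
#' The across-sensor arithmetic mean per hour, the reference against which
#' every sensor is regressed during collocation. The sensor under evaluation
#' is included in the mean (matching the construction of the printed
#' collocation statistics); leave-one-out means are available through
#' [fit_sensor_vs_mean()]. Hours where fewer than \code{min_sensors} sensors
#' report are excluded.
#'
#' @param hourly hourly records (long data.frame: \code{sensor_id},
#'   \code{hour_start}, \code{pm25}).
#' @param min_sensors minimum reporting sensors per qualifying hour; default
#'   75% of the distinct sensors present.
#' @return data.frame with \code{hour_start}, \code{pm25} (network mean) and
#'   \code{n_sensors}.
#' @export
network_mean <- function(hourly, min_sensors = NULL) {
  stopifnot(all(c("sensor_id", "hour_start", "pm25") %in% names(hourly)))
  n_total <- length(unique(hourly$sensor_id))
  if (is.null(min_sensors)) min_sensors <- ceiling(0.75 * n_total)
  ok <- !is.na(hourly$pm25)
  key <- as.numeric(hourly$hour_start)
  sums <- rowsum(ifelse(ok, hourly$pm25, 0), key)
  cnts <- rowsum(as.numeric(ok), key)
  n <- as.integer(cnts[, 1])
  keep <- n >= min_sensors
  if (!any(keep)) stop("insufficient data: no hour reaches min_sensors = ",
                       min_sensors)
  tz <- attr(hourly$hour_start, "tzone")
  out <- data.frame(
    hour_start = as.POSIXct(as.numeric(rownames(sums))[keep],
                            origin = "1970-01-01",
                            tz = if (is.null(tz)) "" else tz),
    pm25 = (sums[, 1] / n)[keep],
    n_sensors = n[keep]
  )
  out[order(out$hour_start), , drop = FALSE]
}

#' Regress one sensor against the network mean
#'
#' Ordinary least squares of the sensor (response) on the network mean
#' (predictor) over their common valid hours. Reports the regression slope
#' and intercept, Pearson R2, the RMSE of the raw sensor-minus-mean
#' differences, and the number of hours. Fits with fewer than
#' \code{min_hours} overlap are flagged invalid.
#'
#' @param sensor hourly series for one sensor (\code{hour_start},
#'   \code{pm25}).
#' @param mean_series network-mean series from [network_mean()].
#' @param min_hours minimum overlap for a valid fit.
#' @param sensor_id optional identifier carried into the result.
#' @param period optional period label (\code{"pre"}, \code{"post"}, ...).
#' @return an object of class \code{sensor_fit}: list with \code{slope},
#'   \code{intercept}, \code{r2}, \code{rmse}, \code{n_hours}, \code{valid}.
#' @export
fit_sensor_vs_mean <- function(sensor, mean_series, min_hours = 24,
                               sensor_id = NA_character_,
                               period = NA_character_) {
  pairs <- align_pairwise(sensor, mean_series)
  n <- nrow(pairs)
  if (n < 2L) stop("insufficient overlap to fit sensor against the mean")
  if (var(pairs$y) == 0) stop("network mean has zero variance over overlap")
  fit <- lm(x ~ y, data = pairs)
  b <- coef(fit)
  structure(list(
    sensor_id = sensor_id,
    period = period,
    slope = unname(b[2L]),
    intercept = unname(b[1L]),
    r2 = cor(pairs$x, pairs$y)^2,
    rmse = sqrt(mean((pairs$x - pairs$y)^2)),
    n_hours = n,
    valid = n >= min_hours
  ), class = "sensor_fit")
}

#' Derive a per-sensor correction factor from collocation fits
#'
#' The correction slope and intercept are the averages of the pre-study and
#' post-study regression coefficients. When the post-study fit is absent or
#' invalid (too few valid hours, e.g. from data gaps limiting the PM range),
#' the pre-study coefficients are used alone and the source is marked
#' \code{"pre_only"}.
#'
#' @param pre \code{sensor_fit} for the pre-study collocation (must be
#'   valid).
#' @param post \code{sensor_fit} for the post-study collocation, or NULL.
#' @return an object of class \code{correction_factor}: list with
#'   \code{sensor_id}, \code{slope}, \code{intercept}, \code{source}.
#' @export
derive_correction <- function(pre, post = NULL) {
  if (is.null(pre) || !isTRUE(pre$valid))
    stop("a valid pre-study fit is required to derive a correction")
  if (!is.null(post) && isTRUE(post$valid)) {
    out <- list(sensor_id = pre$sensor_id,
                slope = mean(c(pre$slope, post$slope)),
                intercept = mean(c(pre$intercept, post$intercept)),
                source = "averaged")
  } else {
    out <- list(sensor_id = pre$sensor_id,
                slope = pre$slope,
                intercept = pre$intercept,
                source = "pre_only")
  }
  if (out$slope <= 0) stop("derived correction slope must be > 0")
  structure(out, class = "correction_factor")
}

#' Apply a correction factor to raw sensor values
#'
#' \code{corrected = (raw - intercept) / slope}. Missing values propagate.
#' Negative corrected values are retained (they carry information about the
#' sensor's offset at low concentrations) but their count is attached as
#' attribute \code{"n_negative"}.
#'
#' @param raw numeric vector of raw PM2.5 values in ug/m3.
#' @param cf a \code{correction_factor} (or any list with \code{slope} > 0
#'   and \code{intercept}).
#' @return corrected numeric vector.
#' @export
apply_correction <- function(raw, cf) {
  if (cf$slope <= 0) stop("correction slope must be > 0")
  out <- (raw - cf$intercept) / cf$slope
  attr(out, "n_negative") <- sum(!is.na(out) & out < 0)
  out
}

#' Fit per-sensor collocation corrections for a sensor network
#'
#' The fitting function of the package. For each collocation period, the
#' hourly network mean across the collocated sensors is formed and each
#' sensor is regressed against it; the per-sensor correction factor is the
#' average of the pre- and post-period coefficients (pre-only fallback when
#' the post fit is invalid). Applying the correction
#' (\code{(raw - intercept)/slope}) makes every sensor report a value
#' comparable to the network mean.
#'
#' @param hourly hourly records of all collocated sensors (long data.frame:
#'   \code{sensor_id}, \code{hour_start}, \code{pm25}).
#' @param periods named list of period time windows, each
#'   \code{c(start, end)} (POSIXct or coercible); typically \code{pre} and
#'   \code{post}. Hours in \code{[start, end)} belong to the period.
#' @param min_sensors minimum reporting sensors per network-mean hour;
#'   default 75% of the sensors present.
#' @param min_hours minimum overlap hours for a valid per-sensor fit.
#' @return an object of class \code{sensor_calibration} with components
#'   \code{fits} (data.frame of per-sensor per-period regressions),
#'   \code{corrections} (data.frame of correction factors), \code{settings}
#'   and \code{call}. Supports \code{print}, \code{summary}, \code{coef} and
#'   \code{predict}.
#' @seealso [predict.sensor_calibration()], [precision_summary()],
#'   [drift_table()]
#' @export
calibrate_sensors <- function(hourly, periods, min_sensors = NULL,
                              min_hours = 24) {
  stopifnot(is.list(periods), length(periods) >= 1L,
            !is.null(names(periods)))
  sensors <- sort(unique(hourly$sensor_id))

  fit_rows <- list()
  fits_by_period <- list()
  for (p in names(periods)) {
    win <- periods[[p]]
    sel <- hourly$hour_start >= win[1] & hourly$hour_start < win[2]
    sub <- hourly[sel, , drop = FALSE]
    if (nrow(sub) == 0L) {
      fits_by_period[[p]] <- list()
      next
    }
    nm <- network_mean(sub, min_sensors = min_sensors)
    pf <- list()
    for (s in sensors) {
      ss <- sub[sub$sensor_id == s, , drop = FALSE]
      f <- tryCatch(
        fit_sensor_vs_mean(ss, nm, min_hours = min_hours,
                           sensor_id = s, period = p),
        error = function(e) NULL
      )
      if (!is.null(f)) {
        pf[[s]] <- f
        fit_rows[[length(fit_rows) + 1L]] <- as.data.frame(unclass(f))
      }
    }
    fits_by_period[[p]] <- pf
  }
  fits <- do.call(rbind, fit_rows)

  pre_name <- if ("pre" %in% names(periods)) "pre" else names(periods)[1L]
  post_name <- if ("post" %in% names(periods)) "post" else
    if (length(periods) >= 2L) names(periods)[2L] else NA_character_

  corr_rows <- list()
  for (s in sensors) {
    pre <- fits_by_period[[pre_name]][[s]]
    post <- if (!is.na(post_name)) fits_by_period[[post_name]][[s]] else NULL
    cf <- tryCatch(derive_correction(pre, post), error = function(e) NULL)
    if (!is.null(cf))
      corr_rows[[length(corr_rows) + 1L]] <- as.data.frame(unclass(cf))
  }
  corrections <- do.call(rbind, corr_rows)

  structure(list(
    fits = fits,
    corrections = corrections,
    settings = list(min_sensors = min_sensors, min_hours = min_hours,
                    periods = periods,
                    pre = pre_name, post = post_name),
    call = match.call()
  ), class = "sensor_calibration")
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat("Collocation calibration of", nrow(x$corrections), "sensors\n")
  cat("Periods:", paste(names(x$settings$periods), collapse = ", "), "\n")
  cat("Correction factors (corrected = (raw - intercept)/slope):\n")
  print(x$corrections, digits = 3)
  invisible(x)
}

#' @export
summary.sensor_calibration <- function(object, ...) {
  out <- precision_summary(object)
  class(out) <- c("summary.sensor_calibration", class(out))
  out
}

#' @export
print.summary.sensor_calibration <- function(x, ...) {
  cat("Per-period precision of collocated sensors:\n")
  print(x$by_period, digits = 3)
  if (!is.null(x$cv))
    cat(sprintf("CV (per-hour across-sensor SD/mean): %.3f +/- %.3f over %d hours\n",
                x$cv$mean, x$cv$sd, x$cv$n_hours))
  invisible(x)
}

#' Correction-factor coefficients of a calibration
#'
#' @param object a \code{sensor_calibration}.
#' @param ... unused.
#' @return matrix with one row per sensor and columns \code{slope},
#'   \code{intercept}.
#' @export
coef.sensor_calibration <- function(object, ...) {
  m <- as.matrix(object$corrections[, c("slope", "intercept")])
  rownames(m) <- object$corrections$sensor_id
  m
}

#' Apply fitted corrections to new raw sensor values
#'
#' @param object a \code{sensor_calibration}.
#' @param newdata data.frame with \code{sensor_id} and \code{pm25} (raw).
#' @param ... unused.
#' @return numeric vector of corrected PM2.5 values, NA for sensors without
#'   a fitted correction.
#' @export
predict.sensor_calibration <- function(object, newdata, ...) {
  stopifnot(all(c("sensor_id", "pm25") %in% names(newdata)))
  idx <- match(newdata$sensor_id, object$corrections$sensor_id)
  slope <- object$corrections$slope[idx]
  intercept <- object$corrections$intercept[idx]
  (newdata$pm25 - intercept) / slope
}

#' Apply a calibration to a long table of hourly records
#'
#' @param calibration a \code{sensor_calibration}.
#' @param hourly long data.frame with \code{sensor_id} and \code{pm25}.
#' @return the input with \code{pm25} replaced by corrected values.
#' @export
correct_hourly <- function(calibration, hourly) {
  hourly$pm25 <- predict(calibration, hourly)
  hourly
}

#' Precision summary of a calibration (R2, RMSE, CV)
#'
#' Per period: mean, min and max of the per-sensor R2 and RMSE versus the
#' network mean. The coefficient of variation is computed per hour as the
#' across-sensor sample SD divided by the across-sensor mean, then averaged
#' over qualifying hours; hours whose mean is zero are skipped and counted.
#' CV requires the hourly records the calibration was fitted on.
#'
#' @param calibration a \code{sensor_calibration}.
#' @param hourly optional hourly records used for the CV; when NULL only the
#'   fit-based metrics are reported.
#' @return list with per-period data.frame \code{by_period} and, when hourly
#'   data are supplied, \code{cv} (mean and SD of the per-hour CV).
#' @export
precision_summary <- function(calibration, hourly = NULL) {
  fits <- calibration$fits
  if (is.null(fits) || nrow(fits) < 2L)
    stop("precision summary needs fits from at least 2 sensors")
  sp <- split(fits, fits$period)
  by_period <- do.call(rbind, lapply(names(sp), function(p) {
    f <- sp[[p]]
    data.frame(period = p, n_sensors = nrow(f),
               r2_mean = mean(f$r2), r2_min = min(f$r2), r2_max = max(f$r2),
               rmse_mean = mean(f$rmse), rmse_min = min(f$rmse),
               rmse_max = max(f$rmse))
  }))
  out <- list(by_period = by_period)
  if (!is.null(hourly)) out$cv <- hourly_cv(hourly)
  out
}

#' Per-hour across-sensor coefficient of variation, averaged
#'
#' @param hourly long hourly records (\code{sensor_id}, \code{hour_start},
#'   \code{pm25}).
#' @param min_sensors minimum sensors reporting for an hour to qualify.
#' @return list with \code{mean}, \code{sd}, \code{n_hours} and
#'   \code{n_skipped_zero_mean}.
#' @export
hourly_cv <- function(hourly, min_sensors = 2L) {
  ok <- !is.na(hourly$pm25)
  sub <- hourly[ok, , drop = FALSE]
  key <- as.numeric(sub$hour_start)
  n <- rowsum(rep(1, nrow(sub)), key)[, 1]
  s1 <- rowsum(sub$pm25, key)[, 1]
  s2 <- rowsum(sub$pm25^2, key)[, 1]
  keep <- n >= min_sensors
  n <- n[keep]; s1 <- s1[keep]; s2 <- s2[keep]
  mu <- s1 / n
  sdv <- sqrt(pmax(0, (s2 - n * mu^2) / (n - 1)))
  zero <- mu == 0
  cv <- sdv[!zero] / mu[!zero]
  list(mean = mean(cv), sd = sd(cv), n_hours = length(cv),
       n_skipped_zero_mean = sum(zero))
}

#' Drift between two collocation fits at fixed concentration levels
#'
#' For each nominal concentration level v, the pre- and post-period fitted
#' readings are \code{slope*v + intercept} from the respective regressions;
#' the drift is their difference in ug/m3 and as a percentage. The percent
#' change is referenced to the pre-period reading by default (the
#' alternative, referencing the nominal level, is available via
#' \code{denominator}).
#'
#' @param pre,post \code{sensor_fit} objects for the two periods.
#' @param levels concentration levels in ug/m3.
#' @param denominator \code{"pre_reading"} (default) or \code{"level"}.
#' @return data.frame with columns \code{level}, \code{reading_pre},
#'   \code{reading_post}, \code{change_abs}, \code{change_pct} (NA, with a
#'   flag column, where the pre reading is nonpositive).
#' @export
drift_table <- function(pre, post, levels = c(5, 10, 20, 30, 40, 50),
                        denominator = c("pre_reading", "level")) {
  denominator <- match.arg(denominator)
  if (!isTRUE(pre$valid) || !isTRUE(post$valid))
    stop("drift evaluation needs valid fits from both periods")
  reading_pre <- pre$slope * levels + pre$intercept
  reading_post <- post$slope * levels + post$intercept
  change_abs <- reading_post - reading_pre
  denom <- if (denominator == "pre_reading") reading_pre else levels
  bad <- denom <= 0
  change_pct <- ifelse(bad, NA_real_, 100 * abs(change_abs) / denom)
  data.frame(level = levels, reading_pre = reading_pre,
             reading_post = reading_post, change_abs = change_abs,
             change_pct = change_pct, undefined_pct = bad)
}

#' Summarise drift across all sensors of a calibration
#'
#' Runs [drift_table()] for every sensor with valid fits in both periods and
#' reports the fraction of sensor-by-level cases with percent drift below
#' \code{threshold_pct}.
#'
#' @param calibration a \code{sensor_calibration} fitted with pre and post
#'   periods.
#' @param levels concentration levels in ug/m3.
#' @param threshold_pct percent-drift threshold for the summary fraction.
#' @param denominator passed to [drift_table()].
#' @return list with \code{per_sensor} (data.frame of all sensor-by-level
#'   drifts) and \code{fraction_below} the summary fraction.
#' @export
drift_summary <- function(calibration, levels = c(5, 10, 20, 30, 40, 50),
                          threshold_pct = 10,
                          denominator = c("pre_reading", "level")) {
  denominator <- match.arg(denominator)
  st <- calibration$settings
  fits <- calibration$fits
  rows <- list()
  for (s in unique(fits$sensor_id)) {
    pre <- fits[fits$sensor_id == s & fits$period == st$pre, ]
    post <- fits[fits$sensor_id == s & fits$period == st$post, ]
    if (nrow(pre) == 1L && nrow(post) == 1L && pre$valid && post$valid) {
      dt <- drift_table(as.list(pre), as.list(post), levels, denominator)
      dt$sensor_id <- s
      rows[[s]] <- dt
    }
  }
  per_sensor <- do.call(rbind, rows)
  rownames(per_sensor) <- NULL
  frac <- mean(per_sensor$change_pct < threshold_pct, na.rm = TRUE)
  list(per_sensor = per_sensor, fraction_below = frac)
}
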