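#' Adjusted coefficient of determination
#'
#' \code{1 - (1 - R2) (n - 1) / (n - k - 1)} for a model with k predictors
#' fitted to n observations.
#'
#' @param r2 unadjusted R2.
#' @param n number of observations.
#' @param k number of predictors (excluding the intercept).
#' @return adjusted R2.
#' @export
adjusted_r2 <- function(r2, n, k) {
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Compare a corrected sensor series to a reference monitor
#'
#' Aligns the two series, fits reference-vs-sensor OLS, and reports R2,
#' slope, intercept, mean bias (sensor minus reference) and n. When a
#' meteorology table is supplied, mean sensor/reference ratios are also
#' reported within bins of each meteorological variable (dew point uses
#' fixed bins at 4 and 10 degrees C, the humidity-growth regimes; the other
#' variables use quartile bins).
#'
#' @param sensor,reference data.frames with a shared time column and
#'   \code{pm25}.
#' @param met optional meteorology table (\code{hour_start}, \code{temp_c},
#'   \code{rh_pct}, \code{ws_ms}, and \code{dew_point_c}; see
#'   [enrich_met()]).
#' @param time_col shared time column name.
#' @param min_overlap minimum aligned points required.
#' @return list with \code{r2}, \code{slope}, \code{intercept},
#'   \code{mean_bias}, \code{n} and (if met given) \code{ratios}, a
#'   data.frame of binned sensor/reference ratios per met variable.
#' @export
compare_to_reference <- function(sensor, reference, met = NULL,
                                 time_col = "hour_start",
                                 min_overlap = 24L) {
  pairs <- align_pairwise(sensor, reference, time_col = time_col)
  if (nrow(pairs) < min_overlap)
    stop("insufficient overlap between sensor and reference (",
         nrow(pairs), " < ", min_overlap, ")")
  fit <- lm(y ~ x, data = pairs)  # reference on sensor
  out <- list(
    r2 = cor(pairs$x, pairs$y)^2,
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    mean_bias = mean(pairs$x - pairs$y),
    n = nrow(pairs)
  )
  if (!is.null(met)) {
    mvars <- intersect(c("rh_pct", "dew_point_c", "temp_c", "ws_ms"),
                       names(met))
    mm <- merge(pairs, met[, c(time_col, mvars)],
                by.x = "time", by.y = time_col)
    ratio <- mm$x / mm$y
    rows <- list()
    for (v in mvars) {
      if (v == "dew_point_c") {
        brk <- c(-Inf, 4, 10, Inf)
      } else {
        brk <- unique(stats::quantile(mm[[v]], c(0, .25, .5, .75, 1),
                                      na.rm = TRUE))
        if (length(brk) < 3L) next
      }
      bin <- cut(mm[[v]], brk, include.lowest = TRUE)
      ok <- !is.na(bin) & is.finite(ratio)
      agg <- tapply(ratio[ok], bin[ok], mean)
      rows[[v]] <- data.frame(variable = v, bin = names(agg),
                              mean_ratio = as.numeric(agg),
                              n = as.integer(table(bin[ok])[names(agg)]))
    }
    ratios <- do.call(rbind, rows)
    rownames(ratios) <- NULL
    out$ratios <- ratios
  }
  out
}

# Model specifications for the meteorological bias regression. The response
# is the reference monitor; the sensor is always a predictor.
.met_terms <- function(model_spec) {
  base <- "sensor"
  mv <- c("temp_c", "dew_point_c", "rh_pct", "ws_ms")
  switch(model_spec,
    initial = base,
    "+temp" = c(base, "temp_c"),
    "+dew" = c(base, "dew_point_c"),
    "+rh" = c(base, "rh_pct"),
    "+ws" = c(base, "ws_ms"),
    all_linear = c(base, mv),
    quadratic_full = {
      sq <- paste0("I(", mv, "^2)")
      cross <- utils::combn(mv, 2, function(p) paste(p, collapse = ":"))
      c(base, mv, sq, cross)
    },
    stop("unknown model_spec: ", model_spec)
  )
}

#' Multi-linear meteorological regression of reference on sensor
#'
#' Fits OLS of the reference monitor on the corrected sensor plus a
#' specified set of meteorological covariates, quantifying how much of the
#' sensor-reference deviation meteorology explains. Model specifications:
#' \code{"initial"} (sensor only), \code{"+temp"}, \code{"+dew"},
#' \code{"+rh"}, \code{"+ws"} (one covariate each), \code{"all_linear"}
#' (all four), and \code{"quadratic_full"} (all four plus their squares and
#' all pairwise cross terms; k = 15 predictors). Wind direction is not used.
#'
#' @param sensor,reference data.frames with a shared time column and
#'   \code{pm25}.
#' @param met meteorology table with \code{temp_c}, \code{dew_point_c},
#'   \code{rh_pct}, \code{ws_ms} and the time column.
#' @param model_spec one of the labels above.
#' @param time_col shared time column name.
#' @return list of class \code{met_regression}: \code{model_spec},
#'   \code{r2}, \code{adjusted_r2}, \code{coefficients}, \code{p_values},
#'   \code{n}, \code{k}. Collinear terms dropped by the fit are reported
#'   with a warning.
#' @export
met_regression <- function(sensor, reference, met,
                           model_spec = "initial",
                           time_col = "hour_start") {
  pairs <- align_pairwise(sensor, reference, time_col = time_col)
  mvars <- c("temp_c", "dew_point_c", "rh_pct", "ws_ms")
  stopifnot(all(c(time_col, mvars) %in% names(met)))
  dat <- merge(pairs, met[, c(time_col, mvars)],
               by.x = "time", by.y = time_col)
  names(dat)[names(dat) == "x"] <- "sensor"
  names(dat)[names(dat) == "y"] <- "reference"
  dat <- dat[complete.cases(dat), , drop = FALSE]

  terms <- .met_terms(model_spec)
  f <- stats::reformulate(terms, response = "reference")
  fit <- lm(f, data = dat)
  sm <- summary(fit)
  cf <- coef(fit)
  if (anyNA(cf)) {
    warning("collinear terms dropped from ", model_spec, " model: ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
    cf <- cf[!is.na(cf)]
  }
  k <- length(cf) - 1L
  n <- nrow(dat)
  structure(list(
    model_spec = model_spec,
    r2 = sm$r.squared,
    adjusted_r2 = adjusted_r2(sm$r.squared, n, k),
    coefficients = cf,
    p_values = sm$coefficients[, 4L],
    n = n,
    k = k
  ), class = "met_regression")
}

#' @export
print.met_regression <- function(x, ...) {
  cat(sprintf("met regression [%s]: R2 = %.4f, adj R2 = %.4f (n = %d, k = %d)\n",
              x$model_spec, x$r2, x$adjusted_r2, x$n, x$k))
  invisible(x)
}

#' Adjusted-R2 table across all meteorological model specifications
#'
#' Fits the full ladder of model specifications and reports their adjusted
#' R2, mirroring the layout used to rank explanatory meteorological
#' variables. Single-covariate rows are ranked by adjusted-R2 gain over the
#' sensor-only model.
#'
#' @inheritParams met_regression
#' @return data.frame with \code{model_spec}, \code{adjusted_r2}, \code{r2},
#'   \code{k}, \code{n} and \code{gain} (adjusted-R2 gain over
#'   \code{"initial"}; NA for the initial row).
#' @export
met_regression_table <- function(sensor, reference, met,
                                 time_col = "hour_start") {
  specs <- c("initial", "+temp", "+dew", "+rh", "+ws",
             "all_linear", "quadratic_full")
  fits <- lapply(specs, function(s)
    met_regression(sensor, reference, met, s, time_col))
  adj <- vapply(fits, `[[`, numeric(1), "adjusted_r2")
  base <- adj[specs == "initial"]
  data.frame(model_spec = specs,
             adjusted_r2 = adj,
             r2 = vapply(fits, `[[`, numeric(1), "r2"),
             k = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
             n = vapply(fits, function(f) as.numeric(f$n), numeric(1)),
             gain = ifelse(specs == "initial", NA_real_, adj - base))
}
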