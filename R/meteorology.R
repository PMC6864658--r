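#' Saturation vapor pressure (Magnus form)
#'
#' \code{es(T) = 6.11 * 10^(7.5 T / (237.3 + T))} hPa. The Magnus constants
#' (6.11 hPa, 7.5, 237.3) are chosen to be self-consistent with the base-10
#' dew-point inversion used by [dew_point()].
#'
#' @param temp_c air temperature in degrees C.
#' @return saturation vapor pressure in hPa.
#' @export
saturation_vapor_pressure <- function(temp_c) {
  6.11 * 10^(7.5 * temp_c / (237.3 + temp_c))
}

#' Actual vapor pressure from temperature and relative humidity
#'
#' \code{RH/100 * es(T)}. Relative humidity at or below zero leaves the dew
#' point undefined; such elements return NA with a warning.
#'
#' @param temp_c air temperature in degrees C (valid range roughly -40..60).
#' @param rh_pct relative humidity in percent, (0, 100].
#' @return vapor pressure in hPa.
#' @export
vapor_pressure <- function(temp_c, rh_pct) {
  bad <- !is.na(rh_pct) & rh_pct <= 0
  if (any(bad)) {
    warning("relative humidity <= 0: dew point undefined, returning NA")
    rh_pct[bad] <- NA_real_
  }
  rh_pct / 100 * saturation_vapor_pressure(temp_c)
}

#' Dew point from vapor pressure
#'
#' \code{(237.3 log10(VP) - 186.52) / (8.29 - log10(VP))} with VP in hPa.
#' The logarithm is base 10: this expression is the inversion of a base-10
#' Magnus formula, and the round-trip
#' \code{dew_point(vapor_pressure(T, 100)) == T} only holds in base 10.
#'
#' @param vp_hpa vapor pressure in hPa (> 0).
#' @return dew point in degrees C; NA for nonpositive vapor pressure.
#' @export
dew_point <- function(vp_hpa) {
  bad <- !is.na(vp_hpa) & vp_hpa <= 0
  if (any(bad)) {
    warning("nonpositive vapor pressure: dew point undefined, returning NA")
    vp_hpa[bad] <- NA_real_
  }
  lv <- log10(vp_hpa)
  if (any(!is.na(lv) & lv >= 8.29))
    stop("vapor pressure out of the dew-point formula's domain")
  (237.3 * lv - 186.52) / (8.29 - lv)
}

#' Dew point from temperature and relative humidity
#'
#' Convenience composition of [vapor_pressure()] and [dew_point()].
#' @inheritParams vapor_pressure
#' @return dew point in degrees C.
#' @export
dew_point_from_met <- function(temp_c, rh_pct) {
  dew_point(vapor_pressure(temp_c, rh_pct))
}

#' Add vapor-pressure and dew-point columns to a meteorology table
#'
#' @param met data.frame with columns \code{temp_c} and \code{rh_pct}.
#' @return the input with columns \code{vp_hpa} and \code{dew_point_c}
#'   added (recomputed if already present).
#' @export
enrich_met <- function(met) {
  stopifnot(all(c("temp_c", "rh_pct") %in% names(met)))
  met$vp_hpa <- vapor_pressure(met$temp_c, met$rh_pct)
  met$dew_point_c <- dew_point(met$vp_hpa)
  met
}
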