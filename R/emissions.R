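#' Assign sites to emissions-inventory grid cells
#'
#' Cells are axis-aligned squares in local projected km coordinates,
#' half-open (\code{[min, max)}) so a site on a shared boundary belongs to
#' the lower-left cell.
#'
#' @param sites data.frame with \code{site_id}, \code{x_km}, \code{y_km}.
#' @param cells data.frame with \code{cell_id}, \code{min_x}, \code{min_y},
#'   \code{max_x}, \code{max_y}.
#' @return character vector: for each site, the containing cell id (NA when
#'   outside all cells).
#' @export
assign_sites_to_cells <- function(sites, cells) {
  vapply(seq_len(nrow(sites)), function(i) {
    hit <- sites$x_km[i] >= cells$min_x & sites$x_km[i] < cells$max_x &
      sites$y_km[i] >= cells$min_y & sites$y_km[i] < cells$max_y
    if (any(hit)) as.character(cells$cell_id[which(hit)[1L]]) else
      NA_character_
  }, character(1))
}

#' Weekday/weekend classification of timestamps
#'
#' Local-calendar classification; holidays count as weekdays unless listed.
#'
#' @param time POSIXct vector.
#' @param tz local time zone for the calendar.
#' @param holidays optional Date vector of holidays to classify as weekend
#'   days.
#' @return character vector \code{"weekday"}/\code{"weekend"}.
#' @export
day_type <- function(time, tz = .default_tz, holidays = NULL) {
  d <- as.Date(time, tz = tz)
  wd <- as.POSIXlt(d)$wday
  out <- ifelse(wd %in% c(0L, 6L), "weekend", "weekday")
  if (!is.null(holidays)) out[d %in% as.Date(holidays)] <- "weekend"
  out
}

#' Grid-cell average concentrations and increments above background
#'
#' For each cell and day type, hourly values are restricted to hours (of
#' that day type) in which every member sensor of the cell reports; the cell
#' value is the mean across those sensors and hours. The increment is the
#' cell mean minus the lowest cell mean of the same day type (the
#' "background" cell), so exactly one cell per day type has increment zero.
#' A fixed-quantile background is available via \code{background}.
#'
#' @param hourly long data.frame with \code{site_id}, \code{hour_start},
#'   \code{pm25}.
#' @param site_cells named character vector mapping site_id to cell_id
#'   (e.g. from [assign_sites_to_cells()]).
#' @param day_types subset of \code{c("weekday", "weekend")} to compute.
#' @param tz local time zone for the weekday/weekend calendar.
#' @param background \code{"minimum"} (default) or a number in [0, 1): the
#'   quantile of cell means used as background.
#' @return data.frame with \code{cell_id}, \code{day_type}, \code{mean_pm},
#'   \code{increment}, \code{n_hours}. Cells with no qualifying hours are
#'   excluded with a warning.
#' @export
cell_average <- function(hourly, site_cells,
                         day_types = c("weekday", "weekend"),
                         tz = .default_tz, background = "minimum") {
  stopifnot(all(c("site_id", "hour_start", "pm25") %in% names(hourly)))
  # collapse to one value per site-hour (sites may host several sensors)
  ok0 <- !is.na(hourly$pm25)
  key <- paste(hourly$site_id, as.numeric(hourly$hour_start))
  sums <- rowsum(ifelse(ok0, hourly$pm25, 0), key)
  cnts <- rowsum(as.numeric(ok0), key)
  first <- !duplicated(key)
  site_hour <- data.frame(
    site_id = hourly$site_id[first],
    hour_start = hourly$hour_start[first],
    stringsAsFactors = FALSE)[match(rownames(sums), key[first]), ]
  site_hour$pm25 <- ifelse(cnts[, 1] > 0, sums[, 1] / cnts[, 1], NA_real_)

  site_hour$cell_id <- site_cells[site_hour$site_id]
  site_hour <- site_hour[!is.na(site_hour$cell_id), , drop = FALSE]
  site_hour$dtype <- day_type(site_hour$hour_start, tz = tz)
  members <- tapply(site_hour$site_id, site_hour$cell_id,
                    function(s) length(unique(s)))
  rows <- list()
  for (dt in day_types) {
    sub <- site_hour[site_hour$dtype == dt, , drop = FALSE]
    for (cid in names(members)) {
      cs <- sub[sub$cell_id == cid, , drop = FALSE]
      ok <- !is.na(cs$pm25)
      # hours where every member site of the cell reports
      cnt <- tapply(ok, as.numeric(cs$hour_start), sum)
      full <- as.numeric(names(cnt))[cnt == members[[cid]]]
      use <- cs[ok & as.numeric(cs$hour_start) %in% full, , drop = FALSE]
      if (nrow(use) == 0L) {
        warning("cell ", cid, " has no qualifying ", dt,
                " hours; excluded")
        next
      }
      rows[[paste(cid, dt)]] <- data.frame(
        cell_id = cid, day_type = dt, mean_pm = mean(use$pm25),
        n_hours = length(full))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$increment <- NA_real_
  for (dt in unique(out$day_type)) {
    sel <- out$day_type == dt
    bg <- if (identical(background, "minimum")) min(out$mean_pm[sel]) else
      stats::quantile(out$mean_pm[sel], background, names = FALSE)
    out$increment[sel] <- out$mean_pm[sel] - bg
  }
  out
}

#' Regress concentration increments on emissions-inventory values
#'
#' Per day type: OLS of the cell increment above background on the cell's
#' inventory emissions (tons/day). Reports slope, intercept, R2, per-cell
#' residuals and the cells with the largest absolute residuals.
#'
#' @param increments data.frame from [cell_average()].
#' @param cells data.frame with \code{cell_id},
#'   \code{weekday_tons_per_day}, \code{weekend_tons_per_day}.
#' @return named list (per day type) of lists with \code{slope},
#'   \code{intercept}, \code{r2}, \code{n_cells}, \code{residuals}
#'   (data.frame) and \code{largest_residual_cells}.
#' @export
regress_increment_vs_ei <- function(increments, cells) {
  out <- list()
  for (dt in unique(increments$day_type)) {
    sub <- increments[increments$day_type == dt, , drop = FALSE]
    ecol <- paste0(dt, "_tons_per_day")
    stopifnot(ecol %in% names(cells))
    ei <- cells[[ecol]][match(sub$cell_id, cells$cell_id)]
    ok <- !is.na(ei)
    if (sum(ok) < 3L) stop("need at least 3 cells per day type, got ",
                           sum(ok), " for ", dt)
    fit <- lm(sub$increment[ok] ~ ei[ok])
    res <- data.frame(cell_id = sub$cell_id[ok], emissions = ei[ok],
                      increment = sub$increment[ok],
                      residual = unname(stats::residuals(fit)))
    ord <- order(-abs(res$residual))
    out[[dt]] <- list(
      day_type = dt,
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r2 = summary(fit)$r.squared,
      n_cells = sum(ok),
      residuals = res,
      largest_residual_cells = res$cell_id[ord][seq_len(min(2L, nrow(res)))])
  }
  out
}
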