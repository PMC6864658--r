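#' Default pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: simulation settings,
#' the thresholds introduced by the data model and statistics (completeness
#' fractions, minimum overlaps, COD threshold, minimum sensors per
#' network-mean hour), the RNG seed and the output directory. All
#' thresholds are surfaced here so every convention the analysis relies on
#' is auditable in one place.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed RNG seed used by the simulation stage.
#' @param generator a [generator_config()] (NULL to skip simulation and
#'   read inputs from \code{paths}).
#' @param paths named list of input paths (\code{sensors}, \code{sites},
#'   \code{met}) used when \code{generator} is NULL.
#' @param stages character vector of stages to run, in order, from
#'   \code{c("simulate", "calibrate", "apply", "evaluate", "spatial",
#'   "compare_ei")}.
#' @param resolution simulation resolution passed to [simulate_campaign()].
#' @param min_minutes,min_hours_day completeness thresholds for hourly and
#'   daily aggregation.
#' @param min_fit_hours minimum overlap for a valid collocation fit.
#' @param min_overlap_hourly,min_overlap_daily minimum pairwise overlaps.
#' @param cod_threshold COD heterogeneity threshold.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = tempfile("pmnet_run_"),
                            seed = 1L,
                            generator = generator_config(),
                            paths = NULL,
                            stages = c("simulate", "calibrate", "apply",
                                       "evaluate", "spatial", "compare_ei"),
                            resolution = "hour",
                            min_minutes = 45L,
                            min_hours_day = 18L,
                            min_fit_hours = 24L,
                            min_overlap_hourly = 72L,
                            min_overlap_daily = 14L,
                            cod_threshold = 0.2) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 generator = generator, paths = paths, stages = stages,
                 resolution = resolution,
                 min_minutes = min_minutes, min_hours_day = min_hours_day,
                 min_fit_hours = min_fit_hours,
                 min_overlap_hourly = min_overlap_hourly,
                 min_overlap_daily = min_overlap_daily,
                 cod_threshold = cod_threshold),
            class = "pipeline_config")
}

# Deterministic CSV writer (fixed field order, no quoting surprises).
.write_stage_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Run the sensor-network analysis pipeline
#'
#' Executes the requested stages in order on a simulated campaign (or on
#' CSV inputs): \code{simulate} (generate the campaign), \code{calibrate}
#' (collocation fits and correction factors), \code{apply} (correct the
#' deployment data), \code{evaluate} (reference comparison and
#' meteorological regression ladder at the first reference site),
#' \code{spatial} (pairwise COD/R2 matrices at both resolutions,
#' homogeneity classification, distance decay, EJ group tests) and
#' \code{compare_ei} (grid-cell increments vs the emissions inventory).
#' Stage outputs are written as CSV/JSON under \code{config$out_dir}
#' together with a machine-readable run manifest; re-running with the same
#' config and seed reproduces every output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a report list with one component per executed stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("simulate", "calibrate", "apply", "evaluate", "spatial",
             "compare_ei")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown pipeline stages: ",
                        paste(bad, collapse = ", "))
  # validate inputs before any computation
  if (is.null(config$generator)) {
    for (p in unlist(config$paths))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()

  camp <- NULL
  hourly <- NULL
  if ("simulate" %in% config$stages) {
    camp <- simulate_campaign(config$generator, seed = config$seed,
                              resolution = config$resolution)
    hourly <- camp$hourly
    .write_stage_csv(camp$sensor_params,
                     file.path(config$out_dir, "truth_sensor_params.csv"))
    .write_stage_csv(
      data.frame(hour_start = format(camp$truth$hour_start,
                                     "%Y-%m-%dT%H:%M:%S"),
                 camp$truth$field, check.names = FALSE),
      file.path(config$out_dir, "truth_field.csv"))
    .write_stage_csv(camp$sites, file.path(config$out_dir, "sites.csv"))
    report$simulate <- list(n_sensors = config$generator$n_sensors,
                            n_hours = length(camp$truth$hour_start))
  } else if (!is.null(config$paths)) {
    minutes <- read_sensor_csv(config$paths$sensors)
    hourly <- aggregate_to_hours(minutes, config$min_minutes)
  }

  cal <- NULL
  if ("calibrate" %in% config$stages) {
    if (is.null(hourly)) stop("calibrate stage needs sensor data")
    periods <- if (!is.null(camp)) camp$config$periods else
      stop("calibrate stage needs configured collocation periods")
    coll <- hourly[hourly$phase %in% c("pre", "post"), , drop = FALSE]
    cal <- calibrate_sensors(coll[, c("sensor_id", "hour_start", "pm25")],
                             periods[c("pre", "post")],
                             min_hours = config$min_fit_hours)
    .write_stage_csv(cal$corrections,
                     file.path(config$out_dir, "corrections.csv"))
    .write_stage_csv(cal$fits, file.path(config$out_dir, "collocation_fits.csv"))
    report$calibrate <- precision_summary(cal, hourly = coll)
  }

  corrected <- NULL
  if ("apply" %in% config$stages) {
    if (is.null(cal)) stop("apply stage needs a calibration")
    dep <- hourly[hourly$phase == "deployment", , drop = FALSE]
    dep$pm25 <- predict(cal, dep)
    corrected <- dep
    out <- dep
    out$hour_start <- format(out$hour_start, "%Y-%m-%dT%H:%M:%S")
    .write_stage_csv(out, file.path(config$out_dir, "corrected_hourly.csv"))
    report$apply <- list(n_records = nrow(dep),
                         n_missing = sum(is.na(dep$pm25)))
  }

  if ("evaluate" %in% config$stages) {
    if (is.null(corrected) || is.null(camp))
      stop("evaluate stage needs corrected simulated data")
    ref1 <- camp$sites$site_id[camp$sites$role == "reference-collocated"][1L]
    sens <- corrected[corrected$site_id == ref1, , drop = FALSE]
    sens <- sens[sens$sensor_id == sens$sensor_id[1L], , drop = FALSE]
    bam <- camp$bam[camp$bam$site_id == ref1, , drop = FALSE]
    tab <- met_regression_table(sens, bam, camp$met)
    .write_stage_csv(tab, file.path(config$out_dir, "met_regression.csv"))
    report$evaluate <- list(table = tab,
                            reference = compare_to_reference(
                              sens, bam, met = camp$met))
  }

  if ("spatial" %in% config$stages) {
    if (is.null(corrected)) stop("spatial stage needs corrected data")
    # one representative (first) sensor per site for multi-sensor sites
    series <- lapply(split(corrected, corrected$site_id), function(d) {
      d[d$sensor_id == sort(unique(d$sensor_id))[1L],
        c("hour_start", "pm25")]
    })
    daily <- lapply(series, function(d) {
      x <- d; x$sensor_id <- "x"
      aggregate_to_days(x, min_hours = config$min_hours_day)
    })
    mats <- list(
      cod_hourly = pairwise_matrix(series, "cod", "hourly",
                                   min_overlap = config$min_overlap_hourly),
      r2_hourly = pairwise_matrix(series, "r2", "hourly",
                                  min_overlap = config$min_overlap_hourly),
      cod_daily = pairwise_matrix(daily, "cod", "daily",
                                  min_overlap = config$min_overlap_daily),
      r2_daily = pairwise_matrix(daily, "r2", "daily",
                                 min_overlap = config$min_overlap_daily))
    for (nm in names(mats))
      .write_stage_csv(as.data.frame(mats[[nm]]$values),
                       file.path(config$out_dir, paste0(nm, ".csv")))
    hom <- classify_homogeneity(mats$cod_hourly, config$cod_threshold)
    ej <- camp$sites$site_id[camp$sites$ej_flag]
    nonej <- setdiff(camp$sites$site_id, ej)
    groups <- list(a = intersect(ej, names(series)),
                   b = intersect(nonej, names(series)))
    welch <- group_test(series, groups, "welch_t")
    report$spatial <- list(
      summaries = lapply(mats, summary),
      fraction_heterogeneous = hom$fraction_heterogeneous,
      welch = welch)
    jsonlite::write_json(
      report$spatial[c("fraction_heterogeneous")],
      file.path(config$out_dir, "spatial_summary.json"),
      auto_unbox = TRUE, digits = 10)
  }

  if ("compare_ei" %in% config$stages) {
    if (is.null(corrected) || is.null(camp))
      stop("compare_ei stage needs corrected simulated data")
    cell_map <- assign_sites_to_cells(camp$sites, camp$ei_grid)
    names(cell_map) <- camp$sites$site_id
    inc <- cell_average(corrected, cell_map, tz = camp$config$tz)
    reg <- regress_increment_vs_ei(inc, camp$ei_grid)
    .write_stage_csv(inc, file.path(config$out_dir, "cell_increments.csv"))
    report$compare_ei <- reg
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pmsensornet")),
    seed = config$seed,
    stages = config$stages,
    thresholds = config[c("min_minutes", "min_hours_day", "min_fit_hours",
                          "min_overlap_hourly", "min_overlap_daily",
                          "cod_threshold")])
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(report)
}
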