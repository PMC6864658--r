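#' Load a packaged fixture table
#'
#' The package ships the printed summary tables of the motivating 19-sensor
#' Sacramento winter campaign as plain-CSV fixtures (see
#' \code{inst/extdata/MANIFEST.md}):
#' \describe{
#'   \item{\code{"precision"}}{per-sensor collocation precision statistics
#'     (hours, R2 and RMSE vs the network mean, pre/post regression
#'     coefficients, averaged correction factors). Alias \code{"table1"}.}
#'   \item{\code{"distances"}}{site-to-site great-circle distances in km.
#'     Alias \code{"table3"}.}
#'   \item{\code{"pairwise_r2"}}{pairwise Pearson R2; hourly values in the
#'     lower triangle, daily in the upper. Alias \code{"table4"}.}
#'   \item{\code{"pairwise_cod"}}{pairwise coefficient of divergence; hourly
#'     lower triangle, daily upper. Alias \code{"table5"}.}
#' }
#'
#' Matrix fixtures are returned with the hourly and daily triangles expanded
#' into full symmetric matrices.
#'
#' @param name fixture name (or alias), see above.
#' @return For \code{"precision"} a data.frame; for \code{"distances"} a list
#'   with \code{site_ids}, \code{communities} and symmetric matrix \code{km};
#'   for the pairwise fixtures a list with \code{site_ids},
#'   \code{communities}, \code{stat} and symmetric matrices \code{hourly} and
#'   \code{daily}.
#' @export
load_fixture_table <- function(name) {
  alias <- c(table1 = "precision", table3 = "distances",
             table4 = "pairwise_r2", table5 = "pairwise_cod")
  if (name %in% names(alias)) name <- alias[[name]]
  path <- function(f) system.file("extdata", f, package = "pmsensornet",
                                  mustWork = TRUE)
  switch(
    name,
    precision = read.csv(path("collocation_precision.csv"),
                         stringsAsFactors = FALSE),
    distances = {
      df <- read.csv(path("site_distances_km.csv"), check.names = FALSE,
                     stringsAsFactors = FALSE)
      m <- as.matrix(df[, -(1:2)])
      m[upper.tri(m)] <- t(m)[upper.tri(m)]
      dimnames(m) <- list(df$site, df$site)
      list(site_ids = df$site, communities = df$community, km = m)
    },
    pairwise_r2 = .load_triangle_fixture(path("pairwise_r2.csv"), "r2"),
    pairwise_cod = .load_triangle_fixture(path("pairwise_cod.csv"), "cod"),
    stop("unknown fixture table: ", name)
  )
}

# Split a printed matrix (hourly lower triangle, daily upper triangle) into
# two full symmetric matrices.
.load_triangle_fixture <- function(file, stat) {
  df <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2)])
  dimnames(m) <- list(df$site, df$site)
  hourly <- m
  hourly[upper.tri(hourly)] <- t(m)[upper.tri(m)]
  daily <- t(m)
  daily[upper.tri(daily)] <- m[upper.tri(m)]
  list(site_ids = df$site, communities = df$community, stat = stat,
       hourly = hourly, daily = daily)
}

#' Off-diagonal entries of one triangle of a symmetric matrix
#'
#' Convenience accessor for summarising fixture matrices: returns the 105
#' unique unordered pair values of a 15-site matrix.
#'
#' @param m symmetric numeric matrix.
#' @return numeric vector of the strictly-lower-triangle entries.
#' @export
pair_values <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[lower.tri(m)]
}
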