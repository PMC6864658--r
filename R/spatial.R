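#' Coefficient of divergence between two aligned series
#'
#' \deqn{COD = \sqrt{\frac{1}{p}\sum_{i=1}^p \left(\frac{x_i - y_i}{x_i + y_i}\right)^2}}
#' over the p aligned pairs. COD lies in [0, 1]: 0 for identical series, with
#' 0.2 the conventional threshold for a heterogeneous spatial distribution.
#' The statistic is defined for nonnegative concentrations: pairs whose sum
#' is zero contribute an undefined term, and negative values (possible after
#' linear correction of near-zero readings) would break the [0, 1] bound.
#' Both kinds of pair are skipped, counted in attribute \code{"n_skipped"},
#' and p is reduced accordingly.
#'
#' @param x,y numeric vectors of equal length (aligned measurements, NA
#'   pairs removed internally).
#' @param min_pairs minimum usable pairs; below this, NA is returned with a
#'   warning.
#' @return COD in [0, 1] with attributes \code{"n"} and \code{"n_skipped"}.
#' @export
cod_pair <- function(x, y, min_pairs = 1L) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  zero <- (x + y) == 0 | x < 0 | y < 0
  n_skipped <- sum(zero)
  x <- x[!zero]; y <- y[!zero]
  p <- length(x)
  if (p < min_pairs) {
    warning("insufficient data for COD: ", p, " usable pairs")
    return(structure(NA_real_, n = p, n_skipped = n_skipped))
  }
  val <- sqrt(mean(((x - y) / (x + y))^2))
  structure(val, n = p, n_skipped = n_skipped)
}

#' Pairwise spatial-variability matrix (COD or R2) across sites
#'
#' For every unordered pair of sites, the two series are aligned on common
#' valid timestamps and the pairwise statistic computed: coefficient of
#' divergence ([cod_pair()]) or squared Pearson correlation. Pairs below the
#' minimum overlap get NA entries.
#'
#' @param series_by_site named list of data.frames (one per site) with a
#'   time column and \code{pm25}.
#' @param stat \code{"cod"} or \code{"r2"}.
#' @param resolution label carried in the result (\code{"hourly"} or
#'   \code{"daily"}); set \code{time_col} accordingly.
#' @param time_col time column name (\code{"hour_start"} or \code{"date"}).
#' @param min_overlap minimum aligned pairs per site pair (default 72 for
#'   hourly, 14 for daily).
#' @return object of class \code{pairwise_stat_matrix}: list with
#'   \code{site_ids}, \code{stat}, \code{resolution}, symmetric
#'   \code{values} matrix (unit diagonal for r2, zero for cod) and
#'   \code{n_overlap} counts.
#' @export
pairwise_matrix <- function(series_by_site, stat = c("cod", "r2"),
                            resolution = c("hourly", "daily"),
                            time_col = NULL, min_overlap = NULL) {
  stat <- match.arg(stat)
  resolution <- match.arg(resolution)
  if (is.null(time_col))
    time_col <- if (resolution == "hourly") "hour_start" else "date"
  if (is.null(min_overlap))
    min_overlap <- if (resolution == "hourly") 72L else 14L
  sites <- names(series_by_site)
  stopifnot(!is.null(sites), length(sites) >= 2L)
  k <- length(sites)
  vals <- matrix(NA_real_, k, k, dimnames = list(sites, sites))
  nov <- matrix(0L, k, k, dimnames = list(sites, sites))
  diag(vals) <- if (stat == "cod") 0 else 1
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      pairs <- suppressWarnings(
        align_pairwise(series_by_site[[i]], series_by_site[[j]],
                       time_col = time_col))
      nov[i, j] <- nov[j, i] <- nrow(pairs)
      if (nrow(pairs) < min_overlap) next
      v <- if (stat == "cod") {
        as.numeric(cod_pair(pairs$x, pairs$y))
      } else {
        cor(pairs$x, pairs$y)^2
      }
      vals[i, j] <- vals[j, i] <- v
    }
  }
  structure(list(site_ids = sites, stat = stat, resolution = resolution,
                 values = vals, n_overlap = nov),
            class = "pairwise_stat_matrix")
}

#' @export
print.pairwise_stat_matrix <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("pairwise %s matrix (%s), %d sites: mean %.3f, range [%.3f, %.3f]\n",
              x$stat, x$resolution, length(x$site_ids),
              s$mean, s$min, s$max))
  invisible(x)
}

#' @export
summary.pairwise_stat_matrix <- function(object, ...) {
  v <- pair_values(object$values)
  v <- v[!is.na(v)]
  list(stat = object$stat, resolution = object$resolution,
       n_pairs = length(v), mean = mean(v), min = min(v), max = max(v))
}

#' Classify site pairs as homogeneous or heterogeneous by COD threshold
#'
#' Pairs with COD below \code{threshold} are homogeneous; at or above it,
#' heterogeneous (0.2 is the conventional threshold).
#'
#' @param m a \code{pairwise_stat_matrix} with \code{stat = "cod"}, or a
#'   symmetric COD matrix.
#' @param threshold COD heterogeneity threshold.
#' @return list with \code{pairs} (data.frame: site_a, site_b, cod, label)
#'   and \code{fraction_heterogeneous}.
#' @export
classify_homogeneity <- function(m, threshold = 0.2) {
  if (inherits(m, "pairwise_stat_matrix")) {
    if (m$stat != "cod") stop("homogeneity classification needs a COD matrix")
    mat <- m$values
  } else {
    mat <- m
  }
  sites <- rownames(mat)
  idx <- which(lower.tri(mat), arr.ind = TRUE)
  cod <- mat[idx]
  pairs <- data.frame(site_a = sites[idx[, 2L]], site_b = sites[idx[, 1L]],
                      cod = cod,
                      label = ifelse(cod < threshold, "homogeneous",
                                     "heterogeneous"))
  list(pairs = pairs,
       fraction_heterogeneous = mean(cod >= threshold, na.rm = TRUE))
}

#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param a,b coordinates as \code{c(lat, lon)} vectors or two-column
#'   (lat, lon) matrices.
#' @return distance(s) in km.
#' @export
haversine_km <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 2, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, ncol = 2, byrow = TRUE)
  if (any(abs(a[, 1]) > 90) || any(abs(b[, 1]) > 90) ||
      any(abs(a[, 2]) > 180) || any(abs(b[, 2]) > 180))
    stop("invalid coordinates: expected (lat, lon) in degrees")
  # geosphere expects (lon, lat)
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = 6371000) / 1000
}

#' Site-to-site distance matrix
#'
#' @param sites data.frame with \code{site_id}, \code{lat}, \code{lon}.
#' @return symmetric matrix of distances in km, zero diagonal.
#' @export
distance_matrix <- function(sites) {
  k <- nrow(sites)
  m <- matrix(0, k, k, dimnames = list(sites$site_id, sites$site_id))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      m[i, j] <- m[j, i] <- haversine_km(c(sites$lat[i], sites$lon[i]),
                                         c(sites$lat[j], sites$lon[j]))
    }
  }
  m
}

#' Distance decay of a pairwise statistic
#'
#' OLS of the pairwise statistic on pairwise distance over all site pairs.
#' COD is expected to increase with distance (positive slope) and pairwise
#' R2 to decrease (negative slope); the direction is reported, not enforced.
#'
#' @param stats a \code{pairwise_stat_matrix} or symmetric statistic matrix.
#' @param dist symmetric distance matrix (km) over the same sites (a
#'   \code{list(km = ...)} from [load_fixture_table()] also works).
#' @return list with \code{slope}, \code{intercept}, \code{p_value},
#'   \code{r2}, \code{n_pairs}.
#' @export
distance_decay <- function(stats, dist) {
  smat <- if (inherits(stats, "pairwise_stat_matrix")) stats$values else stats
  dmat <- if (is.list(dist) && !is.null(dist$km)) dist$km else dist
  if (!identical(dim(smat), dim(dmat)))
    stop("statistic and distance matrices cover different site sets")
  if (!is.null(rownames(smat)) && !is.null(rownames(dmat)) &&
      !identical(rownames(smat), rownames(dmat)))
    stop("statistic and distance matrices have mismatched site ordering")
  y <- pair_values(smat)
  x <- pair_values(dmat)
  ok <- !is.na(y) & !is.na(x)
  fit <- lm(y[ok] ~ x[ok])
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       p_value = unname(sm$coefficients[2L, 4L]),
       r2 = sm$r.squared,
       n_pairs = sum(ok))
}

#' Spatial weight matrix for Moran's I
#'
#' @param sites data.frame with \code{site_id}, \code{lat}, \code{lon}.
#' @param scheme \code{"inverse_distance"} (1/d, zero diagonal) or
#'   \code{"k_nearest"} (binary, k nearest neighbours).
#' @param k neighbours for the k-nearest scheme.
#' @return square weight matrix (not yet row-standardised).
#' @export
spatial_weights <- function(sites, scheme = c("inverse_distance",
                                              "k_nearest"), k = 4L) {
  scheme <- match.arg(scheme)
  d <- distance_matrix(sites)
  n <- nrow(d)
  w <- matrix(0, n, n, dimnames = dimnames(d))
  if (scheme == "inverse_distance") {
    off <- d > 0
    w[off] <- 1 / d[off]
  } else {
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1L)]
      w[i, nb] <- 1
    }
  }
  w
}

#' Global Moran's I with permutation p-value
#'
#' \deqn{I = \frac{n}{S_0}\frac{\sum_i\sum_j w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with z the mean-centred values and \eqn{S_0} the sum of weights. Weights
#' are row-standardised before use. The p-value comes from random
#' permutations of the values over sites; the default alternative is
#' \code{"greater"} (spatial clustering).
#'
#' @param values per-site scalars (at least 4, not all equal).
#' @param weights explicit square weight matrix, or NULL to build one from
#'   \code{sites}.
#' @param sites site table for [spatial_weights()] when \code{weights} is
#'   NULL.
#' @param scheme,k passed to [spatial_weights()].
#' @param n_permutations number of random permutations.
#' @param seed optional RNG seed for the permutation test.
#' @param alternative \code{"greater"}, \code{"less"} or \code{"two.sided"}.
#' @return list with \code{statistic}, \code{expectation} (-1/(n-1)),
#'   \code{p_value}, \code{n_permutations}.
#' @export
morans_i <- function(values, weights = NULL, sites = NULL,
                     scheme = c("inverse_distance", "k_nearest"), k = 4L,
                     n_permutations = 999L, seed = NULL,
                     alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 4L) stop("Moran's I needs at least 4 sites")
  if (var(values) == 0) stop("Moran's I undefined for constant values")
  if (is.null(weights)) {
    if (is.null(sites)) stop("supply either weights or sites")
    weights <- spatial_weights(sites, match.arg(scheme), k)
  }
  stopifnot(is.matrix(weights), nrow(weights) == n, ncol(weights) == n)
  diag(weights) <- 0
  rs <- rowSums(weights)
  if (any(rs == 0)) stop("every site needs at least one positive weight")
  w <- weights / rs

  stat <- function(v) {
    z <- v - mean(v)
    n / sum(w) * as.numeric(z %*% w %*% z) / sum(z^2)
  }
  obs <- stat(values)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(i) stat(sample(values)), numeric(1))
  p <- switch(alternative,
    greater = (1 + sum(perm >= obs)) / (n_permutations + 1),
    less = (1 + sum(perm <= obs)) / (n_permutations + 1),
    two.sided = {
      e <- -1 / (n - 1)
      (1 + sum(abs(perm - e) >= abs(obs - e))) / (n_permutations + 1)
    })
  list(statistic = obs, expectation = -1 / (n - 1), p_value = p,
       n_permutations = n_permutations)
}

#' Compare PM2.5 between two groups of sites
#'
#' \code{"welch_t"} pools all values per group and applies the
#' unequal-variance two-sample t-test. \code{"wilcoxon_rank"} runs the
#' rank-sum test for every cross pair of sites between the two groups (one
#' series per site) and reports per-pair p-values (raw, with a Holm-adjusted
#' column) and mean differences.
#'
#' @param series_by_site named list of data.frames with \code{pm25} (times
#'   are not needed; values are pooled).
#' @param groups list with components \code{a} and \code{b}: character
#'   vectors of site names (e.g. EJ and non-EJ sites).
#' @param test \code{"welch_t"} or \code{"wilcoxon_rank"}.
#' @return For welch: list with \code{test}, \code{statistic},
#'   \code{p_value}, \code{mean_difference} (a minus b), \code{n_a},
#'   \code{n_b}. For wilcoxon: data.frame with one row per cross pair:
#'   \code{site_a}, \code{site_b}, \code{statistic}, \code{p_value},
#'   \code{p_holm}, \code{mean_difference}.
#' @export
group_test <- function(series_by_site, groups,
                       test = c("welch_t", "wilcoxon_rank")) {
  test <- match.arg(test)
  stopifnot(is.list(groups), all(c("a", "b") %in% names(groups)),
            length(groups$a) >= 1L, length(groups$b) >= 1L)
  get_vals <- function(s) {
    v <- series_by_site[[s]]$pm25
    v[!is.na(v)]
  }
  if (test == "welch_t") {
    va <- unlist(lapply(groups$a, get_vals))
    vb <- unlist(lapply(groups$b, get_vals))
    if (length(va) < 2L || length(vb) < 2L)
      stop("each group needs at least 2 values")
    tt <- t.test(va, vb, var.equal = FALSE)
    list(test = "welch_t", statistic = unname(tt$statistic),
         p_value = tt$p.value, mean_difference = mean(va) - mean(vb),
         n_a = length(va), n_b = length(vb))
  } else {
    rows <- list()
    for (sa in groups$a) {
      for (sb in groups$b) {
        va <- get_vals(sa); vb <- get_vals(sb)
        if (length(va) < 2L || length(vb) < 2L)
          stop("each site needs at least 2 values for the rank test")
        wt <- suppressWarnings(wilcox.test(va, vb))
        rows[[paste(sa, sb)]] <- data.frame(
          site_a = sa, site_b = sb,
          statistic = unname(wt$statistic), p_value = wt$p.value,
          mean_difference = mean(va) - mean(vb))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
    out
  }
}

#' Exact two-sided rank-sum p-value by enumeration
#'
#' Brute-force enumeration of all assignments of ranks to the first group,
#' giving the exact two-sided p-value of the Wilcoxon rank-sum statistic for
#' small samples (no ties). Used as an independent oracle for
#' [group_test()]'s rank comparison.
#'
#' @param x,y numeric samples without ties across groups.
#' @return exact two-sided p-value.
#' @export
rank_sum_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(nx + ny, nx)
  sums <- colSums(combs)
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
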