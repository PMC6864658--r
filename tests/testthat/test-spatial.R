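test_that("COD matches hand values and its boundary cases", {
  expect_equal(as.numeric(cod_pair(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(cod_pair(c(1, 3), c(3, 1))), 0.5)
  expect_equal(as.numeric(cod_pair(c(0, 0, 0), c(2, 5, 9))), 1)
  # zero-sum pairs are skipped and counted
  v <- cod_pair(c(0, 1, 3), c(0, 3, 1))
  expect_equal(as.numeric(v), 0.5)
  expect_equal(attr(v, "n_skipped"), 1L)
  expect_equal(attr(v, "n"), 2L)
  expect_warning(out <- cod_pair(c(0), c(0)), "insufficient")
  expect_true(is.na(out))
  # negative values (possible after correction) are excluded, keeping the
  # statistic inside [0, 1]
  v <- cod_pair(c(-2, 6, 9), c(5, 6, 9))
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "n_skipped"), 1L)
})

test_that("COD agrees with the loop oracle and is bounded and symmetric", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- runif(n, 0, 30)
    y <- runif(n, 0, 30)
    v <- as.numeric(cod_pair(x, y))
    expect_equal(v, cod_oracle(x, y), tolerance = 1e-12)
    expect_equal(v, as.numeric(cod_pair(y, x)), tolerance = 1e-15)
    expect_gte(v, 0); expect_lte(v, 1)
    # scale sensitivity: COD(x, c x) > 0 for c != 1
    expect_gt(as.numeric(cod_pair(x, 2.5 * x)), 0)
  }
})

test_that("pairwise matrices are symmetric and order-invariant", {
  set.seed(22)
  base <- runif(120, 3, 25)
  series <- list(A = make_hourly(base + rnorm(120)),
                 B = make_hourly(base * 1.3 + rnorm(120)),
                 C = make_hourly(base * 0.8 + rnorm(120)))
  m <- pairwise_matrix(series, "cod", "hourly", min_overlap = 50)
  expect_true(isSymmetric(m$values))
  expect_true(all(diag(m$values) == 0))
  m2 <- pairwise_matrix(series[c("C", "A", "B")], "cod", "hourly",
                        min_overlap = 50)
  expect_equal(m$values[c("A", "B", "C"), c("A", "B", "C")],
               m2$values[c("A", "B", "C"), c("A", "B", "C")])

  # all sites sharing one series: r2 all 1, cod all 0
  same <- list(A = make_hourly(base), B = make_hourly(base),
               C = make_hourly(base))
  expect_true(all(pairwise_matrix(same, "r2", "hourly",
                                  min_overlap = 50)$values == 1))
  expect_true(all(pairwise_matrix(same, "cod", "hourly",
                                  min_overlap = 50)$values == 0))
})

test_that("homogeneity classification uses the 0.2 threshold boundary", {
  m <- matrix(c(0, 0.19, 0.20,
                0.19, 0, 0.25,
                0.20, 0.25, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cls <- classify_homogeneity(m)
  lab <- setNames(cls$pairs$label, paste(cls$pairs$site_a, cls$pairs$site_b))
  expect_identical(lab[["A B"]], "homogeneous")      # 0.19
  expect_identical(lab[["A C"]], "heterogeneous")    # 0.20 boundary
  expect_equal(cls$fraction_heterogeneous, 2 / 3)

  # daily campaign matrix: label counts agree with a direct threshold count
  # (several printed entries sit exactly on the 0.20 boundary)
  fx <- load_fixture_table("pairwise_cod")
  daily <- classify_homogeneity(fx$daily)
  expect_equal(sum(daily$pairs$label == "homogeneous"),
               sum(pair_values(fx$daily) < 0.2))
  expect_lt(daily$fraction_heterogeneous, 0.15)
  r2 <- pairwise_matrix(list(A = make_hourly(1:100), B = make_hourly(1:100)),
                        "r2", "hourly", min_overlap = 50)
  expect_error(classify_homogeneity(r2), "COD matrix")
})

test_that("haversine distance matches spherical geometry", {
  expect_equal(haversine_km(c(10, 20), c(10, 20)), 0)
  expect_equal(haversine_km(c(0, 0), c(1, 0)), 2 * pi * 6371 / 360,
               tolerance = 1e-4)
  expect_equal(haversine_km(c(0, 0), c(0, 180)), pi * 6371,
               tolerance = 1e-4)
  expect_error(haversine_km(c(91, 0), c(0, 0)), "invalid")
})

test_that("pairwise statistics decay with distance on the fixtures", {
  d <- load_fixture_table("distances")
  cod <- load_fixture_table("pairwise_cod")
  r2 <- load_fixture_table("pairwise_r2")
  dc <- distance_decay(cod$hourly, d)
  expect_gt(dc$slope, 0)
  expect_lt(dc$p_value, 0.001)
  dr <- distance_decay(r2$hourly, d)
  expect_lt(dr$slope, 0)
  # constant statistic -> zero slope
  const <- matrix(0.5, 15, 15, dimnames = dimnames(d$km))
  expect_equal(suppressWarnings(distance_decay(const, d)$slope), 0,
               tolerance = 1e-12)
})

test_that("Moran's I reproduces hand-computed configurations", {
  # two same-valued pairs, each site's only neighbour its partner
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- w[3, 4] <- w[4, 3] <- 1
  res <- morans_i(c(1, 1, -1, -1), weights = w, n_permutations = 99,
                  seed = 1)
  expect_equal(res$statistic, 1)
  # alternating ring with adjacent neighbours
  ring <- matrix(0, 4, 4)
  for (i in 1:4) {
    ring[i, (i %% 4) + 1] <- 1
    ring[(i %% 4) + 1, i] <- 1
  }
  res <- morans_i(c(1, -1, 1, -1), weights = ring, n_permutations = 99,
                  seed = 1)
  expect_equal(res$statistic, -1)
  expect_error(morans_i(rep(1, 4), weights = w), "constant")
})

test_that("Moran's I matches the double-loop oracle on random instances", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    vals <- rnorm(n)
    w <- matrix(runif(n * n, 0.01, 1), n, n)
    diag(w) <- 0
    res <- morans_i(vals, weights = w, n_permutations = 9, seed = i)
    expect_equal(res$statistic, morans_oracle(vals, w), tolerance = 1e-12)
  }
})

test_that("Moran permutation p-values are calibrated under the null", {
  set.seed(24)
  n <- 8
  w <- matrix(runif(n * n, 0.1, 1), n, n); diag(w) <- 0
  p <- replicate(200, morans_i(rnorm(n), weights = w,
                               n_permutations = 199)$p_value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})

test_that("group comparisons: Welch pooling and exact rank-sum", {
  a <- make_hourly(c(4, 7, 9, 12, 5, 8), "A")
  b <- make_hourly(c(4, 7, 9, 12, 5, 8), "B")
  res <- group_test(list(A = a, B = b), list(a = "A", b = "B"), "welch_t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_difference, 0)

  w <- group_test(list(A = make_hourly(c(1, 2, 3)),
                       B = make_hourly(c(4, 5, 6))),
                  list(a = "A", b = "B"), "wilcoxon_rank")
  expect_equal(w$p_value, 0.1)
  expect_equal(w$p_value, rank_sum_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(w$mean_difference, -3)
})

test_that("rank-sum p-values match enumeration for small samples", {
  set.seed(25)
  for (i in 1:25) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)     # continuous, ties a.s. absent
    p_pkg <- group_test(list(A = make_hourly(x), B = make_hourly(y)),
                        list(a = "A", b = "B"), "wilcoxon_rank")$p_value
    expect_equal(p_pkg, rank_sum_exact_p(x, y), tolerance = 1e-12)
  }
})
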