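test_that("weighted moments match hand-computed values", {
  m <- weighted_moments(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$sd, sqrt(2 / 3))
  expect_equal(m$skewness, 0)

  # brute-force moment sums for (0,0,0,1), equal weights:
  # mu = 1/4, var = 3/16, third moment = 3/32
  m2 <- weighted_moments(c(0, 0, 0, 1))
  expect_equal(m2$mean, 0.25)
  expect_equal(m2$sd, sqrt(3) / 4)
  expect_equal(m2$skewness, (3 / 32) / (sqrt(3) / 4)^3)
  expect_equal(m2$skewness, 1.1547005, tolerance = 1e-7)

  m3 <- weighted_moments(rep(5, 4))
  expect_equal(m3$sd, 0)
  expect_true(is.na(m3$skewness))
})

test_that("weighted quantile reduces to the type-7 sample quantile", {
  expect_equal(weighted_quantile(c(1, 2, 3, 4), q = 0.5), 2.5)
  expect_equal(weighted_quantile(c(1, 2, 3, 4), q = 0.75), 3.25)
  expect_equal(weighted_quantile(c(1, 2, 3, 4), q = 0), 1)
  expect_equal(weighted_quantile(c(1, 2, 3, 4), q = 1), 4)
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(2:40, 1))
    q <- runif(5)
    expect_equal(weighted_quantile(x, q = q),
                 unname(quantile(x, q, type = 7)), tolerance = 1e-12)
  }
})

test_that("weighted quantile honours unequal weights", {
  # the weighted CDF's knots are interpolation fixed points: evaluating at
  # p_i = (c_i - w_i) / (c_n - w_n) returns the i-th sorted value
  set.seed(13)
  x <- sort(rnorm(12))
  w <- runif(12, 0.2, 1)
  w <- w / sum(w)
  cw <- cumsum(w)
  p <- (cw - w) / (cw[12] - w[12])
  expect_equal(weighted_quantile(x, w, q = p), x, tolerance = 1e-12)
  # quantiles are monotone in q and weight mass drags the median
  qs <- weighted_quantile(x, w, q = seq(0, 1, 0.05))
  expect_true(all(diff(qs) >= 0))
  heavy <- c(0.9, rep(0.1 / 11, 11))
  expect_lt(weighted_quantile(x, heavy, q = 0.5),
            weighted_quantile(x, w, q = 0.5) + 1e-12)
})

test_that("sum of squares is volume-weighted and scales quadratically", {
  expect_equal(sum_of_squares(c(1, 2, 3)), 14 / 3)
  expect_equal(sum_of_squares(c(0, 0)), 0)
  x <- c(0.3, 0.8, 1.4)
  expect_equal(sum_of_squares(3 * x), 9 * sum_of_squares(x))
  expect_equal(sum_of_squares(c(1, 2, 3), weighted = FALSE), 14)
})

test_that("modal bin mass picks the heaviest intensity interval", {
  spec <- histogram_spec(0.1, c(0, 0.2))
  expect_equal(max_bin_weight(c(0.05, 0.15, 0.16), spec = spec), 2 / 3)
  expect_equal(max_bin_weight(rep(0.5, 10), spec = histogram_spec(0.1)), 1)
  # adding a near-zero-weight voxel barely changes the result
  expect_equal(
    max_bin_weight(c(0.05, 0.15, 0.16, 0.9), c(1, 1, 1, 1e-12) / (3 + 1e-12),
                   spec = spec),
    2 / 3, tolerance = 1e-9
  )
})

test_that("KS distance matches the closed form for a two-point sample", {
  expect_equal(ks_distance(c(-1, 1)), pnorm(1) - 0.5, tolerance = 1e-12)
  expect_equal(ks_distance(c(-1, 1)), 0.3413447, tolerance = 1e-6)
})

test_that("KS distance agrees with the brute-force oracle", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    x <- switch(1 + i %% 3,
                rnorm(n),
                rexp(n),
                sample(1:5, n, replace = TRUE) + rnorm(n, sd = 0.01))
    w <- if (i %% 2 == 0) NULL else {
      raw <- runif(n, 0.1, 1)
      raw / sum(raw)
    }
    if (weighted_moments(x, w)$sd == 0) next
    expect_equal(ks_distance(x, w), ks_oracle(x, w), tolerance = 1e-12)
  }
})

test_that("KS distance of a large Gaussian sample is small", {
  set.seed(5)
  expect_lt(ks_distance(rnorm(1e5)), 0.01)
})

test_that("KS distance approaches 0.5 from below in the two-point limit", {
  # two central atoms plus vanishing far-out mass: the outliers inflate the
  # fitted sigma until both atoms sit at the Gaussian's centre, where the
  # ECDF jump of 1/2 straddles Phi = 1/2
  eps <- 1e-3
  d_prev <- 0
  for (M in c(1e2, 1e3, 1e4)) {
    w <- c((1 - eps) / 2, (1 - eps) / 2, eps / 2, eps / 2)
    d <- ks_distance(c(-1, 1, -M, M), w)
    expect_lt(d, 0.5)
    expect_gt(d, d_prev)
    d_prev <- d
  }
  expect_gt(d_prev, 0.49)
})

test_that("degenerate distributions are rejected by ks_distance", {
  expect_error(ks_distance(c(2, 2, 2)), "degenerate")
})

test_that("standard error composes sd and voxel count", {
  expect_equal(standard_error(c(1, 2, 3)), sqrt(2 / 3) / sqrt(3))
  x <- c(1, 4, 2, 8)
  expect_equal(standard_error(c(x, x)), standard_error(x) / sqrt(2))
  expect_equal(standard_error(rep(3, 5)), 0)
})

test_that("index set aggregates all eight indices consistently", {
  set.seed(3)
  x <- rnorm(500, 1, 0.2)
  s <- region_sample(matrix(0, 500, 3), x)
  iset <- compute_index_set(s)
  expect_named(unclass(iset)[],
               c("std", "sem", "median", "sum_sq", "p75", "max_bin_weight",
                 "skewness", "ks_distance"))
  expect_equal(iset$std, weighted_moments(x)$sd)
  expect_equal(iset$sem, iset$std / sqrt(500))
  expect_gte(iset$p75, iset$median)
  expect_true(iset$max_bin_weight >= 0 && iset$max_bin_weight <= 1)
  # Gaussian sample: near-symmetric and near-Gaussian
  expect_lt(abs(iset$skewness), 0.25)
  expect_lt(iset$ks_distance, 0.06)
})

test_that("indices are invariant under voxel permutation", {
  set.seed(9)
  x <- rexp(64)
  w <- runif(64, 0.5, 2)
  w <- w / sum(w)
  p <- sample(64)
  s1 <- region_sample(matrix(rnorm(64 * 3), 64, 3), x, w)
  s2 <- region_sample(s1$positions[p, ], x[p], w[p])
  expect_equal(unlist(compute_index_set(s1)), unlist(compute_index_set(s2)),
               tolerance = 1e-12)
})

test_that("a constant region yields zero spread and NA shape indices", {
  s <- region_sample(matrix(0, 6, 3), rep(0.4, 6))
  iset <- compute_index_set(s)
  expect_equal(iset$std, 0)
  expect_equal(iset$sem, 0)
  expect_true(is.na(iset$skewness))
  expect_true(is.na(iset$ks_distance))
  expect_equal(iset$max_bin_weight, 1)
})
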