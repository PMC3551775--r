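test_that("one-way ANOVA reproduces the hand sum-of-squares example", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- one_way_compare(v, g, test = "one_way_anova")
  expect_equal(res$statistic, 3, tolerance = 1e-12)
  expect_equal(res$p_value, 0.125, tolerance = 1e-10)
  # identical groups: no between-group variance
  v0 <- rep(c(1, 2, 3), 3)
  res0 <- one_way_compare(v0, g, test = "one_way_anova")
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1, tolerance = 1e-12)
})

test_that("parametric F and Kruskal-Wallis H match brute-force oracles", {
  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    sizes <- sample(4:9, k, replace = TRUE)
    g <- rep(letters[1:k], sizes)
    v <- rnorm(sum(sizes), mean = rep(runif(k, 0, 2), sizes))
    if (i %% 3 == 0) v <- round(v)  # force ties for the tie correction
    if (length(unique(v)) < 2) next
    f <- one_way_compare(v, g, test = "one_way_anova")
    o <- anova_oracle(v, g)
    expect_equal(f$statistic, o$F, tolerance = 1e-10)
    expect_equal(f$p_value, o$p, tolerance = 1e-10)
    h <- one_way_compare(v, g, test = "kruskal_wallis_dunn")
    expect_equal(h$statistic, kw_oracle(v, g), tolerance = 1e-10)
  }
})

test_that("the two-sample rank branch matches a hand rank-sum computation", {
  v <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b"), each = 3)
  res <- one_way_compare(v, g, test = "kruskal_wallis_dunn")
  expect_equal(res$statistic, kw_oracle(v, g), tolerance = 1e-12)
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)
})

test_that("test selection follows the normality and variance gates", {
  # for Gaussian equal-variance groups the residual-normality and Levene
  # gates each pass with probability 1 - alpha, so the parametric branch is
  # selected at a rate near (1 - 0.05)^2 = 0.9025
  set.seed(41)
  picks <- replicate(200, {
    v <- rnorm(48)
    g <- rep(c("a", "b", "c"), each = 16)
    as.character(choose_test(v, g))
  })
  expect_gte(mean(picks == "one_way_anova"), 0.85)
  # a blatantly heavy-tailed group forces the rank branch most of the time
  set.seed(42)
  picks2 <- replicate(100, {
    v <- c(rnorm(16), rnorm(16), rcauchy(16, scale = 5))
    g <- rep(c("a", "b", "c"), each = 16)
    as.character(choose_test(v, g))
  })
  expect_gte(mean(picks2 == "kruskal_wallis_dunn"), 0.8)
})

test_that("groups below three observations are rejected", {
  expect_error(choose_test(c(1, 2, 3, 4, 5), c("a", "a", "a", "b", "b")),
               "insufficient")
})

test_that("Dunn post-hoc z matches a hand computation with ties", {
  v <- c(1, 2, 2, 5, 6, 7, 10, 11, 12)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- one_way_compare(v, g, test = "kruskal_wallis_dunn", alpha = 0.5)
  ph <- res$posthoc
  expect_equal(nrow(ph), 3)
  # hand: midranks 1, 2.5, 2.5, 4..9; tie term sum(t^3-t)/(12(N-1)) with
  # one tie of size 2
  r <- rank(v)
  N <- 9
  varfac <- N * (N + 1) / 12 - (2^3 - 2) / (12 * (N - 1))
  z_ab <- (mean(r[1:3]) - mean(r[4:6])) / sqrt(varfac * (2 / 3))
  got <- ph$z[ph$group1 == "a" & ph$group2 == "b"]
  expect_equal(got, z_ab, tolerance = 1e-12)
  expect_equal(ph$p_value, pmin(1, ph$p_unadjusted * 3))
})

test_that("two-way ANOVA separates severity from pathology effects", {
  set.seed(51)
  hits <- replicate(40, {
    A <- rep(c("scoliosis", "spondylolisthesis"), each = 32)
    B <- rep(rep(c("low", "high"), each = 16), 2)
    v <- rnorm(64) + 2 * (B == "high")  # 2-sigma severity shift only
    res <- two_way_compare(v, A, B, test = "two_way_anova")
    c(sev = res$effects$p[2] < 0.05, path = res$effects$p[1] < 0.05)
  })
  expect_gte(mean(hits["sev", ]), 0.95)
  expect_lt(mean(hits["path", ]), 0.3)
})

test_that("two-way contracts: empty cells error, identical cells give F=0", {
  A <- c("x", "x", "x", "y", "y", "y")
  B <- c("l", "l", "l", "l", "l", "h")
  expect_error(two_way_compare(rnorm(6), A, B), "empty cell")
  A2 <- rep(c("x", "y"), each = 6)
  B2 <- rep(rep(c("l", "h"), each = 3), 2)
  v2 <- rep(1:3, 4)  # every cell identical
  res <- two_way_compare(v2, A2, B2, test = "two_way_anova")
  expect_equal(res$effects$F, c(0, 0, 0))
  expect_equal(res$effects$p, c(1, 1, 1))
})

test_that("rank transform is idempotent on data equal to their ranks", {
  set.seed(61)
  v <- sample(1:24)
  A <- rep(c("x", "y"), each = 12)
  B <- rep(rep(c("l", "h"), each = 6), 2)
  r1 <- two_way_compare(v, A, B, test = "rank_two_way_anova")
  r2 <- two_way_compare(v, A, B, test = "two_way_anova")
  expect_equal(r1$effects$F, r2$effects$F, tolerance = 1e-12)
})

make_cohort <- function(n_per = 8, effect = 0, index = "std", seed = 1) {
  set.seed(seed)
  groups <- c("control", "scoliosis", "spondylolisthesis")
  rows <- list()
  id <- 0
  for (g in groups) {
    sev <- if (g == "control") rep("none", n_per)
           else rep(c("low", "high"), length.out = n_per)
    for (i in seq_len(n_per)) {
      id <- id + 1
      val <- rnorm(1) + if (g != "control") effect else 0
      rows[[id]] <- data.frame(
        subject_id = sprintf("S%03d", id), group = g, severity = sev[i],
        region = "AF", normalization = "csf", index = index, value = val,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

test_that("significance report flags a built-in effect and stays quiet under the null", {
  rep_eff <- significance_report(make_cohort(n_per = 16, effect = 2, seed = 5))
  pv <- attr(rep_eff, "p_values")
  cs <- pv[pv$comparison == "control/scoliosis", ]
  expect_true(nrow(cs) == 1 && cs$p_value < 0.05)
  # null cohorts: flagged-cell fraction compatible with the 5% level
  set.seed(71)
  flags <- replicate(60, {
    r <- significance_report(make_cohort(n_per = 8, effect = 0,
                                         seed = sample.int(1e6, 1)))
    pv <- attr(r, "p_values")
    any(pv$p_value < 0.05, na.rm = TRUE)
  })
  expect_lt(mean(flags), 0.35)  # loose binomial bound at 60 replicates
})

test_that("empty cohorts produce an empty report without error", {
  r <- significance_report(data.frame())
  expect_s3_class(r, "amrsid_report")
  expect_equal(nrow(r), 0L)
  expect_output(print(r), "empty")
})
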