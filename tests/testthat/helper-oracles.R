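# Independent brute-force oracles used to cross-check the implementation.

# Sup-difference between the weighted ECDF and the moment-fitted Gaussian,
# evaluated on a dense grid plus both sides of every sample point.
ks_oracle <- function(v, w = NULL) {
  n <- length(v)
  if (is.null(w)) w <- rep(1 / n, n)
  w <- w / sum(w)
  mu <- sum(w * v)
  s <- sqrt(sum(w * (v - mu)^2))
  ecdf_right <- function(x) vapply(x, function(t) sum(w[v <= t]), numeric(1))
  ecdf_left <- function(x) vapply(x, function(t) sum(w[v < t]), numeric(1))
  grid <- seq(min(v) - 4 * s, max(v) + 4 * s, length.out = 4001)
  max(
    abs(ecdf_right(grid) - pnorm(grid, mu, s)),
    abs(ecdf_right(v) - pnorm(v, mu, s)),
    abs(ecdf_left(v) - pnorm(v, mu, s))
  )
}

# Textbook one-way ANOVA F from explicit sums of squares.
anova_oracle <- function(values, group) {
  g <- factor(group)
  grand <- mean(values)
  means <- tapply(values, g, mean)
  sizes <- table(g)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[g])^2)
  dfb <- nlevels(g) - 1
  dfw <- length(values) - nlevels(g)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = pf(f, dfb, dfw, lower.tail = FALSE))
}

# Kruskal-Wallis H from midrank sums, with the tie correction.
kw_oracle <- function(values, group) {
  g <- factor(group)
  r <- rank(values)
  N <- length(r)
  sizes <- table(g)
  rsums <- tapply(r, g, sum)
  h <- 12 / (N * (N + 1)) * sum(rsums^2 / sizes) - 3 * (N + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / corr
}

# Tiny aligned volume/mask pair for contract tests.
tiny_pair <- function(dims = c(4, 4, 4), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  vol <- volume_grid(array(runif(prod(dims), 50, 150), dims),
                     spacing = spacing)
  labels <- array(0L, dims)
  labels[2:3, 2:3, 2:3] <- 1L  # bare IVD
  labels[2, 2, 2] <- 2L        # one NP voxel
  labels[1, 1, 1] <- 4L        # CSF
  labels[4, 4, 4] <- 5L        # BONE
  list(volume = vol, mask = label_mask(labels))
}
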