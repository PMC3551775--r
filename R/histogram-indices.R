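#' Histogram binning specification
#'
#' Binning is used only by the modal-bin-mass index ([max_bin_weight()]);
#' all other indices operate on raw voxel values. The default bin width of
#' 0.01 normalized-intensity units over `(0, max)` resolves about 100 bins
#' across a typical CSF-normalized disc.
#'
#' @param bin_width Positive bin width in normalized-intensity units.
#' @param range Length-2 `(lo, hi)` with `hi > lo`, or `NULL` for
#'   `(0, max(values))`.
#' @return An object of class `histogram_spec`.
#' @export
histogram_spec <- function(bin_width = 0.01, range = NULL) {
  if (!is_scalar_num(bin_width) || bin_width <= 0) {
    stopf("bin_width must be a positive scalar")
  }
  if (!is.null(range)) {
    if (length(range) != 2L || !all(is.finite(range)) || range[2] <= range[1]) {
      stopf("range must be (lo, hi) with hi > lo")
    }
  }
  structure(list(bin_width = bin_width, range = range),
            class = "histogram_spec")
}

resolve_weights <- function(values, weights) {
  n <- length(values)
  if (n < 1L) stopf("at least one value required")
  if (is.null(weights)) return(rep(1 / n, n))
  if (length(weights) != n) stopf("weights length must match values")
  if (any(weights <= 0)) stopf("all weights must be positive")
  weights / sum(weights)
}

#' Volume-weighted mean, standard deviation and skewness
#'
#' Population-convention weighted moments: mean `sum(w*x)`, standard
#' deviation `sqrt(sum(w*(x-mu)^2))` and skewness
#' `sum(w*(x-mu)^3) / sd^3`. With zero variance the skewness is undefined
#' and returned as `NA` (never coerced to 0), which propagates as a missing
#' value into cohort tables.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, normalized internally; `NULL` for equal.
#' @return List with elements `mean`, `sd`, `skewness`.
#' @export
#' @examples
#' weighted_moments(c(0, 0, 0, 1))  # mean 0.25, sd sqrt(3)/4, skew 2/sqrt(3)
weighted_moments <- function(values, weights = NULL) {
  w <- resolve_weights(values, weights)
  mu <- sum(w * values)
  v <- sum(w * (values - mu)^2)
  s <- sqrt(v)
  skew <- if (s > 0) sum(w * (values - mu)^3) / s^3 else NA_real_
  list(mean = mu, sd = s, skewness = skew)
}

#' Weighted quantile of the intensity distribution
#'
#' Linear interpolation of the weighted empirical CDF at plotting positions
#' `p_i = (c_i - w_i) / (c_n - w_n)` (sorted values, cumulative weights
#' `c_i`), which for equal weights reduces exactly to the standard
#' linear-interpolated sample quantile (type 7). `q = 0` and `q = 1` return
#' the minimum and maximum.
#'
#' @param values Numeric vector.
#' @param weights Positive weights or `NULL` for equal.
#' @param q Quantile level(s) in `[0, 1]`.
#' @return Numeric vector of quantiles, one per `q`.
#' @export
#' @examples
#' weighted_quantile(1:4, q = 0.75)  # 3.25, as quantile(1:4, 0.75)
weighted_quantile <- function(values, weights = NULL, q) {
  if (any(q < 0 | q > 1)) stopf("q must lie in [0, 1]")
  w <- resolve_weights(values, weights)
  ord <- order(values)
  x <- values[ord]
  w <- w[ord]
  n <- length(x)
  if (n == 1L) return(rep(x, length(q)))
  cw <- cumsum(w)
  p <- (cw - w) / (cw[n] - w[n])
  approx(p, x, xout = q, rule = 2, ties = "ordered")$y
}

#' Volume-weighted sum of squared intensities
#'
#' `sum(w * x^2)`. Weighting keeps the index independent of voxel count, in
#' line with the volume-fraction normalization; the raw unweighted sum is
#' available with `weighted = FALSE`. On T2-weighted discs this index
#' tracks the bright, water-rich signal mass and falls as the nucleus
#' dehydrates.
#'
#' @inheritParams weighted_moments
#' @param weighted If `FALSE`, return the plain `sum(x^2)`.
#' @return Scalar.
#' @export
sum_of_squares <- function(values, weights = NULL, weighted = TRUE) {
  if (!weighted) return(sum(values^2))
  w <- resolve_weights(values, weights)
  sum(w * values^2)
}

#' Modal histogram bin mass
#'
#' Maximum over histogram bins of the summed voxel volume fractions: the
#' fraction of region volume concentrated in the most populated intensity
#' interval. Bins are left-open/right-closed, `(lo + (k-1)*bw, lo + k*bw]`,
#' with values equal to `lo` assigned to the first bin; values outside the
#' requested range are excluded (the denominator stays the full region
#' volume).
#'
#' @inheritParams weighted_moments
#' @param spec A [histogram_spec()].
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' max_bin_weight(c(0.05, 0.15, 0.16),
#'   spec = histogram_spec(0.1, c(0, 0.2)))  # 2/3
max_bin_weight <- function(values, weights = NULL, spec = histogram_spec()) {
  stopifnot(inherits(spec, "histogram_spec"))
  w <- resolve_weights(values, weights)
  rng <- if (is.null(spec$range)) c(0, max(values)) else spec$range
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + spec$bin_width
  nbin <- ceiling((rng[2] - rng[1]) / spec$bin_width)
  k <- ceiling((values - rng[1]) / spec$bin_width)
  k[values >= rng[1] & k < 1L] <- 1L  # values exactly at lo
  keep <- k >= 1L & k <= nbin & values >= rng[1]
  if (!any(keep)) return(0)
  masses <- vapply(split(w[keep], k[keep]), sum, numeric(1))
  max(masses)
}

#' Kolmogorov-Smirnov distance to the fitted Gaussian
#'
#' Supremum over x of the absolute difference between the weighted empirical
#' CDF of the intensities and the CDF of a Gaussian fitted to the same data
#' by its volume-weighted mean and (population) standard deviation. The
#' supremum is attained at an ECDF step and is evaluated on both sides of
#' every step. A healthy disc's bimodal nucleus/annulus histogram sits far
#' from any single Gaussian (large distance); a degenerated, homogenised
#' disc approaches one (small distance).
#'
#' @inheritParams weighted_moments
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' ks_distance(c(-1, 1))  # pnorm(1) - 0.5 = 0.34134...
ks_distance <- function(values, weights = NULL) {
  if (length(values) < 2L) stopf("at least two values required")
  w <- resolve_weights(values, weights)
  mom <- weighted_moments(values, w)
  if (mom$sd <= 0) {
    stopf("degenerate distribution: zero variance, KS distance undefined")
  }
  ord <- order(values)
  x <- values[ord]
  w <- w[ord]
  # merge tied values into single ECDF steps
  grp <- cumsum(c(TRUE, diff(x) > 0))
  xs <- x[!duplicated(grp)]
  cw <- cumsum(vapply(split(w, grp), sum, numeric(1)))
  cw_lo <- c(0, cw[-length(cw)])
  z <- pnorm((xs - mom$mean) / mom$sd)
  max(abs(cw - z), abs(cw_lo - z))
}

#' Standard error of the mean intensity
#'
#' The volume-weighted population standard deviation divided by the square
#' root of the voxel count, `sd / sqrt(n)`.
#'
#' @inheritParams weighted_moments
#' @return Scalar.
#' @export
standard_error <- function(values, weights = NULL) {
  weighted_moments(values, weights)$sd / sqrt(length(values))
}

#' Compute the eight histogram indices for one region
#'
#' Aggregates the first-order descriptors of the normalized intensity
#' histogram: standard deviation, standard error of the mean, median, sum
#' of squared values, 75th percentile, modal bin mass, skewness and
#' Kolmogorov-Smirnov distance to the fitted Gaussian. For a degenerate
#' (zero-variance) region, skewness and KS distance are `NA`.
#'
#' @param x A `normalization_result` (preferred) or a bare
#'   [region_sample()] of already-normalized intensities.
#' @param spec A [histogram_spec()] for the modal-bin index.
#' @param sum_sq_weighted Use the volume-weighted sum of squares (default).
#' @return An object of class `index_set`: a list with elements `std`,
#'   `sem`, `median`, `sum_sq`, `p75`, `max_bin_weight`, `skewness`,
#'   `ks_distance`.
#' @export
#' @examples
#' s <- region_sample(matrix(0, 5, 3), c(0.2, 0.4, 0.5, 0.6, 0.9))
#' unlist(compute_index_set(s))
compute_index_set <- function(x, spec = histogram_spec(),
                              sum_sq_weighted = TRUE) {
  sample <- if (inherits(x, "normalization_result")) x$sample else x
  stopifnot(inherits(sample, "region_sample"))
  v <- sample$intensities
  w <- sample$weights
  mom <- weighted_moments(v, w)
  qs <- weighted_quantile(v, w, c(0.5, 0.75))
  ks <- if (mom$sd > 0) ks_distance(v, w) else NA_real_
  structure(
    list(
      std = mom$sd,
      sem = mom$sd / sqrt(sample$n),
      median = qs[1],
      sum_sq = sum_of_squares(v, w, weighted = sum_sq_weighted),
      p75 = qs[2],
      max_bin_weight = max_bin_weight(v, w, spec),
      skewness = mom$skewness,
      ks_distance = ks
    ),
    class = "index_set"
  )
}

#' @export
print.index_set <- function(x, ...) {
  cat("<index_set>\n")
  print(signif(unlist(x), 5))
  invisible(x)
}

# canonical column order shared by CSV output and cohort tables
index_names <- function() {
  c("std", "sem", "median", "sum_sq", "p75", "max_bin_weight",
    "skewness", "ks_distance")
}
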