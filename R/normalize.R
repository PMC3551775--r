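#' Volume-weighted mean intensity of a reference region
#'
#' The normalizing intensity is the mean signal of a tissue of constant
#' composition: cerebrospinal fluid, whose chemistry does not vary between
#' subjects, or the cancellous bone of the vertebra above the disc, which
#' additionally reflects bone remodelling. The mean is volume-weighted,
#' consistent with the voxel volume-fraction weighting used everywhere else;
#' on a uniform grid this equals the plain arithmetic mean.
#'
#' @param sample A [region_sample()] of the reference region (CSF or BONE).
#' @return Scalar mean intensity, in original units.
#' @export
#' @examples
#' csf <- region_sample(matrix(0, 2, 3), c(2, 4))
#' reference_mean(csf)  # 3
reference_mean <- function(sample) {
  stopifnot(inherits(sample, "region_sample"))
  m <- sum(sample$weights * sample$intensities)
  if (!is.finite(m) || m <= 0) {
    stopf("degenerate reference region '%s': mean intensity %s is not > 0",
          sample$region_name, format(m))
  }
  m
}

#' Normalize region intensities by a reference mean
#'
#' Second step of the two-step normalization: divide every voxel intensity
#' by the reference-tissue mean, cancelling acquisition gain and making
#' intensities dimensionless and comparable across subjects and scanners.
#' (The first step -- expressing each voxel as a fraction of the region
#' volume -- lives in the `weights` of the [region_sample()].) Negative
#' intensities, which can arise in synthetic data with additive noise but
#' not in magnitude MR images, are clipped to zero with a warning.
#'
#' @param sample A [region_sample()].
#' @param ref Positive scalar reference mean (see [reference_mean()]).
#' @param reference_kind One of `"csf"`, `"bone"`, `"none"`; metadata only.
#' @return An object of class `normalization_result`: the normalized
#'   `sample` plus `normalized_intensities`, `reference_kind` and
#'   `reference_mean`.
#' @export
#' @examples
#' s <- region_sample(matrix(0, 3, 3), c(2, 4, 6))
#' normalize_intensities(s, 2)$normalized_intensities  # 1 2 3
normalize_intensities <- function(sample, ref,
                                  reference_kind = c("none", "csf", "bone")) {
  stopifnot(inherits(sample, "region_sample"))
  reference_kind <- match.arg(reference_kind)
  if (!is_scalar_num(ref) || ref <= 0) {
    stopf("degenerate reference: normalizing intensity must be > 0, got %s",
          format(ref))
  }
  x <- sample$intensities
  neg <- x < 0
  if (any(neg)) {
    warning(sprintf("clipping %d negative intensity value(s) to 0 in '%s'",
                    sum(neg), sample$region_name), call. = FALSE)
    x[neg] <- 0
  }
  out <- sample
  out$intensities <- x / ref
  structure(
    list(sample = out, normalized_intensities = out$intensities,
         reference_kind = reference_kind, reference_mean = ref),
    class = "normalization_result"
  )
}

#' Normalize a region by a reference region
#'
#' Convenience wrapper: computes the reference mean and applies it.
#'
#' @param sample A [region_sample()] to normalize.
#' @param reference A [region_sample()] of the reference tissue, or `NULL`
#'   with `kind = "none"` for no normalization (reference mean 1).
#' @param kind `"csf"`, `"bone"` or `"none"`.
#' @return A `normalization_result`.
#' @export
normalize_region <- function(sample, reference = NULL,
                             kind = c("csf", "bone", "none")) {
  kind <- match.arg(kind)
  if (kind == "none") {
    return(normalize_intensities(sample, 1, "none"))
  }
  if (is.null(reference)) stopf("reference sample required for '%s'", kind)
  normalize_intensities(sample, reference_mean(reference), kind)
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("<normalization_result> '", x$sample$region_name, "' / ",
      x$reference_kind, " reference (mean ", signif(x$reference_mean, 6),
      ")\n", sep = "")
  invisible(x)
}
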