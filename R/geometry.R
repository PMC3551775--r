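#' Intensity-weighted centre of a region
#'
#' The centre of intensity `W = sum(I_i * P_i) / sum(I_i)` over the
#' region's voxels: each position is weighted by its MR signal. In a
#' healthy, symmetric disc W coincides with the geometric centre; nucleus
#' migration or asymmetric dehydration pulls it off-centre. W is invariant
#' under global intensity scaling, so it does not depend on the
#' normalization reference.
#'
#' @param sample A [region_sample()] or `normalization_result`.
#' @param use_weights Additionally weight by voxel volume fractions
#'   (relevant only off the uniform grid; default `FALSE`, the plain sum
#'   over points).
#' @return Length-3 numeric `(x, y, z)` in the sample's position units.
#' @export
#' @examples
#' s <- region_sample(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 3))
#' weighted_center(s)  # (0.75, 0, 0)
weighted_center <- function(sample, use_weights = FALSE) {
  if (inherits(sample, "normalization_result")) sample <- sample$sample
  stopifnot(inherits(sample, "region_sample"))
  wt <- if (use_weights) sample$intensities * sample$weights
        else sample$intensities
  s <- sum(wt)
  if (!is.finite(s) || s <= 0) {
    stopf("degenerate intensities in '%s': total intensity is not > 0",
          sample$region_name)
  }
  colSums(sample$positions * wt) / s
}

#' Geometric centre of a region
#'
#' Unweighted mean of the voxel-centre positions.
#'
#' @param sample A [region_sample()] or `normalization_result`.
#' @return Length-3 numeric `(x, y, z)`.
#' @export
geometric_center <- function(sample) {
  if (inherits(sample, "normalization_result")) sample <- sample$sample
  stopifnot(inherits(sample, "region_sample"))
  colMeans(sample$positions)
}

#' Normalized distance between weighted and geometric centres
#'
#' `d = |W - G| / N`, the Euclidean distance between the intensity-weighted
#' and geometric centres divided by the region's voxel count N. The
#' division tempers the effect of variable disc sizes; the index is
#' invariant under rigid motion of the coordinate frame and under global
#' intensity gain, and quantifies the undirected shift of signal mass away
#' from the region centre in a degenerating or scoliotic disc. Note the
#' literal division by a count makes the units resolution-dependent
#' (mm/voxel with millimetre positions); compare d only across matched
#' grids, or extract positions in voxel units.
#'
#' @inheritParams weighted_center
#' @return An object of class `center_pair` with elements `W`, `G`
#'   (3-vectors), `d` (scalar) and `N` (voxel count).
#' @export
#' @examples
#' s <- region_sample(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 3))
#' center_distance(s)$d  # 0.25 / 2 = 0.125
center_distance <- function(sample, use_weights = FALSE) {
  if (inherits(sample, "normalization_result")) sample <- sample$sample
  W <- weighted_center(sample, use_weights = use_weights)
  G <- geometric_center(sample)
  structure(
    list(W = W, G = G, d = sqrt(sum((W - G)^2)) / sample$n, N = sample$n),
    class = "center_pair"
  )
}

#' @export
print.center_pair <- function(x, ...) {
  cat("<center_pair> N = ", x$N, "\n", sep = "")
  cat("  W: ", paste(signif(x$W, 5), collapse = ", "), "\n", sep = "")
  cat("  G: ", paste(signif(x$G, 5), collapse = ", "), "\n", sep = "")
  cat("  d = |W - G| / N = ", signif(x$d, 6), "\n", sep = "")
  invisible(x)
}

#' Nucleus-to-disc volume ratio
#'
#' Ratio of the number of voxels in the segmented nucleus pulposus to the
#' number in the whole disc. A voxel-count ratio, integer-exact on a single
#' grid (voxel volumes cancel); it falls as the nucleus shrinks with
#' degeneration.
#'
#' @param np_sample [region_sample()] of the NP.
#' @param ivd_sample [region_sample()] of the whole IVD.
#' @return An object of class `volume_ratio` with elements `ratio`,
#'   `np_voxels`, `ivd_voxels`.
#' @export
volume_ratio <- function(np_sample, ivd_sample) {
  stopifnot(inherits(np_sample, "region_sample"),
            inherits(ivd_sample, "region_sample"))
  if (np_sample$n > ivd_sample$n) {
    stopf("containment violated: NP has %d voxels but IVD only %d",
          np_sample$n, ivd_sample$n)
  }
  structure(
    list(ratio = np_sample$n / ivd_sample$n,
         np_voxels = np_sample$n, ivd_voxels = ivd_sample$n),
    class = "volume_ratio"
  )
}

#' @export
print.volume_ratio <- function(x, ...) {
  cat("<volume_ratio> NP/IVD = ", x$np_voxels, "/", x$ivd_voxels, " = ",
      signif(x$ratio, 5), "\n", sep = "")
  invisible(x)
}
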