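#' Default region label map
#'
#' Package convention for mapping region names to integer codes in a label
#' mask. Codes are exclusive in the mask array; region membership is
#' hierarchical (see [extract_region()]): a voxel coded `NP` or `AF` also
#' belongs to the `IVD` region.
#'
#' @return Named integer vector with entries `IVD`, `NP`, `AF`, `CSF`,
#'   `BONE`.
#' @export
#' @examples
#' default_label_map()
default_label_map <- function() {
  c(IVD = 1L, NP = 2L, AF = 3L, CSF = 4L, BONE = 5L)
}

#' Construct a volume grid
#'
#' A `volume_grid` holds a 3D scalar intensity field sampled on a regular
#' acquisition grid, together with its voxel spacing (mm) and the 4x4 affine
#' mapping 0-based voxel indices (voxel centres) to world millimetres.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing Length-3 positive numeric, mm per voxel. Ignored when
#'   `affine` is supplied (spacing is then derived from the affine's column
#'   norms).
#' @param affine Optional 4x4 voxel-index-to-world transform; defaults to
#'   `diag(c(spacing, 1))`.
#' @return An object of class `volume_grid` with elements `data`, `spacing`,
#'   `affine`.
#' @export
#' @examples
#' v <- volume_grid(array(1:8, c(2, 2, 2)), spacing = c(0.7, 0.7, 3.3))
#' v$affine
volume_grid <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("volume data must be a 3D array, got %s dimension(s)",
          length(dim(data)))
  }
  if (is.null(affine)) {
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
      stopf("spacing must be 3 positive numbers")
    }
    affine <- diag(c(spacing, 1))
  } else {
    affine <- unclass(affine)
    attributes(affine) <- list(dim = dim(affine))
    if (!is.matrix(affine) || any(dim(affine) != c(4L, 4L))) {
      stopf("affine must be a 4x4 matrix")
    }
    d <- det(affine)
    if (!is.finite(d) || abs(d) < 1e-12) stopf("affine must be invertible")
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(spacing <= 0)) stopf("affine has a zero-length voxel axis")
  }
  structure(
    list(data = data, spacing = as.numeric(spacing), affine = affine),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range: [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' Display a mid-volume slice
#'
#' @param x A `volume_grid`.
#' @param slice Axial (third-axis) slice index; defaults to the middle slice.
#' @param ... Passed to [graphics::image()].
#' @export
plot.volume_grid <- function(x, slice = NULL, ...) {
  if (is.null(slice)) slice <- max(1L, round(dim(x$data)[3] / 2))
  graphics::image(
    x = seq_len(dim(x$data)[1]) * x$spacing[1],
    y = seq_len(dim(x$data)[2]) * x$spacing[2],
    z = x$data[, , slice],
    col = grDevices::gray.colors(128, start = 0, end = 1),
    xlab = "x [mm]", ylab = "y [mm]", asp = 1, ...
  )
  invisible(x)
}

# Drop trailing singleton dimensions (e.g. a 3D image stored as X x Y x Z x 1).
drop_trailing_ones <- function(a) {
  d <- dim(a)
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  dim(a) <- d
  a
}

#' Read a NIfTI volume
#'
#' Loads a NIfTI-1/2 image into a [volume_grid()]. The affine is taken from
#' the sform (preferred) or qform; spacing is derived from the affine.
#' Intensities are not rescaled or modified.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume_grid`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- drop_trailing_ones(as.array(img))
  if (length(dim(arr)) != 3L) {
    stopf("expected a 3D image, got %d dimensions in %s",
          length(dim(arr)), path)
  }
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  aff <- rbind(unclass(aff)[1:3, 1:4, drop = FALSE], c(0, 0, 0, 1))
  volume_grid(arr, affine = aff)
}

#' Write a NIfTI volume
#'
#' @param volume A `volume_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  img <- RNifti::asNifti(volume$data, pixdim = volume$spacing)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a label mask
#'
#' An integer mask aligned to a [volume_grid()], with one region code per
#' voxel (0 = background). Region semantics are hierarchical: voxels coded
#' `NP` or `AF` are also members of the `IVD` region, so the invariant
#' NP within IVD holds by construction; an explicit `IVD` code marks disc
#' voxels not attributed to either sub-zone.
#'
#' @param labels 3D integer array of region codes.
#' @param label_map Named integer vector mapping region names to codes; see
#'   [default_label_map()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, label_map = default_label_map()) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stopf("labels must be a 3D array")
  }
  storage.mode(labels) <- "integer"
  if (is.null(names(label_map)) || any(!nzchar(names(label_map)))) {
    stopf("label_map must be a named vector")
  }
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0L]
  unknown <- setdiff(present, as.integer(label_map))
  if (length(unknown)) {
    stopf("mask contains codes absent from label_map: %s",
          paste(unknown, collapse = ", "))
  }
  lm <- setNames(as.integer(label_map), names(label_map))
  structure(
    list(labels = labels, label_map = lm),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", paste(dim(x$labels), collapse = " x "), " voxels\n",
      sep = "")
  tab <- table(factor(x$labels[x$labels != 0L], levels = x$label_map,
                      labels = names(x$label_map)))
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], " voxels\n", sep = "")
  invisible(x)
}

#' Read a NIfTI label mask
#'
#' @param path Path to a NIfTI file of integer region codes.
#' @inheritParams label_mask
#' @return A `label_mask`.
#' @export
load_mask <- function(path, label_map = default_label_map()) {
  vol <- load_volume(path)
  label_mask(array(as.integer(round(vol$data)), dim(vol$data)), label_map)
}

#' Write a NIfTI label mask
#'
#' @param mask A `label_mask`.
#' @param path Output path.
#' @param spacing Voxel spacing (mm) for the written image.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(mask, "label_mask"))
  save_volume(volume_grid(mask$labels + 0, spacing = spacing), path)
}

# Integer codes whose voxels make up `region`, under hierarchical semantics.
# AF falls back to the bare-IVD code (disc minus NP) when no voxel carries an
# explicit AF code.
region_codes <- function(mask, region) {
  lm <- mask$label_map
  need <- function(nms) {
    nms <- intersect(nms, names(lm))
    if (!length(nms)) stopf("region '%s' is not in the label map", region)
    unname(lm[nms])
  }
  switch(region,
    IVD  = need(c("IVD", "NP", "AF")),
    NP   = need("NP"),
    AF   = {
      af_code <- if ("AF" %in% names(lm)) lm[["AF"]] else NA_integer_
      if (!is.na(af_code) && any(mask$labels == af_code)) {
        af_code
      } else {
        # derived annulus: disc voxels not labelled NP
        need("IVD")
      }
    },
    CSF  = need("CSF"),
    BONE = need("BONE"),
    stopf("unknown region '%s'", region)
  )
}

#' Construct a region sample directly
#'
#' Low-level constructor for a per-region sample: world positions,
#' intensities and per-voxel volume-fraction weights. Normally produced by
#' [extract_region()]; exposed for programmatic use and testing.
#'
#' @param positions n x 3 numeric matrix of voxel-centre coordinates (mm, or
#'   voxel indices when extracted with `units = "voxel"`).
#' @param intensities Numeric vector of length n.
#' @param weights Positive volume fractions summing to 1; defaults to
#'   uniform `1/n`.
#' @param region_name Region label carried along for reporting.
#' @return An object of class `region_sample` with elements `positions`,
#'   `intensities`, `weights`, `n`, `region_name`.
#' @export
region_sample <- function(positions, intensities, weights = NULL,
                          region_name = "region") {
  positions <- as.matrix(positions)
  if (is.vector(intensities)) intensities <- as.numeric(intensities)
  n <- length(intensities)
  if (n < 1L) stopf("region sample must contain at least one voxel")
  if (nrow(positions) != n || ncol(positions) != 3L) {
    stopf("positions must be an n x 3 matrix matching intensities")
  }
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stopf("weights length must match intensities")
  if (any(weights <= 0)) stopf("all weights must be positive")
  if (abs(sum(weights) - 1) > 1e-9) stopf("weights must sum to 1")
  colnames(positions) <- c("x", "y", "z")
  structure(
    list(positions = positions, intensities = intensities,
         weights = as.numeric(weights), n = n, region_name = region_name),
    class = "region_sample"
  )
}

#' @export
print.region_sample <- function(x, ...) {
  cat("<region_sample> '", x$region_name, "': ", x$n, " voxels\n", sep = "")
  cat("  intensity: [", signif(min(x$intensities), 5), ", ",
      signif(max(x$intensities), 5), "]\n", sep = "")
  invisible(x)
}

#' Extract a region sample from a volume and mask
#'
#' Collects the voxels carrying a region's code(s), maps their 0-based
#' indices through the volume affine to world coordinates (voxel-centre
#' convention) and attaches uniform volume-fraction weights (`1/n` each; on
#' a regular grid every voxel has the same physical volume). The `IVD`
#' region is the union of the `IVD`, `NP` and `AF` codes; `AF` falls back to
#' disc-minus-NP when no explicit AF code is used.
#'
#' @param volume A `volume_grid`.
#' @param mask A `label_mask` aligned with `volume`.
#' @param region One of `"IVD"`, `"NP"`, `"AF"`, `"CSF"`, `"BONE"`.
#' @param units Position units: world millimetres (default) or raw 0-based
#'   voxel indices.
#' @return A [region_sample()].
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' np <- extract_region(ph$volume, ph$mask, "NP")
#' np$n
extract_region <- function(volume, mask, region,
                           units = c("mm", "voxel")) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "label_mask"))
  units <- match.arg(units)
  if (!identical(dim(volume$data), dim(mask$labels))) {
    stopf("mask (%s) is not aligned with volume (%s)",
          paste(dim(mask$labels), collapse = "x"),
          paste(dim(volume$data), collapse = "x"))
  }
  codes <- region_codes(mask, region)
  idx <- which(mask$labels %in% codes)
  if (!length(idx)) stopf("region '%s' is empty in this mask", region)
  ijk0 <- arrayInd(idx, dim(mask$labels)) - 1L
  pos <- if (units == "mm") {
    h <- cbind(ijk0, 1) %*% t(volume$affine)
    h[, 1:3, drop = FALSE]
  } else {
    ijk0 + 0
  }
  region_sample(pos, volume$data[idx], region_name = region)
}
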