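#' Synthetic disc phantom specification
#'
#' Parameterizes a synthetic sagittal T2-weighted lumbar-disc volume: an
#' ellipsoidal disc whose annulus fibrosus (dark) surrounds a brighter
#' nucleus pulposus core, two rectangular reference blocks of constant
#' composition (CSF, very bright; cancellous bone, intermediate), a uniform
#' soft-tissue background, multiplicative acquisition gain and additive
#' Gaussian noise. Degeneration is modelled minimally as a linear blend of
#' the NP intensity toward the AF value plus a Gaussian blur of the tissue
#' boundaries whose width grows with degeneration. Nucleus displacement
#' (`np_offset`) shifts the NP ellipsoid inside the disc and, mimicking the
#' asymmetric dehydration of a migrating nucleus, imposes a linear
#' intensity gradient inside the NP along the displacement direction with
#' relative magnitude `np_gradient * |np_offset|` (set `np_gradient = 0`
#' for an exactly piecewise-constant two-tissue disc).
#'
#' Default geometry (48 x 36 x 20 voxels at 1 mm, disc semi-axes 16/12/6 mm,
#' NP semi-axes 10/7.5/3.8 mm giving an analytic NP/IVD volume ratio of
#' about 0.247) emulates a lumbar disc at research resolution.
#'
#' @param grid_shape Integer 3-vector of voxel counts.
#' @param spacing Voxel spacing, mm.
#' @param ivd_semi_axes,np_semi_axes Ellipsoid semi-axes, mm.
#' @param ivd_center Disc centre in mm; default places the disc left of the
#'   reference blocks, symmetric on the voxel lattice.
#' @param np_offset NP centre displacement relative to the disc centre, mm.
#' @param intensity_np,intensity_af,intensity_csf,intensity_bone,intensity_background
#'   Noise-free tissue intensities (arbitrary units).
#' @param degeneration Fraction in `[0, 1]`: 0 = healthy, 1 = NP
#'   indistinguishable from AF.
#' @param gain Global multiplicative acquisition gain (> 0).
#' @param noise_sd Additive Gaussian noise standard deviation, pre-gain
#'   units.
#' @param np_gradient Intensity-gradient strength per mm of NP
#'   displacement (relative units).
#' @param blur_per_degeneration Boundary blur sd in mm per unit
#'   degeneration.
#' @param csf_block,bone_block 0-based inclusive index bounds
#'   `(x0, x1, y0, y1, z0, z1)` of the reference blocks.
#' @param seed Integer RNG seed; phantoms are bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 36L, 20L),
                         spacing = c(1, 1, 1),
                         ivd_semi_axes = c(16, 12, 6),
                         np_semi_axes = c(10, 7.5, 3.8),
                         ivd_center = c(20, 17.5, 9.5),
                         np_offset = c(0, 0, 0),
                         intensity_np = 200,
                         intensity_af = 60,
                         intensity_csf = 240,
                         intensity_bone = 90,
                         intensity_background = 20,
                         degeneration = 0,
                         gain = 1,
                         noise_sd = 5,
                         np_gradient = 0.08,
                         blur_per_degeneration = 3,
                         csf_block = c(38L, 45L, 4L, 11L, 6L, 13L),
                         bone_block = c(38L, 45L, 24L, 31L, 6L, 13L),
                         seed = 1L) {
  spec <- list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    ivd_semi_axes = as.numeric(ivd_semi_axes),
    np_semi_axes = as.numeric(np_semi_axes),
    ivd_center = as.numeric(ivd_center), np_offset = as.numeric(np_offset),
    intensity_np = intensity_np, intensity_af = intensity_af,
    intensity_csf = intensity_csf, intensity_bone = intensity_bone,
    intensity_background = intensity_background,
    degeneration = degeneration, gain = gain, noise_sd = noise_sd,
    np_gradient = np_gradient,
    blur_per_degeneration = blur_per_degeneration,
    csf_block = as.integer(csf_block), bone_block = as.integer(bone_block),
    seed = as.integer(seed)
  )
  with(spec, {
    if (any(grid_shape < 1L)) stopf("grid_shape must be positive")
    if (any(spacing <= 0)) stopf("spacing must be positive")
    if (any(ivd_semi_axes <= 0) || any(np_semi_axes <= 0)) {
      stopf("semi-axes must be positive")
    }
    if (any(c(intensity_np, intensity_af, intensity_csf, intensity_bone,
              intensity_background) < 0)) {
      stopf("tissue intensities must be non-negative")
    }
    if (degeneration < 0 || degeneration > 1) {
      stopf("degeneration must lie in [0, 1]")
    }
    if (gain <= 0) stopf("gain must be positive")
    if (noise_sd < 0) stopf("noise_sd must be non-negative")
  })
  # NP (after offset) must stay inside the disc: check the NP surface
  # against the IVD quadratic form on a dense direction sample.
  u <- sphere_directions(500L)
  surf <- sweep(u %*% diag(spec$np_semi_axes), 2, spec$np_offset, "+")
  q <- rowSums(sweep(surf, 2, spec$ivd_semi_axes, "/")^2)
  if (max(q) > 1 + 1e-9) {
    stopf("containment error: displaced NP ellipsoid extends outside the IVD")
  }
  structure(spec, class = "phantom_spec")
}

# Quasi-uniform unit directions (Fibonacci sphere).
sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Separable Gaussian blur with edge replication; sigma in voxels per axis.
gaussian_blur3 <- function(a, sigma) {
  for (axis in 1:3) {
    s <- sigma[axis]
    if (!is.finite(s) || s < 1e-6) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    n <- dim(a)[axis]
    out <- array(0, dim(a))
    for (off in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      shifted <- switch(axis,
                        a[idx, , , drop = FALSE],
                        a[, idx, , drop = FALSE],
                        a[, , idx, drop = FALSE])
      out <- out + k[off + r + 1L] * shifted
    }
    a <- out
  }
  a
}

#' Generate a synthetic disc volume and label mask
#'
#' Realizes a [phantom_spec()]: builds the noise-free tissue map (NP, AF,
#' CSF and bone blocks over background), applies the degeneration blend and
#' boundary blur, adds seeded Gaussian noise and the acquisition gain, and
#' labels the voxels (NP inside the displaced nucleus ellipsoid, AF in the
#' disc shell, CSF/BONE in the reference blocks). Deterministic for a fixed
#' seed. The mask codes follow [default_label_map()].
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `disc_phantom`: list with `volume`
#'   ([volume_grid()]), `mask` ([label_mask()]) and `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' ph$volume
#' ph$mask
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$spacing
  ax <- (seq_len(dims[1]) - 1) * sp[1]
  ay <- (seq_len(dims[2]) - 1) * sp[2]
  az <- (seq_len(dims[3]) - 1) * sp[3]
  qsum <- function(center, semi) {
    e1 <- ((ax - center[1]) / semi[1])^2
    e2 <- ((ay - center[2]) / semi[2])^2
    e3 <- ((az - center[3]) / semi[3])^2
    outer(outer(e1, e2, "+"), e3, "+")
  }
  np_center <- spec$ivd_center + spec$np_offset
  in_ivd <- qsum(spec$ivd_center, spec$ivd_semi_axes) <= 1
  in_np <- qsum(np_center, spec$np_semi_axes) <= 1
  if (any(in_np & !in_ivd)) {
    stopf("containment error: NP voxels fall outside the IVD")
  }

  lm <- default_label_map()
  labels <- array(0L, dims)
  labels[in_ivd & !in_np] <- lm[["AF"]]
  labels[in_np] <- lm[["NP"]]
  block_idx <- function(b) {
    list(seq(b[1] + 1L, b[2] + 1L), seq(b[3] + 1L, b[4] + 1L),
         seq(b[5] + 1L, b[6] + 1L))
  }
  cb <- block_idx(spec$csf_block)
  bb <- block_idx(spec$bone_block)
  labels[cb[[1]], cb[[2]], cb[[3]]] <- lm[["CSF"]]
  labels[bb[[1]], bb[[2]], bb[[3]]] <- lm[["BONE"]]

  np_eff <- spec$intensity_np +
    spec$degeneration * (spec$intensity_af - spec$intensity_np)
  tissue <- array(spec$intensity_background, dims)
  tissue[in_ivd] <- spec$intensity_af
  off_mag <- sqrt(sum(spec$np_offset^2))
  if (off_mag > 0 && spec$np_gradient > 0) {
    u <- spec$np_offset / off_mag
    # effective semi-axis along u, so the projection spans [-1, 1] in NP
    a_u <- 1 / sqrt(sum((u / spec$np_semi_axes)^2))
    g_rel <- min(0.9, spec$np_gradient * off_mag)
    proj <- (outer(outer((ax - np_center[1]) * u[1],
                         (ay - np_center[2]) * u[2], "+"),
                   (az - np_center[3]) * u[3], "+")) / a_u
    tissue[in_np] <- np_eff * (1 - g_rel * proj[in_np])
  } else {
    tissue[in_np] <- np_eff
  }
  tissue[cb[[1]], cb[[2]], cb[[3]]] <- spec$intensity_csf
  tissue[bb[[1]], bb[[2]], bb[[3]]] <- spec$intensity_bone

  if (spec$degeneration > 0 && spec$blur_per_degeneration > 0) {
    sigma_mm <- spec$blur_per_degeneration * spec$degeneration
    tissue <- gaussian_blur3(tissue, sigma_mm / sp)
  }
  noise <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, array(rnorm(prod(dims), 0, spec$noise_sd), dims))
  } else {
    0
  }
  img <- spec$gain * (tissue + noise)
  structure(
    list(volume = volume_grid(img, spacing = sp),
         mask = label_mask(labels), spec = spec),
    class = "disc_phantom"
  )
}

#' @export
print.disc_phantom <- function(x, ...) {
  cat("<disc_phantom> seed ", x$spec$seed, ", degeneration ",
      x$spec$degeneration, ", NP offset (",
      paste(x$spec$np_offset, collapse = ", "), ") mm\n", sep = "")
  print(x$volume)
  invisible(x)
}

#' @export
plot.disc_phantom <- function(x, slice = NULL, ...) {
  plot(x$volume, slice = slice,
       main = sprintf("phantom (deg %.2f, offset %.1f mm)",
                      x$spec$degeneration,
                      sqrt(sum(x$spec$np_offset^2))), ...)
  invisible(x)
}

#' Analytic NP/IVD volume ratio of a phantom
#'
#' Exact ellipsoid-volume ratio `prod(np_semi_axes) / prod(ivd_semi_axes)`
#' implied by a [phantom_spec()]; the voxelized [volume_ratio()] converges
#' to it as resolution increases.
#'
#' @param spec A [phantom_spec()].
#' @return Scalar ratio.
#' @export
analytic_volume_ratio <- function(spec) {
  prod(spec$np_semi_axes) / prod(spec$ivd_semi_axes)
}
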