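#' Synthetic cohort specification
#'
#' Describes the five study groups (low/high severity scoliosis, low/high
#' severity spondylolisthesis, control) as per-group distributions of the
#' phantom parameters that carry the group differences: the NP/IVD volume
#' ratio (the nucleus shrinks in pathological discs), the nucleus
#' displacement magnitude (largest in scoliosis), and the degeneration
#' level (higher at high severity). Group sizes default to 16/16/16/16/15,
#' a 79-subject cohort. Per-group means and standard deviations of the
#' volume ratio default to the cohort values typical of adolescent
#' scoliosis/spondylolisthesis populations (control about 27%, pathological
#' groups 18-22%); displacement means are largest in the scoliosis groups
#' so the weighted-centre distance separates scoliosis from control.
#' Per-subject disc size is jittered by a few percent; displacement
#' direction is drawn uniformly in the disc plane.
#'
#' @param group_sizes Named integer vector over the five groups.
#' @param base A [phantom_spec()] providing geometry, intensities, noise
#'   and blocks shared by all subjects.
#' @param volume_ratio_mean,volume_ratio_sd Per-group NP/IVD target ratio
#'   distribution (fractions).
#' @param np_offset_mean,np_offset_sd Per-group displacement magnitude
#'   distribution, mm (truncated at 0 and at the containment limit).
#' @param degeneration_mean,degeneration_sd Per-group degeneration
#'   distribution (truncated to `[0, 1]`).
#' @param ivd_scale_sd Relative per-subject disc-size jitter.
#' @param seed Master seed; every subject's parameters and noise derive
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(scoliosis_low = 16L,
                                        scoliosis_high = 16L,
                                        spondylolisthesis_low = 16L,
                                        spondylolisthesis_high = 16L,
                                        control = 15L),
                        base = phantom_spec(),
                        volume_ratio_mean = c(scoliosis_low = 0.189,
                                              scoliosis_high = 0.199,
                                              spondylolisthesis_low = 0.222,
                                              spondylolisthesis_high = 0.180,
                                              control = 0.270),
                        volume_ratio_sd = c(scoliosis_low = 0.034,
                                            scoliosis_high = 0.050,
                                            spondylolisthesis_low = 0.036,
                                            spondylolisthesis_high = 0.048,
                                            control = 0.063),
                        np_offset_mean = c(scoliosis_low = 2.0,
                                           scoliosis_high = 2.2,
                                           spondylolisthesis_low = 0.9,
                                           spondylolisthesis_high = 1.5,
                                           control = 1.0),
                        np_offset_sd = c(scoliosis_low = 0.8,
                                         scoliosis_high = 0.8,
                                         spondylolisthesis_low = 0.4,
                                         spondylolisthesis_high = 0.6,
                                         control = 0.4),
                        degeneration_mean = c(scoliosis_low = 0.15,
                                              scoliosis_high = 0.30,
                                              spondylolisthesis_low = 0.15,
                                              spondylolisthesis_high = 0.30,
                                              control = 0.05),
                        degeneration_sd = c(scoliosis_low = 0.05,
                                            scoliosis_high = 0.05,
                                            spondylolisthesis_low = 0.05,
                                            spondylolisthesis_high = 0.05,
                                            control = 0.03),
                        ivd_scale_sd = 0.05,
                        seed = 1L) {
  gnames <- c("scoliosis_low", "scoliosis_high", "spondylolisthesis_low",
              "spondylolisthesis_high", "control")
  as_named <- function(x, what) {
    if (is.null(names(x))) names(x) <- gnames
    if (!all(gnames %in% names(x))) {
      stopf("%s must be named over: %s", what, paste(gnames, collapse = ", "))
    }
    x[gnames]
  }
  group_sizes <- as_named(group_sizes, "group_sizes")
  if (any(group_sizes < 3L)) stopf("every group needs at least 3 subjects")
  spec <- list(
    group_sizes = as.integer(setNames(group_sizes, gnames)),
    base = base,
    volume_ratio_mean = as_named(volume_ratio_mean, "volume_ratio_mean"),
    volume_ratio_sd = as_named(volume_ratio_sd, "volume_ratio_sd"),
    np_offset_mean = as_named(np_offset_mean, "np_offset_mean"),
    np_offset_sd = as_named(np_offset_sd, "np_offset_sd"),
    degeneration_mean = as_named(degeneration_mean, "degeneration_mean"),
    degeneration_sd = as_named(degeneration_sd, "degeneration_sd"),
    ivd_scale_sd = ivd_scale_sd,
    seed = as.integer(seed)
  )
  if (any(spec$volume_ratio_sd < 0) || any(spec$np_offset_sd < 0) ||
      any(spec$degeneration_sd < 0) || ivd_scale_sd < 0) {
    stopf("parameter standard deviations must be non-negative")
  }
  names(spec$group_sizes) <- gnames
  structure(spec, class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Draw the per-subject phantom parameters of a cohort
#'
#' Expands a [cohort_spec()] into one row per subject: group, severity,
#' drawn volume-ratio target, displacement vector, degeneration and child
#' seed. Deterministic given the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per subject.
#' @export
cohort_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(spec$group_sizes)
  gname <- rep(names(spec$group_sizes), spec$group_sizes)
  with_seed(spec$seed, {
    ratio <- offm <- degn <- scale <- theta <- numeric(n_total)
    for (g in names(spec$group_sizes)) {
      sel <- gname == g
      k <- sum(sel)
      ratio[sel] <- rtrunc_norm(k, spec$volume_ratio_mean[[g]],
                                spec$volume_ratio_sd[[g]], 0.05, 0.60)
      offm[sel] <- rtrunc_norm(k, spec$np_offset_mean[[g]],
                               spec$np_offset_sd[[g]], 0, Inf)
      degn[sel] <- rtrunc_norm(k, spec$degeneration_mean[[g]],
                               spec$degeneration_sd[[g]], 0, 1)
      scale[sel] <- rtrunc_norm(k, 1, spec$ivd_scale_sd, 0.85, 1.15)
      theta[sel] <- runif(k, 0, 2 * pi)
    }
    seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n_total)),
      group = sub("_(low|high)$", "", gname),
      severity = ifelse(grepl("_high$", gname), "high",
                        ifelse(grepl("_low$", gname), "low", "none")),
      ratio = ratio, np_offset_mag = offm, np_offset_theta = theta,
      degeneration = degn, ivd_scale = scale, seed = seeds,
      stringsAsFactors = FALSE
    )
  })
}

# Instantiate subject i of a cohort as a phantom_spec.
subject_spec <- function(spec, params, i) {
  p <- params[i, ]
  base <- spec$base
  ivd <- base$ivd_semi_axes * p$ivd_scale
  np <- ivd * p$ratio^(1 / 3)
  # containment cap on in-plane displacement, with a safety margin
  cap <- 0.9 * min(ivd[1:2] - np[1:2])
  mag <- min(p$np_offset_mag, max(cap, 0))
  off <- c(mag * cos(p$np_offset_theta), mag * sin(p$np_offset_theta), 0)
  phantom_spec(
    grid_shape = base$grid_shape, spacing = base$spacing,
    ivd_semi_axes = ivd, np_semi_axes = np,
    ivd_center = base$ivd_center, np_offset = off,
    intensity_np = base$intensity_np, intensity_af = base$intensity_af,
    intensity_csf = base$intensity_csf, intensity_bone = base$intensity_bone,
    intensity_background = base$intensity_background,
    degeneration = p$degeneration, gain = base$gain,
    noise_sd = base$noise_sd, np_gradient = base$np_gradient,
    blur_per_degeneration = base$blur_per_degeneration,
    csf_block = base$csf_block, bone_block = base$bone_block,
    seed = p$seed
  )
}

#' Generate all phantoms of a synthetic cohort
#'
#' Materializes every subject of a [cohort_spec()] as a volume/mask pair.
#' For large simulation studies prefer [simulate_cohort_indices()], which
#' streams subjects one at a time.
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects` (list of `disc_phantom`s, each carrying
#'   `subject_id`, `group`, `severity`) and `params` (the drawn parameter
#'   table).
#' @export
generate_cohort <- function(spec) {
  params <- cohort_params(spec)
  subjects <- lapply(seq_len(nrow(params)), function(i) {
    ph <- tryCatch(
      generate_phantom(subject_spec(spec, params, i)),
      error = function(e) {
        stopf("subject %s (#%d): %s", params$subject_id[i], i,
              conditionMessage(e))
      }
    )
    ph$subject_id <- params$subject_id[i]
    ph$group <- params$group[i]
    ph$severity <- params$severity[i]
    ph
  })
  list(subjects = subjects, params = params)
}

#' Simulate a cohort and compute its index table
#'
#' Streams through the subjects of a synthetic cohort, runs the per-disc
#' analysis on each phantom, and assembles the long cohort table consumed
#' by [significance_report()]. Geometry rows (`center_distance`,
#' `volume_ratio`) are reported under normalization `"none"`: the
#' weighted-centre distance is invariant under intensity scaling and the
#' volume ratio is intensity-free.
#'
#' @param spec A [cohort_spec()].
#' @param normalizations Normalizations for the histogram indices.
#' @param regions Disc regions to analyse.
#' @param measures Subset of `"histogram"`, `"geometry"`,
#'   `"volume_ratio"`; restricting the set skips unneeded computation in
#'   large simulation studies.
#' @param hist_spec A [histogram_spec()].
#' @return Long data frame: `subject_id`, `group`, `severity`, `region`,
#'   `normalization`, `index`, `value`.
#' @export
#' @examples
#' \donttest{
#' cs <- cohort_spec(group_sizes = c(scoliosis_low = 3, scoliosis_high = 3,
#'   spondylolisthesis_low = 3, spondylolisthesis_high = 3, control = 3))
#' tab <- simulate_cohort_indices(cs, measures = "volume_ratio")
#' aggregate(value ~ group, tab, mean)
#' }
simulate_cohort_indices <- function(spec,
                                    normalizations = c("csf", "bone"),
                                    regions = c("IVD", "NP", "AF"),
                                    measures = c("histogram", "geometry",
                                                 "volume_ratio"),
                                    hist_spec = histogram_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  measures <- match.arg(measures, several.ok = TRUE)
  params <- cohort_params(spec)
  out <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    ph <- generate_phantom(subject_spec(spec, params, i))
    rows <- list()
    if ("volume_ratio" %in% measures) {
      vr <- volume_ratio(extract_region(ph$volume, ph$mask, "NP"),
                         extract_region(ph$volume, ph$mask, "IVD"))
      rows[[length(rows) + 1L]] <- data.frame(
        region = "IVD", normalization = "none", index = "volume_ratio",
        value = vr$ratio, stringsAsFactors = FALSE
      )
    }
    if (any(c("histogram", "geometry") %in% measures)) {
      refs <- list()
      if ("histogram" %in% measures) {
        for (nk in normalizations) {
          refs[[nk]] <- extract_region(ph$volume, ph$mask, toupper(nk))
        }
      }
      for (rg in regions) {
        smp <- extract_region(ph$volume, ph$mask, rg)
        if ("geometry" %in% measures) {
          cp <- center_distance(smp)
          rows[[length(rows) + 1L]] <- data.frame(
            region = rg, normalization = "none", index = "center_distance",
            value = cp$d, stringsAsFactors = FALSE
          )
        }
        if ("histogram" %in% measures) {
          for (nk in normalizations) {
            nr <- normalize_region(smp, refs[[nk]], nk)
            iset <- compute_index_set(nr, hist_spec)
            rows[[length(rows) + 1L]] <- data.frame(
              region = rg, normalization = nk, index = index_names(),
              value = unlist(iset, use.names = FALSE),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    sub <- do.call(rbind, rows)
    sub$subject_id <- params$subject_id[i]
    sub$group <- params$group[i]
    sub$severity <- params$severity[i]
    out[[i]] <- sub
  }
  res <- do.call(rbind, out)
  res[c("subject_id", "group", "severity", "region", "normalization",
        "index", "value")]
}
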