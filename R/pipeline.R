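#' Per-disc signal distribution analysis
#'
#' Main entry point for one subject: extracts the disc regions, normalizes
#' their intensities by each requested reference tissue, and computes the
#' eight histogram indices, the weighted/geometric-centre distance and the
#' NP/IVD volume ratio.
#'
#' @param volume A [volume_grid()] (T2-weighted intensities).
#' @param mask An aligned [label_mask()].
#' @param normalizations Character subset of `"csf"`, `"bone"`, `"none"`.
#' @param regions Regions to analyse (default IVD, NP, AF).
#' @param hist_spec A [histogram_spec()].
#' @param units Coordinate units for centre geometry: world mm (default)
#'   or voxel indices.
#' @param sum_sq_weighted Volume-weight the sum of squares (default).
#' @return An object of class `amrsid_indices`: list with `table` (one row
#'   per region x normalization: the eight indices plus `d` and `N`),
#'   `volume_ratio`, `reference_means`, and the configuration used.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 2))
#' res <- disc_indices(ph$volume, ph$mask)
#' res
disc_indices <- function(volume, mask, normalizations = c("csf", "bone"),
                         regions = c("IVD", "NP", "AF"),
                         hist_spec = histogram_spec(),
                         units = c("mm", "voxel"),
                         sum_sq_weighted = TRUE) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "label_mask"))
  units <- match.arg(units)
  normalizations <- match.arg(normalizations, c("csf", "bone", "none"),
                              several.ok = TRUE)
  ref_means <- c()
  refs <- list()
  for (nk in setdiff(normalizations, "none")) {
    refs[[nk]] <- extract_region(volume, mask, toupper(nk), units = units)
    ref_means[nk] <- reference_mean(refs[[nk]])
  }
  rows <- list()
  for (rg in regions) {
    smp <- extract_region(volume, mask, rg, units = units)
    for (nk in normalizations) {
      nr <- normalize_region(smp, refs[[nk]], nk)
      iset <- compute_index_set(nr, hist_spec,
                                sum_sq_weighted = sum_sq_weighted)
      cp <- center_distance(nr)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, normalization = nk,
        as.data.frame(unclass(iset)),
        d = cp$d, N = cp$N, stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  vr <- tryCatch(
    volume_ratio(extract_region(volume, mask, "NP", units = units),
                 extract_region(volume, mask, "IVD", units = units)),
    error = function(e) NULL
  )
  structure(
    list(table = tab, volume_ratio = vr, reference_means = ref_means,
         normalizations = normalizations, units = units,
         hist_spec = hist_spec, sum_sq_weighted = sum_sq_weighted),
    class = "amrsid_indices"
  )
}

#' @export
print.amrsid_indices <- function(x, ...) {
  cat("<amrsid_indices>\n")
  if (length(x$reference_means)) {
    cat("  reference means:",
        paste(sprintf("%s = %.4g", names(x$reference_means),
                      x$reference_means), collapse = ", "), "\n")
  }
  if (!is.null(x$volume_ratio)) {
    cat("  NP/IVD volume ratio: ", signif(x$volume_ratio$ratio, 4),
        " (", x$volume_ratio$np_voxels, "/", x$volume_ratio$ivd_voxels,
        " voxels)\n", sep = "")
  }
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.amrsid_indices <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
as.data.frame.amrsid_indices <- function(x, ...) {
  tab <- x$table
  tab$volume_ratio <- if (!is.null(x$volume_ratio)) x$volume_ratio$ratio
                      else NA_real_
  tab
}

#' Histogram overview of the normalized disc regions
#'
#' @param x An `amrsid_indices` result -- note the plot needs the original
#'   data, so supply `volume` and `mask` again.
#' @param volume,mask The inputs given to [disc_indices()].
#' @param normalization Which normalization to display.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further graphical parameters.
#' @export
plot.amrsid_indices <- function(x, volume, mask, normalization = NULL,
                                breaks = 40, ...) {
  if (is.null(normalization)) normalization <- x$normalizations[1]
  regions <- unique(x$table$region)
  old <- graphics::par(mfrow = c(1, length(regions)))
  on.exit(graphics::par(old))
  ref <- if (normalization == "none") NULL
         else extract_region(volume, mask, toupper(normalization))
  for (rg in regions) {
    nr <- normalize_region(extract_region(volume, mask, rg), ref,
                           normalization)
    graphics::hist(nr$normalized_intensities, breaks = breaks,
                   main = paste(rg, "/", normalization),
                   xlab = "normalized intensity", ...)
  }
  invisible(x)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("[stage %s] %s", stage, conditionMessage(e))
  })
}

#' Compute per-subject index rows from image files
#'
#' File-level wrapper around [disc_indices()]: loads a NIfTI volume and
#' mask, runs the analysis, and returns (optionally writes) the wide CSV
#' rows -- one per region x normalization, with the subject id, the eight
#' indices, the centre distance, voxel count, volume ratio and the
#' reference means used. Errors name the pipeline stage at which they
#' occurred.
#'
#' @param volume_path,mask_path NIfTI file paths.
#' @param out Optional output CSV path.
#' @param subject_id Identifier written into the rows.
#' @param label_map Region code mapping for the mask.
#' @param normalizations,regions,hist_spec,units,sum_sq_weighted Passed to
#'   [disc_indices()].
#' @return The wide data frame, invisibly when `out` is given.
#' @export
cmd_indices <- function(volume_path, mask_path, out = NULL,
                        subject_id = "subject",
                        label_map = default_label_map(),
                        normalizations = c("csf", "bone"),
                        regions = c("IVD", "NP", "AF"),
                        hist_spec = histogram_spec(),
                        units = c("mm", "voxel"),
                        sum_sq_weighted = TRUE) {
  volume <- with_stage("load volume", load_volume(volume_path))
  mask <- with_stage("load mask", load_mask(mask_path, label_map))
  res <- with_stage("indices", disc_indices(
    volume, mask, normalizations = normalizations, regions = regions,
    hist_spec = hist_spec, units = units, sum_sq_weighted = sum_sq_weighted
  ))
  df <- as.data.frame(res)
  df <- cbind(subject_id = subject_id, df, stringsAsFactors = FALSE)
  for (nk in names(res$reference_means)) {
    df[[paste0("ref_mean_", nk)]] <- res$reference_means[[nk]]
  }
  if (!is.null(out)) {
    with_stage("write output", write.csv(df, out, row.names = FALSE))
    return(invisible(df))
  }
  df
}

# Wide per-subject rows (cmd_indices output) -> long cohort table.
indices_to_long <- function(wide, groups) {
  mismatch_a <- setdiff(unique(wide$subject_id), groups$subject_id)
  mismatch_b <- setdiff(groups$subject_id, unique(wide$subject_id))
  if (length(mismatch_a) || length(mismatch_b)) {
    stopf(paste0(
      "subject mismatch between index and group tables; ",
      "missing from groups: [%s]; missing from indices: [%s]"),
      paste(mismatch_a, collapse = ", "),
      paste(mismatch_b, collapse = ", "))
  }
  value_cols <- intersect(c(index_names(), "d", "volume_ratio"), names(wide))
  long <- do.call(rbind, lapply(value_cols, function(cn) {
    data.frame(
      subject_id = wide$subject_id, region = wide$region,
      normalization = wide$normalization, index = cn, value = wide[[cn]],
      stringsAsFactors = FALSE
    )
  }))
  # geometry rows are normalization-independent: keep one copy
  geo <- long$index %in% c("d", "volume_ratio")
  if (any(geo)) {
    keep_norm <- long$normalization[which(!geo)[1]]
    if (is.na(keep_norm)) keep_norm <- long$normalization[1]
    long <- long[!geo | long$normalization == keep_norm, , drop = FALSE]
    long$normalization[long$index %in% c("d", "volume_ratio")] <- "none"
    vr <- long$index == "volume_ratio"
    long <- long[!(vr & long$region != "IVD"), , drop = FALSE]
  }
  long$index[long$index == "d"] <- "center_distance"
  m <- match(long$subject_id, groups$subject_id)
  long$group <- groups$group[m]
  long$severity <- groups$severity[m]
  long[c("subject_id", "group", "severity", "region", "normalization",
         "index", "value")]
}

#' Cohort comparison from CSV tables
#'
#' File-level wrapper around [significance_report()]: joins a per-subject
#' index table (as written by [cmd_indices()], stacked over subjects) with
#' a group-assignment table (`subject_id`, `group`, `severity`), runs the
#' decision-tree statistics, and writes the significance grid and the
#' underlying p-values.
#'
#' @param indices_csv CSV of stacked [cmd_indices()] rows, or the
#'   equivalent data frame.
#' @param groups_csv CSV with columns `subject_id`, `group`, `severity`,
#'   or the equivalent data frame.
#' @param out_prefix Optional path prefix; writes
#'   `<prefix>_grid.csv`, `<prefix>_grid.md` and `<prefix>_stats.json`.
#' @param alpha,alpha2,adjust Passed to [significance_report()].
#' @return The `amrsid_report`, invisibly when `out_prefix` is given.
#' @export
cmd_cohort <- function(indices_csv, groups_csv, out_prefix = NULL,
                       alpha = 0.05, alpha2 = 0.01, adjust = "none") {
  wide <- if (is.character(indices_csv)) {
    with_stage("read indices", read.csv(indices_csv,
                                        stringsAsFactors = FALSE))
  } else indices_csv
  groups <- if (is.character(groups_csv)) {
    with_stage("read groups", read.csv(groups_csv, stringsAsFactors = FALSE))
  } else groups_csv
  if (length(unique(groups$group)) < 2L) {
    stopf("[stage cohort] insufficient groups: need at least 2, got %d",
          length(unique(groups$group)))
  }
  long <- with_stage("join", indices_to_long(wide, groups))
  report <- with_stage("statistics", significance_report(
    long, alpha = alpha, alpha2 = alpha2, adjust = adjust
  ))
  if (!is.null(out_prefix)) {
    with_stage("write output", {
      write_report(report, paste0(out_prefix, "_grid.csv"), "csv")
      write_report(report, paste0(out_prefix, "_grid.md"), "markdown")
      write_report(report, paste0(out_prefix, "_stats.json"), "json")
    })
    return(invisible(report))
  }
  report
}
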