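#' Assumption gates and test selection
#'
#' Chooses between the parametric and rank branches of the analysis
#' decision tree. The parametric branch (one- or two-way ANOVA) is taken
#' only when the data pass a Shapiro-Wilk normality test on the
#' group-mean-centred residuals and Levene's variance-homogeneity test
#' across groups (or design cells), both at `alpha`; otherwise the rank
#' branch (Kruskal-Wallis with Dunn's comparisons, or rank-transform
#' factorial ANOVA) is used. Testing the pooled residuals (rather than each
#' group separately) is the convention of the classical biostatistics
#' packages this decision tree mirrors, and keeps the parametric selection
#' rate near `(1 - alpha)^2` for truly Gaussian groups. Constant data fail
#' normality by convention.
#'
#' @param values Numeric vector of index values.
#' @param group Factor (or coercible) of group membership, aligned with
#'   `values`.
#' @param group2 Second factor for a two-way design (cells =
#'   `group x group2`); `NULL` for one-way.
#' @param alpha Gate level for both assumption tests (default 0.05).
#' @return Character test name: `"one_way_anova"`,
#'   `"kruskal_wallis_dunn"`, `"two_way_anova"` or `"rank_two_way_anova"`,
#'   with attribute `"assumptions"` carrying the gate p-values
#'   `(normality_p, variance_p)`.
#' @export
#' @examples
#' set.seed(1)
#' choose_test(rnorm(30), rep(letters[1:3], each = 10))
choose_test <- function(values, group, group2 = NULL, alpha = 0.05) {
  g <- if (is.null(group2)) factor(group)
       else interaction(factor(group), factor(group2), drop = TRUE)
  sizes <- table(g)
  if (any(sizes < 3L)) {
    stopf("insufficient data: group '%s' has %d observation(s), need >= 3",
          names(sizes)[which.min(sizes)], min(sizes))
  }
  resid <- values - ave(values, g)
  norm_p <- if (length(unique(resid)) < 2L) 0  # constant residuals
            else tryCatch(shapiro.test(resid)$p.value, error = function(e) 0)
  var_p <- tryCatch(
    car::leveneTest(values ~ g)[["Pr(>F)"]][1],
    error = function(e) 0
  )
  parametric <- norm_p > alpha && is.finite(var_p) && var_p > alpha
  name <- if (is.null(group2)) {
    if (parametric) "one_way_anova" else "kruskal_wallis_dunn"
  } else {
    if (parametric) "two_way_anova" else "rank_two_way_anova"
  }
  structure(name, assumptions = c(normality_p = unname(norm_p),
                                  variance_p = unname(var_p)))
}

# Dunn's z-test comparisons on ranks, with midrank tie correction.
# p-values are two-sided and Bonferroni-adjusted over all pairs (the
# family-wise convention of the method); raw p-values are kept alongside.
dunn_posthoc <- function(values, group) {
  g <- factor(group)
  r <- rank(values)
  N <- length(r)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  varfac <- N * (N + 1) / 12 - tie_term
  means <- tapply(r, g, mean)
  sizes <- table(g)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  k <- ncol(pairs)
  z <- p <- numeric(k)
  for (i in seq_len(k)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(varfac * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[i] <- (means[[a]] - means[[b]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ], z = z,
    p_unadjusted = p, p_value = pmin(1, p * k),
    stringsAsFactors = FALSE
  )
}

stat_result <- function(test_name, statistic, p_value, posthoc = NULL,
                        assumptions = c(normality_p = NA_real_,
                                        variance_p = NA_real_),
                        effects = NULL) {
  structure(
    list(test_name = test_name, statistic = unname(statistic),
         p_value = unname(p_value), posthoc = posthoc,
         assumptions = assumptions, effects = effects),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$test_name, "\n", sep = "")
  if (!is.null(x$effects)) {
    print(x$effects, row.names = FALSE)
  } else {
    cat("  statistic = ", signif(x$statistic, 6), ", p = ",
        format.pval(x$p_value, digits = 4), "\n", sep = "")
  }
  if (!is.null(x$posthoc)) {
    cat("  post-hoc comparisons:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' One-way comparison across pathology groups
#'
#' Omnibus comparison of an index between groups, following the decision
#' tree: one-way ANOVA on the parametric branch, Kruskal-Wallis (with
#' midrank tie correction) on the rank branch. Post-hoc pairwise
#' comparisons are attached only when the omnibus test rejects at `alpha`
#' and there are at least three groups: Dunn's method on the rank branch,
#' pooled-SD pairwise t-tests with Holm adjustment on the parametric
#' branch.
#'
#' @inheritParams choose_test
#' @param test Force a branch (`"one_way_anova"` or
#'   `"kruskal_wallis_dunn"`); `NULL` (default) selects via
#'   [choose_test()].
#' @param alpha Level used for the assumption gates and the post-hoc
#'   trigger.
#' @return A `stat_result` with the omnibus statistic (F or H), its
#'   p-value, optional `posthoc` data frame and the assumption-gate
#'   p-values.
#' @export
#' @examples
#' v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
#' g <- rep(c("a", "b", "c"), each = 3)
#' one_way_compare(v, g, test = "one_way_anova")  # F = 3, p = 0.125
one_way_compare <- function(values, group, alpha = 0.05, test = NULL) {
  g <- factor(group)
  if (nlevels(g) < 2L) stopf("at least two groups required")
  if (length(unique(values)) < 2L) {
    stopf("degenerate variance: all values identical across groups")
  }
  assum <- c(normality_p = NA_real_, variance_p = NA_real_)
  if (is.null(test)) {
    test <- choose_test(values, g, alpha = alpha)
    assum <- attr(test, "assumptions")
    test <- as.character(test)
  }
  if (test == "one_way_anova") {
    tab <- anova(aov(values ~ g))
    stat <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    posthoc <- NULL
    if (p < alpha && nlevels(g) >= 3L) {
      pw <- pairwise.t.test(values, g, p.adjust.method = "holm",
                            pool.sd = TRUE)$p.value
      posthoc <- data.frame(
        group1 = rep(colnames(pw), times = nrow(pw)),
        group2 = rep(rownames(pw), each = ncol(pw)),
        p_value = as.vector(t(pw)),
        stringsAsFactors = FALSE
      )
      posthoc <- posthoc[!is.na(posthoc$p_value), , drop = FALSE]
    }
  } else if (test == "kruskal_wallis_dunn") {
    kw <- kruskal.test(values, g)
    stat <- unname(kw$statistic)
    p <- kw$p.value
    posthoc <- if (is.finite(p) && p < alpha && nlevels(g) >= 3L) {
      dunn_posthoc(values, g)
    } else NULL
  } else {
    stopf("unknown one-way test '%s'", test)
  }
  stat_result(test, stat, p, posthoc, assum)
}

#' Two-way comparison: pathology x severity
#'
#' Factorial comparison of an index over two crossed factors (pathology and
#' severity, control excluded), with main effects and interaction. The
#' parametric branch fits an ordinary two-way ANOVA; the rank branch
#' replaces the values by their global ranks and fits the same linear model
#' (the rank-transform reading of "ANOVA on ranks"). The design here is
#' balanced by construction, so sequential sums of squares are the
#' classical ones.
#'
#' @param values Numeric vector of index values (control subjects
#'   excluded).
#' @param factor_a,factor_b Crossed factors (e.g. pathology, severity).
#' @param alpha Gate level for assumption checks.
#' @param test Force `"two_way_anova"` or `"rank_two_way_anova"`; `NULL`
#'   selects via [choose_test()] on the design cells.
#' @return A `stat_result` whose `effects` element is a data frame with
#'   one row per effect (`factor_a`, `factor_b`, interaction) and columns
#'   `F` and `p`; `statistic`/`p_value` mirror the `factor_a` row.
#' @export
two_way_compare <- function(values, factor_a, factor_b, alpha = 0.05,
                            test = NULL) {
  A <- factor(factor_a)
  B <- factor(factor_b)
  if (nlevels(A) < 2L || nlevels(B) < 2L) {
    stopf("both factors need at least two levels")
  }
  if (any(table(A, B) == 0L)) {
    stopf("design error: empty cell in the %d x %d layout",
          nlevels(A), nlevels(B))
  }
  assum <- c(normality_p = NA_real_, variance_p = NA_real_)
  if (is.null(test)) {
    test <- choose_test(values, A, group2 = B, alpha = alpha)
    assum <- attr(test, "assumptions")
    test <- as.character(test)
  }
  v <- if (test == "rank_two_way_anova") rank(values)
       else if (test == "two_way_anova") values
       else stopf("unknown two-way test '%s'", test)
  tab <- anova(aov(v ~ A * B))
  eff_names <- c(
    if (!is.null(attr(factor_a, "label"))) attr(factor_a, "label") else "factor_a",
    if (!is.null(attr(factor_b, "label"))) attr(factor_b, "label") else "factor_b",
    "interaction"
  )
  f <- tab[["F value"]][1:3]
  p <- tab[["Pr(>F)"]][1:3]
  # all-identical cells: zero residual variance gives NaN F; report F=0, p=1
  if (all(!is.finite(f))) {
    ms <- tab[["Mean Sq"]][1:3]
    f[ms == 0] <- 0
    p[ms == 0] <- 1
  }
  effects <- data.frame(effect = eff_names, F = f, p = p,
                        stringsAsFactors = FALSE)
  stat_result(test, f[1], p[1], NULL, assum, effects)
}

star_mark <- function(p, alpha = 0.05, alpha2 = 0.01) {
  ifelse(is.na(p), "",
         ifelse(p < alpha2, "**", ifelse(p < alpha, "*", "")))
}

#' Cohort-wide significance grid
#'
#' Runs the full decision-tree analysis over a cohort table and summarises
#' it as a significance grid: one row per comparison (each pathology pair,
#' plus severity low/high) x normalization x region, one column per index,
#' cells marked `*` (p < `alpha`) or `**` (p < `alpha2`). Pairwise
#' pathology cells are filled from post-hoc comparisons and only when the
#' omnibus test rejects; the severity row uses the severity main effect of
#' the two-way model on the pathology subjects.
#'
#' @param cohort Data frame with columns `subject_id`, `group` (control /
#'   scoliosis / spondylolisthesis), `severity` (none / low / high),
#'   `region`, `normalization`, `index`, `value` -- one value per subject
#'   per cell, as produced by [simulate_cohort_indices()] or
#'   [cmd_indices()] + reshaping.
#' @param alpha,alpha2 Single- and double-star thresholds.
#' @param adjust Multiple-testing adjustment applied across the whole grid
#'   of omnibus/severity p-values (`"none"`, the method's convention, or
#'   any [stats::p.adjust()] method such as `"BH"`).
#' @param control Name of the control group.
#' @return An object of class `amrsid_report`: the star grid (data frame),
#'   with the long table of underlying p-values in `attr(, "p_values")`.
#' @export
significance_report <- function(cohort, alpha = 0.05, alpha2 = 0.01,
                                adjust = "none", control = "control") {
  empty <- data.frame(comparison = character(), normalization = character(),
                      region = character(), index = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (is.null(cohort) || nrow(cohort) == 0L) {
    return(structure(data.frame(), p_values = empty, alpha = alpha,
                     alpha2 = alpha2,
                     class = c("amrsid_report", "data.frame")))
  }
  needed <- c("subject_id", "group", "severity", "region", "normalization",
              "index", "value")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stopf("cohort table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  cells <- unique(cohort[c("normalization", "region", "index")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- cohort[cohort$normalization == cells$normalization[i] &
                    cohort$region == cells$region[i] &
                    cohort$index == cells$index[i], , drop = FALSE]
    sub <- sub[is.finite(sub$value), , drop = FALSE]
    groups <- unique(sub$group)
    pair_p <- function(g1, g2, p) {
      data.frame(comparison = paste(g1, g2, sep = "/"),
                 normalization = cells$normalization[i],
                 region = cells$region[i], index = cells$index[i],
                 p_value = p, stringsAsFactors = FALSE)
    }
    # pairwise pathology comparisons via omnibus + post-hoc
    if (length(groups) >= 2L && all(table(sub$group) >= 3L)) {
      res <- tryCatch(one_way_compare(sub$value, sub$group, alpha = alpha),
                      error = function(e) NULL)
      if (!is.null(res)) {
        prs <- utils::combn(sort(groups), 2)
        for (j in seq_len(ncol(prs))) {
          g1 <- prs[1, j]; g2 <- prs[2, j]
          p <- NA_real_
          if (length(groups) == 2L) {
            p <- res$p_value
          } else if (!is.null(res$posthoc)) {
            hit <- (res$posthoc$group1 == g1 & res$posthoc$group2 == g2) |
                   (res$posthoc$group1 == g2 & res$posthoc$group2 == g1)
            if (any(hit)) p <- res$posthoc$p_value[hit][1]
          } else {
            p <- 1  # omnibus not rejected: pairwise not pursued
          }
          rows[[length(rows) + 1L]] <- pair_p(g1, g2, p)
        }
      }
    }
    # severity effect among pathology subjects
    pat <- sub[sub$group != control & sub$severity %in% c("low", "high"), ,
               drop = FALSE]
    if (nrow(pat) > 0L && length(unique(pat$group)) >= 2L &&
        length(unique(pat$severity)) == 2L &&
        all(table(pat$group, pat$severity) >= 3L)) {
      res2 <- tryCatch(
        two_way_compare(pat$value, pat$group, pat$severity, alpha = alpha),
        error = function(e) NULL
      )
      if (!is.null(res2)) {
        rows[[length(rows) + 1L]] <- pair_p("severity low", "high",
                                            res2$effects$p[2])
      }
    }
  }
  long <- if (length(rows)) do.call(rbind, rows) else empty
  if (adjust != "none" && nrow(long)) {
    long$p_value <- p.adjust(long$p_value, method = adjust)
  }
  if (nrow(long)) {
    long$mark <- star_mark(long$p_value, alpha, alpha2)
    grid <- stats::reshape(
      long[c("comparison", "normalization", "region", "index", "mark")],
      idvar = c("comparison", "normalization", "region"),
      timevar = "index", direction = "wide"
    )
    names(grid) <- sub("^mark\\.", "", names(grid))
    grid <- grid[order(grid$comparison, grid$normalization, grid$region), ,
                 drop = FALSE]
    rownames(grid) <- NULL
    grid[is.na(grid)] <- ""
  } else {
    grid <- data.frame()
  }
  structure(grid, p_values = long, alpha = alpha, alpha2 = alpha2,
            class = c("amrsid_report", "data.frame"))
}

#' @export
print.amrsid_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<amrsid_report> empty\n")
    return(invisible(x))
  }
  cat("<amrsid_report> significance grid (*: p < ", attr(x, "alpha"),
      ", **: p < ", attr(x, "alpha2"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a significance report to disk
#'
#' @param report An `amrsid_report`.
#' @param path Output path.
#' @param format `"csv"` for the star grid, `"markdown"` for a pipe table,
#'   `"json"` for the long table of p-values.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "markdown", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(as.data.frame(report), path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(attr(report, "p_values"), path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    df <- as.data.frame(report)
    lines <- c(
      paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i) {
        paste0("| ", paste(unlist(df[i, ]), collapse = " | "), " |")
      }, character(1))
    )
    writeLines(lines, path)
  }
  invisible(path)
}
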