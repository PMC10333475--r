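# Group comparisons: summary-statistics one-way ANOVA, raw-data test
# batteries, Pearson chi-square, and the cohort summary table.

new_coa_htest <- function(statistic, df, p_value, method, note = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, note = note),
            class = "coa_htest")
}

#' @export
print.coa_htest <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("<coa_htest> %s: statistic = %.4f, df = (%s), p = %.4g\n",
              x$method, x$statistic, dfs, x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' One-way ANOVA from group summaries
#'
#' Computes the one-way ANOVA F statistic directly from per-group
#' `(mean, sem, n)` triplets, without raw data: with
#' `sd_i = sem_i * sqrt(n_i)`, the between-group sum of squares is
#' `SSB = sum n_i (xbar_i - xbar)^2` around the weighted grand mean and the
#' within-group sum of squares is `SSW = sum (n_i - 1) sd_i^2`, giving
#' `F = (SSB / (k - 1)) / (SSW / (N - k))` on `(k - 1, N - k)` degrees of
#' freedom.  This reproduces ANOVA on the raw data exactly whenever the
#' summaries were computed from those data.
#'
#' @param groups A list, each element either a `list(mean =, sem =, n =)`
#'   triplet or a numeric vector with those names.
#' @return A `coa_htest` with `method = "anova_summary"`.
#' @examples
#' anova_from_summary(list(c(mean = 0.6304, sem = 0.02607, n = 27),
#'                         c(mean = 0.6923, sem = 0.03201, n = 25),
#'                         c(mean = 0.6646, sem = 0.02213, n = 43)))
#' @export
anova_from_summary <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  tri <- lapply(groups, function(g) {
    g <- unlist(g)
    if (!all(c("mean", "sem", "n") %in% names(g)))
      stop("each group needs `mean`, `sem`, `n`", call. = FALSE)
    g[c("mean", "sem", "n")]
  })
  m <- vapply(tri, `[[`, numeric(1), "mean")
  sem <- vapply(tri, `[[`, numeric(1), "sem")
  n <- vapply(tri, `[[`, numeric(1), "n")
  if (any(n < 2))
    stop("every group needs n >= 2 (within-group variance undefined)",
         call. = FALSE)
  k <- length(m); N <- sum(n)
  sdv <- sem * sqrt(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * sdv^2)
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  new_coa_htest(Fstat, c(k - 1, N - k),
                stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE),
                "anova_summary")
}

#' Normality, variance-homogeneity and location tests on raw samples
#'
#' Runs, in the published order: a Kolmogorov-Smirnov normality check per
#' group (against a normal with the sample mean and SD; parameters are
#' estimated, so the test is conservative in the Lilliefors sense), a Levene
#' test (mean-centered) of variance homogeneity, and then the group
#' comparison -- pooled-variance one-way ANOVA (Student t for two groups) if
#' Levene does not reject at `alpha`, otherwise the Welch analogue.
#'
#' @param samples Named list of numeric vectors, one per group (each n >= 2).
#' @param alpha Significance level used for the Levene branch.
#' @return A list of `coa_htest` objects: `ks.<group>` per group, `levene`,
#'   and `comparison`.
#' @export
group_tests <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)))
    names(samples) <- paste0("g", seq_along(samples))
  if (any(vapply(samples, length, integer(1)) < 2))
    stop("every group needs n >= 2", call. = FALSE)
  if (any(vapply(samples, stats::sd, numeric(1)) == 0))
    stop("constant group (zero variance): Levene and t are undefined",
         call. = FALSE)
  out <- list()
  for (nm in names(samples)) {
    x <- samples[[nm]]
    ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x),
                                          stats::sd(x)))
    out[[paste0("ks.", nm)]] <-
      new_coa_htest(unname(ks$statistic), NA_real_, ks$p.value,
                    "ks_normality",
                    "parameters estimated from the sample (Lilliefors caveat)")
  }
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), vapply(samples, length, integer(1))))
  lev <- car::leveneTest(x, g, center = mean)
  out$levene <- new_coa_htest(lev[1, "F value"],
                              c(lev[1, "Df"], lev[2, "Df"]),
                              lev[1, "Pr(>F)"], "levene")
  equal_var <- out$levene$p_value >= alpha
  if (length(samples) == 2) {
    tt <- stats::t.test(samples[[1]], samples[[2]], var.equal = equal_var)
    out$comparison <- new_coa_htest(unname(tt$statistic),
                                    unname(tt$parameter), tt$p.value,
                                    if (equal_var) "t_student" else "t_welch")
  } else {
    ow <- stats::oneway.test(x ~ g, var.equal = equal_var)
    out$comparison <- new_coa_htest(unname(ow$statistic),
                                    unname(ow$parameter), ow$p.value,
                                    if (equal_var) "anova_raw" else
                                      "anova_welch")
  }
  out
}

#' Pearson chi-square test on a contingency table
#'
#' @param counts An R x C matrix of non-negative counts.
#' @return A `coa_htest` with the uncorrected Pearson statistic and
#'   `df = (R - 1)(C - 1)`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) == 0)
    stop("`counts` must be non-negative with positive total", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has a zero margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  new_coa_htest(unname(ct$statistic), unname(ct$parameter), ct$p.value,
                "chi_square")
}

#' Cohort summary table
#'
#' Builds the per-group summary table of a measured cohort: mean and SEM for
#' every numeric variable with the group-comparison statistic and p-value
#' (one-way ANOVA via [group_tests()], or a t-test for two groups), and
#' count (percentage) rows with a Pearson chi-square for logical/categorical
#' variables.  With a single group, only the summaries are reported.
#'
#' @param df A data.frame of per-case measurements.
#' @param group_col Name of the grouping column.
#' @param variables Variables to summarise (default: all numeric columns).
#' @param categorical Logical/factor columns to tabulate (default: all
#'   logical columns).
#' @return A data.frame with one row per variable; columns per group plus
#'   `statistic`, `method`, `p_value`.  Group percentages of the cohort are
#'   reported in the header row `n`.
#' @export
build_table1 <- function(df, group_col = "group", variables = NULL,
                         categorical = NULL) {
  stopifnot(is.data.frame(df), group_col %in% names(df))
  g <- factor(df[[group_col]])
  if (any(table(g) == 0) || nlevels(g) == 0)
    stop("empty group in `", group_col, "`", call. = FALSE)
  if (is.null(variables))
    variables <- names(df)[vapply(df, is.numeric, logical(1))]
  variables <- setdiff(variables, group_col)
  if (is.null(categorical))
    categorical <- names(df)[vapply(df, is.logical, logical(1))]

  lv <- levels(g)
  n_g <- as.integer(table(g))
  single <- nlevels(g) == 1

  header <- data.frame(variable = "n", row.names = NULL)
  for (i in seq_along(lv))
    header[[lv[i]]] <- sprintf("%d (%.1f%%)", n_g[i],
                               round(100 * n_g[i] / sum(n_g), 1))
  header$statistic <- NA_real_; header$method <- ""
  header$p_value <- NA_real_

  rows <- list(header)
  for (v in variables) {
    x <- df[[v]]
    cell <- vapply(lv, function(l) {
      xi <- x[g == l]
      sprintf("%.4f +/- %.4f", mean(xi), stats::sd(xi) / sqrt(length(xi)))
    }, character(1))
    row <- c(list(variable = v), as.list(cell))
    if (!single) {
      ht <- group_tests(split(x, g))$comparison
      row$statistic <- ht$statistic; row$method <- ht$method
      row$p_value <- ht$p_value
    } else {
      row$statistic <- NA_real_; row$method <- ""; row$p_value <- NA_real_
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row)
  }
  for (v in categorical) {
    x <- df[[v]]
    tab <- table(g, factor(x))
    cell <- vapply(lv, function(l) {
      k <- sum(x[g == l] %in% c(TRUE, levels(factor(x))[ncol(tab)]))
      sprintf("%d (%.1f%%)", k, round(100 * k / sum(g == l), 1))
    }, character(1))
    row <- c(list(variable = v), as.list(cell))
    if (!single && ncol(tab) > 1 && all(colSums(tab) > 0)) {
      ht <- chi_square_test(tab)
      row$statistic <- ht$statistic; row$method <- ht$method
      row$p_value <- ht$p_value
    } else {
      row$statistic <- NA_real_; row$method <- ""; row$p_value <- NA_real_
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
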