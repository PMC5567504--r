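new_group_test <- function(statistic, df1, df2, p_value, method) {
  structure(
    list(statistic = statistic, df1 = df1, df2 = df2, p_value = p_value,
         method = method),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat("<group_test>", x$method, ": F(", x$df1, ",", x$df2, ") =",
      signif(x$statistic, 4), ", p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' @describeIn anova_raw Tidy one-row summary of a group test (`statistic`,
#'   `df1`, `df2`, `p.value`, `method`).
#' @param x A `group_test`.
#' @export
tidy.group_test <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p.value = x$p_value, method = x$method)
}

#' @describeIn anova_raw Alias of `tidy()` for a `group_test`.
#' @export
glance.group_test <- function(x, ...) tidy(x, ...)

#' One-way ANOVA from raw data
#'
#' Classical F test of equal group means: `F = MS_between / MS_within` with
#' degrees of freedom `(k - 1, N - k)`.
#'
#' @param data Data frame with one row per subject.
#' @param value Name of the numeric outcome column.
#' @param group Name of the group-label column.
#' @param ... Unused.
#'
#' @return A `group_test` (see [tidy.group_test()]).
#' @export
#' @examples
#' cohort <- gen_clinical_cohort(cohort_presets(), seed = 1)
#' tidy(anova_raw(cohort, "fsiq", "group"))
anova_raw <- function(data, value = "value", group = "group", ...) {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  ns <- tabulate(g)
  if (any(ns < 2)) abort("Every group needs n >= 2.")
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  k <- nlevels(g)
  n <- length(y)
  if (ss_within <= 0) {
    abort("Zero within-group variance in every group; F is undefined.")
  }
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  new_group_test(f, k - 1, n - k, pf(f, k - 1, n - k, lower.tail = FALSE),
                 "one-way ANOVA")
}

#' One-way ANOVA from printed group summaries
#'
#' Reconstructs the F test from per-group mean, SD and n alone:
#' `SS_between = sum n_g (mean_g - grand)^2` and
#' `SS_within = sum (n_g - 1) SD_g^2` (sample SDs). On any raw dataset whose
#' summaries match exactly, the result equals [anova_raw()], which lets
#' published summary tables be checked without subject-level data.
#'
#' @param summary Data frame with columns `mean`, `sd`, `n` (one row per
#'   group; an optional `group` column is carried through).
#'
#' @return A `group_test`.
#' @export
#' @examples
#' fsiq <- tibble::tibble(
#'   group = c("TDC", "mADHD", "sADHD"),
#'   mean = c(123.0, 102.9, 104.9), sd = c(15.0, 8.0, 13.9), n = 15
#' )
#' tidy(anova_from_summary(fsiq))
anova_from_summary <- function(summary) {
  need <- setdiff(c("mean", "sd", "n"), names(summary))
  if (length(need) > 0) {
    abort(paste0("`summary` lacks column(s): ", toString(need)))
  }
  if (nrow(summary) < 2) abort("Need at least 2 groups.")
  if (any(summary$n < 2)) abort("Every group needs n >= 2.")
  if (any(summary$sd < 0)) abort("SDs must be >= 0.")
  n <- summary$n
  grand <- sum(n * summary$mean) / sum(n)
  ss_between <- sum(n * (summary$mean - grand)^2)
  ss_within <- sum((n - 1) * summary$sd^2)
  k <- nrow(summary)
  total <- sum(n)
  if (ss_within <= 0) {
    abort("Zero within-group variance in every group; F is undefined.")
  }
  f <- (ss_between / (k - 1)) / (ss_within / (total - k))
  new_group_test(f, k - 1, total - k,
                 pf(f, k - 1, total - k, lower.tail = FALSE),
                 "one-way ANOVA (from summaries)")
}

#' ANCOVA group test with nuisance covariates
#'
#' F test for the group factor from a nested linear-model comparison: the
#' covariates (default age) enter both models, the group dummies only the
#' full one, so the statistic measures group differences adjusted for the
#' covariates.
#'
#' @param data Data frame with one row per subject.
#' @param value Outcome column name.
#' @param group Group-label column name.
#' @param covariates Character vector of covariate column names
#'   (default `"age"`).
#'
#' @return A `group_test`; the covariates used are recorded in `$covariates`.
#' @export
ancova <- function(data, value = "value", group = "group",
                   covariates = "age") {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  Xc <- cbind(`(Intercept)` = 1, as.matrix(data[, covariates, drop = FALSE]))
  if (qr(Xc)$rank < ncol(Xc)) {
    abort("Covariate matrix is rank-deficient (collinear covariates).")
  }
  Xg <- stats::model.matrix(~g)[, -1, drop = FALSE]
  fit_reduced <- stats::lm.fit(Xc, y)
  fit_full <- stats::lm.fit(cbind(Xc, Xg), y)
  rss_r <- sum(fit_reduced$residuals^2)
  rss_f <- sum(fit_full$residuals^2)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - fit_full$rank
  if (rss_f <= 0) abort("Saturated full model; F is undefined.")
  f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  out <- new_group_test(f, df1, df2, pf(f, df1, df2, lower.tail = FALSE),
                        "ANCOVA")
  out$covariates <- covariates
  out
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and `n_a + n_b - 2` degrees of freedom
#' (two-sided p).
#'
#' @param a,b Numeric vectors, each with n >= 2.
#'
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @export
two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("Each sample needs n >= 2.")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0) abort("Zero pooled variance; t is undefined.")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  tibble(statistic = t, df = df, p.value = 2 * pt(-abs(t), df))
}

#' Benjamini-Hochberg step-up FDR correction
#'
#' Sorts the p-values ascending, finds the largest rank `i` with
#' `p_(i) <= (i/m) q`, and rejects all hypotheses up to that rank. Adjusted
#' p-values use the standard monotone cumulative-minimum transform of
#' `m p_(i) / i`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q Target false-discovery rate in (0, 1) (default 0.05).
#'
#' @return Tibble in input order: `p.value`, `p.adjusted`, `significant`.
#' @export
#' @examples
#' bh_correct(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
bh_correct <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  if (q <= 0 || q >= 1) abort("`q` must lie strictly in (0, 1).")
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  ok <- which(ranked <= seq_len(m) / m * q)
  cutoff_rank <- if (length(ok) > 0) max(ok) else 0L
  significant <- logical(m)
  if (cutoff_rank > 0) significant[ord[seq_len(cutoff_rank)]] <- TRUE
  adj_sorted <- rev(cummin(rev(pmin(1, m * ranked / seq_len(m)))))
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  tibble(p.value = p, p.adjusted = adjusted, significant = significant)
}

#' Bonferroni-corrected pairwise post-hoc tests
#'
#' Pooled-variance t-tests for every group pair (or a supplied subset), with
#' p-values multiplied by the number of pairs (capped at 1). Each pair is
#' reported with a direction string such as `"TDC>mADHD"` reflecting the
#' ordering of the sample means. Intended for measures that survived the
#' omnibus test.
#'
#' @param data Data frame with one row per subject.
#' @param value Outcome column name.
#' @param group Group-label column name.
#' @param pairs Optional list of length-2 character vectors naming the pairs
#'   to test (default: all pairs of observed levels).
#' @param alpha Significance level on the corrected scale (default 0.05).
#'
#' @return Tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `df`, `p.value`, `p.bonferroni`, `significant`, `direction`.
#' @export
bonferroni_posthoc <- function(data, value = "value", group = "group",
                               pairs = NULL, alpha = 0.05) {
  g <- factor(data[[group]])
  y <- data[[value]]
  if (is.null(pairs)) {
    lv <- levels(g)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  }
  n_pairs <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- y[g == pr[1]]
    b <- y[g == pr[2]]
    tt <- two_sample_t(a, b)
    p_adj <- min(1, tt$p.value * n_pairs)
    tibble(
      group1 = pr[1], group2 = pr[2],
      statistic = tt$statistic, df = tt$df, p.value = tt$p.value,
      p.bonferroni = p_adj, significant = p_adj < alpha,
      direction = if (mean(a) >= mean(b)) {
        paste0(pr[1], ">", pr[2])
      } else {
        paste0(pr[1], "<", pr[2])
      }
    )
  })
  dplyr::bind_rows(rows)
}

#' Omnibus + FDR + post-hoc comparison across a measure family
#'
#' The full group-comparison recipe for a family of measures (e.g. the 15
#' intra-/inter-module FCDs, or all ROIs of one centrality): run the omnibus
#' test (ANOVA, or ANCOVA when covariates are given) per measure, correct
#' the family of p-values by Benjamini-Hochberg, and annotate the surviving
#' measures with Bonferroni-corrected pairwise directions.
#'
#' @param data Wide data frame: one row per subject, one column per measure,
#'   plus the group (and covariate) columns.
#' @param measures Character vector of measure column names.
#' @param group Group-label column name.
#' @param covariates Optional covariate column names; when given the omnibus
#'   test is ANCOVA.
#' @param q Benjamini-Hochberg false-discovery rate (default 0.05).
#' @param posthoc_alpha Level of the Bonferroni post-hoc flags.
#'
#' @return Tidy tibble, one row per measure: `measure`, `statistic`, `df1`,
#'   `df2`, `p.value`, `p.adjusted`, `significant`, `posthoc` (comma-joined
#'   significant directions, `""` otherwise), `method`.
#' @export
#' @examples
#' cohort <- gen_clinical_cohort(cohort_presets(), seed = 1)
#' compare_groups(cohort, c("fsiq", "adhd_index"), group = "group")
compare_groups <- function(data, measures, group = "group",
                           covariates = NULL, q = 0.05,
                           posthoc_alpha = 0.05) {
  missing_m <- setdiff(measures, names(data))
  if (length(missing_m) > 0) {
    abort(paste0("Measure column(s) missing: ", toString(missing_m)))
  }
  tests <- lapply(measures, function(m) {
    keep <- !is.na(data[[m]])
    d <- data[keep, , drop = FALSE]
    if (is.null(covariates)) {
      anova_raw(d, m, group)
    } else {
      ancova(d, m, group, covariates)
    }
  })
  res <- dplyr::bind_rows(lapply(tests, tidy))
  res <- dplyr::mutate(res, measure = measures, .before = 1)
  corr <- bh_correct(res$p.value, q)
  res$p.adjusted <- corr$p.adjusted
  res$significant <- corr$significant
  res$posthoc <- vapply(seq_along(measures), function(i) {
    if (!res$significant[i]) return("")
    keep <- !is.na(data[[measures[i]]])
    ph <- bonferroni_posthoc(data[keep, , drop = FALSE], measures[i], group,
                             alpha = posthoc_alpha)
    paste(ph$direction[ph$significant], collapse = ", ")
  }, character(1))
  res
}
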