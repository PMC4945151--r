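# The statistical battery applied to crossing tables and ratio sets:
# pooled-variance two-sample t (the printed dfs equal n1 + n2 - 2, so
# Student's pooled form, not Welch), one-way ANOVA on natural-log ratios
# with Tukey HSD, Pearson correlation, and group summaries (mean, s.e.m.,
# t-based 95% CI).

#' Group summary: n, mean, s.e.m., 95% CI
#'
#' s.e.m. = SD / sqrt(n); the CI uses the t quantile with n - 1 df. For a
#' single value the s.e.m. and CI are undefined and flagged `NA`.
#'
#' @param values numeric vector, n >= 1.
#' @return list with `n`, `mean`, `sem`, `ci` (length 2).
#' @export
group_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1L) stop("group_summary needs at least one finite value")
  m <- mean(values)
  if (n == 1L) {
    return(list(n = 1L, mean = m, sem = NA_real_, ci = c(NA_real_, NA_real_)))
  }
  sem <- stats::sd(values) / sqrt(n)
  half <- stats::qt(0.975, n - 1L) * sem
  list(n = n, mean = m, sem = sem, ci = c(m - half, m + half))
}

#' Independent-sample Student's t-test (pooled variance)
#'
#' Two-sided pooled-variance t with df = n1 + n2 - 2, per-group mean +/-
#' s.e.m. and t-based 95% CI, and Cohen's d with the pooled SD.
#'
#' @param group_a,group_b numeric vectors, each n >= 2.
#' @return a `test_result` list: statistic, df, p_value, cohens_d, and
#'   per-group summaries (with CIs).
#' @export
students_t_pooled <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need n >= 2 finite values")
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b))
      stop("zero pooled variance with equal means: t undefined")
    warning("zero pooled variance with unequal means; |t| is infinite")
  }
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(list(statistic = tval, df = df,
                 p_value = 2 * stats::pt(-abs(tval), df),
                 cohens_d = (mean(a) - mean(b)) / sqrt(sp2),
                 group_a = group_summary(a), group_b = group_summary(b),
                 test = "students_t_pooled"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s: statistic %.4g", x$test, x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df %s", paste(x$df, collapse = ",")))
  cat(sprintf(", p %.3g>\n", x$p_value))
  invisible(x)
}

#' One-way ANOVA on log-transformed ratios with Tukey HSD
#'
#' Ratios are natural-log transformed (the F test is base-invariant);
#' non-positive ratios are excluded with a logged count before the
#' transform.
#'
#' @param groups named list of >= 2 numeric ratio vectors.
#' @return a `test_result` list: `statistic` (F), `df` (between, within),
#'   `p_value`, `tukey` (pairwise table), `n_excluded`.
#' @export
anova_log_ratios <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("anova_log_ratios needs a list of >= 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  excluded <- 0L
  for (g in names(groups)) {
    bad <- !(is.finite(groups[[g]]) & groups[[g]] > 0)
    excluded <- excluded + sum(bad)
    groups[[g]] <- groups[[g]][!bad]
    if (length(groups[[g]]) == 0L)
      stop(sprintf("group '%s' is empty after excluding non-positive ratios", g))
  }
  if (excluded > 0L) ab_log("excluded %d non-positive ratios before log ANOVA",
                            excluded)
  y <- log(unlist(groups, use.names = FALSE))
  f <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(y ~ f)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$f
  structure(list(statistic = an[1, "F value"],
                 df = c(between = an[1, "Df"], within = an[2, "Df"]),
                 p_value = an[1, "Pr(>F)"],
                 tukey = data.frame(pair = rownames(tk), tk,
                                    row.names = NULL, check.names = FALSE),
                 n_excluded = excluded, test = "anova_log_ratios"),
            class = "test_result")
}

#' Pearson correlation with two-sided p-value
#'
#' @param series_a,series_b numeric vectors of equal length >= 3,
#'   non-constant.
#' @return a `test_result` list with `statistic` (r), `df`, `p_value`.
#' @export
pearson_r <- function(series_a, series_b) {
  if (length(series_a) != length(series_b))
    stop("series must have equal length")
  ok <- is.finite(series_a) & is.finite(series_b)
  a <- series_a[ok]; b <- series_b[ok]
  if (length(a) < 3L) stop("need at least 3 paired finite values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant series")
  ct <- stats::cor.test(a, b, method = "pearson")
  structure(list(statistic = unname(ct$estimate),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 test = "pearson_r"),
            class = "test_result")
}
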