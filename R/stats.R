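#' One-way ANOVA over an evaluation table
#'
#' Treatments/error/total decomposition of a response (accuracy or ITR)
#' across approaches, computed with [stats::aov()]. Sums of squares are
#' additive (`SS_total = SS_treatments + SS_error`), `MS = SS / df` and
#' `F = MS_treatments / MS_error`.
#'
#' @param data long data.frame of observations.
#' @param response name of the numeric response column.
#' @param group name of the grouping column (default `"approach"`).
#' @return data.frame with rows `treatments`, `error`, `total` and columns
#'   `source`, `df`, `ss`, `ms`, `f`.
#' @export
one_way_anova <- function(data, response, group = "approach") {
  g <- factor(data[[group]])
  y <- data[[response]]
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("need at least 2 observations per group",
                               call. = FALSE)
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1L]]
  ss <- tab[["Sum Sq"]]; df <- tab[["Df"]]
  anova_from_sums(ss[1L], df[1L], ss[2L], df[2L])
}

#' ANOVA table from sums of squares
#'
#' Completes a one-way ANOVA decomposition given the treatment and error sums
#' of squares with their degrees of freedom: mean squares, F statistic, and
#' the total row.
#'
#' @param ss_treatments,df_treatments treatment (between-group) SS and df.
#' @param ss_error,df_error error (within-group) SS and df.
#' @return data.frame with rows `treatments`, `error`, `total`.
#' @export
anova_from_sums <- function(ss_treatments, df_treatments, ss_error, df_error) {
  ms_t <- ss_treatments / df_treatments
  ms_e <- ss_error / df_error
  data.frame(
    source = c("treatments", "error", "total"),
    df = c(df_treatments, df_error, df_treatments + df_error),
    ss = c(ss_treatments, ss_error, ss_treatments + ss_error),
    ms = c(ms_t, ms_e, NA_real_),
    f = c(ms_t / ms_e, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
}

#' Tukey critical difference
#'
#' The honestly-significant-difference threshold `q * sqrt(mse / n_per_group)`
#' for pairwise group-mean comparisons: differences exceeding it are declared
#' significant at the level the studentized-range quantile `q` was taken at.
#'
#' @param q studentized-range quantile (e.g. `qtukey(0.95, groups, df)`).
#' @param mse ANOVA mean square error.
#' @param n_per_group observations per group.
#' @return the critical difference.
#' @export
tukey_critical_difference <- function(q, mse, n_per_group) {
  if (q <= 0 || n_per_group <= 0 || mse < 0) {
    stop("q and n_per_group must be positive, mse non-negative", call. = FALSE)
  }
  q * sqrt(mse / n_per_group)
}

#' Post-hoc Tukey test over an evaluation table
#'
#' Runs the one-way ANOVA, derives the critical difference (studentized-range
#' quantile at `level` unless `q` is supplied) and compares every pair of
#' group means against it.
#'
#' @inheritParams one_way_anova
#' @param level confidence level for the default quantile.
#' @param q optional fixed studentized-range quantile (overrides `level`).
#' @return list with `anova` (the decomposition), `dvs` (critical
#'   difference) and `comparisons` (pairwise data.frame: groups, |mean
#'   difference|, significance).
#' @export
tukey_test <- function(data, response, group = "approach", level = 0.95,
                       q = NULL) {
  g <- factor(data[[group]])
  aov_tab <- one_way_anova(data, response, group)
  mse <- aov_tab$ms[2L]
  df_err <- aov_tab$df[2L]
  n_per <- min(table(g))
  if (is.null(q)) q <- stats::qtukey(level, nlevels(g), df_err)
  dvs <- tukey_critical_difference(q, mse, n_per)
  means <- tapply(data[[response]], g, mean)
  pairs <- utils::combn(levels(g), 2L)
  comparisons <- data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    diff = abs(means[pairs[1L, ]] - means[pairs[2L, ]]),
    stringsAsFactors = FALSE)
  comparisons$significant <- comparisons$diff > dvs
  rownames(comparisons) <- NULL
  list(anova = aov_tab, q = q, dvs = dvs, comparisons = comparisons)
}
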