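#' Statistical battery for segmentation and SUV comparisons
#'
#' Thin, contract-checked wrappers around the classical tests used to
#' compare segmentation accuracy and regional SUVs: paired t-test,
#' one-way ANOVA, variance-ratio F-test, and the two-sample t-test. All
#' p-values are two-sided and uncorrected for multiple comparisons
#' (surfaced in the result metadata); significance is declared at
#' alpha = 0.05.
#'
#' @param statistic,p_value,df,test_name,extra Fields of the result.
#' @return A `test_result` with `statistic`, `p_value`, `df`,
#'   `test_name`, `decision` (`"significant"` iff p < 0.05), `alpha`,
#'   and `correction = "uncorrected"`.
#' @keywords internal
test_result <- function(statistic, p_value, df, test_name, extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(statistic = unname(statistic),
                   p_value = unname(p_value), df = unname(df),
                   test_name = test_name,
                   decision = if (p_value < 0.05) "significant"
                              else "not_significant",
                   alpha = 0.05, correction = "uncorrected"),
              extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$test_name, ": statistic = ",
      signif(x$statistic, 5), ", df = ", paste(signif(x$df, 5),
      collapse = ", "), ", p = ", signif(x$p_value, 4), " (", x$decision,
      ")\n", sep = "")
  invisible(x)
}

#' Paired t-test
#'
#' Classic paired t on the differences `x - y`, two-sided p from the t
#' distribution with n - 1 degrees of freedom.
#'
#' @param x,y Paired numeric vectors of equal length n >= 2.
#' @return A `test_result`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    nq_stop("paired t-test needs equal-length samples with n >= 2",
            class = "validation_error")
  d <- x - y
  if (stats::sd(d) < .Machine$double.eps) {
    if (abs(mean(d)) < .Machine$double.eps)
      return(test_result(0, 1, length(d) - 1, "paired t-test"))
    nq_stop("differences have zero variance with nonzero mean ",
            signif(mean(d), 5), ": statistic is infinite",
            class = "infinite_statistic_error")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  test_result(ht$statistic, ht$p.value, ht$parameter, "paired t-test")
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within with a two-sided p from the F distribution;
#' used to compare quantitative SUVs among segmentation methods.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return A `test_result` (df is `c(between, within)`).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    nq_stop("one_way_anova needs at least 2 groups",
            class = "validation_error")
  if (any(vapply(groups, length, 1L) < 2L))
    nq_stop("every group needs n >= 2", class = "validation_error")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (stats::sd(y) < .Machine$double.eps)
    return(test_result(0, 1, c(nlevels(g) - 1, length(y) - nlevels(g)),
                       "one-way ANOVA"))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  stat <- unname(ht$statistic)
  p <- unname(ht$p.value)
  if (!is.finite(stat)) stat <- 0
  if (is.na(p)) p <- 1
  test_result(stat, p, unname(ht$parameter), "one-way ANOVA")
}

#' Variance-ratio F-test for homogeneity of variances
#'
#' F = s^2_x / s^2_y with a two-sided p (doubling rule); variances are
#' declared homogeneous when p > 0.05 — the precondition for using the
#' pooled two-sample t-test.
#'
#' @param x,y Numeric vectors, each n >= 2.
#' @return A `test_result` with an extra logical field `homogeneous`.
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    nq_stop("variance F-test needs n >= 2 in both samples",
            class = "validation_error")
  if (stats::sd(x) < .Machine$double.eps &&
      stats::sd(y) < .Machine$double.eps)
    nq_stop("both samples have zero variance: F is undefined",
            class = "undefined_input_error")
  ht <- stats::var.test(x, y)
  test_result(ht$statistic, ht$p.value, ht$parameter,
              "variance-ratio F-test",
              extra = list(homogeneous = ht$p.value > 0.05))
}

#' Two-sample t-test (pooled or Welch)
#'
#' Two-tailed two-sample t comparing regional SUVs between groups. With
#' `equal_var = NULL` the variance-homogeneity decision is delegated to
#' [variance_f_test()]: homogeneous variances (p > 0.05) select the
#' pooled test, otherwise Welch.
#'
#' @param x,y Numeric vectors, each n >= 2.
#' @param equal_var `TRUE` (pooled), `FALSE` (Welch), or `NULL`
#'   (decide by F-test).
#' @return A `test_result` with extra fields `equal_var` and
#'   `variance_test` (the F-test result when it was consulted).
#' @export
two_sample_t <- function(x, y, equal_var = NULL) {
  if (length(x) < 2L || length(y) < 2L)
    nq_stop("two-sample t-test needs n >= 2 in both samples",
            class = "validation_error")
  vt <- NULL
  if (is.null(equal_var)) {
    vt <- variance_f_test(x, y)
    equal_var <- vt$homogeneous
  }
  if (stats::sd(c(x, y)) < .Machine$double.eps)
    return(test_result(0, 1, length(x) + length(y) - 2,
                       "two-sample t-test",
                       extra = list(equal_var = equal_var,
                                    variance_test = vt)))
  ht <- stats::t.test(x, y, var.equal = equal_var)
  test_result(ht$statistic, ht$p.value, ht$parameter,
              if (equal_var) "two-sample t-test (pooled)"
              else "two-sample t-test (Welch)",
              extra = list(equal_var = equal_var, variance_test = vt))
}

#' Region-wise group comparison of SUV quantifications
#'
#' For each region, compares the per-subject `suv_mean` between two
#' groups with the variance-F-then-t decision rule.
#'
#' @param quant_by_subject data.frame with columns `subject`, `group`,
#'   `label`, `name`, `suv_mean` (one row per subject x region), e.g.
#'   stacked outputs of [regional_quantify()].
#' @param group_a,group_b Group levels to compare (x = a, y = b).
#' @return data.frame with per-region group means/SDs, F statistic and
#'   its p, t statistic, p-value and decision.
#' @export
compare_groups_by_region <- function(quant_by_subject, group_a, group_b) {
  need <- c("group", "label", "name", "suv_mean")
  if (!all(need %in% names(quant_by_subject)))
    nq_stop("quant table must have columns ",
            paste(need, collapse = ", "), class = "validation_error")
  labs <- unique(quant_by_subject$label)
  rows <- lapply(labs, function(lab) {
    sub <- quant_by_subject[quant_by_subject$label == lab, ]
    x <- sub$suv_mean[sub$group == group_a]
    y <- sub$suv_mean[sub$group == group_b]
    vt <- variance_f_test(x, y)
    tt <- two_sample_t(x, y, equal_var = vt$homogeneous)
    data.frame(label = lab, name = sub$name[1],
               mean_a = mean(x), sd_a = stats::sd(x),
               mean_b = mean(y), sd_b = stats::sd(y),
               f_statistic = vt$statistic, f_p = vt$p_value,
               variance_homogeneous = vt$homogeneous,
               t_statistic = tt$statistic, p_value = tt$p_value,
               decision = tt$decision)
  })
  do.call(rbind, rows)
}
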