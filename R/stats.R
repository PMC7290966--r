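#' Welch two-sample t-test
#'
#' Two-tailed Welch t-test (unequal variances, Welch-Satterthwaite degrees
#' of freedom) via [stats::t.test()], returned as a flat comparison record.
#'
#' @param x,y Numeric samples, each with at least 2 values.
#' @param label Comparison label carried into result tables.
#' @return List of class `group_comparison`: `statistic`, `df`,
#'   `p_two_tailed`, `estimate` (mean difference x - y), `cohens_d`,
#'   `comparison_label`, `test`.
#' @export
welch_t_test <- function(x, y, label = "x vs y") {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both samples")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  sp <- sqrt((stats::var(x) * (length(x) - 1) + stats::var(y) * (length(y) - 1)) /
               (length(x) + length(y) - 2))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_two_tailed = ht$p.value,
                 estimate = mean(x) - mean(y),
                 cohens_d = if (sp > 0) (mean(x) - mean(y)) / sp else NA_real_,
                 comparison_label = label, test = "welch_t"),
            class = "group_comparison")
}

#' Paired t-test
#'
#' One-sample two-tailed t-test on index-paired differences via
#' [stats::t.test()].
#'
#' @param x,y Equal-length numeric samples (n >= 2), paired by index.
#' @param label Comparison label.
#' @return A `group_comparison` record.
#' @export
paired_t_test <- function(x, y, label = "paired x vs y") {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::var(d) == 0) stop("paired differences have zero variance")
  ht <- stats::t.test(d)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_two_tailed = ht$p.value, estimate = mean(d),
                 cohens_d = mean(d) / stats::sd(d),
                 comparison_label = label, test = "paired_t"),
            class = "group_comparison")
}

#' One-way ANOVA
#'
#' Classical equal-variance one-way ANOVA
#' (`F = MS_between / MS_within`, `df1 = k - 1`, `df2 = n - k`) via
#' [stats::oneway.test()] with `var.equal = TRUE`.
#'
#' @param groups Named or unnamed list of numeric samples (>= 2 groups,
#'   each n >= 2).
#' @param label Comparison label.
#' @return A `group_comparison` record with `df1`, `df2` in place of `df`.
#' @export
one_way_anova <- function(groups, label = "one-way ANOVA") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("every group needs n >= 2")
  if (all(vapply(groups, stats::var, numeric(1)) == 0))
    stop("zero within-group variance everywhere")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  structure(list(statistic = unname(ht$statistic),
                 df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
                 p_two_tailed = ht$p.value, estimate = NA_real_,
                 cohens_d = NA_real_,
                 comparison_label = label, test = "anova"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (identical(x$test, "anova")) {
    cat(sprintf("%s: F(%g, %g) = %.3f, p = %.4g\n", x$comparison_label,
                x$df1, x$df2, x$statistic, x$p_two_tailed))
  } else {
    cat(sprintf("%s: t(%.2f) = %.3f, p = %.4g\n", x$comparison_label,
                x$df, x$statistic, x$p_two_tailed))
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()] (`method = "BH"`),
#' order-preserving with the input and capped at 1. Inputs must lie in
#' `(0, 1]`.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values), length(p_values) >= 1)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
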