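# Automatic test selection for group comparisons: normality is checked
# first (Shapiro-Wilk per group); non-normal data route to the
# Mann-Whitney U test, otherwise a median-centered Levene test decides
# between Student's t (equal variances) and Welch's t. All tests are
# two-sided at alpha = 0.05 by default, and the decision trail is
# recorded so the selected test is fully reproducible.

new_st_test <- function(test_name, statistic, p_value, alpha, trail,
                        note = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), alpha = alpha,
                 decision_trail = trail, note = note),
            class = "st_test")
}

#' @export
print.st_test <- function(x, ...) {
  cat(sprintf("<st_test> %s: statistic %.4g, p = %.4g (alpha %.3g)%s\n",
              x$test_name, x$statistic, x$p_value, x$alpha,
              if (x$p_value < x$alpha) " *" else ""))
  tr <- x$decision_trail
  if (length(tr))
    cat("  trail:", paste(names(tr), vapply(tr, format, ""), sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Median-centered Levene (Brown-Forsythe) test for equal variances
#'
#' One-way ANOVA on absolute deviations from the group medians.
#'
#' @param groups list of numeric vectors.
#' @return list with `statistic` (F) and `p_value`.
#' @export
levene_test <- function(groups) {
  z <- unlist(lapply(groups, function(g) abs(g - median(g))))
  f <- factor(rep(seq_along(groups), lengths(groups)))
  if (sd(z) == 0) return(list(statistic = 0, p_value = 1))
  a <- anova(lm(z ~ f))
  list(statistic = a$`F value`[1L], p_value = a$`Pr(>F)`[1L])
}

#' Two-group comparison with automatic test selection
#'
#' Implements the selection scheme used throughout the analyses:
#' Shapiro-Wilk normality on each group at `alpha`; if either group
#' rejects (or is degenerate/constant), the two-sided Mann-Whitney U
#' test is used. Otherwise a median-centered Levene test decides
#' between Welch's t (unequal variances) and Student's t. The outcome
#' of every check is returned in `decision_trail`.
#'
#' @param a,b numeric vectors, each with at least 3 observations.
#' @param alpha significance level for the comparison and for the
#'   selection checks.
#' @param n_comparisons Bonferroni divisor for families of comparisons;
#'   the reported p-value is multiplied by it (default 1 — no
#'   correction, as none is applied to single comparisons).
#' @return an [`st_test`][print.st_test] object with `test_name` one of
#'   `"student_t"`, `"welch_t"`, `"mann_whitney"`.
#' @examples
#' set.seed(1)
#' select_and_compare(rnorm(20), rnorm(20, 1))
#' @export
select_and_compare <- function(a, b, alpha = 0.05, n_comparisons = 1) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stopf("each group needs >= 3 observations (got %d and %d)",
          length(a), length(b),
          class = "spatialtime_insufficient_data_error")
  check_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE)
  sw <- function(x) {
    if (sd(x) == 0) return(0)      # constant group: clearly non-normal
    shapiro.test(x)$p.value
  }
  sp_a <- sw(a); sp_b <- sw(b)
  normal <- sp_a >= alpha && sp_b >= alpha
  trail <- list(shapiro_p_a = sp_a, shapiro_p_b = sp_b,
                normal = normal, levene_p = NA_real_,
                equal_variance = NA)
  if (!normal) {
    ht <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    res <- new_st_test("mann_whitney", ht$statistic, ht$p.value, alpha,
                       trail)
  } else {
    lev <- levene_test(list(a, b))
    trail$levene_p <- lev$p_value
    trail$equal_variance <- lev$p_value >= alpha
    ht <- t.test(a, b, var.equal = trail$equal_variance,
                 alternative = "two.sided")
    res <- new_st_test(if (trail$equal_variance) "student_t" else "welch_t",
                       ht$statistic, ht$p.value, alpha, trail)
  }
  if (n_comparisons > 1)
    res$p_value <- min(1, res$p_value * n_comparisons)
  res
}

#' One-way ANOVA across multiple groups
#'
#' Ordinary (equal-variance) one-way ANOVA, as used for multi-group
#' comparisons such as uninjured vs day-7 vs day-21 quantifications.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha significance level recorded in the result.
#' @return an `st_test` with `test_name = "anova"`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need a list of >= 2 groups", class = "spatialtime_config_error")
  if (any(lengths(groups) < 2L))
    stopf("every group needs >= 2 observations",
          class = "spatialtime_insufficient_data_error")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  if (ssw == 0)
    stopf("zero within-group variance; ANOVA is degenerate",
          class = "spatialtime_degenerate_input_error")
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  new_st_test("anova", ht$statistic, ht$p.value, alpha,
              list(n_groups = length(groups)))
}

#' Percent-positive cell quantification
#'
#' The percentage of positive cells among all counted cells, as used
#' for immunofluorescence ROI quantifications.
#'
#' @param n_positive,n_total non-negative counts with
#'   `n_positive <= n_total`, `n_total > 0`; vectors are accepted
#'   elementwise.
#' @return `100 * n_positive / n_total`.
#' @export
percent_positive <- function(n_positive, n_total) {
  if (any(n_total <= 0))
    stopf("n_total must be positive", class = "spatialtime_validation_error")
  if (any(n_positive < 0) || any(n_positive > n_total))
    stopf("need 0 <= n_positive <= n_total",
          class = "spatialtime_validation_error")
  100 * n_positive / n_total
}
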