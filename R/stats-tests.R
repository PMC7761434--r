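#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' SD estimated from the sample, with the Lilliefors-corrected p-value
#' (delegated to \code{nortest::lillie.test}). Used to check that the
#' populations of cross-validation accuracies are compatible with
#' normality before the pooled t-test.
#'
#' @param x Numeric sample, at least 4 non-degenerate values.
#' @param alpha Significance level for the reject flag.
#' @return A one-row tibble: `method`, `statistic`, `p_value`, `alpha`,
#'   `reject` (`p_value <= alpha`).
#' @export
lilliefors_test <- function(x, alpha = 0.05) {
  check_sequence(x)
  check_alpha(alpha)
  if (length(x) < 4L) abort("need at least 4 observations")
  if (is_constant(x)) abort("degenerate sample: zero standard deviation")
  res <- nortest::lillie.test(x)
  test_row("Lilliefors normality", unname(res$statistic), res$p.value, alpha)
}

#' Test for equality of two group variances
#'
#' Bartlett's test by default (the classical grouped-data equal-variance
#' test); Levene's test (ANOVA on absolute deviations, via
#' \code{car::leveneTest}) is available as a robust alternative.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @param method `"bartlett"` or `"levene"`.
#' @param alpha Significance level.
#' @return A one-row tibble as in [lilliefors_test()].
#' @export
equal_variance_test <- function(x, y, method = c("bartlett", "levene"),
                                alpha = 0.05) {
  method <- match.arg(method)
  check_sequence(x); check_sequence(y)
  check_alpha(alpha)
  if (length(x) < 2L || length(y) < 2L) {
    abort("both samples need at least 2 observations")
  }
  if (is_constant(x) && is_constant(y)) {
    abort("degenerate samples: both variances are zero")
  }
  if (method == "bartlett") {
    res <- stats::bartlett.test(list(x, y))
    test_row("Bartlett equal variances", unname(res$statistic),
             res$p.value, alpha)
  } else {
    g <- factor(rep(c("x", "y"), c(length(x), length(y))))
    lv <- car::leveneTest(c(x, y), g, center = stats::median)
    test_row("Levene equal variances", lv$`F value`[1], lv$`Pr(>F)`[1],
             alpha)
  }
}

#' Pooled two-sample t-test
#'
#' Equal-variance two-sample t statistic
#' \deqn{t = \frac{\bar x - \bar y}{\sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}
#' {n_1+n_2-2}\left(\frac{1}{n_1}+\frac{1}{n_2}\right)}}}
#' with `n1 + n2 - 2` degrees of freedom, used to compare two populations
#' of cross-validation accuracies. Two-sided by default; the null is
#' rejected when `p <= alpha`. When the pooled variance is zero the
#' statistic degenerates: `t = 0, p = 1` for equal means and
#' `t = +/-Inf, p = 0` otherwise.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @param alpha Significance level.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `alpha`, `reject`.
#' @examples
#' pooled_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
pooled_t_test <- function(x, y, alpha = 0.05,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_sequence(x); check_sequence(y)
  check_alpha(alpha)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) abort("both samples need at least 2 observations")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    t_stat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(t_stat), df),
    greater = pt(t_stat, df, lower.tail = FALSE),
    less = pt(t_stat, df)
  )
  out <- test_row("Pooled two-sample t", t_stat, p, alpha)
  tibble::add_column(out, df = df, .after = "statistic")
}

#' Full statistical comparison of two accuracy populations
#'
#' The comparison chain applied to two populations of repeated-CV
#' accuracies: Lilliefors normality on each group, an equal-variance test
#' across groups, then the pooled two-sample t-test.
#'
#' @inheritParams equal_variance_test
#' @inheritParams pooled_t_test
#' @param var_method Passed to [equal_variance_test()].
#' @return A tibble with one row per test (`test` column identifies them)
#'   and the columns of the individual test tibbles.
#' @examples
#' compare_cv(rnorm(100, 93.9), rnorm(100, 93.2))
#' @export
compare_cv <- function(x, y, alpha = 0.05,
                       var_method = c("bartlett", "levene"),
                       alternative = c("two.sided", "greater", "less")) {
  var_method <- match.arg(var_method)
  alternative <- match.arg(alternative)
  dplyr::bind_rows(
    dplyr::mutate(lilliefors_test(x, alpha), test = "normality_x"),
    dplyr::mutate(lilliefors_test(y, alpha), test = "normality_y"),
    dplyr::mutate(equal_variance_test(x, y, var_method, alpha),
                  test = "equal_variance"),
    dplyr::mutate(pooled_t_test(x, y, alpha, alternative), test = "t_test")
  ) |>
    dplyr::relocate("test")
}

#' Group and pooled summary of two samples
#'
#' Per-group and combined counts and means, as reported alongside the
#' comparison chain (the pooled mean of two groups of 100 with means 93.86
#' and 93.18 is 93.52).
#'
#' @param x,y Numeric samples.
#' @return A tibble with rows `group1`, `group2`, `pooled` and columns
#'   `group`, `n`, `mean`, `sd`.
#' @export
pooled_summary <- function(x, y) {
  check_sequence(x); check_sequence(y)
  tibble::tibble(
    group = c("group1", "group2", "pooled"),
    n = c(length(x), length(y), length(x) + length(y)),
    mean = c(mean(x), mean(y), mean(c(x, y))),
    sd = c(sd(x), sd(y), sd(c(x, y)))
  )
}

test_row <- function(method, statistic, p_value, alpha) {
  tibble::tibble(method = method, statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value), alpha = alpha,
                 reject = p_value <= alpha)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("alpha must be a single number in (0, 1)")
  }
  invisible(alpha)
}
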