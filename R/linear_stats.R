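#' Point-biserial correlation of expression against a binary label
#'
#' The Pearson product-moment correlation between a continuous vector and the
#' 0/1 encoding of a binary label (the point-biserial correlation). The sign
#' follows the label encoding (second label lexicographically is 1); the
#' magnitude, and hence \code{r2}, does not depend on it.
#'
#' @inheritParams mic_binary
#' @return A list with \code{r}, \code{r2} (\code{= r^2}), and \code{abs_r}.
#'   For a constant \code{x} the correlation is undefined: all three fields
#'   are \code{NA}, which downstream NDC scoring converts into a rank-last
#'   sentinel.
#' @export
point_biserial <- function(x, y) {
  y01 <- .validate_series(x, y)
  if (stats::var(x) == 0)
    return(list(r = NA_real_, r2 = NA_real_, abs_r = NA_real_))
  r <- stats::cor(x, y01)
  list(r = r, r2 = r * r, abs_r = abs(r))
}

#' Two-sample t-test comparator
#'
#' The linear differential-expression baseline: a two-sample t-test of
#' expression between the two label classes, Welch's unequal-variance form by
#' default (Welch-Satterthwaite degrees of freedom), or the pooled-variance
#' form with \code{var_equal = TRUE}. The statistic is oriented as
#' class-0 mean minus class-1 mean, so swapping the labels negates \code{t}
#' and leaves \code{p} unchanged.
#'
#' @inheritParams mic_binary
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @return A list with \code{t} (statistic) and \code{p} (two-sided p-value).
#' @export
welch_t <- function(x, y, var_equal = FALSE) {
  y01 <- .validate_series(x, y)
  if (sum(y01 == 0L) < 2L || sum(y01 == 1L) < 2L)
    stop("each class needs at least 2 samples for the t-test")
  ht <- stats::t.test(x[y01 == 0L], x[y01 == 1L], var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Yates-corrected chi-square test on a 2x2 contingency table
#'
#' Pearson's chi-square test of association with Yates' continuity
#' correction, df = 1: per cell \code{(max(|O - E| - 0.5, 0))^2 / E}, summed.
#' This is the convention that reproduces printed contingency p-values for
#' tumor-grade and vital-status cross-tabulations of expression groups.
#'
#' @param a,b,c,d Cell counts, row-wise: \code{rbind(c(a, b), c(c, d))}.
#'   Alternatively \code{a} may be a 2x2 matrix with \code{b}, \code{c},
#'   \code{d} missing.
#' @return A list with \code{statistic} and \code{p} (upper tail of
#'   chi-square with 1 df).
#' @examples
#' chi2_yates(16, 10, 10, 29)  # p = 0.0084
#' chi2_yates(28, 8, 4, 11)    # p = 0.0018
#' @export
chi2_yates <- function(a, b, c, d) {
  # `c` is a formal here; base::c must be called explicitly
  tab <- if (is.matrix(a)) a else rbind(base::c(a, b), base::c(c, d))
  if (!identical(dim(tab), base::c(2L, 2L))) stop("a 2x2 table is required")
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("cell counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("every row and column marginal must be positive")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
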