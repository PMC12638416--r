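#' Pearson correlation with a two-sided t-test
#'
#' @param x,y paired numeric vectors (n >= 3, neither constant).
#' @return list with `rho`, `p_value` and `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("pearson_corr needs n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("pearson_corr undefined for constant input", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Deming errors-in-variables regression
#'
#' Fits `y = intercept + slope * x` assuming measurement error in both
#' variables, governed by the error-variance ratio `lambda`. Closed form:
#' `slope = (s_yy - lambda*s_xx + sqrt((s_yy - lambda*s_xx)^2 +
#' 4*lambda*s_xy^2)) / (2*s_xy)`, `intercept = mean(y) - slope*mean(x)`.
#' `lambda = 1` is orthogonal regression, the usual default for method
#' comparison; `lambda -> Inf` approaches ordinary least squares of y on x.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param lambda positive error-variance ratio (default 1).
#' @return A `deming_fit` list: `slope`, `intercept`, `lambda`, `n`,
#'   `degenerate` (TRUE when the covariance is zero and the slope is
#'   undefined).
#' @export
deming_regression <- function(x, y, lambda = 1) {
  stopifnot(length(x) == length(y), lambda > 0)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("deming_regression needs n >= 3", call. = FALSE)
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  if (sxx == 0 && syy == 0) {
    stop("deming_regression undefined: degenerate scatter", call. = FALSE)
  }
  if (sxy == 0) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          lambda = lambda, n = length(x), degenerate = TRUE),
                     class = "deming_fit"))
  }
  slope <- (syy - lambda * sxx +
              sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
    (2 * sxy)
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 lambda = lambda, n = length(x), degenerate = FALSE),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming regression (lambda = %g, n = %d): y = %.4g + %.4g x\n",
              x$lambda, x$n, x$intercept, x$slope))
  invisible(x)
}

#' Two-tailed Mann-Whitney test
#'
#' Rank-sum test with midranks for ties. The exact null distribution is used
#' when `n_x * n_y <= 400` and there are no ties; otherwise the normal
#' approximation with tie and continuity correction. `U` counts pairs with
#' `x > y` (ties as 1/2), so `1 - U/(n_x*n_y)` is the empirical AUC treating
#' `x` as the negative group.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `U`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`) and the sample sizes.
#' @export
mann_whitney_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) * length(y) <= 400) && !has_ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal_approx",
       n_x = length(x), n_y = length(y))
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' The two-tailed p-value sums the hypergeometric probabilities of all tables
#' (with the observed margins) no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return The p-value.
#' @export
fisher_exact_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("fisher_exact_test requires positive margins", call. = FALSE)
  }
  fisher.test(table, alternative = "two.sided")$p.value
}
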