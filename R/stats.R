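#' Two-sided Fisher's exact test with cross-product odds ratio
#'
#' Exact test of association in a 2x2 contingency table. The two-sided
#' p-value is the classical one: the sum of all hypergeometric probabilities
#' (conditional on the table margins) that do not exceed the probability of
#' the observed table. The reported odds ratio is the sample (cross-product)
#' odds ratio `(a*d)/(b*c)`, with the Haldane-Anscombe correction (0.5 added
#' to every cell) whenever any cell is zero. This differs from the
#' conditional maximum-likelihood odds ratio that [stats::fisher.test()]
#' reports; the cross-product form is the one used for intersample
#' enrichment comparison throughout this package.
#'
#' @param x A 2x2 matrix of non-negative integer counts, or a length-4
#'   numeric vector `c(a, b, c, d)` filled row-wise.
#' @return A one-row tibble with columns `p_value` and `odds_ratio`.
#' @examples
#' fisher_exact(matrix(c(7, 1, 1, 5), nrow = 2, byrow = TRUE))
#' @export
fisher_exact <- function(x) {
  if (is.numeric(x) && length(x) == 4L && !is.matrix(x)) {
    x <- matrix(x, nrow = 2L, byrow = TRUE)
  }
  if (!is.matrix(x) || !all(dim(x) == c(2L, 2L))) {
    abort("`x` must be a 2x2 matrix or a length-4 vector (a, b, c, d).")
  }
  if (any(is.na(x)) || any(x < 0) || any(x != trunc(x))) {
    abort("All cells must be non-negative integers.")
  }
  a <- x[1L, 1L]; b <- x[1L, 2L]; c_ <- x[2L, 1L]; d <- x[2L, 2L]
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  if (m1 + m2 == 0) return(tibble(p_value = 1, odds_ratio = 1))
  lo <- max(0, k - m2); hi <- min(k, m1)
  support <- lo:hi
  probs <- dhyper(support, m1, m2, k)
  p_obs <- probs[support == a]
  # Relative tolerance guards against ties decided by floating-point noise.
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  if (any(x == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  tibble(p_value = p, odds_ratio = or)
}

#' Student's t-test (pooled-variance or paired)
#'
#' Two-tailed Student's t-test. Unpaired mode uses the equal-variance
#' (pooled) statistic by default; `welch = TRUE` switches to the
#' Welch-Satterthwaite approximation. Paired mode is the one-sample t-test
#' on the differences `x - y`. Degenerate inputs follow a fixed convention:
#' a zero-variance comparison with zero effect gives `t = 0, p = 1`; a
#' zero-variance comparison with non-zero effect gives `p = 0` (the
#' statistic is infinite).
#'
#' @param x,y Numeric vectors of observations (each of length >= 2; equal
#'   lengths when `paired = TRUE`).
#' @param paired Logical; test the pairwise differences?
#' @param welch Logical; use the unequal-variance statistic (unpaired only)?
#' @return A one-row tibble with columns `estimate` (mean difference),
#'   `statistic`, `df`, `p_value`.
#' @examples
#' students_t_test(c(1, 2, 3), c(4, 5, 6))
#' students_t_test(c(2, 3, 4), c(1, 1, 1), paired = TRUE)
#' @export
students_t_test <- function(x, y, paired = FALSE, welch = FALSE) {
  if (!is.numeric(x) || !is.numeric(y)) abort("`x` and `y` must be numeric.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not supported.")
  if (paired) {
    if (length(x) != length(y)) abort("Paired test requires equal-length vectors.")
    if (length(x) < 2L) abort("Paired test requires at least 2 pairs.")
    d <- x - y
    n <- length(d)
    est <- mean(d)
    s <- sd(d)
    df <- n - 1
    if (s == 0) {
      return(tibble(estimate = est, statistic = if (est == 0) 0 else sign(est) * Inf,
                    df = df, p_value = if (est == 0) 1 else 0))
    }
    tstat <- est / (s / sqrt(n))
  } else {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2L || n2 < 2L) abort("Each group requires at least 2 observations.")
    est <- mean(x) - mean(y)
    v1 <- var(x); v2 <- var(y)
    if (welch) {
      se2 <- v1 / n1 + v2 / n2
      if (se2 == 0) {
        return(tibble(estimate = est, statistic = if (est == 0) 0 else sign(est) * Inf,
                      df = NA_real_, p_value = if (est == 0) 1 else 0))
      }
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      tstat <- est / sqrt(se2)
    } else {
      df <- n1 + n2 - 2
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
      if (sp2 == 0) {
        return(tibble(estimate = est, statistic = if (est == 0) 0 else sign(est) * Inf,
                      df = df, p_value = if (est == 0) 1 else 0))
      }
      tstat <- est / sqrt(sp2 * (1 / n1 + 1 / n2))
    }
  }
  tibble(estimate = est, statistic = tstat, df = df,
         p_value = 2 * pt(-abs(tstat), df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by the
#' Benjamini-Hochberg false-discovery-rate procedure: sort ascending,
#' multiply the i-th smallest by n/i, enforce monotonicity from the largest
#' down, cap at 1, and restore the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) abort("`p` must be a non-empty numeric vector.")
  if (anyNA(p) || any(p < 0) || any(p > 1)) abort("All p-values must lie in [0, 1].")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[order(o)]
}

#' Pearson product-moment correlation
#'
#' Pearson's r with a two-tailed p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Perfect correlation (`|r| = 1`) reports `p = 0`.
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with non-zero
#'   variance.
#' @return A one-row tibble with columns `r`, `statistic`, `df`, `p_value`.
#' @examples
#' pearson_cor(1:10, (1:10) * 2 + 1)
#' @export
pearson_cor <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort("`x` and `y` must be equal-length numeric vectors.")
  }
  if (length(x) < 3L) abort("Pearson correlation requires at least 3 observations.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not supported.")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0) abort("Zero variance: correlation is undefined.")
  r <- sum(xc * yc) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  n <- length(x)
  df <- n - 2
  if (abs(r) == 1) {
    return(tibble(r = r, statistic = sign(r) * Inf, df = df, p_value = 0))
  }
  tstat <- r * sqrt(df / (1 - r^2))
  tibble(r = r, statistic = tstat, df = df, p_value = 2 * pt(-abs(tstat), df))
}
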