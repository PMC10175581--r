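#' Choose the normality test by sample size
#'
#' The dispatch rule used throughout the reporting layer: the
#' D'Agostino-Pearson omnibus test when the sample size is at least 8, the
#' Shapiro-Wilk test below that; fewer than 3 observations support neither.
#'
#' @param n Sample size (integer >= 3).
#' @return `"dagostino_pearson"` or `"shapiro_wilk"`.
#' @examples
#' choose_normality_test(8)
#' choose_normality_test(5)
#' @export
choose_normality_test <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 3) {
    abort("`n` must be at least 3 for a normality test")
  }
  if (n >= 8) "dagostino_pearson" else "shapiro_wilk"
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis z-statistics into
#' K^2 = z1^2 + z2^2, chi-squared with 2 df under normality. Uses the
#' standard normalising transformations (D'Agostino's skewness
#' approximation; Anscombe-Glynn for kurtosis) on moment-based g1 and g2.
#'
#' @param x Numeric vector, n >= 8 (the transformations are unreliable
#'   below that, which is why the dispatch rule switches to Shapiro-Wilk).
#' @return One-row tibble: `statistic` (K^2), `p_value`, `z_skew`,
#'   `z_kurtosis`, `n`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort("D'Agostino-Pearson requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 <= 0) abort("zero variance sample")
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  tibble(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
         z_skew = z1, z_kurtosis = z2, n = n)
}

#' Run the dispatched normality test
#'
#' @param x Numeric vector (n >= 3).
#' @return One-row tibble: `test` name, `statistic`, `p_value`, `n`,
#'   `normal` (not rejected at the 0.05 level).
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  test <- choose_normality_test(length(x))
  if (test == "dagostino_pearson") {
    r <- dagostino_pearson_test(x)
    tibble(test = test, statistic = r$statistic, p_value = r$p_value,
           n = length(x), normal = r$p_value > 0.05)
  } else {
    r <- shapiro.test(x)
    tibble(test = test, statistic = unname(r$statistic),
           p_value = r$p.value, n = length(x), normal = r$p.value > 0.05)
  }
}
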