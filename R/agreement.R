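#' Bland-Altman agreement analysis
#'
#' Computes the mean of the paired differences (`device - reference`), their
#' standard deviation (n-1 denominator), the 95% limits of agreement
#' `mean +/- 1.96*sd`, and the classical standard errors
#' `SE(mean) = sd/sqrt(n)` and `SE(LoA) = sd*sqrt(3/n)` (the latter applying
#' to both limits equally).
#'
#' @param device Numeric vector of device measurements (L/min).
#' @param reference Numeric vector of reference measurements, same length,
#'   `n >= 3`.
#' @return An object of class `ba_result` with fields `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `se_mean`, `se_loa`, `n`.
#' @examples
#' ba <- bland_altman(c(1, 2, 3) + 0.5, c(1, 2, 3))
#' ba$mean_diff # 0.5
#' @export
bland_altman <- function(device, reference) {
  if (length(device) != length(reference)) {
    stop("device and reference must have the same length")
  }
  n <- length(device)
  if (n < 3) stop("need at least 3 paired observations")
  d <- device - reference
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 se_mean = s / sqrt(n), se_loa = s * sqrt(3 / n),
                 n = n),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("<ba_result> n = %d\n", x$n))
  cat(sprintf("  mean difference %.4f (SE %.4f)\n", x$mean_diff, x$se_mean))
  cat(sprintf("  limits of agreement [%.4f, %.4f] (SE %.4f)\n",
              x$loa_low, x$loa_high, x$se_loa))
  invisible(x)
}

#' Fisher-Snedecor variance-ratio test
#'
#' `F = var(x)/var(y)` with sample variances (n-1 denominators), one-sided
#' upper-tail p-value from the F distribution with `(n_x - 1, n_y - 1)`
#' degrees of freedom, and the upper-`alpha` critical value. The null
#' hypothesis of equal variances is rejected when `F > F_crit` (the standard
#' convention). With `larger_first = TRUE` the larger sample variance is
#' placed in the numerator (swapping the roles of `x` and `y` when needed).
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param alpha Significance level.
#' @param larger_first Put the larger variance in the numerator.
#' @return An object of class `ftest_result` with fields `F`, `p_one_sided`,
#'   `F_crit`, `df1`, `df2`, `reject`.
#' @export
fisher_variance_test <- function(x, y, alpha = 0.05, larger_first = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2, alpha > 0, alpha < 1)
  if (larger_first && stats::var(y) > stats::var(x)) {
    tmp <- x; x <- y; y <- tmp
  }
  vy <- stats::var(y)
  if (vy == 0) stop("denominator sample has zero variance: F undefined")
  f <- stats::var(x) / vy
  df1 <- length(x) - 1
  df2 <- length(y) - 1
  fc <- stats::qf(1 - alpha, df1, df2)
  structure(list(F = f,
                 p_one_sided = stats::pf(f, df1, df2, lower.tail = FALSE),
                 F_crit = fc, df1 = df1, df2 = df2,
                 reject = f > fc),
            class = "ftest_result")
}

#' @export
print.ftest_result <- function(x, ...) {
  cat(sprintf("<ftest_result> F = %.4f, df = (%d, %d)\n", x$F, x$df1, x$df2))
  cat(sprintf("  one-sided p = %.4f, critical F = %.4f -> %s H0\n",
              x$p_one_sided, x$F_crit,
              if (x$reject) "reject" else "fail to reject"))
  invisible(x)
}

#' Finite-population sample size
#'
#' `n = N*Z^2*p*q / (e^2*(N-1) + Z^2*p*q)` with `q = 1 - p`, returned
#' unrounded. Strictly increasing in `N`, strictly decreasing in `e`, and
#' never larger than `N`.
#'
#' @param N Population size (>= 1).
#' @param Z Standard-normal critical value for the confidence level
#'   (1.96 for 95%).
#' @param e Maximum acceptable error (proportion).
#' @param p Assumed success probability, in (0, 1).
#' @return Real-valued sample size.
#' @examples
#' sample_size(N = 4000, Z = 1.96, e = 0.05, p = 0.05) # 71.70
#' @export
sample_size <- function(N, Z = 1.96, e = 0.05, p = 0.05) {
  stopifnot(N >= 1, Z > 0, e > 0, p > 0, p < 1)
  q <- 1 - p
  N * Z^2 * p * q / (e^2 * (N - 1) + Z^2 * p * q)
}
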