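#' Empirical cumulative distribution function
#'
#' Builds the right-continuous ECDF of a sample: `F(x)` is the fraction of
#' sample values `<= x`, jumping by `k/n` at a `k`-fold tied value.
#'
#' @param sample Numeric vector, length >= 1, no missing values.
#' @return A function mapping numeric vectors to cumulative fractions.
#' @export
#' @examples
#' F <- ecdf_step(c(1, 2, 3))
#' F(c(1, 2.5, 3))
ecdf_step <- function(sample) {
  stopifnot(length(sample) >= 1L, !anyNA(sample))
  sorted <- sort(sample)
  n <- length(sorted)
  function(x) findInterval(x, sorted) / n
}

# Asymptotic Kolmogorov survival function Q(lambda) = 2 sum_{j>=1} (-1)^{j-1}
# exp(-2 j^2 lambda^2), clipped to [0, 1]. The series converges fast; 100
# terms is far beyond machine precision for any lambda of interest.
kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  j <- seq_len(100L)
  q <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, q))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the supremum distance `D` between the ECDFs of two samples,
#' evaluated over the pooled values (ties handled by the right-continuous
#' step functions), and an asymptotic p-value from the Kolmogorov series
#' evaluated at `lambda = sqrt(ne) * D` with effective sample size
#' `ne = n1 * n2 / (n1 + n2)`, clipped to `[0, 1]`.
#'
#' @param x,y Numeric samples, each non-empty, no missing values.
#' @return A list of class `ks_result` with elements `D`, `p`, `n1`, `n2`.
#' @export
#' @examples
#' ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D
ks_two_sample <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  stopifnot(!anyNA(x), !anyNA(y))
  n1 <- length(x)
  n2 <- length(y)
  pooled <- sort(unique(c(x, y)))
  fx <- ecdf_step(x)(pooled)
  fy <- ecdf_step(y)(pooled)
  D <- max(abs(fx - fy))
  ne <- n1 * n2 / (n1 + n2)
  p <- kolmogorov_q(sqrt(ne) * D)
  if (D == 0) p <- 1
  structure(list(D = D, p = p, n1 = n1, n2 = n2), class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample K-S: D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$D, x$p, x$n1, x$n2))
  invisible(x)
}

#' Fit an exponential distribution with confidence bounds on the mean
#'
#' Maximum-likelihood exponential fit for a sample of positive dwell times:
#' the fitted mean is the sample mean (`mean_hat = 1/lambda_hat`), and the
#' `1 - alpha` confidence interval for the mean uses the exact chi-square
#' pivot `2 n mean_hat / lambda ~ chi^2_{2n}`:
#' `[2 n m / qchisq(1 - alpha/2, 2n), 2 n m / qchisq(alpha/2, 2n)]`.
#' For the fitted model the mean equals the standard deviation, `1/lambda`.
#'
#' @param sample Positive numeric values.
#' @param alpha Two-sided error rate (default 0.05 for 95% bounds).
#' @return A list of class `exponential_fit` with `n`, `mean_hat`,
#'   `lambda_hat`, `ci_lower`, `ci_upper`, `alpha`.
#' @export
fit_exponential <- function(sample, alpha = 0.05) {
  stopifnot(length(sample) >= 1L, !anyNA(sample))
  if (any(sample <= 0)) {
    stop("exponential fit requires strictly positive values", call. = FALSE)
  }
  n <- length(sample)
  m <- mean(sample)
  lower <- 2 * n * m / stats::qchisq(1 - alpha / 2, df = 2 * n)
  upper <- 2 * n * m / stats::qchisq(alpha / 2, df = 2 * n)
  structure(
    list(n = n, mean_hat = m, lambda_hat = 1 / m,
         ci_lower = lower, ci_upper = upper, alpha = alpha),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential fit (n = %d): mean %.2f [%.2f, %.2f] (%.0f%% CI), rate %.4g\n",
    x$n, x$mean_hat, x$ci_lower, x$ci_upper, 100 * (1 - x$alpha),
    x$lambda_hat
  ))
  invisible(x)
}
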