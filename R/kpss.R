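#' KPSS test for level stationarity
#'
#' Tests the null hypothesis that a series is stationary around a constant
#' level against a unit-root alternative. The statistic is the scaled sum of
#' squared partial sums of the demeaned series, with the long-run variance
#' estimated by a Bartlett-kernel (Newey-West) estimator. Rejection indicates
#' nonstationarity.
#'
#' P-values are obtained by linear interpolation of the published critical
#' values (0.347, 0.463, 0.574, 0.739 for the 10%, 5%, 2.5% and 1% levels)
#' and are truncated to the interval `[0.01, 0.10]`; a reported p-value of
#' 0.01 therefore means "0.01 or smaller".
#'
#' @param x Numeric series (`NA`s dropped).
#' @param lags Bartlett truncation lag; default the common data-driven rule
#'   `ceiling(12 * (n/100)^0.25)`.
#' @return List with `statistic`, `p_value`, `lags`, `n`.
#' @examples
#' kpss_test(rnorm(200))$p_value # stationary: ~0.1
#' kpss_test(cumsum(rnorm(200)))$p_value # random walk: 0.01
#' @export
kpss_test <- function(x, lags = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) {
    return(list(statistic = NA_real_, p_value = NA_real_, lags = NA_integer_, n = n))
  }
  if (is.null(lags)) lags <- as.integer(ceiling(12 * (n / 100)^0.25))
  lags <- min(lags, n - 1L)
  e <- x - mean(x)
  s2 <- sum(e^2) / n
  if (lags > 0L && s2 > 0) {
    for (j in seq_len(lags)) {
      w <- 1 - j / (lags + 1)
      s2 <- s2 + 2 * w * sum(e[(j + 1):n] * e[1:(n - j)]) / n
    }
  }
  if (s2 <= 0) {
    # degenerate (constant or near-constant) series: no evidence against
    # stationarity
    return(list(statistic = 0, p_value = 0.10, lags = lags, n = n))
  }
  eta <- sum(cumsum(e)^2) / n^2
  stat <- eta / s2
  crit <- c(0.347, 0.463, 0.574, 0.739)
  pvals <- c(0.10, 0.05, 0.025, 0.01)
  p <- stats::approx(crit, pvals, xout = stat, rule = 2)$y
  list(statistic = stat, p_value = p, lags = lags, n = n)
}
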