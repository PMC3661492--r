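# Zero-truncated Poisson: the event-size distribution of the hurdle model.
# pmf(n; lambda) = lambda^n exp(-lambda) / (n! (1 - exp(-lambda))), n >= 1.

#' Zero-truncated Poisson log-pmf
#'
#' Computed in log space with `expm1` so small `lambda` stays stable.
#'
#' @param n integer counts, `>= 1`.
#' @param lambda ZTP size parameter, `> 0`.
#' @return log-probabilities, vectorised over `n`.
#' @export
ztp_log_pmf <- function(n, lambda) {
  if (any(n < 1 | n != floor(n))) {
    stopf("ztp_log_pmf(): counts must be integers >= 1 (zero is truncated)")
  }
  if (any(lambda <= 0)) stopf("ztp_log_pmf(): lambda must be > 0")
  n * log(lambda) - lambda - lgamma(n + 1) - log(-expm1(-lambda))
}

#' Mean of the zero-truncated Poisson
#'
#' @param lambda size parameter, `> 0`.
#' @return `lambda / (1 - exp(-lambda))`.
#' @export
ztp_mean <- function(lambda) {
  lambda / -expm1(-lambda)
}

#' Solve the ZTP size from an observed mean event size
#'
#' Inverts the mean identity `lambda / (1 - exp(-lambda)) = m` by bisection
#' on the given interval (the identity is strictly increasing).
#'
#' @param mean_size observed mean captures per capture event (`> 1`).
#' @param interval search interval for `lambda`.
#' @param tol bisection tolerance.
#' @return the size `lambda`.
#' @examples
#' ztp_lambda_from_mean(119 / 50) # ~ 2.1
#' @export
ztp_lambda_from_mean <- function(mean_size, interval = c(0.5, 30),
                                 tol = 1e-10) {
  f <- function(l) ztp_mean(l) - mean_size
  lo <- interval[1]; hi <- interval[2]
  if (f(lo) > 0 || f(hi) < 0) {
    stopf("ztp_lambda_from_mean(): mean %.3f outside [%.3f, %.3f]",
          mean_size, ztp_mean(lo), ztp_mean(hi))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Draw from the zero-truncated Poisson
#'
#' Exact inverse-CDF sampling over the pmf (no rejection): uniform draws are
#' placed in the cumulative distribution truncated far into the upper tail.
#'
#' @param n_draws number of draws.
#' @param lambda size parameter.
#' @return integer vector of draws, all `>= 1`.
#' @export
sample_ztp <- function(n_draws, lambda) {
  if (n_draws == 0) return(integer(0))
  top <- max(qpois(1 - 1e-13, lambda) + 10, 10)
  cdf <- cumsum(exp(ztp_log_pmf(seq_len(top), lambda)))
  findInterval(runif(n_draws), cdf) + 1L
}
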