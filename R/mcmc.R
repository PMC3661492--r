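# Generic componentwise adaptive random-walk Metropolis ("Metropolis within
# Gibbs"): Gaussian proposals per coordinate, scales tuned during burn-in to
# a target acceptance band and then frozen so the kept draws satisfy
# detailed balance. Also split-Rhat and autocorrelation ESS diagnostics.

#' Adaptive Metropolis-within-Gibbs sampler
#'
#' Componentwise Gaussian random-walk Metropolis over an arbitrary
#' log-density. During burn-in each coordinate's proposal scale is reviewed
#' every `adapt_interval` sweeps and multiplied/divided by 1.5 until the
#' acceptance rate sits in `accept_band`; scales are frozen afterwards.
#' Coordinates with finite bounds reflect proposals at the bounds (a
#' symmetric proposal, so no correction is needed).
#'
#' @param log_post function mapping a parameter vector to a log-density
#'   (need not be normalised); `-Inf` outside the support.
#' @param init named numeric vector of initial values (finite log-density
#'   required).
#' @param n_burn,n_iter,thin burn-in sweeps, post-burn-in sweeps, thinning
#'   stride (`thin` must divide `n_iter`).
#' @param n_chains number of chains; chain `c` uses `seed + c`.
#' @param seed integer base seed.
#' @param lower,upper optional bound vectors (reflection).
#' @param scale0 initial proposal standard deviations (scalar or vector).
#' @param adapt_interval sweeps between scale reviews.
#' @param accept_band target acceptance-rate band.
#' @return list of class `mwg_samples`: `chains` (list of draws matrices,
#'   `n_iter/thin` rows each), `scales`, `accept`, and the configuration.
#' @export
adaptive_mwg <- function(log_post, init, n_burn = 1000, n_iter = 2000,
                         thin = 2, n_chains = 2, seed = 1,
                         lower = -Inf, upper = Inf, scale0 = 0.1,
                         adapt_interval = 50, accept_band = c(0.2, 0.5)) {
  d <- length(init)
  if (n_iter %% thin != 0) stopf("adaptive_mwg(): thin must divide n_iter")
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  scale0 <- rep_len(scale0, d)
  chains <- vector("list", n_chains)
  scales_out <- accept_out <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch)
    theta <- init
    lp <- log_post(theta)
    if (!is.finite(lp)) {
      stopf("adaptive_mwg(): log-density not finite at initial values [%s]",
            paste(sprintf("%s=%.3g", names(init), init), collapse = ", "))
    }
    s <- scale0
    n_keep <- n_iter %/% thin
    draws <- matrix(NA_real_, n_keep, d, dimnames = list(NULL, names(init)))
    acc <- att <- numeric(d)
    acc_total <- att_total <- numeric(d)
    kept <- 0L
    for (it in seq_len(n_burn + n_iter)) {
      for (j in seq_len(d)) {
        prop <- theta
        pj <- theta[j] + rnorm(1, 0, s[j])
        # reflect at finite bounds
        for (r in 1:10) {
          if (pj < lower[j]) pj <- 2 * lower[j] - pj
          else if (pj > upper[j]) pj <- 2 * upper[j] - pj
          else break
        }
        prop[j] <- pj
        lp_prop <- log_post(prop)
        att[j] <- att[j] + 1; att_total[j] <- att_total[j] + 1
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
          theta <- prop; lp <- lp_prop
          acc[j] <- acc[j] + 1; acc_total[j] <- acc_total[j] + 1
        }
      }
      if (it <= n_burn && it %% adapt_interval == 0) {
        rate <- acc / pmax(att, 1)
        s <- ifelse(rate > accept_band[2], s * 1.5,
                    ifelse(rate < accept_band[1], s / 1.5, s))
        acc[] <- 0; att[] <- 0
      }
      if (it > n_burn && (it - n_burn) %% thin == 0) {
        kept <- kept + 1L
        draws[kept, ] <- theta
      }
    }
    chains[[ch]] <- draws
    scales_out[[ch]] <- s
    accept_out[[ch]] <- acc_total / pmax(att_total, 1)
  }
  structure(list(chains = chains, scales = scales_out, accept = accept_out,
                 n_burn = n_burn, n_iter = n_iter, thin = thin, seed = seed),
            class = "mwg_samples")
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also registers. Chains with zero total
#' variance return exactly 1.
#'
#' @param chains list of draws matrices (same columns), at least 2 chains
#'   with at least 10 draws each.
#' @return named numeric vector of Rhat values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) stopf("gelman_rubin(): need at least 2 chains")
  if (any(vapply(chains, nrow, 0L) < 10)) {
    stopf("gelman_rubin(): need at least 10 draws per chain")
  }
  half <- function(m) {
    n <- nrow(m) %/% 2
    list(m[seq_len(n), , drop = FALSE], m[(nrow(m) - n + 1):nrow(m), , drop = FALSE])
  }
  split_chains <- do.call(c, lapply(chains, half))
  m <- length(split_chains)
  n <- nrow(split_chains[[1]])
  p <- ncol(split_chains[[1]])
  out <- numeric(p)
  for (j in seq_len(p)) {
    xs <- vapply(split_chains, function(c) mean(c[, j]), 0)
    vs <- vapply(split_chains, function(c) var(c[, j]), 0)
    W <- mean(vs)
    B <- n * var(xs)
    if (W == 0 && B == 0) { out[j] <- 1; next }
    if (W == 0) { out[j] <- Inf; next }
    var_plus <- (n - 1) / n * W + B / n
    out[j] <- sqrt(var_plus / W)
  }
  setNames(out, colnames(split_chains[[1]]))
}

#' Autocorrelation-based effective sample size
#'
#' Sums sample autocorrelations truncated at the first negative sum of an
#' adjacent lag pair (initial positive sequence), per parameter, pooling
#' chains. Constant chains are degenerate and return `NA` with a warning.
#'
#' @param chains list of draws matrices, or a single matrix.
#' @return named numeric vector of ESS values.
#' @export
effective_sample_size <- function(chains) {
  if (is.matrix(chains)) chains <- list(chains)
  n <- nrow(chains[[1]])
  if (n < 100) stopf("effective_sample_size(): need at least 100 draws")
  p <- ncol(chains[[1]])
  out <- numeric(p)
  for (j in seq_len(p)) {
    ess <- 0
    degenerate <- FALSE
    for (ch in chains) {
      x <- ch[, j]
      if (var(x) == 0) { degenerate <- TRUE; next }
      rho <- acf(x, lag.max = min(n - 2, 1000), plot = FALSE)$acf[-1]
      tau <- 1
      k <- 1
      while (k + 1 <= length(rho)) {
        pair <- rho[k] + rho[k + 1]
        if (pair < 0) break
        tau <- tau + 2 * pair
        k <- k + 2
      }
      ess <- ess + n / tau
    }
    if (degenerate && ess == 0) {
      warnf("effective_sample_size(): constant chain for parameter %d", j)
      out[j] <- NA_real_
    } else {
      out[j] <- ess
    }
  }
  setNames(out, colnames(chains[[1]]))
}
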