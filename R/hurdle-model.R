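# Two-stage Bayesian hurdle model. Stage one: hierarchical logistic
# regression for whether a capture event occurs on tow i,
#   logit(p_i) = alpha_{t(i)} + sum_k beta_k x_ik,
# with fishing-year effects alpha_t ~ N(mu_alpha, sigma_alpha). Stage two:
# a zero-truncated Poisson of size lambda for the number of animals caught
# on a capture event. Fitted by adaptive Metropolis-within-Gibbs.

#' Prior specification for the hurdle model
#'
#' Diffuse normals on the regression coefficients and on the mean of the
#' year effects; a half-Cauchy (scale 25) on the standard deviation of the
#' year effects; a uniform on the ZTP size.
#'
#' @param beta_sd,mu_alpha_sd standard deviations of the diffuse normal
#'   priors (default 100).
#' @param sigma_alpha_scale half-Cauchy scale (default 25).
#' @param lambda_bounds uniform-prior support for the ZTP size.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(beta_sd = 100, mu_alpha_sd = 100,
                       sigma_alpha_scale = 25, lambda_bounds = c(0.5, 30)) {
  stopifnot(beta_sd > 0, mu_alpha_sd > 0, sigma_alpha_scale > 0,
            lambda_bounds[1] > 0, lambda_bounds[2] > lambda_bounds[1])
  structure(list(beta_sd = beta_sd, mu_alpha_sd = mu_alpha_sd,
                 sigma_alpha_scale = sigma_alpha_scale,
                 lambda_bounds = lambda_bounds), class = "prior_spec")
}

#' MCMC protocol configuration
#'
#' Defaults follow the fitting protocol of the analysis: 10 000 burn-in
#' iterations, 100 000 further iterations with every 20th kept, two chains
#' (5000 kept draws per chain).
#'
#' @param n_burn,n_iter,thin,n_chains see [adaptive_mwg()].
#' @param seed base seed; chain `c` uses `seed + c`.
#' @param adapt_interval,accept_band proposal adaptation controls.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 10000, n_iter = 100000, thin = 20,
                        n_chains = 2, seed = 1, adapt_interval = 50,
                        accept_band = c(0.2, 0.5)) {
  if (n_iter %% thin != 0) stopf("mcmc_config(): thin must divide n_iter")
  if (n_chains < 1) stopf("mcmc_config(): need at least one chain")
  structure(list(n_burn = n_burn, n_iter = n_iter, thin = thin,
                 n_chains = n_chains, seed = seed,
                 adapt_interval = adapt_interval, accept_band = accept_band),
            class = "mcmc_config")
}

#' Kept draws per chain implied by a configuration
#' @param config an [mcmc_config()].
#' @return integer, `n_iter / thin`.
#' @export
draws_per_chain <- function(config) config$n_iter %/% config$thin

#' One hurdle-model parameter state
#'
#' @param beta named coefficient vector (one per design column).
#' @param alpha year effects, one per fishing year (logit scale).
#' @param mu_alpha,sigma_alpha year-effect hyperparameters (`sigma_alpha > 0`).
#' @param lambda ZTP size.
#' @return object of class `hurdle_params`.
#' @export
hurdle_params <- function(beta, alpha, mu_alpha, sigma_alpha, lambda) {
  stopifnot(sigma_alpha > 0, lambda > 0)
  structure(list(beta = beta, alpha = alpha, mu_alpha = mu_alpha,
                 sigma_alpha = sigma_alpha, lambda = lambda),
            class = "hurdle_params")
}

#' Capture-event probability of a tow
#'
#' `p = plogis(alpha_t + sum(beta * x))`, overflow-safe.
#'
#' @param params a [hurdle_params()].
#' @param x design row (same order as `params$beta`); may be a matrix of
#'   rows.
#' @param year_index integer index into `params$alpha` (vectorised with
#'   rows).
#' @return probabilities in (0, 1).
#' @export
capture_probability <- function(params, x, year_index) {
  if (is.matrix(x)) {
    eta <- params$alpha[year_index] + drop(x %*% params$beta)
  } else {
    stopifnot(length(x) == length(params$beta))
    eta <- params$alpha[year_index] + sum(params$beta * x)
  }
  plogis(eta)
}

# stable log(1 + exp(eta))
log1pexp <- function(eta) ifelse(eta > 30, eta, log1p(exp(eta)))

#' Hurdle log-likelihood over observed tows
#'
#' Bernoulli stage for the capture-event indicator plus the zero-truncated
#' Poisson stage for counts on event tows.
#'
#' @param params a [hurdle_params()].
#' @param design a [build_design_matrix()] object; only observed rows enter.
#' @return log-likelihood value.
#' @export
hurdle_log_likelihood <- function(params, design) {
  obs <- design$observed
  y <- design$y[obs]
  n <- design$n[obs]
  if (any(y == 1 & (is.na(n) | n < 1))) {
    stopf("hurdle_log_likelihood(): capture event recorded with count < 1")
  }
  X <- design$X[obs, , drop = FALSE]
  t_idx <- as.integer(design$year)[obs]
  eta <- params$alpha[t_idx] + drop(X %*% params$beta)
  ll <- sum(y * eta - log1pexp(eta))
  ev <- y == 1
  if (any(ev)) ll <- ll + sum(ztp_log_pmf(n[ev], params$lambda))
  ll
}

#' Hurdle log-prior
#'
#' @param params a [hurdle_params()].
#' @param priors a [prior_spec()].
#' @return log-prior density (`-Inf` outside support). No change-of-variable
#'   Jacobians: densities are on the natural scale of each parameter.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  if (params$sigma_alpha <= 0 ||
      params$lambda < priors$lambda_bounds[1] ||
      params$lambda > priors$lambda_bounds[2]) {
    return(-Inf)
  }
  sum(dnorm(params$beta, 0, priors$beta_sd, log = TRUE)) +
    dnorm(params$mu_alpha, 0, priors$mu_alpha_sd, log = TRUE) +
    sum(dnorm(params$alpha, params$mu_alpha, params$sigma_alpha, log = TRUE)) +
    log(2) + dcauchy(params$sigma_alpha, 0, priors$sigma_alpha_scale,
                     log = TRUE) -
    log(diff(priors$lambda_bounds))
}

# --- packing between hurdle_params and the sampler's flat vector ----------
# layout: beta (p), alpha (T), mu_alpha, log_sigma_alpha, lambda

pack_params <- function(params) {
  c(params$beta, params$alpha, mu_alpha = params$mu_alpha,
    log_sigma_alpha = log(params$sigma_alpha), lambda = params$lambda)
}

unpack_params <- function(theta, p, T_years) {
  hurdle_params(beta = theta[seq_len(p)],
                alpha = theta[p + seq_len(T_years)],
                mu_alpha = theta[p + T_years + 1],
                sigma_alpha = exp(theta[p + T_years + 2]),
                lambda = theta[p + T_years + 3])
}

param_names <- function(design) {
  c(paste0("beta_", colnames(design$X)),
    paste0("alpha_", levels(design$year)),
    "mu_alpha", "log_sigma_alpha", "lambda")
}

#' Hurdle log-posterior as a function of the flat parameter vector
#'
#' The sampler walks `log(sigma_alpha)`, so the half-Cauchy prior picks up a
#' `+log(sigma_alpha)` Jacobian here; `lambda` stays on its natural scale.
#'
#' @param design a [build_design_matrix()] object.
#' @param priors a [prior_spec()].
#' @return function of the packed parameter vector.
#' @export
hurdle_log_posterior <- function(design, priors = prior_spec()) {
  p <- ncol(design$X)
  T_years <- nlevels(design$year)
  # cache the observed-row quantities once: the sampler evaluates this
  # function tens of thousands of times
  obs <- design$observed
  yo <- design$y[obs]
  no <- design$n[obs]
  if (any(yo == 1 & (is.na(no) | no < 1))) {
    stopf("hurdle_log_posterior(): capture event recorded with count < 1")
  }
  Xo <- design$X[obs, , drop = FALSE]
  t_o <- as.integer(design$year)[obs]
  n_ev <- sum(yo == 1)
  sum_n <- sum(no[yo == 1])                       # ZTP sufficient statistics
  lgam <- sum(lgamma(no[yo == 1] + 1))
  lb <- priors$lambda_bounds
  function(theta) {
    beta <- theta[seq_len(p)]
    alpha <- theta[p + seq_len(T_years)]
    mu <- theta[p + T_years + 1]
    log_sig <- theta[p + T_years + 2]
    sig <- exp(log_sig)
    lambda <- theta[p + T_years + 3]
    if (lambda < lb[1] || lambda > lb[2] || !is.finite(sig)) return(-Inf)
    lp <- sum(dnorm(beta, 0, priors$beta_sd, log = TRUE)) +
      dnorm(mu, 0, priors$mu_alpha_sd, log = TRUE) +
      sum(dnorm(alpha, mu, sig, log = TRUE)) +
      log(2) + dcauchy(sig, 0, priors$sigma_alpha_scale, log = TRUE) -
      log(lb[2] - lb[1]) +
      log_sig                                     # Jacobian for the log walk
    eta <- alpha[t_o] + drop(Xo %*% beta)
    ll <- sum(yo * eta - log1pexp(eta)) +
      sum_n * log(lambda) - n_ev * lambda - lgam -
      n_ev * log(-expm1(-lambda))
    lp + ll
  }
}

#' Fit the hurdle model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs over the regression coefficients, year
#' effects, hyperparameters (`log sigma_alpha`) and the ZTP size (reflected
#' at its uniform bounds). Initial values: `beta = 0`, year effects and
#' `mu_alpha` at the logit of the overall event rate, `sigma_alpha = 1`,
#' `lambda` at the mean count among events.
#'
#' @param design a [build_design_matrix()] object with at least one observed
#'   capture event and at least two fishing years.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @return object of class `hurdle_posterior`: per-chain draw matrices,
#'   parameter names, split-Rhat, ESS, and the configuration.
#' @export
sample_posterior <- function(design, priors = prior_spec(),
                             config = mcmc_config()) {
  obs <- design$observed
  y <- design$y[obs]
  if (sum(y) < 1) stopf("sample_posterior(): no capture events in the data")
  if (nlevels(design$year) < 2) {
    stopf("sample_posterior(): need at least two fishing years for the hierarchy")
  }
  p <- ncol(design$X)
  T_years <- nlevels(design$year)
  rate <- mean(y)
  rate <- min(max(rate, 1 / (length(y) + 1)), 1 - 1 / (length(y) + 1))
  n_ev <- design$n[obs][y == 1]
  init <- c(rep(0, p), rep(log(rate / (1 - rate)), T_years),
            log(rate / (1 - rate)), 0,
            min(max(mean(n_ev), priors$lambda_bounds[1] + 0.01, 1),
                priors$lambda_bounds[2] - 0.01))
  names(init) <- param_names(design)
  lower <- c(rep(-Inf, p + T_years + 2), priors$lambda_bounds[1])
  upper <- c(rep(Inf, p + T_years + 2), priors$lambda_bounds[2])
  lp <- hurdle_log_posterior(design, priors)
  raw <- adaptive_mwg(lp, init, n_burn = config$n_burn, n_iter = config$n_iter,
                      thin = config$thin, n_chains = config$n_chains,
                      seed = config$seed, lower = lower, upper = upper,
                      scale0 = c(rep(0.1, p), rep(0.3, T_years), 0.3, 0.3, 0.3),
                      adapt_interval = config$adapt_interval,
                      accept_band = config$accept_band)
  rhat <- if (config$n_chains >= 2) gelman_rubin(raw$chains) else NULL
  ess <- if (draws_per_chain(config) >= 100) {
    effective_sample_size(raw$chains)
  } else NULL
  structure(list(chains = raw$chains, param_names = param_names(design),
                 n_beta = p, year_levels = levels(design$year),
                 rhat = rhat, ess = ess, accept = raw$accept,
                 priors = priors, config = config),
            class = "hurdle_posterior")
}

#' Pooled draws matrix of a fitted posterior
#' @param posterior a `hurdle_posterior`.
#' @return matrix with all chains stacked.
#' @export
posterior_draws <- function(posterior) {
  do.call(rbind, posterior$chains)
}

#' Extract one draw as a `hurdle_params`
#' @param posterior a `hurdle_posterior`.
#' @param i draw index into [posterior_draws()].
#' @return a [hurdle_params()].
#' @export
posterior_params <- function(posterior, i) {
  th <- posterior_draws(posterior)[i, ]
  unpack_params(th, posterior$n_beta, length(posterior$year_levels))
}

#' @export
print.hurdle_posterior <- function(x, ...) {
  d <- posterior_draws(x)
  cat("<hurdle_posterior> ", length(x$chains), " chain(s) x ",
      nrow(x$chains[[1]]), " draws\n", sep = "")
  qs <- t(apply(d, 2, quantile, c(0.025, 0.5, 0.975)))
  summ <- cbind(mean = colMeans(d), qs)
  if (!is.null(x$rhat)) summ <- cbind(summ, Rhat = x$rhat)
  print(round(summ, 3))
  invisible(x)
}

#' Posterior summary of the regression coefficients
#'
#' Mean and 2.5/50/97.5% quantiles per coefficient; discrete-factor
#' coefficients optionally exponentiated so they read as multiplicative
#' odds ratios.
#'
#' @param posterior a `hurdle_posterior`.
#' @param exponentiate_factors names of coefficients to exponentiate.
#' @return tibble with one row per coefficient plus the ZTP size.
#' @export
coefficient_table <- function(posterior, exponentiate_factors = character()) {
  d <- posterior_draws(posterior)
  cols <- c(colnames(d)[seq_len(posterior$n_beta)], "lambda")
  rows <- lapply(cols, function(cn) {
    x <- d[, cn]
    nm <- sub("^beta_", "", cn)
    if (nm %in% exponentiate_factors) x <- exp(x)
    tibble::tibble(term = nm, mean = mean(x),
                   q2.5 = quantile(x, 0.025), q50 = quantile(x, 0.5),
                   q97.5 = quantile(x, 0.975))
  })
  do.call(rbind, rows)
}
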