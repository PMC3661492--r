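# Likelihood, priors, posterior wiring and scaled-down sampler checks.

toy_design <- function(n = 40, seed = 2, p_event = 0.3, lambda = 2) {
  set.seed(seed)
  X <- cbind(headline_depth = rnorm(n, 60, 25), log_duration = rnorm(n, 1.4, 0.3))
  y <- as.numeric(runif(n) < p_event)
  counts <- ifelse(y == 1, sample_ztp(n, lambda), NA)[seq_len(n)]
  counts[y == 0] <- NA
  structure(list(
    X = X, y = y, n = as.integer(counts),
    year = factor(rep(c("2001-02", "2002-03"), length.out = n)),
    vessel_id = rep("V01", n), observed = rep(TRUE, n),
    tow_id = sprintf("T%03d", seq_len(n)),
    dropped = list(n = 0, tow_id = character())
  ), class = "design_matrix")
}

test_that("capture probability is the inverse-logit of year + covariates", {
  pr <- hurdle_params(beta = c(0, 0), alpha = c(0, 0), mu_alpha = 0,
                      sigma_alpha = 1, lambda = 2)
  expect_equal(capture_probability(pr, c(1, 1), 1), 0.5)
  # direct evaluation: eta = -5 - 0.033*30 + 1.470*log(4)
  pr2 <- hurdle_params(beta = c(-0.033, 1.470), alpha = c(-5, -5),
                       mu_alpha = -5, sigma_alpha = 1, lambda = 2)
  expect_equal(capture_probability(pr2, c(30, log(4)), 1),
               plogis(-5 - 0.99 + 1.470 * log(4)), tolerance = 1e-12)
  expect_lt(abs(capture_probability(pr2, c(30, log(4)), 1) - 0.0189), 1e-4)
  # strictly decreasing in headline depth for a negative coefficient
  p_deep <- capture_probability(pr2, c(60, log(4)), 1)
  expect_lt(p_deep, capture_probability(pr2, c(30, log(4)), 1))
})

test_that("hurdle log-likelihood composes Bernoulli and ZTP stages", {
  dm <- toy_design(n = 1)
  dm$y <- 0; dm$n <- NA_integer_
  pr <- hurdle_params(beta = c(0, 0), alpha = c(0, 0), mu_alpha = 0,
                      sigma_alpha = 1, lambda = 2.1)
  dm$X[] <- 0
  expect_equal(hurdle_log_likelihood(pr, dm), log(0.5))
  # adding one event tow with count 2 adds log 0.5 + log pmf(2; 2.1)
  dm2 <- toy_design(n = 2)
  dm2$X[] <- 0
  dm2$y <- c(0, 1); dm2$n <- c(NA_integer_, 2L)
  expect_equal(hurdle_log_likelihood(pr, dm2),
               2 * log(0.5) + ztp_log_pmf(2, 2.1))
  # permutation invariance
  dm3 <- toy_design(n = 30, seed = 9)
  perm <- sample(30)
  dm3p <- dm3
  dm3p$X <- dm3$X[perm, ]; dm3p$y <- dm3$y[perm]; dm3p$n <- dm3$n[perm]
  dm3p$year <- dm3$year[perm]; dm3p$observed <- dm3$observed[perm]
  expect_equal(hurdle_log_likelihood(pr, dm3), hurdle_log_likelihood(pr, dm3p))
  # event with count zero is a data inconsistency
  dm4 <- dm2; dm4$n <- c(NA_integer_, 0L)
  expect_error(hurdle_log_likelihood(pr, dm4), "count")
})

test_that("log-prior matches closed forms and support bounds", {
  priors <- prior_spec()
  base <- hurdle_params(beta = c(0, 0), alpha = c(0, 0), mu_alpha = 0,
                        sigma_alpha = 25, lambda = 2)
  # half-Cauchy(25) at its scale point: density 1/(25 pi)
  lp <- log_prior(base, priors)
  lp_wo_sigma <- sum(dnorm(c(0, 0), 0, 100, log = TRUE)) +
    dnorm(0, 0, 100, log = TRUE) +
    sum(dnorm(c(0, 0), 0, 25, log = TRUE)) - log(diff(c(0.5, 30)))
  expect_equal(lp - lp_wo_sigma, log(1 / (25 * pi)), tolerance = 1e-12)
  # lambda outside its uniform support
  out <- base; out$lambda <- 40
  expect_equal(log_prior(out, priors), -Inf)
  # a wider beta prior penalises a fixed coefficient in its far tail less
  big <- base; big$beta <- c(300, 0)
  expect_gt(log_prior(big, prior_spec(beta_sd = 200)),
            log_prior(big, prior_spec(beta_sd = 100)))
})

test_that("log-posterior = log-likelihood + log-prior (finite differences)", {
  dm <- toy_design(n = 25, seed = 4)
  priors <- prior_spec()
  lp <- hurdle_log_posterior(dm, priors)
  th0 <- c(0.01, 0.2, -1, -1.2, -1, 0.1, 2.0)
  names(th0) <- c("beta_headline_depth", "beta_log_duration",
                  "alpha_2001-02", "alpha_2002-03", "mu_alpha",
                  "log_sigma_alpha", "lambda")
  unpack <- function(th) hurdle_params(th[1:2], th[3:4], th[5], exp(th[6]), th[7])
  for (j in seq_along(th0)) {
    th1 <- th0; th1[j] <- th1[j] + 0.05
    dl <- lp(th1) - lp(th0)
    dlik <- hurdle_log_likelihood(unpack(th1), dm) -
      hurdle_log_likelihood(unpack(th0), dm)
    dpri <- (log_prior(unpack(th1), priors) + th1[6]) -
      (log_prior(unpack(th0), priors) + th0[6])   # + Jacobian of the log walk
    expect_equal(unname(dl), unname(dlik + dpri), tolerance = 1e-9)
  }
})

test_that("the two hurdle stages factorise over event-count permutations", {
  dm <- toy_design(n = 60, seed = 12)
  ev <- which(dm$y == 1)
  dmp <- dm
  dmp$n[ev] <- dm$n[ev][sample(length(ev))]
  pr <- hurdle_params(beta = c(0.01, -0.3), alpha = c(-0.5, -1), mu_alpha = -1,
                      sigma_alpha = 0.8, lambda = 1.7)
  expect_equal(hurdle_log_likelihood(pr, dm), hurdle_log_likelihood(pr, dmp))
})

test_that("default protocol yields 5000 kept draws per chain, two chains", {
  cfg <- mcmc_config()
  expect_equal(draws_per_chain(cfg), 5000)
  expect_equal(cfg$n_chains, 2)
  expect_equal(cfg$n_burn, 10000)
  expect_error(mcmc_config(n_iter = 1000, thin = 3), "divide")
})

test_that("posterior concentrates at the ML solution on easy logistic data", {
  # Bernstein-von Mises: one covariate, many tows, weak hierarchy
  set.seed(31)
  n <- 1500
  x <- rnorm(n)
  y <- as.numeric(runif(n) < plogis(-1 + 0.8 * x))
  nn <- rep(NA_integer_, n); nn[y == 1] <- 1L
  dm <- structure(list(
    X = cbind(x = x), y = y, n = nn,
    year = factor(rep(c("A", "B"), length.out = n)),
    vessel_id = rep("V01", n), observed = rep(TRUE, n),
    tow_id = as.character(seq_len(n)),
    dropped = list(n = 0, tow_id = character())
  ), class = "design_matrix")
  post <- sample_posterior(dm, prior_spec(),
                           mcmc_config(n_burn = 800, n_iter = 2400, thin = 3,
                                       n_chains = 2, seed = 5))
  ml <- fit_binomial_glm(cbind(x = x), y)
  draws <- posterior_draws(post)[, "beta_x"]
  expect_lt(abs(mean(draws) - ml$coefficients["x"]), 2 * sd(draws))
  expect_true(all(post$rhat[c("beta_x", "lambda")] < 1.1))
  expect_error(sample_posterior(dm, config = mcmc_config(n_chains = 0)),
               "chain")
})
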