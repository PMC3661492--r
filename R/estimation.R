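# Extrapolation of captures to unobserved effort and summary products.
# For each posterior draw, every unobserved tow gets a simulated capture
# event (Bernoulli at its modelled probability) and, given an event, a
# ZTP-distributed count; group totals are observed captures plus the
# simulated captures, so totals never fall below what observers reported.

#' Posterior totals of captures per group
#'
#' For each posterior draw and each unobserved tow, simulates an event from
#' the tow's capture probability and a count from the ZTP size of the same
#' draw (joint uncertainty propagation), then accumulates per-group totals
#' as observed captures + simulated captures on unobserved tows.
#'
#' @param posterior a `hurdle_posterior`.
#' @param design a [build_design_matrix()] over *all* tows (observed rows
#'   carry their counts).
#' @param grouping `"year_vessel"` or `"year"`.
#' @param seed seed for the prediction-side simulation.
#' @return tibble of class `group_estimates`: group keys, tow counts,
#'   observed captures, posterior mean and equal-tailed 95% interval of
#'   total captures, and the capture rate per 100 tows with its interval.
#'   The per-draw totals matrix is attached as attribute `draws`
#'   (groups x draws).
#' @export
predict_group_totals <- function(posterior, design, grouping = c("year_vessel", "year"),
                                 seed = 1) {
  grouping <- match.arg(grouping)
  if (anyNA(design$X)) stopf("predict_group_totals(): missing covariates on prediction rows")
  draws <- posterior_draws(posterior)
  n_draws <- nrow(draws)
  key <- if (grouping == "year_vessel") {
    paste(as.character(design$year), design$vessel_id, sep = "|")
  } else {
    as.character(design$year)
  }
  groups <- sort(unique(key))
  gidx <- match(key, groups)
  obs <- design$observed
  O <- tapply(ifelse(obs, design$n, 0), factor(key, levels = groups),
              sum, default = 0)
  O[is.na(O)] <- 0
  un <- which(!obs)
  totals <- matrix(rep(as.numeric(O), n_draws), length(groups), n_draws)
  if (length(un)) {
    Xu <- design$X[un, , drop = FALSE]
    t_u <- as.integer(design$year)[un]
    g_u <- gidx[un]
    p <- posterior$n_beta
    T_years <- length(posterior$year_levels)
    set.seed(seed)
    for (s in seq_len(n_draws)) {
      th <- draws[s, ]
      lambda_s <- th[p + T_years + 3]
      pi_u <- plogis(drop(Xu %*% th[seq_len(p)]) + th[p + t_u])
      ev <- runif(length(un)) < pi_u
      if (any(ev)) {
        counts <- sample_ztp(sum(ev), lambda_s)
        totals[, s] <- totals[, s] + tapply_sum(g_u[ev], counts, length(groups))
      }
    }
  }
  tot_tows <- tabulate(gidx, length(groups))
  obs_tows <- tabulate(gidx[obs], length(groups))
  mean_tot <- rowMeans(totals)
  qs <- t(apply(totals, 1, quantile, c(0.025, 0.975)))
  out <- tibble::tibble(
    group = groups,
    fishing_year = sub("\\|.*$", "", groups),
    vessel_id = if (grouping == "year_vessel") sub("^.*\\|", "", groups) else NA,
    total_tows = tot_tows,
    observed_tows = obs_tows,
    observed_captures = as.numeric(O),
    est_mean = mean_tot,
    est_lwr = qs[, 1],
    est_upr = qs[, 2],
    rate_mean = 100 * mean_tot / tot_tows,
    rate_lwr = 100 * qs[, 1] / tot_tows,
    rate_upr = 100 * qs[, 2] / tot_tows
  )
  attr(out, "draws") <- totals
  attr(out, "grouping") <- grouping
  class(out) <- c("group_estimates", class(out))
  out
}

# sum `values` into `n_bins` bins indexed by `bins`
tapply_sum <- function(bins, values, n_bins) {
  out <- numeric(n_bins)
  agg <- rowsum(as.numeric(values), bins)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Collapse vessel-group estimates to per-year totals
#'
#' Year totals are the draw-by-draw sums of that year's vessel groups, so
#' interval arithmetic respects the joint posterior.
#'
#' @param estimates a `group_estimates` from grouping `"year_vessel"`.
#' @return a `group_estimates` tibble keyed by fishing year.
#' @export
collapse_to_years <- function(estimates) {
  draws <- attr(estimates, "draws")
  yr <- estimates$fishing_year
  years <- sort(unique(yr))
  agg <- rowsum(draws, yr)
  tot <- rowsum(estimates$total_tows, yr)[, 1]
  obs <- rowsum(estimates$observed_tows, yr)[, 1]
  O <- rowsum(estimates$observed_captures, yr)[, 1]
  qs <- t(apply(agg, 1, quantile, c(0.025, 0.975)))
  out <- tibble::tibble(
    group = years, fishing_year = years, vessel_id = NA,
    total_tows = tot, observed_tows = obs, observed_captures = O,
    est_mean = rowMeans(agg), est_lwr = qs[, 1], est_upr = qs[, 2],
    rate_mean = 100 * rowMeans(agg) / tot,
    rate_lwr = 100 * qs[, 1] / tot,
    rate_upr = 100 * qs[, 2] / tot
  )
  attr(out, "draws") <- agg
  attr(out, "grouping") <- "year"
  class(out) <- c("group_estimates", class(out))
  out
}

#' Capture rate per 100 tows
#'
#' @param captures capture count, or a vector of posterior draws of counts.
#' @param tows tow count (`> 0`; zero tows gives `NA`).
#' @return `100 * captures / tows` (vectorised over draws).
#' @export
capture_rate_per_100 <- function(captures, tows) {
  if (any(tows == 0)) return(rep(NA_real_, length(captures)))
  100 * captures / tows
}

#' Headline-depth halving distance
#'
#' The increase in headline depth that halves the odds of a capture event
#' (approximately the probability, when events are rare): `ln(2) / |beta|`.
#'
#' @param beta_headline per-metre logistic coefficient, `< 0`.
#' @return metres.
#' @examples
#' halving_distance(-0.033) # ~ 21 m
#' @export
halving_distance <- function(beta_headline) {
  if (beta_headline >= 0) {
    stopf("halving_distance(): coefficient must be negative (risk must fall with depth)")
  }
  log(2) / abs(beta_headline)
}

#' Annual summary table
#'
#' Per fishing year: effort, percentage observed, observed captures and
#' capture events, the observed capture rate per 100 observed tows, and the
#' posterior mean and 95% interval of total captures and of the capture
#' rate per 100 tows. Years with no observed tows get `NA` observed rates.
#'
#' @param cov covariate table of all tows ([derive_covariates()]).
#' @param estimates per-year `group_estimates` (use [collapse_to_years()]
#'   if fitted by year x vessel).
#' @return tibble, one row per fishing year.
#' @export
annual_summary_table <- function(cov, estimates) {
  yrs <- estimates$fishing_year
  eff <- estimates$total_tows
  obs_tows <- estimates$observed_tows
  ev <- vapply(yrs, function(y) {
    sum(cov$observed & cov$fishing_year == y &
          !is.na(cov$captures) & cov$captures > 0)
  }, 0)
  tibble::tibble(
    fishing_year = yrs,
    effort = eff,
    percent_observed = round(100 * obs_tows / eff, 1),
    observed_captures = estimates$observed_captures,
    observed_events = as.numeric(ev),
    observed_rate = ifelse(obs_tows > 0,
                           round(100 * estimates$observed_captures / obs_tows, 2),
                           NA_real_),
    est_captures = round(estimates$est_mean),
    est_lwr = round(estimates$est_lwr),
    est_upr = round(estimates$est_upr),
    est_rate = round(estimates$rate_mean, 2),
    est_rate_lwr = round(estimates$rate_lwr, 2),
    est_rate_upr = round(estimates$rate_upr, 2)
  )
}

#' Reconstruct observed-tow counts from a published effort summary
#'
#' When only annual effort and observer-coverage percentages are available
#' (replication from a printed summary), observed tows are reconstructed as
#' `round(effort * percent / 100)`.
#'
#' @param effort annual tow counts.
#' @param percent_observed observer coverage, percent.
#' @return integer vector of observed tows.
#' @export
reconstruct_observed_tows <- function(effort, percent_observed) {
  as.integer(round(effort * percent_observed / 100))
}

#' Posterior predictive check of captures per event
#'
#' For each posterior draw, simulates as many event sizes from the draw's
#' ZTP size as there are observed events, tabulates them by size, and
#' reports the median, quartiles and equal-tailed 95% band of the count at
#' each size alongside the observed counts.
#'
#' @param posterior a `hurdle_posterior` (its `lambda` draws are used).
#' @param observed_counts integer vector of observed event sizes (`>= 1`).
#' @param seed simulation seed.
#' @param max_size largest size tabulated (default: observed max + 3).
#' @return tibble: size, observed count, median/quartile/95% band of the
#'   predicted count, and whether the observation falls outside the band.
#' @export
ppc_event_size <- function(posterior, observed_counts, seed = 1,
                           max_size = max(observed_counts) + 3) {
  stopifnot(length(observed_counts) >= 1, all(observed_counts >= 1))
  lam <- posterior_draws(posterior)[, "lambda"]
  n_ev <- length(observed_counts)
  set.seed(seed)
  sims <- vapply(lam, function(l) {
    tabulate(pmin(sample_ztp(n_ev, l), max_size), max_size)
  }, numeric(max_size))
  obs_tab <- tabulate(pmin(observed_counts, max_size), max_size)
  qs <- t(apply(sims, 1, quantile, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  tibble::tibble(
    size = seq_len(max_size),
    observed = obs_tab,
    lwr = qs[, 1], q25 = qs[, 2], median = qs[, 3], q75 = qs[, 4],
    upr = qs[, 5],
    outside = obs_tab < qs[, 1] | obs_tab > qs[, 5]
  )
}
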