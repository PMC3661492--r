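# Synthetic fleet generator. The real effort and observer data are
# confidential, so every stage of the pipeline is exercised on a generated
# fleet whose scale and covariate structure emulate the west-coast North
# Island mackerel fishery: 16 fishing years, 7 main vessels, published
# annual effort and observer-coverage fractions, a shallow/deep headline
# mixture coupled to the diel cycle (night tows shallower), and captures
# generated from the hurdle model with the published coefficient values.

#' Published annual effort and observer summary
#'
#' The printed annual summary of the west-coast North Island large-vessel
#' mackerel fishery, 1995-96 to 2010-11: trawl effort (tows), observer
#' coverage (percent of tows observed), observed common dolphin captures,
#' observed capture events, and the printed observed capture rate per 100
#' observed tows. Used both as the default scale of the synthetic fleet and
#' for replication of the observed-rate arithmetic.
#'
#' @return tibble with 16 rows.
#' @export
wcni_annual_summary <- function() {
  tibble::tibble(
    fishing_year = c("1995-96", "1996-97", "1997-98", "1998-99", "1999-00",
                     "2000-01", "2001-02", "2002-03", "2003-04", "2004-05",
                     "2005-06", "2006-07", "2007-08", "2008-09", "2009-10",
                     "2010-11"),
    effort = c(406L, 230L, 560L, 350L, 412L, 974L, 1577L, 2249L, 2309L,
               2424L, 2117L, 2167L, 2164L, 1820L, 2189L, 1551L),
    percent_observed = c(29.6, 70.4, 38.9, 24.0, 17.2, 12.2, 7.0, 9.9, 7.1,
                         23.1, 30.6, 28.7, 34.0, 38.1, 30.1, 29.9),
    captures = c(2L, 0L, 0L, 0L, 1L, 1L, 1L, 21L, 17L, 21L, 2L, 11L, 20L,
                 11L, 4L, 7L),
    events = c(1L, 0L, 0L, 0L, 1L, 1L, 1L, 6L, 7L, 10L, 1L, 5L, 4L, 5L,
               2L, 6L),
    printed_rate = c(1.67, 0.00, 0.00, 0.00, 1.41, 0.84, 0.90, 9.42, 10.37,
                     3.74, 0.31, 1.77, 2.72, 1.59, 0.61, 1.51)
  )
}

#' Scenario configuration for the synthetic fleet
#'
#' Defaults reproduce the study conditions: 16 fishing years starting
#' 1995-96 with the published annual effort (23 499 tows in total) and
#' observer-coverage fractions; 7 main vessels (over 90 m) splitting effort
#' evenly; headline depth a two-component mixture (60% shallow, mean 30 m
#' SD 15; 40% deep, mean 90 m SD 40; truncated above 5 m) coupled to the
#' diel cycle so night tows are shallower; tow duration log-normal with
#' median 4 h; true hurdle coefficients at the published posterior means
#' (headline depth -0.033 per m, log duration 1.470, light ln 0.177, black
#' ln 1.078, south ln 0.539) and ZTP size 2.1.
#'
#' @param n_years number of fishing years.
#' @param first_year first fishing-year start (calendar year).
#' @param effort_per_year tow counts per fishing year.
#' @param coverage observer-coverage fraction per year, in `[0, 1]`.
#' @param n_vessels main vessels; effort is split evenly across them.
#' @param vessel_lengths metres (all over 90).
#' @param beta named true coefficient vector on the design columns
#'   `headline_depth`, `log_duration`, `light_light`, `light_black`,
#'   `subarea_south`.
#' @param mu_alpha,sigma_alpha year-effect hyperparameters (logit scale).
#' @param lambda true ZTP size.
#' @param p_night probability a tow hauls at night.
#' @param p_shallow_night,p_shallow_day probability of the shallow headline
#'   mixture component for night/day tows (their effort-weighted mean is
#'   the 60% shallow fraction).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_years = 16,
                            first_year = 1995,
                            effort_per_year = wcni_annual_summary()$effort,
                            coverage = wcni_annual_summary()$percent_observed / 100,
                            n_vessels = 7,
                            vessel_lengths = seq(95, 119, by = 4),
                            beta = c(headline_depth = -0.033,
                                     log_duration = 1.470,
                                     light_light = log(0.177),
                                     light_black = log(1.078),
                                     subarea_south = log(0.539)),
                            mu_alpha = -3.4,
                            sigma_alpha = 0.6,
                            lambda = 2.1,
                            p_night = 0.45,
                            p_shallow_night = 0.78,
                            p_shallow_day = 0.45) {
  stopifnot(length(effort_per_year) == n_years,
            length(coverage) == n_years,
            all(coverage >= 0 & coverage <= 1),
            sigma_alpha > 0, lambda > 0)
  structure(list(n_years = n_years, first_year = first_year,
                 effort_per_year = effort_per_year, coverage = coverage,
                 n_vessels = n_vessels,
                 vessel_lengths = rep_len(vessel_lengths, n_vessels),
                 beta = beta, mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 lambda = lambda, p_night = p_night,
                 p_shallow_night = p_shallow_night,
                 p_shallow_day = p_shallow_day),
            class = "scenario_config")
}

#' The default (study-scale) scenario
#' @return the default [scenario_config()].
#' @export
study_scale_scenario <- function() scenario_config()

#' The covariate specs of the final capture-event model
#'
#' Headline depth, log tow duration, light condition and sub-area — the
#' four covariates the selection stage retains.
#' @return named list of [covariate_spec()]s.
#' @export
final_model_specs <- function() {
  default_covariate_specs()[c("headline_depth", "log_duration", "light", "subarea")]
}

#' Generate synthetic fleet effort (no captures)
#'
#' Tows are laid out per fishing year and vessel with seasonally weighted
#' start dates (effort concentrated October-December), day/night haul times
#' on the local clock, positions inside the study area, and gear geometry
#' consistent with the headline-depth mixture.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return tow tibble in the canonical schema (`observed = FALSE`,
#'   `captures = NA`).
#' @export
generate_effort <- function(config = scenario_config(), seed = 1) {
  set.seed(seed)
  area <- study_area()
  rows <- vector("list", config$n_years)
  month_w <- c(2.0, 1.0, 3.0, 1.0, 1.0, 1.0, 0.7, 1.2, 1.2, 0.5, 0.3, 0.4)
  # fishing-year months Oct..Sep
  for (yi in seq_len(config$n_years)) {
    n <- config$effort_per_year[yi]
    y0 <- config$first_year + yi - 1
    vessel <- sprintf("V%02d", 1 + (seq_len(n) - 1) %% config$n_vessels)
    vlen <- config$vessel_lengths[1 + (seq_len(n) - 1) %% config$n_vessels]
    mo <- sample(1:12, n, replace = TRUE, prob = month_w)
    cal_year <- ifelse(mo <= 3, y0, y0 + 1)          # months 1..3 = Oct..Dec
    cal_month <- ifelse(mo <= 3, mo + 9, mo - 3)
    day <- sample(1:28, n, replace = TRUE)
    night <- runif(n) < config$p_night
    # haul-hour on the local clock: day hauls mid-morning..evening, night
    # hauls between dusk and dawn
    haul_hour <- ifelse(night,
                        (21 + runif(n) * 9) %% 24,   # 21:00 .. 06:00
                        7.5 + runif(n) * 10)         # 07:30 .. 17:30
    duration <- rlnorm(n, log(4), 0.35)
    duration <- pmin(pmax(duration, 1), 12)
    end_local <- as.POSIXct(sprintf("%d-%02d-%02d 00:00:00",
                                    cal_year, cal_month, day), tz = "UTC") +
      round(haul_hour * 3600)
    end_time <- end_local - 12 * 3600                # local (+12) -> UTC
    start_time <- end_time - round(duration * 3600)
    shallow <- runif(n) < ifelse(night, config$p_shallow_night,
                                 config$p_shallow_day)
    headline_depth <- ifelse(shallow, rnorm(n, 30, 15), rnorm(n, 90, 40))
    headline_depth <- pmax(headline_depth, 5.1)
    headline_height <- runif(n, 15, 35)
    groundline_depth <- headline_depth + headline_height
    lat <- runif(n, area$south_bound_lat + 0.1, -37.2)
    lon <- runif(n, area$west_bound_lon + 0.2, area$east_bound_lon - 0.1)
    rows[[yi]] <- tibble::tibble(
      tow_id = sprintf("T%04d-%05d", y0, seq_len(n)),
      vessel_id = vessel,
      vessel_length = vlen,
      trip_id = paste(vessel, y0, 1 + (seq_len(n) - 1) %/% (config$n_vessels * 15),
                      sep = "/"),
      start_time = start_time, end_time = end_time,
      start_lat = lat, start_lon = lon,
      end_lat = lat + rnorm(n, 0, 0.03), end_lon = lon + rnorm(n, 0, 0.03),
      target_species = sample(c("JMA", "EMA", "BAR"), n, replace = TRUE,
                              prob = c(0.8, 0.15, 0.05)),
      catch_weight = round(rlnorm(n, log(20), 0.6), 1),
      groundline_depth = round(groundline_depth, 1),
      headline_height = round(headline_height, 1),
      trawl_speed = round(rnorm(n, 4.5, 0.4), 1),
      bottom_depth = round(groundline_depth + runif(n, 10, 150), 0),
      observed = FALSE,
      captures = NA_integer_
    )
  }
  do.call(rbind, rows)
}

#' Simulate captures on every tow from the hurdle model
#'
#' Derives the final-model covariates, draws one year effect per fishing
#' year from the hierarchy, computes each tow's capture-event probability,
#' draws events and ZTP event sizes. Counts are attached to *all* tows as
#' ground truth (`captures` column); `attr(x, "truth")` records the
#' realised year effects and true parameters.
#'
#' @param tows effort tibble from [generate_effort()].
#' @param config the [scenario_config()] holding the true parameters.
#' @param seed simulation seed.
#' @param cov optional precomputed covariate table for `tows` (saves
#'   re-deriving ephemeris covariates across replicated simulations).
#' @return the tows with `captures` filled on every row.
#' @export
simulate_captures <- function(tows, config = scenario_config(), seed = 1,
                              cov = NULL) {
  set.seed(seed)
  if (is.null(cov)) cov <- derive_covariates(tows)
  cov$observed <- TRUE            # ground truth: design over every tow
  dm <- build_design_matrix(cov, final_model_specs())
  if (nrow(dm$X) != nrow(tows)) {
    stopf("simulate_captures(): %d tows lost deriving covariates",
          nrow(tows) - nrow(dm$X))
  }
  stopifnot(identical(colnames(dm$X), names(config$beta)))
  alpha <- rnorm(nlevels(dm$year), config$mu_alpha, config$sigma_alpha)
  eta <- alpha[as.integer(dm$year)] + drop(dm$X %*% config$beta)
  event <- runif(nrow(tows)) < plogis(eta)
  counts <- integer(nrow(tows))
  if (any(event)) counts[event] <- sample_ztp(sum(event), config$lambda)
  out <- tows
  out$captures <- counts
  attr(out, "truth") <- list(alpha = setNames(alpha, levels(dm$year)),
                             beta = config$beta, lambda = config$lambda,
                             total_captures = sum(counts),
                             p_event = plogis(eta))
  out
}

#' Apply partial observer coverage
#'
#' Per fishing year, a simple random sample (without replacement) of
#' `round(coverage * n)` tows is flagged observed; capture counts are
#' exposed only on observed tows. The full truth is returned alongside for
#' evaluation.
#'
#' @param tows tows with true captures from [simulate_captures()].
#' @param coverage per-year coverage fractions (recycled to the years
#'   present, in fishing-year order).
#' @param seed sampling seed.
#' @return list: `observable` (captures masked on unobserved tows),
#'   `truth` (the input, untouched).
#' @export
apply_observer_coverage <- function(tows, coverage, seed = 1) {
  stopifnot(all(coverage >= 0 & coverage <= 1))
  set.seed(seed)
  fy <- assign_fishing_year(tows$start_time)
  years <- sort(unique(fy))
  coverage <- rep_len(coverage, length(years))
  observed <- logical(nrow(tows))
  for (i in seq_along(years)) {
    idx <- which(fy == years[i])
    n_obs <- round(coverage[i] * length(idx))
    if (n_obs > 0) observed[idx[sample.int(length(idx), n_obs)]] <- TRUE
  }
  observable <- tows
  observable$observed <- observed
  observable$captures[!observed] <- NA_integer_
  attr(observable, "truth") <- NULL
  list(observable = observable, truth = tows)
}
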