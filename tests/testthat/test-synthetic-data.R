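# The synthetic fleet generator: conservation, determinism, and the
# generative hurdle process hitting its analytic targets.

test_that("default scenario reproduces the study-scale conditions", {
  cfg <- study_scale_scenario()
  expect_equal(sum(cfg$effort_per_year), 23499)
  expect_equal(cfg$n_years, 16)
  expect_equal(cfg$lambda, 2.1)
  expect_equal(unname(cfg$beta["headline_depth"]), -0.033)
  expect_equal(unname(cfg$beta["log_duration"]), 1.470)
  expect_true(all(cfg$coverage >= 0.069 & cfg$coverage <= 0.705))
})

test_that("generated effort conserves configured totals and is deterministic", {
  cfg <- mini_scenario()
  t1 <- generate_effort(cfg, seed = 5)
  expect_equal(nrow(t1), sum(cfg$effort_per_year))
  t2 <- generate_effort(cfg, seed = 5)
  expect_equal(t1, t2)
  t3 <- generate_effort(cfg, seed = 6)
  expect_false(identical(t1$start_time, t3$start_time))
  # structural invariants the readers enforce
  expect_true(all(t1$end_time > t1$start_time))
  expect_true(all(t1$headline_height < t1$groundline_depth))
  expect_true(all(in_study_area(t1)))
  yrs <- assign_fishing_year(t1$start_time)
  expect_lte(length(unique(yrs)), cfg$n_years + 1)  # starts can cross 1 Oct
})

test_that("headline-depth mixture hits its analytic shallow fraction", {
  cfg <- scenario_config(n_years = 2, first_year = 2002,
                         effort_per_year = c(4000, 4000),
                         coverage = c(0.3, 0.3))
  tows <- generate_effort(cfg, seed = 8)
  hd <- tows$groundline_depth - tows$headline_height
  n <- length(hd)
  # mixture CDF at 40 m (truncation at 5 m has negligible mass)
  p_night <- cfg$p_night
  w_shallow <- p_night * cfg$p_shallow_night + (1 - p_night) * cfg$p_shallow_day
  p40 <- w_shallow * pnorm(40, 30, 15) + (1 - w_shallow) * pnorm(40, 90, 40)
  se <- sqrt(p40 * (1 - p40) / n)
  expect_lt(abs(mean(hd < 40) - p40), 3 * se + 0.01)
})

test_that("simulated captures follow the hurdle generative process", {
  # flat covariates isolate the intercept: event rate ~ 1%
  tows <- make_tows(8000)
  tows$start_time <- tows$start_time[1] + runif(8000, 0, 300) * 86400
  tows$end_time <- tows$start_time + 4 * 3600
  cfg <- scenario_config(n_years = 1, first_year = 2004,
                         effort_per_year = 8000, coverage = 1,
                         beta = c(headline_depth = 0, log_duration = 0,
                                  light_light = 0, light_black = 0,
                                  subarea_south = 0),
                         mu_alpha = qlogis(0.01), sigma_alpha = 1e-6,
                         lambda = 2.1)
  # two fishing years can appear at the 1 Oct boundary; keep seeds fixed
  sim <- simulate_captures(tows, cfg, seed = 13)
  ev <- mean(sim$captures > 0)
  expect_lt(abs(ev - 0.01), 3 * sqrt(0.01 * 0.99 / 8000))
  # mean event size near the ZTP mean 2.393
  sizes <- sim$captures[sim$captures > 0]
  expect_lt(abs(mean(sizes) - ztp_mean(2.1)), 3 * sd(sizes) / sqrt(length(sizes)))
  # a -50 intercept shuts captures off entirely
  cfg0 <- cfg; cfg0$mu_alpha <- -50
  sim0 <- simulate_captures(tows, cfg0, seed = 13)
  expect_equal(sum(sim0$captures), 0)
})

test_that("observer coverage masks exactly the sampled tows", {
  cfg <- mini_scenario()
  tows <- simulate_captures(generate_effort(cfg, 1), cfg, 2)
  # full coverage exposes everything
  all_seen <- apply_observer_coverage(tows, 1, 3)
  expect_true(all(all_seen$observable$observed))
  expect_equal(all_seen$observable$captures, tows$captures)
  # zero coverage hides everything, truth intact
  none <- apply_observer_coverage(tows, 0, 3)
  expect_false(any(none$observable$observed))
  expect_true(all(is.na(none$observable$captures)))
  expect_equal(none$truth$captures, tows$captures)
  # 30% coverage: exact without-replacement sampling per year
  some <- apply_observer_coverage(tows, 0.3, 3)
  fy <- assign_fishing_year(tows$start_time)
  for (y in unique(fy)) {
    idx <- fy == y
    expect_equal(sum(some$observable$observed[idx]), round(0.3 * sum(idx)))
  }
  # observed counts agree with the truth where exposed
  obs <- some$observable$observed
  expect_equal(some$observable$captures[obs], tows$captures[obs])
})

test_that("generated data survive a full reader round-trip", {
  cfg <- mini_scenario()
  sp <- apply_observer_coverage(
    simulate_captures(generate_effort(cfg, 1), cfg, 2), cfg$coverage, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_effort_table(sp$observable, path)
  back <- read_effort_table(path)
  expect_equal(attr(back, "load_report")$n_dropped, 0)
  expect_equal(nrow(back), nrow(sp$observable))
  expect_equal(back$observed, sp$observable$observed)
  expect_equal(back$captures, sp$observable$captures)
})
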