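# The light-condition rule, night hours, gear geometry and design assembly.

local_time <- function(x) as.POSIXct(x, tz = "UTC") - 12 * 3600

test_that("light classification follows the twilight/moon rule", {
  lat <- -39; lon <- 172
  # mid-afternoon is light regardless of the moon
  t_day <- local_time("2006-01-20 14:00:00")
  expect_equal(as.character(classify_light_condition(t_day, lat, lon)), "light")
  # pick a dark night (new moon) and a moonlit night (full moon)
  dark_new <- as.Date("2006-03-29")    # solar eclipse: new moon
  lit_full <- as.Date("2008-02-21")    # lunar eclipse: full moon
  t_ev_dark <- local_time(paste(dark_new, "22:00:00"))
  t_mo_dark <- local_time(paste(dark_new, "02:00:00"))
  t_ev_lit <- local_time(paste(lit_full, "22:00:00"))
  t_mo_lit <- local_time(paste(lit_full, "02:00:00"))
  expect_lt(moon_illuminated_fraction(t_ev_dark), 0.17)
  expect_gt(moon_illuminated_fraction(t_ev_lit), 0.17)
  expect_equal(as.character(classify_light_condition(t_ev_dark, lat, lon)), "dark")
  expect_equal(as.character(classify_light_condition(t_mo_dark, lat, lon)), "black")
  expect_equal(as.character(classify_light_condition(t_ev_lit, lat, lon)), "light")
  expect_equal(as.character(classify_light_condition(t_mo_lit, lat, lon)), "dark")
})

test_that("light classification partitions all haul times into 3 levels", {
  set.seed(11)
  ts <- local_time("2005-06-01 00:00:00") + runif(60, 0, 300 * 86400)
  lev <- classify_light_condition(ts, -39, 172)
  expect_false(anyNA(lev))
  expect_setequal(levels(lev), c("dark", "light", "black"))
  # daytime hauls are light irrespective of lunar fraction
  tw <- civil_twilight_times(as.Date("2005-08-15"), -39, 172)
  mid <- tw$dawn + (as.numeric(tw$dusk) - as.numeric(tw$dawn)) / 2
  expect_equal(as.character(classify_light_condition(mid, -39, 172)), "light")
})

test_that("night hours complement day hours and handle straddling tows", {
  lat <- -39; lon <- 172
  # tow entirely in daylight
  s <- local_time("2006-01-20 10:00:00")
  expect_equal(night_hours(s, s + 4 * 3600, lat, lon), 0)
  # tow exactly dusk -> dawn covers the whole night
  tw1 <- civil_twilight_times(as.Date("2006-01-20"), lat, lon)
  tw2 <- civil_twilight_times(as.Date("2006-01-21"), lat, lon)
  full_night <- (as.numeric(tw2$dawn) - as.numeric(tw1$dusk)) / 3600
  expect_equal(night_hours(tw1$dusk, tw2$dawn, lat, lon), full_night,
               tolerance = 1e-3)
  # tow straddling dusk by one hour
  expect_equal(night_hours(tw1$dusk - 3600, tw1$dusk + 3600, lat, lon), 1,
               tolerance = 1e-3)
  # night + day = total duration (property, random tows)
  set.seed(3)
  for (i in 1:10) {
    s <- local_time("2007-03-01 00:00:00") + runif(1, 0, 200 * 86400)
    dur <- runif(1, 1, 30) * 3600
    nh <- night_hours(s, s + dur, lat, lon)
    expect_gte(nh, 0)
    expect_lte(nh, dur / 3600 + 1e-6)
  }
})

test_that("headline depth is the ground line minus the headline height", {
  expect_equal(derive_headline_depth(100, 60), 40)
  expect_equal(derive_headline_depth(210, 10), 200)
  expect_error(derive_headline_depth(50, 60), "invalid gear")
  expect_error(derive_headline_depth(-5, 10), "positive")
})

test_that("the 210 m depth factor threshold is strict", {
  expect_equal(as.character(classify_depth_factor(100)), "shallow")
  expect_equal(as.character(classify_depth_factor(210)), "deep")
  expect_equal(as.character(classify_depth_factor(1000)), "deep")
})

test_that("bottom depth lookup takes the minimum of start and end cells", {
  # plane-sloped raster: depth = 10 * col index (lon), analytic oracle
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 20", "nrows 10", "xllcorner 171.0", "yllcorner -41.0",
               "cellsize 0.2", "NODATA_value -9999",
               paste(vapply(1:10, function(r) paste(10 * (1:20), collapse = " "),
                            ""), collapse = "\n")), path)
  grid <- read_depth_grid(path)
  tows <- make_tows(2)
  tows$start_lon <- c(171.1, 171.5); tows$end_lon <- c(172.1, 171.5)
  tows$start_lat <- -40.5; tows$end_lat <- -40.5
  d <- lookup_bottom_depth(tows, grid)
  # cell centres: col = floor((lon-171)/0.2)+1; depths 10*col
  expect_equal(unname(d[1]), 10)    # min(col 1 -> 10, col 6 -> 60)
  expect_equal(unname(d[2]), 30)    # identical positions -> that cell
  # off-grid position flagged
  tows$start_lon[1] <- 180
  d2 <- lookup_bottom_depth(tows, grid)
  expect_true(is.na(d2[1]))
  expect_true(attr(d2, "outside")[1])
})

test_that("design matrix applies transforms, offsets and treatment coding", {
  tows <- make_tows(6)
  tows$catch_weight <- c(0, 1, 5, 10, 2, 3)
  tows$observed <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  tows$captures <- c(2L, 0L, 1L, NA, NA, NA)
  cov <- derive_covariates(tows)
  specs <- default_covariate_specs()[c("log_catch_weight", "log_duration",
                                       "light", "subarea")]
  dm <- build_design_matrix(cov, specs)
  # zero catch with the one-tonne offset -> log(1) = 0
  expect_equal(unname(dm$X[1, "log_catch_weight"]), 0)
  expect_equal(unname(dm$X[3, "log_catch_weight"]), log(6))
  expect_equal(unname(dm$X[2, "log_duration"]), log(4), tolerance = 1e-9)
  # treatment coding against dark/north references
  expect_setequal(colnames(dm$X),
                  c("log_catch_weight", "log_duration", "light_light",
                    "light_black", "subarea_south"))
  lv <- as.character(cov$light)
  expect_equal(unname(dm$X[, "light_light"]), as.numeric(lv == "light"))
  # response defined only on observed rows; counts preserved
  expect_equal(dm$y, c(1, 0, 1, NA, NA, NA))
  expect_equal(dm$n[1], 2L)
  # invalid gear rows are excluded upstream with a report
  tows2 <- tows; tows2$headline_height[4] <- 999
  cov2 <- derive_covariates(tows2)
  expect_equal(attr(cov2, "excluded")$n, 1)
  expect_equal(attr(cov2, "excluded")$tow_id, tows$tow_id[4])
})
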