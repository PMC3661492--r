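test_that("effort tables round-trip through the canonical CSV schema", {
  cfg <- mini_scenario()
  tows <- generate_effort(cfg, seed = 7)[1:100, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_effort_table(tows, path)
  back <- read_effort_table(path)
  expect_equal(attr(back, "load_report")$n_dropped, 0)
  expect_equal(nrow(back), 100)
  expect_equal(back$tow_id, tows$tow_id)
  expect_equal(as.numeric(back$start_time), as.numeric(tows$start_time))
  expect_equal(back$groundline_depth, tows$groundline_depth)
  expect_equal(back$start_lat, tows$start_lat)
})

test_that("malformed rows are dropped and counted, not fatal", {
  tows <- make_tows(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_effort_table(tows, path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$end_time[2] <- df$start_time[2]           # end before/equal start
  df$start_time[3] <- "not a time"
  write.csv(df, path, row.names = FALSE)
  back <- read_effort_table(path)
  expect_equal(nrow(back), 1)
  rep <- attr(back, "load_report")
  expect_equal(rep$n_dropped, 2)
  expect_equal(unname(rep$dropped_by_reason["times_not_ordered"]), 1)
  expect_error(read_effort_table(tempfile()), "no such file")
})

test_that("a missing mandatory column is a hard error naming it", {
  tows <- make_tows(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_effort_table(tows, path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$vessel_id <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_effort_table(path), "vessel_id")
})

test_that("observer records link onto their tows within tolerances", {
  tows <- make_tows(6)
  obs <- tibble::tibble(
    vessel_id = "V01",
    start_time = tows$start_time[c(2, 5)] + c(0, 10 * 60),  # +10 min shift
    end_time = tows$end_time[c(2, 5)],
    start_lat = tows$start_lat[c(2, 5)], start_lon = tows$start_lon[c(2, 5)],
    target_species = "JMA",
    captures = c(3L, 0L)
  )
  res <- link_observer_records(tows, obs, time_tol_min = 30, dist_tol_km = 10)
  expect_equal(res$n_matched, 2)
  expect_equal(which(res$tows$observed), c(2L, 5L))
  expect_equal(res$tows$captures[2], 3L)
  expect_equal(res$tows$captures[5], 0L)
  # linking is idempotent
  res2 <- link_observer_records(res$tows, obs, 30, 10)
  expect_equal(res2$tows, res$tows)
  # a record for an unknown vessel comes back unmatched
  stranger <- obs[1, ]; stranger$vessel_id <- "V99"
  res3 <- link_observer_records(tows, stranger, 30, 10)
  expect_equal(res3$n_matched, 0)
  expect_equal(nrow(res3$unmatched), 1)
  # two records hitting the same tow is an ambiguity error
  dup <- rbind(obs[1, ], obs[1, ])
  expect_error(link_observer_records(tows, dup, 30, 10), "match tow")
})

test_that("fleet filter keeps and drops whole trips atomically", {
  t1 <- make_tows(10)                              # 95+ m, mixed targets
  t1$vessel_length <- 95
  t1$target_species <- c("BAR", "BAR", "JMA", rep("BAR", 7))
  t2 <- make_tows(5, vessel = "V02", length_m = 80) # small vessel, all mackerel
  t2$tow_id <- paste0("S", t2$tow_id)
  t3 <- make_tows(4, vessel = "V03", length_m = 95) # big vessel, no mackerel
  t3$tow_id <- paste0("N", t3$tow_id)
  t3$target_species <- "BAR"
  out <- filter_large_vessel_mackerel_fleet(rbind(t1, t2, t3))
  expect_equal(sort(out$tow_id), sort(t1$tow_id))  # whole trip kept
  # filter is monotone: adding tows to a kept trip never drops it
  extra <- make_tows(2)
  extra$tow_id <- c("X001", "X002")
  extra$vessel_length <- 95
  extra$target_species <- "BAR"
  out2 <- filter_large_vessel_mackerel_fleet(rbind(t1, extra))
  expect_true(all(t1$tow_id %in% out2$tow_id))
})

test_that("fishing years follow the 1 October boundary", {
  at <- function(x) as.POSIXct(paste(x, "12:00:00"), tz = "UTC") - 12 * 3600
  expect_equal(assign_fishing_year(at("1995-10-01")), "1995-96")
  expect_equal(assign_fishing_year(at("1996-09-30")), "1995-96")
  expect_equal(assign_fishing_year(at("1996-10-01")), "1996-97")
  expect_equal(assign_fishing_year(at("1999-12-31")), "1999-00")
})

test_that("every position maps to exactly one sub-area, boundary south", {
  expect_equal(as.character(assign_subarea(-38.0)), "north")
  expect_equal(as.character(assign_subarea(-40.0)), "south")
  expect_equal(as.character(assign_subarea(-39.3)), "south")
  lats <- runif(100, -41, -37)
  expect_false(anyNA(assign_subarea(lats)))
})

test_that("study-area membership is the configured rectangle", {
  mk <- function(lat, lon) {
    t <- make_tows(1); t$start_lat <- lat; t$start_lon <- lon; t
  }
  expect_true(in_study_area(mk(-38.5, 172.0)))
  expect_false(in_study_area(mk(-42.0, 172.0)))   # south of 41 S
  expect_false(in_study_area(mk(-38.5, 174.5)))   # east of 173 2.8' E
  expect_false(in_study_area(mk(-38.5, 170.5)))   # west of 171 E
  # the eastern bound is 173 deg 2.8 min
  expect_true(in_study_area(mk(-38.5, 173.04)))
  expect_false(in_study_area(mk(-38.5, 173.05)))
  expect_error(study_area(subarea_split_lat = -50), "inside")
})
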