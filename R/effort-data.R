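# Per-tow effort records, observer records, study area, linking and
# filtering. Records live in tibbles with a canonical column schema; times
# are stored as POSIXct UTC instants and interpreted on a local civil clock
# at a configurable UTC offset (default +12:00, New Zealand standard time).

tow_columns <- c(
  "tow_id", "vessel_id", "vessel_length", "trip_id", "start_time", "end_time",
  "start_lat", "start_lon", "end_lat", "end_lon", "target_species",
  "catch_weight", "groundline_depth", "headline_height", "trawl_speed",
  "bottom_depth", "observed", "captures"
)

observer_columns <- c("vessel_id", "start_time", "end_time", "start_lat",
                      "start_lon", "target_species", "captures")

#' Study-area rectangle with a north/south split
#'
#' Rectangular approximation of the west-coast North Island region: bounded
#' east by 173 deg 2.8 min E, south by 41 deg S (Cook Strait), west by
#' 171 deg E, and north by a configurable latitude standing in for the EEZ
#' boundary. The region is split into northern and southern sub-areas at
#' 39 deg 18 min S.
#'
#' @param east_bound_lon,west_bound_lon,south_bound_lat,north_bound_lat
#'   rectangle edges, decimal degrees.
#' @param subarea_split_lat latitude of the north/south split.
#' @return an object of class `study_area`.
#' @export
study_area <- function(east_bound_lon = 173 + 2.8 / 60,
                       west_bound_lon = 171,
                       south_bound_lat = -41,
                       north_bound_lat = -36.5,
                       subarea_split_lat = -39.3) {
  if (!(subarea_split_lat > south_bound_lat && subarea_split_lat < north_bound_lat)) {
    stopf("study_area(): split latitude must lie strictly inside the area")
  }
  structure(list(east_bound_lon = east_bound_lon,
                 west_bound_lon = west_bound_lon,
                 south_bound_lat = south_bound_lat,
                 north_bound_lat = north_bound_lat,
                 subarea_split_lat = subarea_split_lat),
            class = "study_area")
}

#' Is a tow's start position inside the study area?
#'
#' @param tows a tow tibble (needs `start_lat`, `start_lon`).
#' @param area a [study_area()].
#' @return logical vector, one element per tow.
#' @export
in_study_area <- function(tows, area = study_area()) {
  tows$start_lat >= area$south_bound_lat &
    tows$start_lat <= area$north_bound_lat &
    tows$start_lon >= area$west_bound_lon &
    tows$start_lon <= area$east_bound_lon
}

#' Assign the New Zealand fishing year
#'
#' The fishing year runs 1 October to 30 September: dates from 1 Oct of
#' calendar year Y through 30 Sep of Y+1 are labelled `"Y-(Y+1 mod 100)"`,
#' e.g. `"1995-96"`.
#'
#' @param time `POSIXct` vector.
#' @param utc_offset local civil offset in hours used to resolve the date.
#' @return character vector of fishing-year labels.
#' @export
assign_fishing_year <- function(time, utc_offset = 12) {
  d <- local_date(time, utc_offset)
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  start <- ifelse(m >= 10, y, y - 1)
  sprintf("%d-%02d", start, (start + 1) %% 100)
}

#' Assign the north/south sub-area
#'
#' Latitudes above the split are "north"; the split itself and everything
#' south of it is "south" (closed-south convention).
#'
#' @param lat latitude, decimal degrees (negative southern hemisphere).
#' @param split_lat split latitude (default -39.3, i.e. 39 deg 18 min S).
#' @return factor with levels `north`, `south` ("north" is the modelling
#'   reference level).
#' @export
assign_subarea <- function(lat, split_lat = -39.3) {
  factor(ifelse(lat > split_lat, "north", "south"), levels = c("north", "south"))
}

#' Column dialect for delimited effort/observer tables
#'
#' Maps the canonical schema onto the columns of a particular file and fixes
#' the timestamp format and local clock offset.
#'
#' @param columns named character vector mapping canonical names to file
#'   column names; canonical names absent from the map are assumed to be
#'   spelled canonically in the file.
#' @param time_format `strptime` format of timestamp columns.
#' @param utc_offset hours; file timestamps are local civil clock at this
#'   offset.
#' @return a list of class `table_dialect`.
#' @export
table_dialect <- function(columns = character(), time_format = "%Y-%m-%d %H:%M:%S",
                          utc_offset = 12) {
  structure(list(columns = columns, time_format = time_format,
                 utc_offset = utc_offset), class = "table_dialect")
}

parse_local_time <- function(x, dialect) {
  t <- as.POSIXct(as.character(x), tz = "UTC", format = dialect$time_format)
  as.POSIXct(as.numeric(t) - dialect$utc_offset * 3600,
             origin = "1970-01-01", tz = "UTC")
}

format_local_time <- function(t, dialect = table_dialect()) {
  format(local_clock(t, dialect$utc_offset), "%Y-%m-%d %H:%M:%S")
}

map_columns <- function(df, wanted, dialect, mandatory, what) {
  out <- list()
  for (nm in wanted) {
    file_col <- unname(dialect$columns[nm])
    if (is.na(file_col) || is.null(file_col)) file_col <- nm
    if (file_col %in% names(df)) {
      out[[nm]] <- df[[file_col]]
    } else if (nm %in% mandatory) {
      stopf("%s: mandatory column '%s' (file column '%s') is missing",
            what, nm, file_col)
    } else {
      out[[nm]] <- rep(NA, nrow(df))
    }
  }
  tibble::as_tibble(out)
}

#' Read a fisher-reported effort table
#'
#' Reads a delimited file of per-tow effort records into the canonical
#' schema. Rows whose mandatory fields fail to parse, whose times are not
#' ordered, or whose coordinates are impossible are dropped and counted in
#' the attached load report (`attr(x, "load_report")`).
#'
#' @param path CSV file path.
#' @param dialect a [table_dialect()].
#' @return tibble of tow records; attribute `load_report` holds counts of
#'   rows read/kept/dropped by reason.
#' @export
read_effort_table <- function(path, dialect = table_dialect()) {
  if (!file.exists(path)) stopf("read_effort_table(): no such file: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("tow_id", "vessel_id", "vessel_length", "start_time",
                 "end_time", "start_lat", "start_lon", "target_species")
  df <- map_columns(raw, tow_columns, dialect, mandatory, "read_effort_table()")
  df$start_time <- parse_local_time(df$start_time, dialect)
  df$end_time <- parse_local_time(df$end_time, dialect)
  for (nm in c("vessel_length", "start_lat", "start_lon", "end_lat", "end_lon",
               "catch_weight", "groundline_depth", "headline_height",
               "trawl_speed", "bottom_depth")) {
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  }
  df$observed <- if (all(is.na(df$observed))) FALSE else isTRUE_vec(df$observed)
  df$captures <- suppressWarnings(as.integer(df$captures))

  reasons <- list(
    unparseable_time = is.na(df$start_time) | is.na(df$end_time),
    times_not_ordered = !is.na(df$start_time) & !is.na(df$end_time) &
      df$end_time <= df$start_time,
    bad_position = is.na(df$start_lat) | is.na(df$start_lon) |
      abs(df$start_lat) > 90,
    bad_mandatory = is.na(df$tow_id) | is.na(df$vessel_id) |
      is.na(df$vessel_length)
  )
  drop <- Reduce(`|`, reasons)
  report <- list(n_read = nrow(df), n_kept = sum(!drop), n_dropped = sum(drop),
                 dropped_by_reason = vapply(reasons, sum, integer(1)))
  out <- df[!drop, , drop = FALSE]
  attr(out, "load_report") <- report
  out
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write tow records in the canonical CSV schema
#'
#' @param tows tow tibble.
#' @param path output path.
#' @param dialect a [table_dialect()] fixing time format and offset.
#' @return `path`, invisibly.
#' @export
write_effort_table <- function(tows, path, dialect = table_dialect()) {
  out <- tows[, intersect(tow_columns, names(tows)), drop = FALSE]
  out$start_time <- format_local_time(out$start_time, dialect)
  out$end_time <- format_local_time(out$end_time, dialect)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an observer table
#'
#' @inheritParams read_effort_table
#' @return tibble of observer records with a `load_report` attribute.
#' @export
read_observer_table <- function(path, dialect = table_dialect()) {
  if (!file.exists(path)) stopf("read_observer_table(): no such file: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("vessel_id", "start_time", "target_species", "captures")
  df <- map_columns(raw, observer_columns, dialect, mandatory,
                    "read_observer_table()")
  df$start_time <- parse_local_time(df$start_time, dialect)
  df$end_time <- parse_local_time(df$end_time, dialect)
  df$start_lat <- suppressWarnings(as.numeric(df$start_lat))
  df$start_lon <- suppressWarnings(as.numeric(df$start_lon))
  df$captures <- suppressWarnings(as.integer(df$captures))
  drop <- is.na(df$start_time) | is.na(df$captures) | df$captures < 0
  report <- list(n_read = nrow(df), n_kept = sum(!drop), n_dropped = sum(drop))
  out <- df[!drop, , drop = FALSE]
  attr(out, "load_report") <- report
  out
}

#' Link observer records onto effort tows
#'
#' Each observer record is matched to at most one effort tow of the same
#' vessel and target species whose start time lies within `time_tol_min`
#' minutes and whose start position lies within `dist_tol_km` km
#' (great-circle). Matched tows get `observed = TRUE` and the observer's
#' capture count; ties on a tow are an ambiguity error; observer records
#' with no candidate tow are returned for audit.
#'
#' @param effort tow tibble.
#' @param obs observer tibble.
#' @param time_tol_min,dist_tol_km matching tolerances (> 0).
#' @return list with `tows` (effort with `observed`/`captures` filled),
#'   `unmatched` (observer rows that matched nothing) and `n_matched`.
#' @export
link_observer_records <- function(effort, obs, time_tol_min = 60,
                                  dist_tol_km = 10) {
  stopifnot(nrow(effort) > 0, nrow(obs) > 0,
            time_tol_min > 0, dist_tol_km > 0)
  matched_tow <- rep(NA_integer_, nrow(obs))
  for (j in seq_len(nrow(obs))) {
    cand <- which(effort$vessel_id == obs$vessel_id[j] &
                    effort$target_species == obs$target_species[j])
    if (!length(cand)) next
    dt <- abs(as.numeric(effort$start_time[cand]) -
                as.numeric(obs$start_time[j])) / 60
    cand <- cand[dt <= time_tol_min]
    if (!length(cand)) next
    dd <- geosphere::distHaversine(
      cbind(effort$start_lon[cand], effort$start_lat[cand]),
      c(obs$start_lon[j], obs$start_lat[j])) / 1000
    cand <- cand[dd <= dist_tol_km]
    if (!length(cand)) next
    dt <- abs(as.numeric(effort$start_time[cand]) -
                as.numeric(obs$start_time[j]))
    matched_tow[j] <- cand[which.min(dt)]
  }
  dup <- matched_tow[!is.na(matched_tow)][duplicated(matched_tow[!is.na(matched_tow)])]
  if (length(dup)) {
    stopf("link_observer_records(): observer records %s all match tow '%s'",
          paste(which(matched_tow %in% dup), collapse = ", "),
          paste(unique(effort$tow_id[dup]), collapse = ", "))
  }
  tows <- effort
  ok <- !is.na(matched_tow)
  tows$observed[matched_tow[ok]] <- TRUE
  tows$captures[matched_tow[ok]] <- obs$captures[ok]
  list(tows = tows, unmatched = obs[!ok, , drop = FALSE], n_matched = sum(ok))
}

# Trip structure: explicit trip_id when present, else maximal runs of a
# vessel's tows with inter-tow gaps under `gap_days`.
derive_trips <- function(tows, gap_days = 7) {
  if ("trip_id" %in% names(tows) && !all(is.na(tows$trip_id))) {
    return(as.character(tows$trip_id))
  }
  trip <- character(nrow(tows))
  for (v in unique(tows$vessel_id)) {
    idx <- which(tows$vessel_id == v)
    idx <- idx[order(tows$start_time[idx])]
    gaps <- c(0, diff(as.numeric(tows$start_time[idx])) / 86400)
    run <- cumsum(gaps >= gap_days) + 1
    trip[idx] <- paste(v, run, sep = "/")
  }
  trip
}

#' Restrict to the large-vessel mackerel fleet
#'
#' Keeps whole trips, atomically: a trip is retained iff its vessel is
#' longer than `min_length` metres and at least one of its tows targets a
#' mackerel code. Trips come from an explicit `trip_id` column when present,
#' otherwise from maximal runs of a vessel's tows separated by less than 7
#' days.
#'
#' @param tows tow tibble.
#' @param min_length vessel length gate in metres (strictly greater than).
#' @param mackerel_codes target-species codes counted as mackerel.
#' @return the retained tows, with a `trip_id` column filled in.
#' @export
filter_large_vessel_mackerel_fleet <- function(tows, min_length = 90,
                                               mackerel_codes = c("JMA", "EMA")) {
  if (!nrow(tows)) return(tows)
  if (!"start_time" %in% names(tows)) {
    stopf("filter_large_vessel_mackerel_fleet(): no trip_id and no start times; supply trip_id")
  }
  tows$trip_id <- derive_trips(tows)
  has_mack <- tapply(tows$target_species %in% mackerel_codes, tows$trip_id, any)
  big <- tapply(tows$vessel_length > min_length, tows$trip_id, all)
  keep_trip <- names(has_mack)[has_mack & big[names(has_mack)]]
  tows[tows$trip_id %in% keep_trip, , drop = FALSE]
}
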