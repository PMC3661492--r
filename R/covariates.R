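# Per-tow covariate engineering: light condition from civil twilight and
# lunar illumination, night hours, headline depth, depth factor, bathymetry
# lookup, and assembly of the treatment-coded design matrix.

#' Classify the light condition of a haul
#'
#' Three-valued factor driven by the haul time relative to civil twilight
#' and by the lunar phase: *light* (haul between dawn and dusk, or between
#' dusk and local midnight on a moonlit night), *dark* (between dusk and
#' midnight on a dark night, or between midnight and dawn on a moonlit
#' night), and *black* (between midnight and dawn on a dark night). A night
#' is moonlit when strictly more than 17% of the lunar disc is illuminated,
#' evaluated at the haul time. Midnight is 00:00 on the local civil clock.
#'
#' @param haul_time `POSIXct` vector (UTC instants) of net-haul times.
#' @param lat,lon haul position, decimal degrees (vectorised).
#' @param utc_offset local civil clock offset, hours.
#' @param moonlit_threshold illuminated-disc fraction above which the night
#'   counts as moonlit.
#' @return factor with levels `dark`, `light`, `black` (`dark` is the
#'   modelling reference level).
#' @export
classify_light_condition <- function(haul_time, lat, lon, utc_offset = 12,
                                     moonlit_threshold = 0.17) {
  n <- length(haul_time)
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  out <- character(n)
  moonlit <- moon_illuminated_fraction(haul_time) > moonlit_threshold
  d <- local_date(haul_time, utc_offset)
  tnum <- as.numeric(haul_time)
  for (i in seq_len(n)) {
    tw <- civil_twilight_sec(d[i], lat[i], lon[i], utc_offset)
    t <- tnum[i]
    if (t >= tw[1] && t <= tw[2]) {
      out[i] <- "light"
    } else if (t > tw[2]) {              # evening: dusk -> local midnight
      out[i] <- if (moonlit[i]) "light" else "dark"
    } else {                             # morning: local midnight -> dawn
      out[i] <- if (moonlit[i]) "dark" else "black"
    }
  }
  factor(out, levels = c("dark", "light", "black"))
}

#' Night hours of a tow
#'
#' Total duration of the tow spent between civil dusk and the following
#' civil dawn, summed over every night the tow spans.
#'
#' @param start,end `POSIXct` tow start and end (UTC instants); `end >
#'   start`, tows under 48 h.
#' @param lat,lon tow position, decimal degrees.
#' @param utc_offset local civil clock offset, hours.
#' @return hours of darkness, `>= 0`.
#' @export
night_hours <- function(start, end, lat, lon, utc_offset = 12) {
  stopifnot(length(start) == length(end))
  n <- length(start)
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (end[i] <= start[i]) stopf("night_hours(): end must follow start")
    if (as.numeric(end[i]) - as.numeric(start[i]) > 48 * 3600) {
      stopf("night_hours(): tows over 48 h not supported")
    }
    d0 <- local_date(start[i], utc_offset)
    total <- 0
    # nights are [dusk(D), dawn(D+1)]; the tow can touch the night ending at
    # dawn(d0) and the ones starting at dusk(d0), dusk(d0+1), dusk(d0+2)
    tw <- vapply(-1:3, function(k) {
      civil_twilight_sec(d0 + k, lat[i], lon[i], utc_offset)
    }, numeric(2))           # row 1 dawn, row 2 dusk, per date d0-1 .. d0+3
    s0 <- as.numeric(start[i]); e0 <- as.numeric(end[i])
    for (k in 1:4) {
      lo <- max(s0, tw[2, k])       # dusk of date d0 + (k - 2)
      hi <- min(e0, tw[1, k + 1])   # dawn of the following date
      if (hi > lo) total <- total + (hi - lo)
    }
    out[i] <- total / 3600
  }
  out
}

#' Headline depth from gear geometry
#'
#' Depth of the top of the net: ground-line depth minus headline height.
#' Records where the result would be non-positive are invalid gear records.
#'
#' @param groundline_depth,headline_height metres, both `> 0`.
#' @return headline depth in metres.
#' @export
derive_headline_depth <- function(groundline_depth, headline_height) {
  if (any(groundline_depth <= 0 | headline_height <= 0, na.rm = TRUE)) {
    stopf("derive_headline_depth(): gear depths/heights must be positive")
  }
  res <- groundline_depth - headline_height
  if (any(res <= 0, na.rm = TRUE)) {
    stopf("derive_headline_depth(): headline height >= ground-line depth (invalid gear record)")
  }
  res
}

#' Shallow/deep depth factor
#'
#' @param bottom_depth metres, `> 0`.
#' @param threshold metres; water strictly shallower than this is "shallow".
#' @return factor with levels `shallow`, `deep`.
#' @export
classify_depth_factor <- function(bottom_depth, threshold = 210) {
  factor(ifelse(bottom_depth < threshold, "shallow", "deep"),
         levels = c("shallow", "deep"))
}

#' Read a plain-text depth raster
#'
#' ESRI ASCII-grid layout: header lines `ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`, then `nrows` rows of
#' `ncols` values, first row northernmost.
#'
#' @param path file path.
#' @return object of class `depth_grid`.
#' @export
read_depth_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  structure(list(depth = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, ncols = hdr$ncols,
                 nrows = hdr$nrows), class = "depth_grid")
}

grid_cell_depth <- function(grid, lat, lon) {
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row <- grid$nrows - floor((lat - grid$yll) / grid$cellsize)
  inside <- col >= 1 & col <= grid$ncols & row >= 1 & row <= grid$nrows
  out <- rep(NA_real_, length(lat))
  out[inside] <- grid$depth[cbind(row[inside], col[inside])]
  out
}

#' Bottom depth for tows from a depth raster
#'
#' Minimum of the nearest-cell depths at the tow's start and end positions.
#' Positions outside the raster yield `NA` and are flagged.
#'
#' @param tows tow tibble with start/end positions.
#' @param grid a [read_depth_grid()] raster.
#' @return numeric vector of depths (m); attribute `outside` flags tows with
#'   a position off the grid.
#' @export
lookup_bottom_depth <- function(tows, grid) {
  d1 <- grid_cell_depth(grid, tows$start_lat, tows$start_lon)
  d2 <- grid_cell_depth(grid, tows$end_lat %||% tows$start_lat,
                        tows$end_lon %||% tows$start_lon)
  d2[is.na(d2)] <- d1[is.na(d2)]
  out <- pmin(d1, d2, na.rm = FALSE)
  attr(out, "outside") <- is.na(d1) | is.na(d2)
  out
}

#' Specify one model covariate
#'
#' @param name design name of the covariate.
#' @param source column of the derived covariate table it is built from.
#' @param transform one of `"identity"`, `"log"`, `"log_offset"`.
#' @param offset added before the log under `"log_offset"` (1 tonne for
#'   catch weight, 1 hour for night hours).
#' @param levels,reference factor levels and reference for discrete
#'   covariates (treatment coding).
#' @param excludes names of covariates that may not co-occur with this one
#'   in a model (a variable and its log transform are mutually exclusive).
#' @return object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, source = name, transform = "identity",
                           offset = NULL, levels = NULL, reference = NULL,
                           excludes = character()) {
  transform <- match.arg(transform, c("identity", "log", "log_offset"))
  if (!is.null(offset) && transform != "log_offset") {
    stopf("covariate_spec('%s'): offset only applies to transform 'log_offset'", name)
  }
  if (transform == "log_offset" && is.null(offset)) {
    stopf("covariate_spec('%s'): 'log_offset' needs an offset", name)
  }
  structure(list(name = name, source = source, transform = transform,
                 offset = offset, levels = levels, reference = reference,
                 excludes = excludes), class = "covariate_spec")
}

#' The candidate covariates considered for selection
#'
#' Continuous gear/effort measures enter both raw and log-transformed (an
#' offset of one tonne is added to catch weight and one hour to night hours
#' before the log; tow duration takes a plain log). Discrete factors:
#' light condition (reference `dark`), sub-area (reference `north`), depth
#' factor, month, season. A variable and its log transform are mutually
#' exclusive within one model.
#'
#' @return named list of [covariate_spec()] objects.
#' @export
default_covariate_specs <- function() {
  sp <- list(
    covariate_spec("trawl_speed"),
    covariate_spec("duration", source = "duration_h"),
    covariate_spec("log_duration", source = "duration_h", transform = "log",
                   excludes = "duration"),
    covariate_spec("fishing_depth", source = "groundline_depth"),
    covariate_spec("log_fishing_depth", source = "groundline_depth",
                   transform = "log", excludes = "fishing_depth"),
    covariate_spec("headline_height"),
    covariate_spec("headline_depth"),
    covariate_spec("bottom_depth"),
    covariate_spec("log_bottom_depth", source = "bottom_depth",
                   transform = "log", excludes = "bottom_depth"),
    covariate_spec("depth_factor", levels = c("shallow", "deep"),
                   reference = "shallow"),
    covariate_spec("catch_weight"),
    covariate_spec("log_catch_weight", source = "catch_weight",
                   transform = "log_offset", offset = 1,
                   excludes = "catch_weight"),
    covariate_spec("subarea", levels = c("north", "south"),
                   reference = "north"),
    covariate_spec("light", levels = c("dark", "light", "black"),
                   reference = "dark"),
    covariate_spec("moon_fraction"),
    covariate_spec("night_hours", source = "night_h"),
    covariate_spec("log_night_hours", source = "night_h",
                   transform = "log_offset", offset = 1,
                   excludes = "night_hours"),
    covariate_spec("month", levels = month.abb, reference = "Jan"),
    covariate_spec("season", levels = c("JFM", "AMJ", "JAS", "OND"),
                   reference = "JFM")
  )
  names(sp) <- vapply(sp, `[[`, "", "name")
  sp
}

#' Derive the per-tow covariate table
#'
#' Computes every derived covariate the candidate list needs: duration,
#' headline depth, light condition, night hours, moon fraction, sub-area,
#' fishing year, depth factor, month and season. Tows whose gear geometry is
#' invalid (headline height >= ground-line depth) are excluded and counted.
#'
#' @param tows tow tibble.
#' @param area a [study_area()] (for the sub-area split).
#' @param utc_offset local civil clock offset, hours.
#' @return tibble of covariates aligned with the retained tows; attribute
#'   `excluded` reports dropped rows.
#' @export
derive_covariates <- function(tows, area = study_area(), utc_offset = 12) {
  bad_gear <- is.na(tows$groundline_depth) | is.na(tows$headline_height) |
    tows$groundline_depth <= 0 | tows$headline_height <= 0 |
    tows$groundline_depth <= tows$headline_height
  kept <- tows[!bad_gear, , drop = FALSE]
  haul <- kept$end_time   # covariates tied to the haul use the end of the tow
  lat <- kept$end_lat; lat[is.na(lat)] <- kept$start_lat[is.na(lat)]
  lon <- kept$end_lon; lon[is.na(lon)] <- kept$start_lon[is.na(lon)]
  ld <- local_date(haul, utc_offset)
  mo <- as.integer(format(ld, "%m"))
  out <- tibble::tibble(
    tow_id = kept$tow_id,
    vessel_id = kept$vessel_id,
    fishing_year = assign_fishing_year(kept$start_time, utc_offset),
    observed = kept$observed,
    captures = kept$captures,
    duration_h = as.numeric(kept$end_time - kept$start_time, units = "hours"),
    trawl_speed = kept$trawl_speed,
    groundline_depth = kept$groundline_depth,
    headline_height = kept$headline_height,
    headline_depth = derive_headline_depth(kept$groundline_depth,
                                           kept$headline_height),
    bottom_depth = kept$bottom_depth,
    depth_factor = classify_depth_factor(kept$bottom_depth),
    catch_weight = kept$catch_weight,
    subarea = assign_subarea(kept$start_lat, area$subarea_split_lat),
    light = classify_light_condition(haul, lat, lon, utc_offset),
    moon_fraction = moon_illuminated_fraction(haul),
    night_h = night_hours(kept$start_time, kept$end_time, lat, lon, utc_offset),
    month = factor(month.abb[mo], levels = month.abb),
    season = factor(c("JFM", "AMJ", "JAS", "OND")[(mo - 1) %/% 3 + 1],
                    levels = c("JFM", "AMJ", "JAS", "OND"))
  )
  attr(out, "excluded") <- list(n = sum(bad_gear), reason = "invalid_gear",
                                tow_id = tows$tow_id[bad_gear])
  out
}

transform_column <- function(x, spec) {
  switch(spec$transform,
         identity = x,
         log = log(x),
         log_offset = log(x + spec$offset))
}

#' Assemble the model design matrix
#'
#' Builds the covariate matrix for the capture-event model: numeric columns
#' transformed per spec (log offsets applied as `log(value + offset)`),
#' discrete covariates treatment-coded against their stated reference
#' (light against `dark`, sub-area against `north`). Rows with any
#' underivable covariate are excluded and counted.
#'
#' @param cov covariate table from [derive_covariates()].
#' @param specs list of [covariate_spec()]s to include (model order).
#' @return object of class `design_matrix`: list with `X` (matrix, no
#'   intercept column), `y` (event indicator; `NA` on unobserved rows), `n`
#'   (capture counts), `year` (factor), `vessel_id`, `observed`, `tow_id`,
#'   and `dropped` (exclusion report).
#' @export
build_design_matrix <- function(cov, specs) {
  if (inherits(specs, "covariate_spec")) specs <- list(specs)
  cols <- list()
  for (spec in specs) {
    x <- cov[[spec$source]]
    if (is.null(x)) stopf("build_design_matrix(): no source column '%s'", spec$source)
    if (!is.null(spec$levels)) {
      f <- factor(x, levels = c(spec$reference,
                                setdiff(spec$levels, spec$reference)))
      mm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste(spec$name, levels(f)[-1], sep = "_")
      # model.matrix drops NA rows; rebuild with NAs kept
      full <- matrix(NA_real_, nrow(cov), ncol(mm),
                     dimnames = list(NULL, colnames(mm)))
      full[!is.na(f), ] <- mm
      for (cn in colnames(full)) cols[[cn]] <- full[, cn]
    } else {
      cols[[spec$name]] <- transform_column(x, spec)
    }
  }
  X <- do.call(cbind, cols)
  ok <- rowSums(is.na(X)) == 0
  if (!any(ok)) stopf("build_design_matrix(): every row has missing covariates")
  y <- ifelse(cov$observed, as.numeric(!is.na(cov$captures) & cov$captures > 0), NA)
  structure(list(
    X = X[ok, , drop = FALSE],
    y = y[ok],
    n = ifelse(cov$observed, cov$captures, NA_integer_)[ok],
    year = factor(cov$fishing_year[ok]),
    vessel_id = cov$vessel_id[ok],
    observed = cov$observed[ok],
    tow_id = cov$tow_id[ok],
    dropped = list(n = sum(!ok), tow_id = cov$tow_id[!ok])
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " tows x ", ncol(x$X), " columns (",
      sum(x$observed), " observed, ", sum(x$y %in% 1), " capture events)\n",
      sep = "")
  cat("columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}
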