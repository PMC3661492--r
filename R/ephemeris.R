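# Low-precision closed-form ephemeris: geometric solar position to ~0.01 deg
# and lunar phase angle to ~0.5 deg. That is ample for a 6 deg twilight
# crossing and a 17% moon-illumination threshold; no refraction, no delta-T.

DEG <- pi / 180

#' Julian day number of a time instant
#'
#' @param time a `POSIXct` vector (any time zone; the underlying instant is
#'   used).
#' @return numeric Julian day (days since -4712-01-01 12:00 UT).
#' @keywords internal
julian_day <- function(time) {
  as.numeric(time) / 86400 + 2440587.5
}

# Solar right ascension and declination (degrees), plus apparent sidereal
# time, from the standard low-precision almanac series.
sun_equatorial <- function(jd) {
  n <- jd - 2451545.0
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * DEG
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * DEG
  eps <- (23.439 - 4e-7 * n) * DEG
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda)) / DEG
  dec <- asin(sin(eps) * sin(lambda)) / DEG
  gmst <- (280.46061837 + 360.98564736629 * n) %% 360
  list(ra = ra %% 360, dec = dec, gmst = gmst)
}

#' Geometric solar elevation angle
#'
#' Elevation of the centre of the solar disc above the geometric horizon,
#' without atmospheric refraction. Used for the civil-twilight definition
#' (sun centre 6 degrees below the horizon).
#'
#' @param time `POSIXct` vector of instants.
#' @param lat,lon observer position in decimal degrees (south and west
#'   negative). Latitudes beyond +/-66 degrees are refused: the tow
#'   classification logic assumes every date has a dawn and a dusk.
#' @return solar elevation in degrees, vectorised over `time`.
#' @examples
#' # local solar noon at an equinox, latitude -39: elevation ~ 51 degrees
#' solar_elevation(as.POSIXct("2003-03-21 00:20:00", tz = "UTC"), -39, 172)
#' @export
solar_elevation <- function(time, lat, lon) {
  if (any(abs(lat) > 66)) {
    stopf("solar_elevation(): latitudes beyond +/-66 deg are not supported")
  }
  s <- sun_equatorial(julian_day(time))
  H <- (s$gmst + lon - s$ra) * DEG
  phi <- lat * DEG
  dec <- s$dec * DEG
  asin(pmin(1, pmax(-1, sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H)))) / DEG
}

# Instant of local solar transit (upper culmination) nearest local noon of
# `date` (a Date, interpreted as the local civil date at utc_offset hours).
local_noon_utc <- function(date, utc_offset) {
  as.POSIXct(as.numeric(as.POSIXct(paste(date, "12:00:00"), tz = "UTC")) -
               utc_offset * 3600, origin = "1970-01-01", tz = "UTC")
}

# elevation from unix seconds, pure arithmetic (no POSIXct churn): the hot
# path of the twilight root-finder
solar_elevation_sec <- function(tsec, lat, lon) {
  s <- sun_equatorial(tsec / 86400 + 2440587.5)
  H <- (s$gmst + lon - s$ra) * DEG
  phi <- lat * DEG
  dec <- s$dec * DEG
  asin(pmin(1, pmax(-1, sin(phi) * sin(dec) +
                      cos(phi) * cos(dec) * cos(H)))) / DEG
}

# numeric-time twilight solver; returns unix seconds c(dawn, dusk).
# Hour-angle fixed point: at the crossing, cos H0 = (sin(-6 deg) -
# sin phi sin dec) / (cos phi cos dec); iterate because dec and the
# equation of time drift slowly. Converges below 1 s in a few rounds.
civil_twilight_sec <- function(date, lat, lon, utc_offset) {
  t0 <- as.numeric(local_noon_utc(date, utc_offset))
  if (solar_elevation_sec(t0, lat, lon) <= -6) {
    stopf("civil_twilight_times(): sun below -6 deg at local noon (%s)", date)
  }
  phi <- lat * DEG
  target <- sin(-6 * DEG)
  solve_side <- function(sign) {
    t <- t0 + sign * 6 * 3600
    for (it in 1:12) {
      s <- sun_equatorial(t / 86400 + 2440587.5)
      dec <- s$dec * DEG
      cosH0 <- (target - sin(phi) * sin(dec)) / (cos(phi) * cos(dec))
      if (abs(cosH0) > 1) {
        stopf("civil_twilight_times(): no -6 deg crossing on %s at lat %.2f",
              date, lat)
      }
      H_now <- (s$gmst + lon - s$ra) %% 360
      if (H_now > 180) H_now <- H_now - 360
      dt <- (sign * acos(cosH0) / DEG - H_now) / 360.98564736629 * 86400
      t <- t + dt
      if (abs(dt) < 0.5) break
    }
    t
  }
  c(solve_side(-1), solve_side(1))
}

#' Civil dawn and dusk for a local date
#'
#' Finds the two instants on the given local civil date when the solar
#' elevation crosses -6 degrees: rising (civil dawn) and setting (civil
#' dusk). Roots are bracketed around local noon and solved to 1 s.
#'
#' @param date a `Date`, the local civil date (at `utc_offset`).
#' @param lat,lon observer position, decimal degrees.
#' @param utc_offset local civil offset from UTC in hours (default +12, New
#'   Zealand standard time).
#' @return a list with `POSIXct` elements `dawn` and `dusk` (UTC instants);
#'   `dawn < dusk`.
#' @export
civil_twilight_times <- function(date, lat, lon, utc_offset = 12) {
  tw <- civil_twilight_sec(date, lat, lon, utc_offset)
  list(dawn = as.POSIXct(tw[1], origin = "1970-01-01", tz = "UTC"),
       dusk = as.POSIXct(tw[2], origin = "1970-01-01", tz = "UTC"))
}

#' Illuminated fraction of the lunar disc
#'
#' Phase-angle approximation from the low-precision lunar series: the
#' elongation-corrected phase angle `i` gives the fraction `(1 + cos i)/2`.
#' Accuracy is ~0.005 in the fraction, far inside the 0.17 moonlit
#' threshold used for light classification.
#'
#' @param time `POSIXct` vector of instants (1900--2100).
#' @return illuminated fraction in `[0, 1]`, vectorised.
#' @export
moon_illuminated_fraction <- function(time) {
  jd <- julian_day(time)
  if (any(jd < 2415020 | jd > 2488070)) {
    stopf("moon_illuminated_fraction(): dates outside 1900-2100 not supported")
  }
  T <- (jd - 2451545.0) / 36525
  D <- (297.8501921 + 445267.1114034 * T - 0.0018819 * T^2) %% 360
  M <- (357.5291092 + 35999.0502909 * T) %% 360
  Mp <- (134.9633964 + 477198.8675055 * T + 0.0087414 * T^2) %% 360
  i <- 180 - D - 6.289 * sin(Mp * DEG) + 2.100 * sin(M * DEG) -
    1.274 * sin((2 * D - Mp) * DEG) - 0.658 * sin(2 * D * DEG) -
    0.214 * sin(2 * Mp * DEG) - 0.110 * sin(D * DEG)
  (1 + cos(i * DEG)) / 2
}

# Local civil clock time of a UTC instant, as a POSIXct whose UTC-rendered
# clock face reads local time. Only used for clock arithmetic (dates, hours).
local_clock <- function(time, utc_offset) {
  as.POSIXct(as.numeric(time) + utc_offset * 3600, origin = "1970-01-01",
             tz = "UTC")
}

local_date <- function(time, utc_offset) {
  as.Date(local_clock(time, utc_offset))
}
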