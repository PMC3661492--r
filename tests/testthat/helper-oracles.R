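# Independent reference implementations used as oracles. The solar oracle
# follows the NOAA solar-calculator formulation (geometric mean longitude,
# equation of center, apparent longitude with nutation term, equation of
# time) — structurally different from the package's almanac series.

noaa_solar_elevation <- function(time, lat, lon) {
  jd <- as.numeric(time) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525
  deg <- pi / 180
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- 357.52911 + 35999.05029 * T - 0.0001537 * T^2
  e <- 0.016708634 - 0.000042037 * T - 0.0000001267 * T^2
  C <- sin(M * deg) * (1.914602 - 0.004817 * T - 0.000014 * T^2) +
    sin(2 * M * deg) * (0.019993 - 0.000101 * T) +
    sin(3 * M * deg) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * deg)
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * deg)
  decl <- asin(sin(eps * deg) * sin(app_long * deg)) / deg
  y <- tan(eps / 2 * deg)^2
  eqtime <- 4 / deg * (y * sin(2 * L0 * deg) - 2 * e * sin(M * deg) +
                         4 * e * y * sin(M * deg) * cos(2 * L0 * deg) -
                         0.5 * y^2 * sin(4 * L0 * deg) -
                         1.25 * e^2 * sin(2 * M * deg))
  lt <- as.POSIXlt(time, tz = "UTC")
  clock_min <- lt$hour * 60 + lt$min + lt$sec / 60
  tst <- (clock_min + eqtime + 4 * lon) %% 1440
  ha <- ifelse(tst / 4 < 0, tst / 4 + 180, tst / 4 - 180)
  phi <- lat * deg
  asin(sin(phi) * sin(decl * deg) +
         cos(phi) * cos(decl * deg) * cos(ha * deg)) / deg
}

# reference civil twilight by bisection on the NOAA elevation
noaa_civil_twilight <- function(date, lat, lon, utc_offset = 12) {
  noon <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC") - utc_offset * 3600
  f <- function(t) {
    noaa_solar_elevation(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
                         lat, lon) + 6
  }
  t0 <- as.numeric(noon)
  c(dawn = uniroot(f, c(t0 - 12 * 3600, t0), tol = 0.5)$root,
    dusk = uniroot(f, c(t0, t0 + 12 * 3600), tol = 0.5)$root)
}

# Catalogued eclipse instants (UTC): exact syzygies, so the illuminated
# fraction is 0 (solar eclipse = new moon) or 1 (lunar eclipse = full moon).
eclipse_new_moons <- function() {
  as.POSIXct(c("1999-08-11 11:03:00", "2006-03-29 10:11:00",
               "2012-11-13 22:12:00", "2017-08-21 18:26:00"), tz = "UTC")
}

eclipse_full_moons <- function() {
  as.POSIXct(c("2000-01-21 04:44:00", "2008-02-21 03:26:00",
               "2011-06-15 20:13:00", "2015-09-28 02:47:00"), tz = "UTC")
}

# fixed 20-instant ephemeris test vector: 12 twilight/elevation cases inside
# the study region across the study period, plus the 8 lunar anchors
ephemeris_test_dates <- function() {
  as.Date(c("1995-12-21", "1996-06-21", "1998-03-20", "2000-09-22",
            "2002-01-15", "2003-11-02", "2005-05-10", "2007-02-28",
            "2008-07-04", "2009-10-17", "2010-08-23", "2011-04-05"))
}
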