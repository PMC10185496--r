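## Solar and lunar ephemeris: positions, phases, rise/set events.
##
## Truncated trigonometric series of standard almanac theory.  Accuracy
## contract of this backend: geocentric positions <= 0.05 deg (sun) and
## <= 0.05 deg (moon, after the truncation used here), phase angle
## <= 0.5 deg, rise/set event times <= 2 min.  All times are POSIXct UTC;
## nights are grouped by the local solar date (longitude/15 hour offset).

DEG <- pi / 180

#' @keywords internal
.sind <- function(x) sin(x * DEG)
.cosd <- function(x) cos(x * DEG)

#' Julian day from a UTC timestamp
#'
#' @param time POSIXct (UTC assumed).
#' @return Julian day number (UT scale).
#' @keywords internal
jd_utc <- function(time) {
  as.numeric(time) / 86400 + 2440587.5
}

## Terrestrial-time offset (delta-T), seconds; adequate as a constant over
## the 2000--2030 span the package targets.
.DELTA_T <- 70

.jde <- function(time) jd_utc(time) + .DELTA_T / 86400

.wrap360 <- function(x) x %% 360
.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y
}

## Geocentric solar position (low-accuracy series, ~0.01 deg).
## Returns apparent ecliptic longitude (deg), distance (AU), RA/Dec (deg).
.sun_position <- function(jde) {
  T <- (jde - 2451545) / 36525
  L0 <- .wrap360(280.46646 + 36000.76983 * T + 0.0003032 * T^2)
  M <- .wrap360(357.52911 + 35999.05029 * T - 0.0001537 * T^2)
  e <- 0.016708634 - 0.000042037 * T
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * .sind(M) +
    (0.019993 - 0.000101 * T) * .sind(2 * M) +
    0.000289 * .sind(3 * M)
  true_lon <- L0 + C
  nu <- M + C
  R <- 1.000001018 * (1 - e^2) / (1 + e * .cosd(nu))
  Omega <- 125.04 - 1934.136 * T
  lambda <- true_lon - 0.00569 - 0.00478 * .sind(Omega)
  eps0 <- 23.43929111 - 0.0130041667 * T - 1.638889e-7 * T^2
  eps <- eps0 + 0.00256 * .cosd(Omega)
  alpha <- atan2(.cosd(eps) * .sind(lambda), .cosd(lambda)) / DEG
  delta <- asin(pmin(1, pmax(-1, .sind(eps) * .sind(lambda)))) / DEG
  list(lon = .wrap360(lambda), dist_au = R,
       ra = .wrap360(alpha), dec = delta, obliquity = eps)
}

## Principal periodic terms of the lunar theory.
## Columns: multiples of D (mean elongation), M (solar anomaly),
## Mp (lunar anomaly), F (argument of latitude); l in 1e-6 deg
## (longitude), r in 1e-3 km (distance).
.MOON_LR <- matrix(c(
  0, 0, 1, 0, 6288774, -20905355,
  2, 0, -1, 0, 1274027, -3699111,
  2, 0, 0, 0, 658314, -2955968,
  0, 0, 2, 0, 213618, -569925,
  0, 1, 0, 0, -185116, 48888,
  0, 0, 0, 2, -114332, -3149,
  2, 0, -2, 0, 58793, 246158,
  2, -1, -1, 0, 57066, -152138,
  2, 0, 1, 0, 53322, -170733,
  2, -1, 0, 0, 45758, -204586,
  0, 1, -1, 0, -40923, -129620,
  1, 0, 0, 0, -34720, 108743,
  0, 1, 1, 0, -30383, 104755,
  2, 0, 0, -2, 15327, 10321,
  0, 0, 1, 2, -12528, 0,
  0, 0, 1, -2, 10980, 79661,
  4, 0, -1, 0, 10675, -34782,
  0, 0, 3, 0, 10034, -23210,
  4, 0, -2, 0, 8548, -21636,
  2, 1, -1, 0, -7888, 24208,
  2, 1, 0, 0, -6766, 30824,
  1, 0, -1, 0, -5163, -8379,
  1, 1, 0, 0, 4987, -16675,
  2, -1, 1, 0, 4036, -12831,
  2, 0, 2, 0, 3994, -10445,
  4, 0, 0, 0, 3861, -11650,
  2, 0, -3, 0, 3665, 14403,
  0, 1, -2, 0, -2689, -7003,
  2, 0, -1, 2, -2602, 0,
  2, -1, -2, 0, 2390, 10056,
  1, 0, 1, 0, -2348, 6322,
  2, -2, 0, 0, 2236, -9884,
  0, 1, 2, 0, -2120, 5751,
  0, 2, 0, 0, -2069, 0,
  2, -2, -1, 0, 2048, -4950,
  2, 0, 1, -2, -1773, 4130,
  2, 0, 0, 2, -1595, 0,
  4, -1, -1, 0, 1215, -3958,
  0, 0, 2, 2, -1110, 0,
  3, 0, -1, 0, -892, 3258,
  2, 1, 1, 0, -810, 2616,
  4, -1, -2, 0, 759, -1897,
  0, 2, -1, 0, -713, -2117,
  2, 2, -1, 0, -700, 2354,
  2, 1, -2, 0, 691, 0,
  2, -1, 0, -2, 596, 0,
  4, 0, 1, 0, 549, -1423,
  0, 0, 4, 0, 537, -1117
), ncol = 6, byrow = TRUE)

## Latitude terms, b in 1e-6 deg.
.MOON_B <- matrix(c(
  0, 0, 0, 1, 5128122,
  0, 0, 1, 1, 280602,
  0, 0, 1, -1, 277693,
  2, 0, 0, -1, 173237,
  2, 0, -1, 1, 55413,
  2, 0, -1, -1, 46271,
  2, 0, 0, 1, 32573,
  0, 0, 2, 1, 17198,
  2, 0, 1, -1, 9266,
  0, 0, 2, -1, 8822,
  2, -1, 0, -1, 8216,
  2, 0, -2, -1, 4324,
  2, 0, 1, 1, 4200,
  2, 1, 0, -1, -3359,
  2, -1, -1, 1, 2463,
  2, -1, 0, 1, 2211,
  2, -1, -1, -1, 2065,
  0, 1, -1, -1, -1870,
  4, 0, -1, -1, 1828,
  0, 1, 0, 1, -1794,
  0, 0, 0, 3, -1749,
  0, 1, -1, 1, -1565,
  1, 0, 0, 1, -1491,
  0, 1, 1, 1, -1475,
  0, 1, 1, -1, -1410,
  0, 1, 0, -1, -1344,
  1, 0, 0, -1, -1335,
  0, 0, 3, 1, 1107,
  4, 0, 0, -1, 1021,
  4, 0, -1, 1, 833
), ncol = 5, byrow = TRUE)

## Geocentric lunar position.  Returns ecliptic longitude/latitude (deg),
## distance (km), equatorial horizontal parallax (deg), RA/Dec (deg).
.moon_position <- function(jde) {
  T <- (jde - 2451545) / 36525
  Lp <- .wrap360(218.3164477 + 481267.88123421 * T - 0.0015786 * T^2 +
                   T^3 / 538841 - T^4 / 65194000)
  D <- .wrap360(297.8501921 + 445267.1114034 * T - 0.0018819 * T^2 +
                  T^3 / 545868 - T^4 / 113065000)
  M <- .wrap360(357.5291092 + 35999.0502909 * T - 0.0001536 * T^2 +
                  T^3 / 24490000)
  Mp <- .wrap360(134.9633964 + 477198.8675055 * T + 0.0087414 * T^2 +
                   T^3 / 69699 - T^4 / 14712000)
  F <- .wrap360(93.2720950 + 483202.0175233 * T - 0.0036539 * T^2 -
                  T^3 / 3526000 + T^4 / 863310000)
  A1 <- .wrap360(119.75 + 131.849 * T)
  A2 <- .wrap360(53.09 + 479264.290 * T)
  A3 <- .wrap360(313.45 + 481266.484 * T)
  E <- 1 - 0.002516 * T - 0.0000074 * T^2

  tab <- .MOON_LR
  arg <- tab[, 1] * D + tab[, 2] * M + tab[, 3] * Mp + tab[, 4] * F
  efac <- E^abs(tab[, 2])
  sum_l <- sum(tab[, 5] * efac * .sind(arg))
  sum_r <- sum(tab[, 6] * efac * .cosd(arg))
  sum_l <- sum_l + 3958 * .sind(A1) + 1962 * .sind(Lp - F) + 318 * .sind(A2)

  tb <- .MOON_B
  argb <- tb[, 1] * D + tb[, 2] * M + tb[, 3] * Mp + tb[, 4] * F
  efacb <- E^abs(tb[, 2])
  sum_b <- sum(tb[, 5] * efacb * .sind(argb))
  sum_b <- sum_b - 2235 * .sind(Lp) + 382 * .sind(A3) +
    175 * .sind(A1 - F) + 175 * .sind(A1 + F) +
    127 * .sind(Lp - Mp) - 115 * .sind(Lp + Mp)

  lambda <- .wrap360(Lp + sum_l / 1e6)
  beta <- sum_b / 1e6
  dist <- 385000.56 + sum_r / 1000
  parallax <- asin(6378.14 / dist) / DEG

  T2 <- T
  eps <- 23.43929111 - 0.0130041667 * T2 - 1.638889e-7 * T2^2
  alpha <- atan2(.sind(lambda) * .cosd(eps) - tan(beta * DEG) * .sind(eps),
                 .cosd(lambda)) / DEG
  delta <- asin(pmin(1, pmax(-1, .sind(beta) * .cosd(eps) +
                               .cosd(beta) * .sind(eps) * .sind(lambda)))) / DEG
  list(lon = lambda, lat = beta, dist_km = dist, parallax = parallax,
       ra = .wrap360(alpha), dec = delta)
}

## Greenwich mean sidereal time, degrees.
.gmst <- function(jd) {
  T <- (jd - 2451545) / 36525
  .wrap360(280.46061837 + 360.98564736629 * (jd - 2451545) +
             0.000387933 * T^2 - T^3 / 38710000)
}

## Geocentric altitude (deg) of a body with equatorial coordinates ra/dec
## at a site; refraction not applied.
.altitude <- function(jd, ra, dec, latitude, longitude) {
  H <- .wrap360(.gmst(jd) + longitude - ra)
  asin(pmin(1, pmax(-1, .sind(latitude) * .sind(dec) +
                      .cosd(latitude) * .cosd(dec) * .cosd(H)))) / DEG
}

.sun_altitude <- function(time, latitude, longitude) {
  jd <- jd_utc(time)
  s <- .sun_position(.jde(time))
  .altitude(jd, s$ra, s$dec, latitude, longitude)
}

## Topocentric (parallax-corrected) lunar altitude, deg.
.moon_altitude <- function(time, latitude, longitude, topocentric = TRUE) {
  jd <- jd_utc(time)
  m <- .moon_position(.jde(time))
  alt <- .altitude(jd, m$ra, m$dec, latitude, longitude)
  if (topocentric) alt <- alt - m$parallax * .cosd(alt)
  alt
}

#' Solar and lunar sky geometry at an instant
#'
#' Solar and lunar zenith angles, the lunar phase angle (0 deg = full moon)
#' and the illuminated fraction of the lunar disc, for a site and a UTC
#' instant.
#'
#' @param latitude Site latitude, degrees (-90..90).
#' @param longitude Site longitude, degrees (-180..180), east positive.
#' @param time POSIXct instant; interpreted as UTC.
#' @return A list of class \code{sky_geometry} with elements
#'   \code{solar_zenith}, \code{solar_altitude}, \code{lunar_zenith},
#'   \code{lunar_altitude} (degrees; lunar values parallax-corrected),
#'   \code{lunar_phase_angle} (degrees, 0 at full moon) and
#'   \code{illuminated_fraction} (0..1).
#' @examples
#' sky_geometry(29.5, 34.9, as.POSIXct("2020-09-02 05:22", tz = "UTC"))
#' @export
sky_geometry <- function(latitude, longitude, time) {
  stopifnot(is.finite(latitude), latitude >= -90, latitude <= 90,
            is.finite(longitude), longitude >= -180, longitude <= 180)
  time <- as.POSIXct(time, tz = "UTC")
  jd <- jd_utc(time)
  jde <- .jde(time)
  s <- .sun_position(jde)
  m <- .moon_position(jde)
  salt <- .altitude(jd, s$ra, s$dec, latitude, longitude)
  malt_geo <- .altitude(jd, m$ra, m$dec, latitude, longitude)
  malt <- malt_geo - m$parallax * .cosd(malt_geo)

  ## geocentric elongation and phase angle
  cospsi <- .cosd(m$lat) * .cosd(m$lon - s$lon)
  psi <- acos(pmin(1, pmax(-1, cospsi))) / DEG
  R_km <- s$dist_au * 1.495978707e8
  ## sun-moon-earth angle; 0 at full moon (opposition), 180 at new moon
  phase <- atan2(R_km * .sind(psi), m$dist_km - R_km * cospsi) / DEG
  frac <- (1 + .cosd(phase)) / 2

  structure(list(
    solar_zenith = 90 - salt, solar_altitude = salt,
    lunar_zenith = 90 - malt, lunar_altitude = malt,
    lunar_phase_angle = phase, illuminated_fraction = frac,
    time = time, latitude = latitude, longitude = longitude
  ), class = "sky_geometry")
}

#' @export
print.sky_geometry <- function(x, ...) {
  cat(sprintf("Sky geometry at %s (%.3f, %.3f)\n",
              format(x$time, "%Y-%m-%d %H:%M:%S UTC"), x$latitude, x$longitude))
  cat(sprintf("  sun  altitude %7.2f deg (zenith %7.2f)\n",
              x$solar_altitude, x$solar_zenith))
  cat(sprintf("  moon altitude %7.2f deg, phase angle %6.2f deg, lit %.3f\n",
              x$lunar_altitude, x$lunar_phase_angle, x$illuminated_fraction))
  invisible(x)
}

## Find all crossings of f(t) = target within [t0, t1], refined by uniroot.
## f must be vectorised over POSIXct.  direction: "up", "down" or "both".
.crossings <- function(f, t0, t1, target, direction = "both",
                       step_s = 360) {
  tt <- seq(as.numeric(t0), as.numeric(t1), by = step_s)
  if (tt[length(tt)] < as.numeric(t1)) tt <- c(tt, as.numeric(t1))
  vals <- vapply(tt, function(s)
    f(as.POSIXct(s, origin = "1970-01-01", tz = "UTC")), numeric(1)) - target
  out <- numeric(0)
  for (i in seq_len(length(tt) - 1)) {
    a <- vals[i]; b <- vals[i + 1]
    if (is.na(a) || is.na(b) || a == 0 || a * b > 0) next
    dir <- if (b > a) "up" else "down"
    if (direction != "both" && dir != direction) next
    r <- stats::uniroot(function(s)
      f(as.POSIXct(s, origin = "1970-01-01", tz = "UTC")) - target,
      lower = tt[i], upper = tt[i + 1], tol = 1)$root
    out <- c(out, r)
  }
  as.POSIXct(out, origin = "1970-01-01", tz = "UTC")
}

## Standard rise/set altitude for the sun (refraction + semi-diameter).
.SUN_H0 <- -0.833

## Rise/set altitude for the moon given its parallax (deg):
## refraction -0.583 deg plus mean semidiameter/parallax convention,
## applied to the geocentric altitude.
.moon_h0 <- function(parallax) 0.7275 * parallax - 0.583

#' Night events for a site and local civil date
#'
#' Sunset, twilight dusk/dawn thresholds, sunrise, and the first
#' moonrise/moonset for the night that begins on the given local solar
#' date.  The "night" spans local solar noon to the next local solar noon,
#' where local solar time is UTC + longitude/15 hours.
#'
#' @inheritParams sky_geometry
#' @param date Local civil date (class \code{Date}) of the evening on which
#'   the night begins.
#' @return List of class \code{night_events}: POSIXct fields \code{sunset},
#'   \code{civil_dusk}, \code{nautical_dusk}, \code{astronomical_dusk},
#'   \code{astronomical_dawn}, \code{nautical_dawn}, \code{civil_dawn},
#'   \code{sunrise}, \code{moonrise}, \code{moonset} (the last two NA when
#'   the event does not occur that night), logical \code{moon_up_at_sunset},
#'   and \code{date}.  Polar day/night yield NA events, never silent zeros.
#' @examples
#' night_events(29.5, 34.9, as.Date("2020-09-02"))
#' @export
night_events <- function(latitude, longitude, date) {
  stopifnot(inherits(date, "Date"))
  ## local solar noon (UTC) on `date`
  noon <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC") - longitude / 15 * 3600
  next_noon <- noon + 86400
  fsun <- function(t) .sun_altitude(t, latitude, longitude)

  dn <- function(th) {
    x <- .crossings(fsun, noon, next_noon, th, "down")
    if (length(x)) x[1] else as.POSIXct(NA)
  }
  up <- function(th, after) {
    lo <- if (is.na(after)) noon else after
    x <- .crossings(fsun, lo, next_noon, th, "up")
    if (length(x)) x[1] else as.POSIXct(NA)
  }
  sunset <- dn(.SUN_H0)
  civil_dusk <- dn(-6)
  nautical_dusk <- dn(-12)
  astronomical_dusk <- dn(-18)
  astronomical_dawn <- up(-18, astronomical_dusk)
  nautical_dawn <- up(-12, nautical_dusk)
  civil_dawn <- up(-6, civil_dusk)
  sunrise <- up(.SUN_H0, sunset)

  ## moon events searched over the whole local night (sunset..sunrise when
  ## defined, otherwise the full noon-to-noon span)
  lo <- if (!is.na(sunset)) sunset else noon
  hi <- if (!is.na(sunrise)) sunrise else next_noon
  fmoon <- function(t) {
    m <- .moon_position(.jde(t))
    .altitude(jd_utc(t), m$ra, m$dec, latitude, longitude) - .moon_h0(m$parallax)
  }
  mr <- .crossings(fmoon, lo, hi, 0, "up")
  ms <- .crossings(fmoon, lo, hi, 0, "down")
  moon_up <- fmoon(lo) > 0

  structure(list(
    date = date, latitude = latitude, longitude = longitude,
    sunset = sunset, civil_dusk = civil_dusk, nautical_dusk = nautical_dusk,
    astronomical_dusk = astronomical_dusk,
    astronomical_dawn = astronomical_dawn, nautical_dawn = nautical_dawn,
    civil_dawn = civil_dawn, sunrise = sunrise,
    moonrise = if (length(mr)) mr[1] else as.POSIXct(NA),
    moonset = if (length(ms)) ms[1] else as.POSIXct(NA),
    moon_up_at_sunset = isTRUE(moon_up)
  ), class = "night_events")
}

#' @export
print.night_events <- function(x, ...) {
  cat(sprintf("Night of %s at (%.3f, %.3f)\n", x$date, x$latitude, x$longitude))
  fields <- c("sunset", "civil_dusk", "nautical_dusk", "astronomical_dusk",
              "moonrise", "moonset", "astronomical_dawn", "nautical_dawn",
              "civil_dawn", "sunrise")
  for (f in fields) {
    v <- x[[f]]
    cat(sprintf("  %-18s %s\n", f,
                if (is.na(v)) "--" else format(v, "%Y-%m-%d %H:%M:%S UTC")))
  }
  if (x$moon_up_at_sunset) cat("  (moon already above horizon at sunset)\n")
  invisible(x)
}

#' Instants of full moon within a year
#'
#' @param year Calendar year (supported span roughly 1950--2050).
#' @return POSIXct vector (UTC) of the 12--13 full-moon instants.
#' @examples
#' full_moon_instants(2020)
#' @export
full_moon_instants <- function(year) {
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year + 1), tz = "UTC")
  elong <- function(t) {
    jde <- .jde(t)
    s <- .sun_position(jde); m <- .moon_position(jde)
    .wrap180(m$lon - s$lon - 180)
  }
  ## elongation-minus-180 sweeps upward through 0 once per synodic month
  tt <- seq(as.numeric(t0) - 2 * 86400, as.numeric(t1) + 2 * 86400, by = 6 * 3600)
  vals <- vapply(tt, function(s)
    elong(as.POSIXct(s, origin = "1970-01-01", tz = "UTC")), numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(tt) - 1)) {
    a <- vals[i]; b <- vals[i + 1]
    if (a < 0 && b >= 0 && (b - a) < 90) {
      r <- stats::uniroot(function(s)
        elong(as.POSIXct(s, origin = "1970-01-01", tz = "UTC")),
        lower = tt[i], upper = tt[i + 1], tol = 1)$root
      roots <- c(roots, r)
    }
  }
  out <- as.POSIXct(roots, origin = "1970-01-01", tz = "UTC")
  out[format(out, "%Y") == as.character(year)]
}

#' Local solar date of an instant
#'
#' The civil date at local solar time (UTC + longitude/15 hours); used to
#' assign nights and full moons to dates.
#' @inheritParams sky_geometry
#' @return Date.
#' @export
local_solar_date <- function(time, longitude) {
  as.Date(as.POSIXct(time, tz = "UTC") + longitude / 15 * 3600, tz = "UTC")
}

#' Days of spawning relative to the nearest full moon
#'
#' Signed whole-day offset of a local night from the nearest full-moon
#' night (negative before full moon).  Ties at exactly half a synodic
#' month are broken toward the earlier full moon.
#'
#' @param date Local civil date(s) of the night (Date).
#' @param longitude Site longitude, degrees east.
#' @param full_moons Optional POSIXct vector of full-moon instants covering
#'   the dates (computed from \code{\link{full_moon_instants}} when omitted).
#' @return Integer vector of signed day offsets.
#' @export
days_from_full_moon <- function(date, longitude, full_moons = NULL) {
  stopifnot(inherits(date, "Date"))
  if (is.null(full_moons)) {
    yrs <- sort(unique(as.integer(format(date, "%Y"))))
    yrs <- seq(min(yrs) - 1, max(yrs) + 1)
    full_moons <- do.call(c, lapply(yrs, full_moon_instants))
  }
  fm_dates <- local_solar_date(full_moons, longitude)
  vapply(as.numeric(date), function(d) {
    diffs <- d - as.numeric(fm_dates)
    i <- which.min(abs(diffs) - 1e-9 * sign(diffs))  # tie -> earlier full moon
    as.integer(diffs[i])
  }, integer(1))
}
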