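## Five-minute sea-surface light timelines, detection of the extended
## period of minimum light intensity between sunset and moonrise, and the
## ALAN-induced advance of the first post-full-moon trigger night.

.EVENT_THRESHOLDS <- c(sunset = -0.833, sunrise = -0.833,
                       civil_dusk = -6, civil_dawn = -6,
                       nautical_dusk = -12, nautical_dawn = -12,
                       astronomical_dusk = -18, astronomical_dawn = -18)

## Broadband (uW m^-2) of each natural component at one instant.
.components_at <- function(time, latitude, longitude, atm, grid) {
  jd <- jd_utc(time); jde <- .jde(time)
  s <- .sun_position(jde)
  m <- .moon_position(jde)
  salt <- .altitude(jd, s$ra, s$dec, latitude, longitude)
  malt_geo <- .altitude(jd, m$ra, m$dec, latitude, longitude)
  malt <- malt_geo - m$parallax * .cosd(malt_geo)
  doy <- as.integer(format(as.POSIXct(time, tz = "UTC"), "%j"))

  solar <- 0; twilight <- 0; lunar <- 0
  if (salt > 0) {
    cs <- clear_sky_surface(toa_solar(doy, grid = grid), 90 - salt, atm)
    solar <- (broadband(cs$direct) + broadband(cs$diffuse)) * 1e6
  } else {
    twilight <- broadband(twilight_irradiance(salt, atm, grid)) * 1e6
  }
  if (malt > 0) {
    cospsi <- .cosd(m$lat) * .cosd(m$lon - s$lon)
    psi <- acos(pmin(1, pmax(-1, cospsi))) / DEG
    R_km <- s$dist_au * 1.495978707e8
    g <- atan2(R_km * .sind(psi), m$dist_km - R_km * cospsi) / DEG
    tl <- toa_lunar(doy, g, grid = grid)
    lunar <- broadband(surface_lunar(tl, 90 - malt, atm)) * 1e6
  }
  c(solar = solar, twilight = twilight, lunar = lunar, sun_alt = salt,
    moon_alt = malt)
}

#' Build a 5-minute sea-surface light timeline
#'
#' Composes the broadband (400--700 nm) irradiance time series at the sea
#' surface for one site from the spectral components: clear-sky solar,
#' twilight, lunar, optional artificial light, and the constant dark-sky
#' floor.  The total is the sum of all components, so it never falls
#' below the floor.
#'
#' @inheritParams sky_geometry
#' @param start,end Local civil dates (Date); the timeline spans local
#'   noon of \code{start} to local noon of the day after \code{end}.
#' @param alan \code{\link{alan_config}} or NULL for a natural sky.  The
#'   artificial component is on while the sun is below the altitude of the
#'   configured on/off events (default: the civil -6 deg crossings).
#' @param atm \code{\link{atmosphere_params}}.
#' @param step_min Time step in minutes (default 5).
#' @param grid Wavelength grid, nm.
#' @return Data frame of class \code{light_timeline} with columns
#'   \code{time} (POSIXct UTC), \code{solar}, \code{twilight},
#'   \code{lunar}, \code{alan}, \code{floor}, \code{total} (uW m^-2),
#'   \code{sun_alt}, \code{moon_alt} (deg) and \code{night} (local civil
#'   date the step belongs to, nights running noon-to-noon).
#' @export
build_timeline <- function(latitude, longitude, start, end, alan = NULL,
                           atm = atmosphere_params(), step_min = 5,
                           grid = spectral_grid()) {
  stopifnot(inherits(start, "Date"), inherits(end, "Date"), end >= start)
  noon0 <- as.POSIXct(paste(start, "12:00:00"), tz = "UTC") -
    longitude / 15 * 3600
  noon1 <- as.POSIXct(paste(end + 1, "12:00:00"), tz = "UTC") -
    longitude / 15 * 3600
  times <- seq(noon0, noon1, by = step_min * 60)

  comp <- vapply(as.numeric(times), function(s) {
    .components_at(as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
                   latitude, longitude, atm, grid)
  }, numeric(5))
  comp <- t(comp)

  floor_uw <- broadband(dark_sky_floor(grid)) * 1e6
  alan_uw <- rep(0, length(times))
  if (!is.null(alan)) {
    stopifnot(inherits(alan, "alan_config"))
    on_th <- .EVENT_THRESHOLDS[[alan$on_event]]
    alan_bb <- broadband(alan_spectrum(alan, grid)) * 1e6
    alan_uw[comp[, "sun_alt"] < on_th] <- alan_bb
  }
  ## night label: local civil date of the preceding local noon
  night <- as.Date(as.POSIXct(times, tz = "UTC") + longitude / 15 * 3600 -
                     12 * 3600, tz = "UTC")
  out <- data.frame(
    time = times,
    solar = comp[, "solar"], twilight = comp[, "twilight"],
    lunar = comp[, "lunar"], alan = alan_uw, floor = floor_uw,
    sun_alt = comp[, "sun_alt"], moon_alt = comp[, "moon_alt"],
    night = night
  )
  out$total <- out$solar + out$twilight + out$lunar + out$alan + out$floor
  attr(out, "site") <- c(latitude = latitude, longitude = longitude)
  attr(out, "step_min") <- step_min
  attr(out, "alan") <- alan
  class(out) <- c("light_timeline", "data.frame")
  out
}

#' Add an artificial-light component to a natural timeline
#'
#' Returns a timeline identical to \code{tl} except for the ALAN
#' component; useful for paired natural/lit comparisons.
#' @param tl \code{light_timeline} built with \code{alan = NULL}.
#' @param alan \code{\link{alan_config}}.
#' @param grid Wavelength grid used to integrate the ALAN spectrum.
#' @return \code{light_timeline}.
#' @export
add_alan <- function(tl, alan, grid = spectral_grid()) {
  stopifnot(inherits(tl, "light_timeline"), inherits(alan, "alan_config"))
  on_th <- .EVENT_THRESHOLDS[[alan$on_event]]
  alan_bb <- broadband(alan_spectrum(alan, grid)) * 1e6
  tl$alan <- ifelse(tl$sun_alt < on_th, alan_bb, 0)
  tl$total <- tl$solar + tl$twilight + tl$lunar + tl$alan + tl$floor
  attr(tl, "alan") <- alan
  tl
}

#' @export
print.light_timeline <- function(x, ...) {
  site <- attr(x, "site")
  cat(sprintf("<light_timeline> %d steps of %d min at (%.3f, %.3f), %s .. %s\n",
              nrow(x), attr(x, "step_min"), site["latitude"],
              site["longitude"], format(min(x$time), "%Y-%m-%d"),
              format(max(x$time), "%Y-%m-%d")))
  cat(sprintf("  ALAN: %s\n", if (is.null(attr(x, "alan"))) "none" else
    sprintf("%.3g uW m-2 broadband", attr(x, "alan")$total)))
  invisible(x)
}

#' Scan one night window for periods of minimum light intensity
#'
#' Pure detection core: within the window, the nightly minimum is the
#' smallest total irradiance, and maximal runs of consecutive steps whose
#' total stays within \code{(1 + tolerance_rel)} times that minimum are
#' reported when they span at least \code{min_duration} minutes.
#'
#' @param times POSIXct (or numeric seconds) step times, increasing.
#' @param totals Total irradiance per step, uW m^-2.
#' @param window_start,window_end Window bounds (same scale as
#'   \code{times}).
#' @param tolerance_rel Relative tolerance above the minimum.
#' @param min_duration Minimum duration, minutes.
#' @return Data frame: start, end, duration_min, level (the window
#'   minimum); zero rows when no run qualifies or the window holds fewer
#'   than two steps.
#' @export
scan_minimum_periods <- function(times, totals, window_start, window_end,
                                 tolerance_rel = 0.05, min_duration = 30) {
  sel <- times >= window_start & times <= window_end
  empty <- data.frame(start = numeric(), end = numeric(),
                      duration_min = numeric(), level = numeric())
  if (sum(sel) < 2) return(empty)
  tt <- times[sel]; tot <- totals[sel]
  nmin <- min(tot)
  ok <- tot <= (1 + tolerance_rel) * nmin
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- list()
  for (k in which(r$values)) {
    dur <- (as.numeric(tt[ends[k]]) - as.numeric(tt[starts[k]])) / 60
    if (dur >= min_duration)
      out[[length(out) + 1]] <- data.frame(
        start = tt[starts[k]], end = tt[ends[k]], duration_min = dur,
        level = nmin)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect extended periods of minimum light intensity
#'
#' For each night in the timeline, searches the window between sunset and
#' the night's moonrise (or sunrise when the moon does not rise) for
#' maximal runs during which the total irradiance stays within
#' \code{(1 + tolerance_rel)} times the night's own minimum.  Runs lasting
#' at least \code{min_duration} minutes are reported.  Because the
#' reference is the night's own minimum, the same detector serves natural
#' and artificially lit skies: under ALAN the minimum is the ALAN plateau.
#' Nights on which the moon is already up at sunset have no
#' sunset-to-moonrise window and report no period.
#'
#' @param tl \code{light_timeline}.
#' @param tolerance_rel Relative tolerance above the nightly minimum
#'   (default 0.05).
#' @param min_duration Minimum qualifying duration, minutes (default 30).
#' @param events Optional precomputed list of \code{\link{night_events}},
#'   one per night of the timeline in order (computed when omitted).
#' @return Data frame with one row per detected period: \code{night},
#'   \code{start}, \code{end}, \code{duration_min}, \code{level} (the
#'   nightly minimum, uW m^-2).
#' @export
detect_minimum_periods <- function(tl, tolerance_rel = 0.05,
                                   min_duration = 30, events = NULL) {
  stopifnot(inherits(tl, "light_timeline"),
            tolerance_rel >= 0, min_duration > 0)
  site <- attr(tl, "site")
  nights <- unique(tl$night)
  if (is.null(events))
    events <- lapply(as.list(nights), function(nd)
      night_events(site[["latitude"]], site[["longitude"]], nd))
  res <- list()
  for (i in seq_along(nights)) {
    nd <- nights[i]
    ev <- events[[i]]
    if (is.na(ev$sunset)) next
    if (ev$moon_up_at_sunset) next
    end_t <- if (!is.na(ev$moonrise)) ev$moonrise else ev$sunrise
    if (is.na(end_t) || end_t <= ev$sunset) next
    per <- scan_minimum_periods(tl$time, tl$total, ev$sunset, end_t,
                                tolerance_rel, min_duration)
    if (nrow(per)) {
      per$night <- nd
      per$start <- as.POSIXct(per$start, origin = "1970-01-01", tz = "UTC")
      per$end <- as.POSIXct(per$end, origin = "1970-01-01", tz = "UTC")
      res[[length(res) + 1]] <- per[c("night", "start", "end",
                                      "duration_min", "level")]
    }
  }
  if (!length(res))
    return(data.frame(night = as.Date(character()),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_min = numeric(), level = numeric()))
  do.call(rbind, res)
}

#' First post-full-moon trigger night under natural and lit skies
#'
#' For a pair of timelines identical except for their artificial-light
#' component, finds for each the first night at 0..14 days after the full
#' moon on which a qualifying minimum-light period exists, and the number
#' of nights by which artificial light advances that trigger.
#'
#' @param tl_natural,tl_lit \code{light_timeline}s covering the full-moon
#'   night plus at least 14 following nights.
#' @param full_moon_night Local civil date of the full-moon night.
#' @param tolerance_rel,min_duration Passed to
#'   \code{\link{detect_minimum_periods}}.
#' @param events Optional precomputed per-night \code{\link{night_events}}
#'   list shared by both timelines.
#' @return List of class \code{trigger_result}: \code{full_moon_night},
#'   \code{first_trigger_night_natural}, \code{first_trigger_night_lit}
#'   (integer days after full moon, NA when no trigger within 14 nights)
#'   and \code{advance_days} (natural minus lit; NA when either is absent).
#' @export
first_trigger_night <- function(tl_natural, tl_lit, full_moon_night,
                                tolerance_rel = 0.05, min_duration = 30,
                                events = NULL) {
  stopifnot(inherits(full_moon_night, "Date"))
  if (is.null(events)) {
    site <- attr(tl_natural, "site")
    events <- lapply(as.list(unique(tl_natural$night)), function(nd)
      night_events(site[["latitude"]], site[["longitude"]], nd))
  }
  first_of <- function(tl) {
    per <- detect_minimum_periods(tl, tolerance_rel, min_duration, events)
    if (!nrow(per)) return(NA_integer_)
    dos <- as.integer(per$night - full_moon_night)
    dos <- dos[dos >= 0 & dos <= 14]
    if (!length(dos)) return(NA_integer_)
    min(dos)
  }
  nat <- first_of(tl_natural)
  lit <- first_of(tl_lit)
  structure(list(
    full_moon_night = full_moon_night,
    first_trigger_night_natural = nat,
    first_trigger_night_lit = lit,
    advance_days = if (is.na(nat) || is.na(lit)) NA_integer_ else nat - lit
  ), class = "trigger_result")
}

#' @export
print.trigger_result <- function(x, ...) {
  cat(sprintf("Full moon night %s: natural trigger +%s d, lit +%s d, advance %s d\n",
              x$full_moon_night, x$first_trigger_night_natural,
              x$first_trigger_night_lit, x$advance_days))
  invisible(x)
}

#' Default artificial-light scenario
#'
#' Broadband ALAN set just above the twilight level at the top of the
#' nautical band (1.05 times the twilight surrogate at 6 degrees solar
#' depression), as an LED-class source, switching on at civil dusk and
#' off at civil dawn.  This reproduces the mechanism by which bright
#' coastal lighting masks the latter stages of twilight.
#' @param atm \code{\link{atmosphere_params}}.
#' @param grid Wavelength grid, nm.
#' @return \code{\link{alan_config}}.
#' @export
default_alan_config <- function(atm = atmosphere_params(),
                                grid = spectral_grid()) {
  lvl <- broadband(twilight_irradiance(-6, atm, grid)) * 1e6
  alan_config("LED", total = 1.05 * lvl)
}

#' Trigger advance for one site and one full moon
#'
#' Convenience wrapper: builds the natural timeline spanning the full-moon
#' night plus 14 nights, derives the lit twin, and runs
#' \code{\link{first_trigger_night}}.
#'
#' @inheritParams sky_geometry
#' @param full_moon POSIXct instant (or Date of the local full-moon night).
#' @param alan \code{\link{alan_config}}; default scenario when omitted.
#' @param tolerance_rel,min_duration Detector settings.
#' @param atm \code{\link{atmosphere_params}}.
#' @return \code{trigger_result}.
#' @export
trigger_advance <- function(latitude, longitude, full_moon,
                            alan = default_alan_config(atm),
                            tolerance_rel = 0.05, min_duration = 30,
                            atm = atmosphere_params()) {
  fm_night <- if (inherits(full_moon, "Date")) full_moon else
    local_solar_date(full_moon, longitude)
  nat <- build_timeline(latitude, longitude, fm_night, fm_night + 14,
                        alan = NULL, atm = atm)
  lit <- add_alan(nat, alan)
  first_trigger_night(nat, lit, fm_night, tolerance_rel, min_duration)
}

#' Trigger advance across a sweep of window durations
#'
#' Builds the natural/lit timeline pair once and evaluates the trigger
#' advance for each minimum-period duration, to show robustness of the
#' whole-night result to the window definition.
#'
#' @inheritParams trigger_advance
#' @param durations Minimum-period durations to sweep, minutes.
#' @return Data frame: min_duration, natural, lit, advance_days.
#' @export
trigger_advance_sweep <- function(latitude, longitude, full_moon,
                                  alan = default_alan_config(atm),
                                  durations = c(20, 30, 45, 60),
                                  tolerance_rel = 0.05,
                                  atm = atmosphere_params()) {
  fm_night <- if (inherits(full_moon, "Date")) full_moon else
    local_solar_date(full_moon, longitude)
  nat <- build_timeline(latitude, longitude, fm_night, fm_night + 14,
                        alan = NULL, atm = atm)
  lit <- add_alan(nat, alan)
  events <- lapply(as.list(unique(nat$night)), function(nd)
    night_events(latitude, longitude, nd))
  out <- lapply(durations, function(d) {
    tr <- first_trigger_night(nat, lit, fm_night, tolerance_rel, d, events)
    data.frame(min_duration = d,
               natural = tr$first_trigger_night_natural,
               lit = tr$first_trigger_night_lit,
               advance_days = tr$advance_days)
  })
  do.call(rbind, out)
}
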