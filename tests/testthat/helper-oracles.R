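# Independent oracles and fixture builders used across the suite.

# Exhaustive window-scan oracle for minimum-light periods: checks every
# index pair for the "within tolerance of the window minimum, maximal,
# long enough" property directly.  Intentionally naive (O(n^3)).
oracle_scan <- function(times, totals, ws, we, tol = 0.05, min_dur = 30) {
  sel <- which(times >= ws & times <= we)
  if (length(sel) < 2)
    return(data.frame(start = numeric(), end = numeric(),
                      duration_min = numeric(), level = numeric()))
  tt <- as.numeric(times[sel]); tot <- totals[sel]
  m <- Inf
  for (v in tot) if (v < m) m <- v
  thresh <- (1 + tol) * m
  out <- list()
  n <- length(tt)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (any(tot[i:j] > thresh)) next
    if (i > 1 && tot[i - 1] <= thresh) next      # not maximal on the left
    if (j < n && tot[j + 1] <= thresh) next      # not maximal on the right
    dur <- (tt[j] - tt[i]) / 60
    if (dur < min_dur) next
    out[[length(out) + 1]] <- data.frame(start = tt[i], end = tt[j],
                                         duration_min = dur, level = m)
  }
  if (!length(out))
    return(data.frame(start = numeric(), end = numeric(),
                      duration_min = numeric(), level = numeric()))
  unique(do.call(rbind, out))
}

# Random piecewise-constant step timeline on a 5-min grid.
random_step_timeline <- function(n_steps = 48, n_levels = 4) {
  times <- seq(0, by = 300, length.out = n_steps)
  cuts <- sort(sample(seq_len(n_steps - 1), n_levels - 1))
  lens <- diff(c(0, cuts, n_steps))
  totals <- rep(round(stats::runif(n_levels, 0.25, 50), 3), lens)
  list(times = times, totals = totals)
}

# Hand-built light_timeline + matching night-events list, for detector
# tests with fully controlled geometry.
fake_night <- function(night_date, sunset, moonrise, totals, step_s = 300,
                       sunrise_offset_h = 10) {
  n <- length(totals)
  t0 <- as.POSIXct(paste(night_date, "18:00:00"), tz = "UTC")
  times <- t0 + seq(0, by = step_s, length.out = n)
  tl <- data.frame(time = times, solar = 0, twilight = 0, lunar = 0,
                   alan = 0, floor = 0.25, sun_alt = -20, moon_alt = -5,
                   night = night_date, total = totals)
  attr(tl, "site") <- c(latitude = 0, longitude = 0)
  attr(tl, "step_min") <- step_s / 60
  class(tl) <- c("light_timeline", "data.frame")
  ev <- structure(list(
    date = night_date, latitude = 0, longitude = 0,
    sunset = t0 + sunset * 60,
    civil_dusk = t0 + (sunset + 25) * 60,
    nautical_dusk = t0 + (sunset + 50) * 60,
    astronomical_dusk = t0 + (sunset + 75) * 60,
    astronomical_dawn = t0 + sunrise_offset_h * 3600 - 75 * 60,
    nautical_dawn = t0 + sunrise_offset_h * 3600 - 50 * 60,
    civil_dawn = t0 + sunrise_offset_h * 3600 - 25 * 60,
    sunrise = t0 + sunrise_offset_h * 3600,
    moonrise = if (is.na(moonrise)) as.POSIXct(NA) else t0 + moonrise * 60,
    moonset = as.POSIXct(NA),
    moon_up_at_sunset = FALSE
  ), class = "night_events")
  list(tl = tl, events = list(ev))
}

# Small synthetic analysis set: classified, filtered, transformed.
small_study <- function(seed = 7, n_sites = 40, n_obs = 50, ...) {
  cfg <- synth_config(n_sites = n_sites, n_obs_per_site = n_obs,
                      seed = seed, ...)
  ds <- gen_dataset(cfg)
  obs <- build_site_covariates(ds$observations, ds$raster, ds$traits)
  pt <- positive_transform(obs$DoSRtNF)
  obs$y <- pt$values
  obs$dSST <- 0
  obs$dKd490 <- 0
  flt <- apply_filters(obs)
  list(cfg = cfg, ds = ds, data = flt, pt = pt)
}

# Published 2020 full-moon calendar (UTC), for cross-checking the
# ephemeris against an independent almanac.
known_full_moons_2020 <- as.POSIXct(c(
  "2020-01-10 19:21", "2020-02-09 07:33", "2020-03-09 17:48",
  "2020-04-08 02:35", "2020-05-07 10:45", "2020-06-05 19:12",
  "2020-07-05 04:44", "2020-08-03 15:59", "2020-09-02 05:22",
  "2020-10-01 21:05", "2020-10-31 14:49", "2020-11-30 09:30",
  "2020-12-30 03:28"), tz = "UTC")
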