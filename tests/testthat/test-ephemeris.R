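test_that("full-moon instants match the published 2020 lunar calendar", {
  fm <- full_moon_instants(2020)
  expect_length(fm, 13)
  expect_equal(as.numeric(fm), as.numeric(known_full_moons_2020),
               tolerance = 20 * 60 / mean(as.numeric(known_full_moons_2020)))
  # elementwise: within 20 minutes of the almanac
  expect_true(all(abs(as.numeric(fm) - as.numeric(known_full_moons_2020))
                  <= 20 * 60))
  spacing <- diff(as.numeric(fm)) / 86400
  expect_true(all(spacing >= 29.2 & spacing <= 29.9))
})

test_that("the moon is essentially fully illuminated at computed full moons", {
  fm <- full_moon_instants(2020)
  fr <- vapply(fm, function(t)
    sky_geometry(0, 0, t)$illuminated_fraction, numeric(1))
  # the disc is not exactly full unless the moon sits on the ecliptic;
  # with ecliptic latitudes up to ~5 deg the fraction stays above 0.998
  expect_true(all(fr >= 0.998))
})

test_that("sky geometry obeys its internal identities", {
  times <- as.POSIXct("2020-03-01 00:00", tz = "UTC") + (0:24) * 3.7 * 86400
  for (t in as.list(times)) {
    g <- sky_geometry(29.5, 34.9, t)
    expect_equal(g$solar_altitude, 90 - g$solar_zenith, tolerance = 1e-12)
    expect_equal(g$lunar_altitude, 90 - g$lunar_zenith, tolerance = 1e-12)
    expect_gte(g$illuminated_fraction, 0)
    expect_lte(g$illuminated_fraction, 1)
    expect_equal(g$illuminated_fraction,
                 (1 + cos(g$lunar_phase_angle * pi / 180)) / 2,
                 tolerance = 1e-6)
  }
})

test_that("opposition and conjunction geometry bound the illuminated fraction", {
  full <- sky_geometry(29.5, 34.9, as.POSIXct("2020-09-02 05:22", tz = "UTC"))
  expect_gte(full$illuminated_fraction, 0.99)
  new <- sky_geometry(29.5, 34.9, as.POSIXct("2020-09-17 11:00", tz = "UTC"))
  expect_lte(new$illuminated_fraction, 0.01)
  # local solar noon at Eilat: the sun is clearly above the horizon
  noon <- sky_geometry(29.5, 34.9, as.POSIXct("2020-06-21 09:40", tz = "UTC"))
  expect_lt(noon$solar_zenith, 90)
})

test_that("night events are ordered and consistent with altitude crossings", {
  ne <- night_events(29.5, 34.9, as.Date("2020-09-05"))
  expect_true(ne$sunset < ne$astronomical_dusk)
  expect_true(ne$astronomical_dusk < ne$astronomical_dawn)
  expect_true(ne$astronomical_dawn < ne$sunrise)
  # round trip: the sun altitude at each dusk equals its threshold
  alt_civil <- sky_geometry(29.5, 34.9, ne$civil_dusk)$solar_altitude
  expect_equal(alt_civil, -6, tolerance = 0.1)
  alt_astro <- sky_geometry(29.5, 34.9, ne$astronomical_dusk)$solar_altitude
  expect_equal(alt_astro, -18, tolerance = 0.1)
})

test_that("the full moon rises near sunset and then later each night", {
  ne0 <- night_events(29.5, 34.9, as.Date("2020-09-02"))
  gap0 <- abs(as.numeric(difftime(ne0$moonrise, ne0$sunset, units = "mins")))
  expect_lte(gap0, 40)
  rises <- lapply(0:5, function(k)
    night_events(29.5, 34.9, as.Date("2020-09-02") + k)$moonrise)
  delays <- diff(vapply(rises, as.numeric, numeric(1))) / 60 - 24 * 60
  expect_true(all(delays >= 20 & delays <= 90))
  expect_true(all(diff(vapply(rises, as.numeric, numeric(1))) > 0))
})

test_that("equatorial twilight is short: astronomical dusk 60-80 min after sunset", {
  ne <- night_events(-5.06, 119.4, as.Date("2020-03-10"))
  gap <- as.numeric(difftime(ne$astronomical_dusk, ne$sunset, units = "mins"))
  expect_gte(gap, 60)
  expect_lte(gap, 80)
})

test_that("polar night yields explicit absent events, not zeros", {
  ne <- night_events(78, 15, as.Date("2020-12-21"))
  expect_true(is.na(ne$sunset))
  expect_true(is.na(ne$sunrise))
})

test_that("day offsets from full moon are antisymmetric around each full moon", {
  fm <- full_moon_instants(2020)
  for (lon in c(34.9, 119.4)) {
    fm_night <- local_solar_date(fm[9], lon)
    for (k in 1:14) {
      d <- days_from_full_moon(fm_night + c(-k, k), lon, fm)
      expect_identical(d, c(-k, k))
    }
    expect_identical(days_from_full_moon(fm_night, lon, fm), 0L)
  }
})
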