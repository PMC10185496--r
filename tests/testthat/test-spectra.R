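test_that("eccentricity correction scales the TOA spectrum as (1 + e cos)^2", {
  base <- toa_solar(100, eccentricity = 0)
  perihelion_side <- toa_solar(3, eccentricity = 0.0167)
  ratio <- broadband(perihelion_side) / broadband(base)
  expect_equal(ratio, 1.0167^2, tolerance = 1e-6)
  aphelion_side <- toa_solar(185, eccentricity = 0.0167)
  mult <- (1 + 0.0167 * cos(2 * pi * (185 - 3) / 365))^2
  expect_equal(broadband(aphelion_side) / broadband(base), mult,
               tolerance = 1e-9)
  expect_equal(mult, 0.9669, tolerance = 1e-4)
  # e = 0 returns the reference table unchanged
  expect_equal(toa_solar(200, eccentricity = 0)$values, base$values)
})

test_that("a supplied TOA table is used and resampled with a warning", {
  g <- spectral_grid()
  tab <- data.frame(wavelength_nm = seq(380, 750, by = 5), value = 1.5)
  expect_warning(e0 <- toa_solar(100, eccentricity = 0, h0 = tab),
                 "resampling")
  expect_equal(e0$values, rep(1.5, length(g)))
  short <- data.frame(wavelength_nm = 450:650, value = 1)
  expect_error(toa_solar(100, h0 = short), "cover")
})

test_that("clear-sky partition is additive, bounded and airmass-monotone", {
  toa <- toa_solar(80)
  zeniths <- c(0, 15, 30, 45, 60, 75, 85, 89)
  tot <- vapply(zeniths, function(z) {
    cs <- clear_sky_surface(toa, z)
    expect_true(all(cs$direct$values >= 0))
    expect_true(all(cs$diffuse$values >= 0))
    broadband(cs$direct) + broadband(cs$diffuse)
  }, numeric(1))
  expect_true(all(diff(tot) < 0))
  # diffuse fraction grows toward the horizon
  dfrac <- vapply(zeniths, function(z) {
    cs <- clear_sky_surface(toa, z)
    broadband(cs$diffuse) / (broadband(cs$direct) + broadband(cs$diffuse))
  }, numeric(1))
  expect_true(all(diff(dfrac) > 0))
  # overhead sun: full-spectrum equivalent of the visible-band total is
  # of order 1 kW m^-2, and the direct transmittance is a proper fraction
  cs0 <- clear_sky_surface(toa, 0)
  full_equiv <- (broadband(cs0$direct) + broadband(cs0$diffuse)) / 0.47
  expect_gt(full_equiv, 800)
  expect_lt(full_equiv, 1200)
  tdir <- broadband(cs0$direct) / broadband(toa)
  expect_gt(tdir, 0)
  expect_lt(tdir, 1)
  expect_error(clear_sky_surface(toa, 92), "twilight")
})

test_that("twilight partitions follow the civil/nautical/astronomical bands", {
  expect_identical(attr(twilight_irradiance(-3), "partition"), "civil")
  expect_identical(attr(twilight_irradiance(-7), "partition"), "nautical")
  expect_identical(attr(twilight_irradiance(-15), "partition"), "astronomical")
  expect_identical(attr(twilight_irradiance(-20), "partition"), "night")
  expect_error(twilight_irradiance(5), "below the horizon")
})

test_that("twilight decays monotonically and meets its anchors", {
  alts <- seq(-0.5, -17.5, by = -0.5)
  bb <- vapply(alts, function(a) broadband(twilight_irradiance(a)), numeric(1))
  expect_true(all(diff(bb) < 0))
  # continuity with the clear-sky value at the horizon (within 20%)
  cs <- clear_sky_surface(toa_solar(80), 89.5)
  horizon <- broadband(cs$direct) + broadband(cs$diffuse)
  expect_equal(broadband(twilight_irradiance(-1e-3)) / horizon, 1,
               tolerance = 0.2)
  # at -18 deg the sky has reached the dark-sky floor (within 10x)
  floor_bb <- broadband(dark_sky_floor())
  expect_lt(broadband(twilight_irradiance(-18)) / floor_bb, 10)
  expect_gt(broadband(twilight_irradiance(-18)) / floor_bb, 0.1)
})

test_that("a measured twilight lookup table can replace the surrogate", {
  lut <- data.frame(depression_deg = c(0, 6, 12, 18),
                    broadband_w_m2 = c(1, 1e-2, 1e-4, 0.25e-6))
  tw <- twilight_irradiance(-6, lut = lut)
  expect_equal(broadband(tw), 1e-2, tolerance = 1e-6)
})

test_that("the photometric chain reproduces the dark-sky constants", {
  L <- mag_to_luminance(22)
  expect_equal(L, 1.712e-4, tolerance = 5e-4)
  expect_equal(luminance_to_irradiance(L), 0.25, tolerance = 5e-3)
  expect_equal(mag_to_luminance(0), 1.08e5)
  # 2.5 magnitudes are exactly a factor of ten
  expect_equal(mag_to_luminance(12.5) / mag_to_luminance(10), 0.1)
  expect_identical(luminance_to_irradiance(0), 0)
  expect_equal(luminance_to_irradiance(683e-6), 1)
})

test_that("the dark-sky floor is flat, constant, and 0.25 uW m^-2", {
  fl <- dark_sky_floor()
  expect_equal(broadband(fl) * 1e6, 0.25, tolerance = 0.01)
  expect_length(unique(fl$values), 1)   # flat shape
  expect_equal(unique(fl$values) * 1e6, 0.25 / 300, tolerance = 0.01)
  expect_identical(dark_sky_floor()$values, fl$values)
})

test_that("TOA lunar irradiance is the diluted, phase-modulated solar spectrum", {
  expect_equal(sin(0.26 * pi / 180)^2, 2.06e-5, tolerance = 1e-3)
  # flat 0.12 albedo: ratio to solar ~ 2.5e-6 at full moon
  g <- spectral_grid()
  tl <- toa_lunar(245, 0, albedo = rep(0.12, length(g)))
  ratio <- broadband(tl) / broadband(toa_solar(245))
  expect_equal(ratio, 2.5e-6, tolerance = 0.02)
  # five-orders-of-magnitude separation with the default albedo
  ratio_d <- broadband(toa_lunar(245, 0)) / broadband(toa_solar(245))
  expect_gte(ratio_d, 1e-6)
  expect_lte(ratio_d, 1e-5)
  # quarter moon is far dimmer than full
  expect_lt(broadband(toa_lunar(245, 90)), 0.15 * broadband(tl))
  # the phase curve is normalised and non-increasing
  expect_equal(lunar_phase_factor(0), 1)
  expect_true(all(diff(lunar_phase_factor(seq(0, 180, 5))) <= 0))
})

test_that("surface lunar irradiance is zero below the horizon and ~1 mW at full moon", {
  tl <- toa_lunar(245, 0)
  below <- surface_lunar(tl, 95)
  expect_true(all(below$values == 0))
  at_zenith <- broadband(surface_lunar(tl, 5)) * 1e3   # mW m^-2
  expect_gt(at_zenith, 0.5)
  expect_lt(at_zenith, 5)
  # the transmittance model is linear in the source: scaling the TOA
  # spectrum scales the surface value by the same factor
  tl2 <- spectral_irradiance(tl$values * 3.7, tl$grid, "lunar")
  expect_equal(broadband(surface_lunar(tl2, 40)) /
                 broadband(surface_lunar(tl, 40)), 3.7, tolerance = 1e-9)
})

test_that("ALAN spectra honour their band integrals and totals", {
  zero <- alan_spectrum(alan_config(blue = 0, green = 0, red = 0))
  expect_true(all(zero$values == 0))
  rgb <- alan_spectrum(alan_config(blue = 1, green = 1, red = 1))
  expect_equal(broadband(rgb) * 1e6, 3, tolerance = 0.01)
  bands <- alan_band_integrals(rgb)
  expect_equal(unname(bands), c(1, 1, 1), tolerance = 0.01)
  for (cls in c("LED", "HPS", "LPS")) {
    sp <- alan_spectrum(alan_config(cls, total = 10))
    expect_equal(broadband(sp) * 1e6, 10, tolerance = 0.01)
  }
  expect_error(alan_config(blue = -1), ">= 0")
})

test_that("every spectral component is non-negative everywhere", {
  specs <- list(
    toa_solar(180),
    clear_sky_surface(toa_solar(180), 60)$direct,
    clear_sky_surface(toa_solar(180), 60)$diffuse,
    twilight_irradiance(-10),
    toa_lunar(180, 45),
    surface_lunar(toa_lunar(180, 45), 50),
    alan_spectrum(alan_config("LED", total = 5)),
    dark_sky_floor())
  for (s in specs) expect_true(all(s$values >= 0))
})
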