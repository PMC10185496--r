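test_that("detector matches the exhaustive window-scan oracle on random step timelines", {
  set.seed(42)
  n_cases <- 300
  for (i in seq_len(n_cases)) {
    st <- random_step_timeline(n_steps = sample(20:60, 1),
                               n_levels = sample(2:6, 1))
    ws <- sample(st$times, 1)
    we <- ws + sample(c(3600, 7200, 10800), 1)
    tol <- sample(c(0, 0.05, 0.2), 1)
    dur <- sample(c(20, 30, 45), 1)
    got <- scan_minimum_periods(st$times, st$totals, ws, we, tol, dur)
    want <- oracle_scan(st$times, st$totals, ws, we, tol, dur)
    expect_equal(nrow(got), nrow(want), info = paste("case", i))
    if (nrow(got)) {
      o <- order(got$start); ow <- order(want$start)
      expect_equal(got$start[o], want$start[ow], info = paste("case", i))
      expect_equal(got$end[o], want$end[ow], info = paste("case", i))
      expect_equal(got$level[o], want$level[ow], info = paste("case", i))
    }
  }
})

test_that("a constant-floor gap between sunset and moonrise yields one period", {
  # constant floor from sunset; moonrise 90 min after sunset
  fn <- fake_night(as.Date("2021-01-05"), sunset = 10, moonrise = 100,
                   totals = rep(0.25, 120))
  per <- detect_minimum_periods(fn$tl, events = fn$events)
  expect_equal(nrow(per), 1)
  expect_equal(per$duration_min, 90, tolerance = 0.12)  # edge steps
  expect_equal(per$level, 0.25)
  # the same night under bright ALAN: the plateau defines the minimum
  fn2 <- fake_night(as.Date("2021-01-05"), sunset = 10, moonrise = 100,
                    totals = rep(0.25, 120))
  fn2$tl$total <- fn2$tl$total + 25    # 100x the floor
  per2 <- detect_minimum_periods(fn2$tl, events = fn2$events)
  expect_equal(per2$level, 25.25)
  # a declining series has no qualifying window
  fn3 <- fake_night(as.Date("2021-01-05"), sunset = 10, moonrise = 100,
                    totals = 100 * 0.9^(0:119))
  expect_equal(nrow(detect_minimum_periods(fn3$tl, events = fn3$events)), 0)
})

test_that("timeline components compose additively with the expected scales", {
  tl <- build_timeline(29.5, 34.9, as.Date("2020-09-16"),
                       as.Date("2020-09-17"))
  expect_s3_class(tl, "light_timeline")
  expect_equal(unique(round(diff(as.numeric(tl$time)))), 300)
  expect_equal(tl$total,
               tl$solar + tl$twilight + tl$lunar + tl$alan + tl$floor)
  expect_true(all(tl$total >= tl$floor - 1e-12))
  # daytime: solar dominates moonlight by orders of magnitude
  day <- tl[tl$sun_alt > 40, ]
  expect_true(all(day$solar > 1e3 * pmax(day$lunar, 1e-12)))
  # deep new-moon night: only the floor remains (within 1%)
  night <- tl[tl$sun_alt < -25 & tl$moon_alt < 0, ]
  expect_gt(nrow(night), 10)
  expect_true(all(abs(night$total / night$floor - 1) < 0.01))
})

test_that("ALAN adds a plateau between dusk and dawn and nothing else changes", {
  nat <- build_timeline(29.5, 34.9, as.Date("2020-09-16"),
                        as.Date("2020-09-16"))
  lit <- add_alan(nat, alan_config(blue = 4, green = 3, red = 3))
  expect_equal(lit$solar, nat$solar)
  expect_equal(lit$twilight, nat$twilight)
  expect_equal(lit$lunar, nat$lunar)
  on <- lit$sun_alt < -6
  expect_true(all(lit$alan[on] > 0))
  expect_true(all(lit$alan[!on] == 0))
  expect_equal(unique(round(lit$alan[on], 6)), 10, tolerance = 0.01)
  expect_true(all(lit$total[on] >= 10))
})

test_that("no artificial light means no advance, and the result is deterministic", {
  fm <- as.Date("2020-09-02")
  nat <- build_timeline(29.5, 34.9, fm, fm + 14)
  dark <- add_alan(nat, alan_config(blue = 0, green = 0, red = 0))
  tr <- first_trigger_night(nat, dark, fm)
  expect_identical(tr$advance_days, 0L)
  expect_identical(tr$first_trigger_night_natural,
                   tr$first_trigger_night_lit)
  tr2 <- first_trigger_night(nat, dark, fm)
  expect_identical(tr, tr2)
})

test_that("brighter artificial light never delays the trigger", {
  fm <- as.Date("2020-09-02")
  nat <- build_timeline(29.5, 34.9, fm, fm + 14)
  events <- lapply(as.list(unique(nat$night)), function(nd)
    night_events(29.5, 34.9, nd))
  # dusk-switched lights: monotone for sources below the twilight level
  # at switch-on (brighter sources carve a pre-switch-on notch that
  # removes the stable period altogether; see the methods vignette)
  levels <- c(5, 500, 5000)   # uW m^-2 broadband
  trig <- vapply(levels, function(lv) {
    lit <- add_alan(nat, alan_config("LED", total = lv))
    first_trigger_night(nat, lit, fm, events = events)$advance_days
  }, integer(1))
  expect_true(all(diff(trig) >= 0))
  expect_true(all(!is.na(trig)))
  # sunset-switched lights: monotone without restriction
  trig2 <- vapply(c(500, 50000), function(lv) {
    lit <- add_alan(nat, alan_config("LED", total = lv,
                                     on_event = "sunset",
                                     off_event = "sunrise"))
    first_trigger_night(nat, lit, fm, events = events)$advance_days
  }, integer(1))
  expect_true(all(!is.na(trig2)))
  expect_true(all(diff(trig2) >= 0))
})
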