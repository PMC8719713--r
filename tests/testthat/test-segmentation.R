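test_that("territory model: identical fixes give a zero-spread centroid", {
  fx <- make_fixes(utc("2015-01-01") + (0:4) * 3600, rep(55, 5), rep(-70, 5))
  m <- fit_territory_model(fx)
  expect_equal(unname(m$centroid), c(55, -70))
  expect_equal(m$mean_disp_km, 0)
  expect_equal(m$sd_disp_km, 0)
  expect_error(fit_territory_model(fx[1:2, ]), "at least 3")
})

test_that("territory model: a small square has its centroid at the centre", {
  fx <- make_fixes(utc("2015-01-01") + (0:3) * 3600,
                   c(50.0, 50.0, 50.1, 50.1), c(-60.0, -60.1, -60.0, -60.1))
  m <- fit_territory_model(fx)
  expect_equal(unname(m$centroid["lat"]), 50.05)
  expect_equal(unname(m$centroid["lon"]), -60.05)
  disp <- great_circle_km(fx$lat, fx$lon, 50.05, -60.05)
  # corners are near-equidistant by symmetry
  expect_lt(m$sd_disp_km, 0.01 * m$mean_disp_km)
})

test_that("territory centroid handles the antimeridian by circular mean", {
  fx <- make_fixes(utc("2015-01-01") + (0:3) * 3600,
                   c(60, 60, 60.1, 60.1), c(179.9, -179.9, 179.9, -179.9))
  m <- fit_territory_model(fx)
  expect_gt(abs(unname(m$centroid["lon"])), 179)  # near +-180, not 0
  expect_lt(m$mean_disp_km, 20)
})

test_that("no breakout is reported while the animal stays inside its range", {
  trk <- stationary_track(30)
  m <- fit_territory_model(trk$fixes[1:10, ])
  expect_null(detect_breakout(trk, m, from_time = trk$fixes$timestamp[10]))
})

test_that("a single outlier followed by a return is not a departure", {
  t0 <- utc("2015-01-01")
  lat <- rep(50, 20); lat[12] <- 50.5  # ~55 km excursion, then back
  trk <- track("a1", make_fixes(t0 + (0:19) * 7200, lat, rep(-60, 20)))
  m <- fit_territory_model(trk$fixes[1:8, ])
  expect_null(detect_breakout(trk, m, from_time = trk$fixes$timestamp[8]))
})

test_that("a sustained breakout is detected at its first fix", {
  t0 <- utc("2015-01-01")
  lat <- c(rep(50, 10), 50.5, 51.2, 52.5, 54)  # monotone leave
  trk <- track("a1", make_fixes(t0 + seq_along(lat) * 7200, lat, rep(-60, length(lat))))
  m <- fit_territory_model(trk$fixes[1:10, ])
  ev <- detect_breakout(trk, m, from_time = trk$fixes$timestamp[10])
  expect_s3_class(ev, "flyway_event")
  expect_equal(ev$observed_fix$lat, 50.5)
})

test_that("event-time interpolation follows the flight-speed rule", {
  # apparent speed 5 m/s over 264.6 km: below 10.68 m/s, so the event is
  # back-shifted by 264.6 km at 52.92 km/h = exactly 5 h
  t0 <- utc("2015-07-07 12:00:00")
  dt_s <- 264.6e3 / 5
  neighbor <- make_fixes(t0, 50, -60)
  observed <- make_fixes(t0 + dt_s, 50 + 264.6 / 111.195, -60)
  ev <- structure(list(kind = "departure", season = NA, observed_fix = observed,
                       event_time = observed$timestamp, interpolated = FALSE),
                  class = "flyway_event")
  out <- interpolate_event_time(ev, neighbor)
  expect_true(out$interpolated)
  offset_h <- as.numeric(observed$timestamp - out$event_time, units = "hours")
  expect_equal(offset_h, 5, tolerance = 1e-4)
  # at 14 m/s (above threshold) the observed time is kept
  observed_fast <- make_fixes(t0 + 264.6e3 / 14, 50 + 264.6 / 111.195, -60)
  ev2 <- structure(list(kind = "departure", season = NA, observed_fix = observed_fast,
                        event_time = observed_fast$timestamp, interpolated = FALSE),
                   class = "flyway_event")
  out2 <- interpolate_event_time(ev2, neighbor)
  expect_false(out2$interpolated)
  expect_equal(out2$event_time, observed_fast$timestamp)
  # zero distance: event time equals the observed time either way
  ev3 <- structure(list(kind = "departure", season = NA, observed_fix = neighbor,
                        event_time = neighbor$timestamp, interpolated = FALSE),
                   class = "flyway_event")
  n2 <- make_fixes(t0 - 3600, 50, -60)
  out3 <- interpolate_event_time(ev3, n2)
  expect_equal(out3$event_time, neighbor$timestamp)
})

test_that("arrival interpolation anchors at the last in-flight fix", {
  t0 <- utc("2015-09-01 00:00:00")
  flight_fix <- make_fixes(t0, 10, -60)
  # first on-territory fix 30 h later, 100 km on: bird arrived early in the gap
  terr_fix <- make_fixes(t0 + 30 * 3600, 10 + 100 / 111.195, -60)
  ev <- structure(list(kind = "arrival", season = NA, observed_fix = terr_fix,
                       event_time = terr_fix$timestamp, interpolated = FALSE),
                  class = "flyway_event")
  out <- interpolate_event_time(ev, flight_fix)
  expect_true(out$interpolated)
  expect_equal(as.numeric(out$event_time - t0, units = "hours"),
               100 / 52.92, tolerance = 1e-3)
  expect_lte(as.numeric(out$event_time), as.numeric(terr_fix$timestamp))
})

test_that("stationary periods: a ballistic track has none", {
  t0 <- utc("2015-01-01")
  trk <- track("a1", make_fixes(t0 + (0:20) * 3600, seq(0, 10, by = 0.5), rep(0, 21)))
  expect_equal(nrow(detect_stationary_periods(trk)), 0)
})

test_that("stationary periods: two stops separated by a flight are kept apart", {
  t0 <- utc("2015-01-01")
  fx <- rbind(
    make_fixes(t0 + (0:9) * 3600, rep(0, 10), rep(0, 10)),
    make_fixes(t0 + 10 * 3600 + (1:2) * 3600, c(1.5, 3), c(0, 0)),  # 2-h flight
    make_fixes(t0 + 13 * 3600 + (0:9) * 3600, rep(4.5, 10), rep(0, 10))
  )
  p <- detect_stationary_periods(track("a1", fx), min_duration_h = 6)
  expect_equal(nrow(p), 2)
  expect_equal(p$lat, c(0, 4.5), tolerance = 1e-6)
})

test_that("stationary period detection on a synthetic staging stay covers it", {
  sch <- preset_schedule("mackenzie_delta")
  g <- generate_annual_track(sch, movement_config(), seed = 21)
  trk <- filter_quality(g$track)
  p <- detect_stationary_periods(trk)
  staging <- g$truth$visits[g$truth$visits$kind == "staging", ]
  for (k in seq_len(nrow(staging))) {
    # a stay shorter than ~1.5 duty cycles (58 h each) may fall entirely in
    # off-periods and is not reliably observable
    if (as.numeric(staging$end[k] - staging$start[k], units = "days") < 4) next
    near <- p[great_circle_km(p$lat, p$lon, staging$lat[k], staging$lon[k]) < 50, ]
    expect_gte(nrow(near), 1)
    # detected interval covers the true stay within one duty-cycle gap (58 h)
    expect_lt(abs(as.numeric(near$start[1] - staging$start[k], units = "hours")), 58)
    expect_lt(abs(as.numeric(near$end[nrow(near)] - staging$end[k], units = "hours")), 58)
  }
})

test_that("season delineation reproduces calendar spans and partitions time", {
  ev <- list(autumn_departure = utc("2015-07-07"),
             winter_arrival = utc("2015-08-30"),
             winter_departure = utc("2016-04-06"),
             breeding_arrival = utc("2016-05-31"))
  cyc <- delineate_seasons(ev)
  expect_equal(cyc$autumn_duration_d, 54)
  expect_equal(cyc$autumn_duration_d + cyc$winter_duration_d + cyc$spring_duration_d,
               as.numeric(utc("2016-05-31") - utc("2015-07-07"), units = "days"))
  expect_true(all(c(cyc$autumn_duration_d, cyc$winter_duration_d,
                    cyc$spring_duration_d) > 0))
  # out-of-order events are refused with the offending pair named
  bad <- ev; bad$winter_arrival <- utc("2015-07-01")
  expect_error(delineate_seasons(bad), "out of order")
})

test_that("breakout detection is invariant to a longitude translation", {
  t0 <- utc("2015-01-01")
  lat <- c(rep(50, 10), 50.5, 51.2, 52.5)
  base_lon <- rep(-60, length(lat))
  for (shift in c(0, 37)) {
    trk <- track("a1", make_fixes(t0 + seq_along(lat) * 7200, lat, base_lon + shift))
    m <- fit_territory_model(trk$fixes[1:10, ])
    ev <- detect_breakout(trk, m, from_time = trk$fixes$timestamp[10])
    expect_equal(ev$observed_fix$timestamp, t0 + 11 * 7200)
  }
})
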