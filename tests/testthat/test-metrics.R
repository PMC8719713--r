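test_that("great-circle distance matches hand geodesy", {
  expect_equal(great_circle_km(0, 0, 0, 0), 0)
  # one degree of longitude on the equator: 2*pi*R/360
  expect_equal(great_circle_km(0, 0, 0, 1), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-9)
  # pole to pole: pi*R
  expect_equal(great_circle_km(90, 10, -90, 120), pi * 6371.0088,
               tolerance = 1e-9)
  # symmetry
  expect_equal(great_circle_km(12, -70, 45, 8), great_circle_km(45, 8, 12, -70))
})

test_that("haversine stays within 0.6% of the ellipsoidal oracle", {
  withr::with_seed(901, {
    n <- 300
    lat1 <- runif(n, -85, 85); lat2 <- runif(n, -85, 85)
    lon1 <- runif(n, -180, 180); lon2 <- runif(n, -180, 180)
    hav <- great_circle_km(lat1, lon1, lat2, lon2)
    ell <- geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
    keep <- ell > 1  # relative error is meaningless at zero distance
    expect_lt(max(abs(hav[keep] - ell[keep]) / ell[keep]), 0.006)
  })
})

test_that("path length sums great-circle segments and bounds the chord", {
  p2 <- data.frame(lat = c(0, 10), lon = c(0, 10))
  expect_equal(path_length_km(p2), great_circle_km(0, 0, 10, 10))
  # collinear equidistant points on the equator add up exactly
  p3 <- data.frame(lat = c(0, 0, 0), lon = c(0, 5, 10))
  expect_equal(path_length_km(p3), great_circle_km(0, 0, 0, 10),
               tolerance = 1e-9)
  expect_warning(len1 <- path_length_km(data.frame(lat = 1, lon = 1)), "fewer")
  expect_equal(len1, 0)
  # triangle inequality on random paths
  withr::with_seed(902, {
    for (k in 1:20) {
      m <- 2 + rpois(1, 6)
      p <- data.frame(lat = runif(m, -60, 60), lon = runif(m, -170, 170))
      expect_gte(path_length_km(p) + 1e-9,
                 great_circle_km(p$lat[1], p$lon[1], p$lat[m], p$lon[m]))
    }
  })
})

test_that("path length can exclude local movements inside stationary intervals", {
  t0 <- utc("2015-01-01")
  path <- tibble::tibble(
    time = t0 + (0:9) * 3600,
    lat = c(0, 1, 2, 2.01, 1.99, 2.01, 1.99, 2, 3, 4),
    lon = rep(0, 10))
  stops <- tibble::tibble(start = t0 + 2 * 3600, end = t0 + 7 * 3600)
  full <- path_length_km(path)
  clean <- path_length_km(path, exclude_intervals = stops)
  expect_lt(clean, full)
  expect_equal(clean, great_circle_km(0, 0, 4, 0), tolerance = 0.01)
})

test_that("leg summary computes speed as length over elapsed days", {
  t0 <- utc("2015-07-01")
  path <- tibble::tibble(time = c(t0, t0 + 10 * 86400),
                         lat = c(0, 0), lon = c(0, 8.993))
  leg <- summarize_leg(t0, t0 + 10 * 86400, path)
  expect_equal(leg$duration_d, 10)
  expect_equal(leg$speed_kmd, leg$distance_km / 10)
  expect_equal(leg$distance_km, 1000, tolerance = 0.01)
  expect_error(summarize_leg(t0 + 86400, t0, path), "not after")
})

test_that("migration speed decreases as stopover time is added at fixed path", {
  t0 <- utc("2015-07-01")
  path <- tibble::tibble(time = c(t0, t0 + 5 * 86400), lat = c(0, 10), lon = c(0, 0))
  speeds <- sapply(c(0, 2, 5, 9), function(stop_d) {
    summarize_leg(t0, t0 + (5 + stop_d) * 86400, path)$speed_kmd
  })
  expect_true(all(diff(speeds) < 0))
})

test_that("pooled t from printed summaries reproduces the published statistic", {
  spring <- list(mean = 206.9, se = 10.47, n = 25)
  autumn <- list(mean = 173.8, se = 8.79, n = 30)
  ct <- two_sample_t(spring, autumn, method = "pooled")
  expect_equal(ct$df, 53)
  expect_equal(round(ct$t_statistic, 1), 2.4)
  expect_lt(ct$p_two_tailed, 0.05)
})

test_that("summary t equals raw-sample t and matches t.test", {
  withr::with_seed(903, {
    x <- rnorm(12, 5, 2); y <- rnorm(17, 6, 2)
    raw <- two_sample_t(x, y, method = "pooled")
    sm <- two_sample_t(list(mean = mean(x), se = sd(x) / sqrt(12), n = 12),
                       list(mean = mean(y), se = sd(y) / sqrt(17), n = 17),
                       method = "pooled")
    expect_equal(raw$t_statistic, sm$t_statistic, tolerance = 1e-12)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(raw$t_statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(raw$p_two_tailed, tt$p.value, tolerance = 1e-12)
    w <- two_sample_t(x, y, method = "welch")
    tw <- t.test(x, y)
    expect_equal(w$t_statistic, unname(tw$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(tw$parameter), tolerance = 1e-9)
  })
})

test_that("the t statistic is antisymmetric and p invariant under group swap", {
  a <- list(mean = 10, se = 1, n = 10); b <- list(mean = 12, se = 1.5, n = 8)
  ab <- two_sample_t(a, b); ba <- two_sample_t(b, a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_two_tailed, ba$p_two_tailed)
  # identical groups give t = 0
  expect_equal(two_sample_t(a, a)$t_statistic, 0)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.03), 0.03)
  expect_equal(bonferroni(0.01, family_size = 5), 0.05)
  expect_equal(bonferroni(0.4, family_size = 5), 1)
  expect_error(bonferroni(c(0.1, 0.2), family_size = 1), "family_size")
})

test_that("date arithmetic reproduces the published season spans", {
  expect_equal(date_diff("7 July", "22 July"), 15)
  expect_equal(date_diff("30 August", "18 September"), 19)
  expect_equal(date_diff("6 April", "20 April"), 14)
  expect_equal(date_diff("3 June", "18 September"), 107)
  expect_equal(date_diff("31 May", "30 August"), 91)
})

test_that("date stats give the mean date with SE in days", {
  st <- date_stats(c("7 July", "7 July"))
  expect_equal(format(st$mean_date, "%d %B"), "07 July")
  expect_equal(st$se, 0)
  st2 <- date_stats(parse_day_month(c("1 July", "11 July")))
  expect_equal(st2$se, 5)
  expect_error(date_stats(parse_day_month(c("1 January", "30 December"))), "180")
})

test_that("summary tables have one row per population-season and consistent sites", {
  mv <- movement_config()
  cycles <- NULL
  for (pn in c("mackenzie_delta", "hudson_bay")) {
    sch <- preset_schedule(pn)
    for (s in 11:12) {
      g <- generate_annual_track(sch, mv, seed = s,
                                 animal_id = sprintf("%s_%d", pn, s))
      trk <- filter_quality(g$track)
      seg <- segment_annual_cycle(trk, territory_hints = territory_hints_for(sch))
      cyc <- seg$cycles
      cyc$population <- pn
      cycles <- rbind(cycles, cyc)
    }
  }
  tb <- build_tables(cycles = cycles)
  expect_setequal(unique(tb$phenology$season),
                  c("breeding", "autumn", "winter", "spring"))
  expect_equal(nrow(tb$phenology), 8)  # 2 populations x 4 seasons
  expect_true(all(tb$phenology$se_d >= 0))
  # empty inputs give header-only tables
  tb0 <- build_tables()
  expect_equal(nrow(tb0$phenology), 0)
  expect_equal(nrow(tb0$migration), 0)
})

test_that("a noise-free densely sampled leg is measured within 2% of truth", {
  sch <- preset_schedule("hudson_bay")
  mv <- movement_config(duty_cycle = c(off_h = 0, on_h = 24),
                        fixes_per_on = list(mean = 24, max = 34,
                                            dispersion = "fixed"),
                        fix_spacing = "regular", error_scale = 0,
                        territory_radius_km = 0, lc_mix = c(LC3 = 1))
  g <- generate_annual_track(sch, mv, seed = 14)
  trk <- filter_quality(g$track)
  seg <- segment_annual_cycle(trk, territory_hints = territory_hints_for(sch))
  leg <- measure_leg(trk, seg$cycles$autumn_departure,
                     seg$cycles$winter_arrival, season = "autumn")
  truth_km <- g$truth$legs$distance_km[1]
  expect_lt(abs(leg$distance_km - truth_km) / truth_km, 0.02)
})

test_that("a duty-cycled cohort recovers the published mean autumn distance", {
  # 24 h off / 5 h on transmitters resolve the route at the scale needed for
  # along-path length; the cohort mean lands within 2 SE of the published
  # 11,332 km
  sch <- preset_schedule("mackenzie_delta")
  mv <- movement_config(duty_cycle = c(off_h = 24, on_h = 5))
  hints <- territory_hints_for(sch)
  meas <- c()
  for (i in 1:8) {
    g <- generate_annual_track(sch, mv, seed = 1 + 131L * i)
    trk <- filter_quality(g$track)
    seg <- segment_annual_cycle(trk, territory_hints = hints)
    leg <- measure_leg(trk, seg$cycles$autumn_departure,
                       seg$cycles$winter_arrival, season = "autumn")
    meas <- c(meas, leg$distance_km)
  }
  expect_lt(abs(mean(meas) - 11332), 2 * 333.8)
})
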