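visit_row <- function(animal, lat, lon, start, dur_d, id = NULL) {
  tibble::tibble(animal_id = animal, start = utc(start),
                 end = utc(start) + dur_d * 86400,
                 lat = lat, lon = lon, n_fixes = 10L, duration_d = dur_d)
}

test_that("a single visit forms a single cluster equal to itself", {
  v <- visit_row("a", 40, -75, "2015-08-01", 10)
  cl <- cluster_visits(v)
  expect_equal(cl$site_id, 1L)
  sites <- attr(cl, "sites")
  expect_equal(sites$lat, 40)
  expect_equal(sites$n_visits, 1L)
})

test_that("single linkage at 250 km matches brute-force pair distances", {
  # three visits with mutual distances ~{100, 100, 600} km: chains of short
  # links merge, the far one stays apart... here A-B ~100 km, B-C ~600 km
  v <- rbind(visit_row("a", 40.0, -75.0, "2015-08-01", 3),
             visit_row("b", 40.9, -75.0, "2015-08-02", 3),
             visit_row("c", 46.3, -75.0, "2015-08-03", 3))
  d_ab <- great_circle_km(40, -75, 40.9, -75)
  d_bc <- great_circle_km(40.9, -75, 46.3, -75)
  expect_lt(d_ab, 250); expect_gt(d_bc, 250)
  cl <- cluster_visits(v, link_km = 250)
  expect_equal(length(unique(cl$site_id)), 2)
  expect_equal(cl$site_id[1], cl$site_id[2])
  expect_false(cl$site_id[3] == cl$site_id[1])
})

test_that("clustering is invariant to input permutation", {
  withr::with_seed(41, {
    v <- rbind(visit_row("a", 33.0, -79.5, "2015-08-01", 20),
               visit_row("b", 33.4, -79.0, "2015-08-05", 18),
               visit_row("c", 47.3, -62.0, "2015-08-02", 19),
               visit_row("d", 47.5, -62.5, "2015-08-06", 21),
               visit_row("e", 10.0, -60.0, "2015-09-01", 2))
    cl1 <- cluster_visits(v)
    perm <- sample(nrow(v))
    cl2 <- cluster_visits(v[perm, ])
    # same partition: site of each animal matches after relabelling
    key1 <- cl1$site_id[order(cl1$animal_id)]
    key2 <- cl2$site_id[order(cl2$animal_id)]
    expect_identical(key1, key2)
  })
})

test_that("classification applies the staging criteria conjunctively", {
  crit <- site_criteria()
  # long stay, long onward leg, reused over years -> staging
  v1 <- rbind(visit_row("a", 47.3, -62.0, "2015-08-01", 19.3),
              visit_row("b", 47.3, -62.1, "2016-08-02", 19.2))
  itin <- rbind(v1[, c("animal_id", "lat", "lon", "start")],
                tibble::tibble(animal_id = c("a", "b"), lat = 1, lon = -48,
                               start = utc(c("2015-09-15", "2016-09-15"))))
  cl <- cluster_visits(v1)
  s <- classify_sites(cl, itinerary = itin, criteria = crit, n_population = 10)
  expect_equal(s$label, "staging")
  expect_gt(s$next_leg_km, 1000)
  # one 1-day visit in one year -> stopover
  v2 <- visit_row("a", 30, -80, "2015-08-01", 1)
  s2 <- classify_sites(cluster_visits(v2), criteria = crit, n_population = 10)
  expect_equal(s2$label, "stopover")
  # long stay but short onward leg -> not staging; too long for stopover
  v3 <- rbind(visit_row("a", 40.0, -75.0, "2015-08-01", 10),
              visit_row("b", 40.0, -75.1, "2016-08-01", 10))
  itin3 <- rbind(v3[, c("animal_id", "lat", "lon", "start")],
                 tibble::tibble(animal_id = c("a", "b"), lat = 43, lon = -74,
                                start = utc(c("2015-09-15", "2016-09-15"))))
  s3 <- classify_sites(cluster_visits(v3), itinerary = itin3, criteria = crit,
                       n_population = 10)
  expect_equal(s3$label, "unclassified")
  # missing itinerary errors with the animal named
  expect_error(classify_sites(cluster_visits(v1), itinerary = itin[1, ],
                              criteria = crit), "b")
})

test_that("labels partition the clusters", {
  withr::with_seed(42, {
    v <- do.call(rbind, lapply(1:12, function(k) {
      visit_row(paste0("a", k %% 4), runif(1, 0, 60), runif(1, -100, -50),
                sprintf("2015-08-%02d", k), runif(1, 0.5, 30))
    }))
    s <- classify_sites(cluster_visits(v), n_population = 4)
    expect_true(all(s$label %in% c("staging", "stopover", "unclassified")))
    expect_equal(nrow(s), length(unique(cluster_visits(v)$site_id)))
  })
})

test_that("raising the onward-leg threshold never creates new staging sites", {
  withr::with_seed(43, {
    v <- do.call(rbind, lapply(1:10, function(k) {
      visit_row(paste0("a", k %% 3), runif(1, 0, 60), runif(1, -100, -50),
                sprintf("2015-08-%02d", k), runif(1, 3, 25))
    }))
    cl <- cluster_visits(v)
    for (thr in c(500, 1000, 2000, 4000)) {
      s_lo <- classify_sites(cl, criteria = site_criteria(min_next_leg_km = thr),
                             n_population = 3)
      s_hi <- classify_sites(cl, criteria = site_criteria(min_next_leg_km = thr * 2),
                             n_population = 3)
      was_staging <- s_lo$site_id[s_lo$label == "staging"]
      now_staging <- s_hi$site_id[s_hi$label == "staging"]
      expect_true(all(now_staging %in% was_staging))
    }
  })
})

test_that("stopovers map to their upstream staging area by recency and vote", {
  v <- rbind(
    visit_row("a", 47.3, -62.0, "2015-08-01", 20),   # staging A
    visit_row("b", 47.4, -62.1, "2015-08-01", 20),
    visit_row("c", 47.2, -61.9, "2015-08-01", 20),
    visit_row("a", 58.5, -93.0, "2015-07-01", 15),   # staging B (earlier)
    visit_row("b", 58.6, -93.1, "2015-07-01", 15),
    visit_row("c", 58.4, -92.9, "2015-07-01", 15),
    visit_row("a", 30.0, -70.0, "2015-08-25", 1),    # stopover after A
    visit_row("b", 30.1, -70.1, "2015-08-26", 1),
    visit_row("c", 30.0, -70.1, "2015-07-10", 1)     # this one came after B
  )
  cl <- cluster_visits(v)
  itin <- rbind(cl[, c("animal_id", "lat", "lon", "start")],
                tibble::tibble(animal_id = c("a", "b", "c"), lat = 1, lon = -48,
                               start = utc(rep("2015-09-20", 3))))
  s <- classify_sites(cl, itinerary = itin,
                      criteria = site_criteria(min_population_fraction = 0.5),
                      n_population = 3)
  s <- associate_stopovers(cl, s)
  stag_a <- s$site_id[s$label == "staging" & abs(s$lat - 47.3) < 1]
  stop_row <- s[s$label == "stopover" & abs(s$lat - 30) < 1, ]
  expect_equal(stop_row$upstream_site, stag_a)  # 2 votes A vs 1 vote B
  expect_false(stop_row$origin_flagged)
  # a stopover before any staging is origin-flagged
  v0 <- visit_row("z", 20, -60, "2015-06-01", 1)
  cl0 <- cluster_visits(v0)
  s0 <- classify_sites(cl0, n_population = 1)
  s0 <- associate_stopovers(cl0, s0)
  expect_true(s0$origin_flagged)
  expect_true(is.na(s0$upstream_site))
})

test_that("site fidelity counts repeat-year reuse", {
  # 26 birds using one staging area for three consecutive years: the 2015 and
  # 2016 uses are 52 repeat-year events
  ev <- tibble::tibble(animal_id = rep(sprintf("w%02d", 1:26), each = 3),
                       site_id = 1L, season = "autumn",
                       year = rep(2015:2017, 26))
  cov <- unique(ev[, c("animal_id", "season", "year")])
  f_all <- site_fidelity(ev, cov)
  expect_equal(f_all$n_events, 52)
  expect_equal(f_all$proportion, 1)
  # one bird overflies the area in its final year: exactly one exception
  ev2 <- ev[!(ev$animal_id == "w01" & ev$year == 2017L), ]
  f <- site_fidelity(ev2, cov)
  expect_equal(f$n_events, 52)
  expect_equal(f$n_consistent, 51)
  expect_equal(round(100 * f$proportion), 98)
  # 10 events, 3 switches -> 0.7
  ev3 <- tibble::tibble(animal_id = rep(sprintf("x%02d", 1:10), each = 2),
                        site_id = rep(1L, 20), season = "spring",
                        year = rep(c(2015L, 2016L), 10))
  ev3$site_id[ev3$year == 2016L & ev3$animal_id %in% c("x01", "x02", "x03")] <- 2L
  f3 <- site_fidelity(ev3)
  expect_equal(f3$proportion, 0.7)
  # no repeat-year animals: undefined, not zero
  solo <- tibble::tibble(animal_id = "y1", site_id = 1L, season = "autumn",
                         year = 2015L)
  expect_message(f0 <- site_fidelity(solo), "undefined")
  expect_true(is.na(f0$proportion))
})

test_that("fidelity is invariant to site relabelling and stays in [0, 1]", {
  ev <- tibble::tibble(animal_id = rep(c("a", "b"), each = 2),
                       site_id = c(3L, 3L, 7L, 9L), season = "autumn",
                       year = rep(c(2015L, 2016L), 2))
  f1 <- site_fidelity(ev)
  ev2 <- ev; ev2$site_id <- match(ev2$site_id, unique(ev2$site_id))
  f2 <- site_fidelity(ev2)
  expect_equal(f1$proportion, f2$proportion)
  expect_gte(f1$proportion, 0); expect_lte(f1$proportion, 1)
})
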