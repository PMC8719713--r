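# Synthetic annual-cycle telemetry with known ground truth. The generator is
# schedule-driven: per-individual season-transition dates are drawn around the
# population means, the true path is a great-circle polyline through route
# waypoints with staging stays and Poisson-sampled unplanned stopovers, and
# staging/stopover stays are rescaled so flights plus stays exactly fill the
# drawn season span. The path is then observed through the transmitter duty
# cycle with location-class-dependent positional error.

#' Construct a population schedule
#'
#' @param name Population label.
#' @param breeding,winter Named numeric `c(lat =, lon =)` territory centroids.
#' @param mean_dates List with elements `breeding_arrival`,
#'   `autumn_departure`, `winter_arrival`, `spring_departure`, each
#'   `c(doy =, sd =)`: mean day-of-year and between-individual SD in days.
#' @param autumn_leg,spring_leg Data frames describing the route from origin
#'   to destination territory, one row per intermediate point with columns
#'   `lat`, `lon`, `stay_mean_d`, `stay_sd_d`, `site` (`NA` site and zero stay
#'   for pure shaping waypoints).
#' @param stopover_rate Named vector `c(autumn =, spring =)`: expected
#'   unplanned stopovers per migration leg.
#' @return A list of class `flyway_schedule`.
#' @export
population_schedule <- function(name, breeding, winter, mean_dates,
                                autumn_leg, spring_leg,
                                stopover_rate = c(autumn = 1.3, spring = 2.4)) {
  stopifnot(all(c("breeding_arrival", "autumn_departure", "winter_arrival",
                  "spring_departure") %in% names(mean_dates)))
  for (leg in list(autumn_leg, spring_leg)) {
    stopifnot(all(leg$stay_mean_d >= 0), all(leg$stay_sd_d >= 0))
  }
  structure(list(name = name, breeding = breeding, winter = winter,
                 mean_dates = mean_dates, autumn_leg = tibble::as_tibble(autumn_leg),
                 spring_leg = tibble::as_tibble(spring_leg),
                 stopover_rate = stopover_rate),
            class = "flyway_schedule")
}

leg_row <- function(lat, lon, stay_mean_d = 0, stay_sd_d = 0, site = NA_character_) {
  tibble::tibble(lat = lat, lon = lon, stay_mean_d = stay_mean_d,
                 stay_sd_d = stay_sd_d, site = site)
}

#' Built-in population schedules
#'
#' Two presets emulating boreal-breeding whimbrel populations on the Western
#' Atlantic Flyway: a western (Mackenzie Delta) population making a long loop
#' migration with autumn staging on the Beaufort Sea, Hudson Bay and Atlantic
#' Canada and spring staging on the Gulf Coast, and an eastern (Hudson Bay)
#' population using the same Atlantic route in both directions with staging on
#' Hudson Bay and the South Atlantic coast. Transition-date means/SDs, staging
#' stays and per-leg stopover rates follow the published population summaries;
#' the route geography is synthetic, with shaping waypoints chosen so each
#' leg's great-circle length matches the published mean migration distances.
#'
#' @param name `"mackenzie_delta"` or `"hudson_bay"`.
#' @return A [population_schedule()].
#' @export
preset_schedule <- function(name = c("mackenzie_delta", "hudson_bay")) {
  name <- match.arg(name)
  winter_md <- c(lat = 1.0, lon = -48.0)
  if (name == "mackenzie_delta") {
    population_schedule(
      name = "mackenzie_delta",
      breeding = c(lat = 69.372, lon = -134.894),
      winter = winter_md,
      mean_dates = list(
        breeding_arrival = c(doy = 151, sd = 2.5 * sqrt(18)),   # 31 May
        autumn_departure = c(doy = 188, sd = 2.0 * sqrt(26)),   # 7 July
        winter_arrival   = c(doy = 242, sd = 3.3 * sqrt(25)),   # 30 August
        spring_departure = c(doy = 96,  sd = 1.6 * sqrt(21))    # 6 April
      ),
      autumn_leg = rbind(
        leg_row(70.2, -127.5, 7.6, 1.25 * sqrt(17), "Beaufort Sea"),
        leg_row(70.8, -115.0), leg_row(68.5, -100.0), leg_row(64.0, -94.5),
        leg_row(58.5, -93.0, 18.0, 2.58 * sqrt(16), "Hudson Bay"),
        leg_row(51.5, -70.5),
        leg_row(47.3, -62.0, 19.3, 2.52 * sqrt(19), "Atlantic Canada"),
        leg_row(33.5, -42.0), leg_row(14.5, -39.5)
      ),
      spring_leg = rbind(
        leg_row(5.0, -53.5), leg_row(9.5, -61.0), leg_row(11.5, -69.5),
        leg_row(15.0, -81.5), leg_row(21.5, -91.0),
        leg_row(29.3, -94.7, 25.0, 2.51 * sqrt(16), "Gulf Coast"),
        leg_row(34.0, -101.5), leg_row(41.0, -106.0), leg_row(49.5, -112.5),
        leg_row(58.0, -120.5), leg_row(65.0, -130.5)
      ),
      stopover_rate = c(autumn = 1.4, spring = 2.4)
    )
  } else {
    population_schedule(
      name = "hudson_bay",
      breeding = c(lat = 57.0, lon = -92.5),
      winter = winter_md,
      mean_dates = list(
        breeding_arrival = c(doy = 154, sd = 4.24 * sqrt(21)),  # 3 June
        autumn_departure = c(doy = 203, sd = 3.0 * sqrt(17)),   # 22 July
        winter_arrival   = c(doy = 261, sd = 4.1 * sqrt(15)),   # 18 September
        spring_departure = c(doy = 110, sd = 2.8 * sqrt(10))    # 20 April
      ),
      autumn_leg = rbind(
        leg_row(58.5, -93.0, 15.5, 3.66 * sqrt(7), "Hudson Bay"),
        leg_row(50.0, -72.0), leg_row(41.5, -73.5),
        leg_row(33.0, -79.5, 28.4, 1.79 * sqrt(13), "South Atlantic"),
        leg_row(23.0, -64.0), leg_row(12.5, -57.5), leg_row(5.5, -51.0)
      ),
      spring_leg = rbind(
        leg_row(6.5, -53.0), leg_row(14.0, -61.5), leg_row(25.0, -69.5),
        leg_row(33.0, -79.5, 29.2, 3.96 * sqrt(10), "South Atlantic"),
        leg_row(41.5, -76.0), leg_row(45.5, -83.0), leg_row(49.5, -90.5)
      ),
      stopover_rate = c(autumn = 2.8, spring = 1.2)
    )
  }
}

#' Movement and observation configuration for the generator
#'
#' @param flight_speed_mps Mean and SD of the migratory flight speed (m/s);
#'   defaults 14.7 and 2.01.
#' @param territory_radius_km Radius of within-territory/staging wander (km).
#' @param stopover_rate Optional `c(autumn =, spring =)` override of the
#'   schedule's expected unplanned stopovers per leg.
#' @param stopover_stay_mean_d Mean of the exponential stopover stay (days).
#' @param lc_mix Probability over location classes LC3..LCB (must sum to 1).
#' @param lc_error_m Per-class circular positional error scale (metres, RMS).
#' @param duty_cycle `c(off_h =, on_h =)` transmitter schedule; `off_h = 0`
#'   means always on.
#' @param fixes_per_on `list(mean =, max =)`: fixes per on-period are
#'   `1 + Poisson(mean - 1)` truncated at `max`; add `dispersion = "fixed"`
#'   for exactly `round(mean)` fixes per on-period.
#' @param fix_spacing `"uniform"` (random times within each on-window) or
#'   `"regular"` (evenly spaced).
#' @param error_scale Multiplier on all positional error scales (0 =
#'   noise-free observation).
#' @return A list of class `flyway_movement_config`.
#' @export
movement_config <- function(flight_speed_mps = c(mean = 14.7, sd = 2.01),
                            territory_radius_km = 5,
                            stopover_rate = NULL,
                            stopover_stay_mean_d = 2,
                            lc_mix = c(LC3 = 0.18, LC2 = 0.25, LC1 = 0.27,
                                       LC0 = 0.12, LCA = 0.10, LCB = 0.08),
                            lc_error_m = c(LC3 = 100, LC2 = 250, LC1 = 700,
                                           LC0 = 1500, LCA = 3000, LCB = 5000),
                            duty_cycle = c(off_h = 48, on_h = 10),
                            fixes_per_on = list(mean = 5.48, max = 34),
                            fix_spacing = c("uniform", "regular"),
                            error_scale = 1) {
  if (abs(sum(lc_mix) - 1) > 1e-8) stop("lc_mix must sum to 1")
  stopifnot(all(lc_error_m >= 0), error_scale >= 0,
            duty_cycle[["on_h"]] > 0, duty_cycle[["off_h"]] >= 0,
            fixes_per_on$mean >= 1, fixes_per_on$max >= 1)
  structure(list(flight_speed_mps = flight_speed_mps,
                 territory_radius_km = territory_radius_km,
                 stopover_rate = stopover_rate,
                 stopover_stay_mean_d = stopover_stay_mean_d,
                 lc_mix = lc_mix, lc_error_m = lc_error_m,
                 duty_cycle = duty_cycle, fixes_per_on = fixes_per_on,
                 fix_spacing = match.arg(fix_spacing),
                 error_scale = error_scale),
            class = "flyway_movement_config")
}

date_instant <- function(year, doy) {
  as.POSIXct(as.Date(sprintf("%d-01-01", year)), tz = "UTC") + (doy - 1) * 86400
}

# Build one migration leg's timeline. points: origin + intermediates + dest
# with sampled stays (days). Returns segments, true distance, and visits.
build_leg <- function(points, t_dep, t_arr, v_kmh, n_stopovers,
                      stopover_stay_mean_d, season) {
  # insert unplanned stopovers at random positions along flight segments
  if (n_stopovers > 0) {
    nseg <- nrow(points) - 1
    d <- great_circle_km(points$lat[-nrow(points)], points$lon[-nrow(points)],
                         points$lat[-1], points$lon[-1])
    # unplanned stops go on long flight segments only, at least 150 km from
    # either endpoint, so they never coincide with a staging site or territory
    wt <- ifelse(d >= 400, d, 0)
    if (all(wt == 0)) wt <- d
    seg <- sample.int(nseg, n_stopovers, replace = TRUE, prob = wt)
    lo <- pmin(0.4, 150 / d[seg])
    frac <- stats::runif(n_stopovers, lo, 1 - lo)
    stay <- stats::rexp(n_stopovers, 1 / stopover_stay_mean_d)
    ins <- data.frame(seg = seg, frac = frac, stay = stay)
    ins <- ins[order(ins$seg, ins$frac), , drop = FALSE]
    out <- points[1, , drop = FALSE]
    for (s in seq_len(nseg)) {
      sub <- ins[ins$seg == s, , drop = FALSE]
      if (nrow(sub)) {
        pos <- gc_interpolate(points$lat[s], points$lon[s],
                              points$lat[s + 1], points$lon[s + 1], sub$frac)
        for (r in seq_len(nrow(sub))) {
          out <- rbind(out, leg_row(as.numeric(pos[r, "lat"]),
                                    as.numeric(pos[r, "lon"]),
                                    sub$stay[r], 0, NA_character_))
        }
      }
      out <- rbind(out, points[s + 1, , drop = FALSE])
    }
    points <- out
  }
  n <- nrow(points)
  d <- great_circle_km(points$lat[-n], points$lon[-n],
                       points$lat[-1], points$lon[-1])
  flight_h <- sum(d) / v_kmh
  span_h <- as.numeric(t_arr - t_dep, units = "hours")
  stays_h <- points$stay_mean_d * 24  # already sampled values stored here
  stays_h[c(1, n)] <- 0
  tot_stay <- sum(stays_h)
  if (span_h < flight_h) {
    stop("season span (", round(span_h / 24, 1), " d) shorter than flight time (",
         round(flight_h / 24, 1), " d): staging stays exceed the season length")
  }
  scale <- if (tot_stay > 0) (span_h - flight_h) / tot_stay else 1
  stays_h <- stays_h * scale
  segs <- list(); visits <- list()
  t <- as.numeric(t_dep)
  for (i in seq_len(n - 1)) {
    fly_s <- d[i] / v_kmh * 3600
    segs[[length(segs) + 1]] <- data.frame(
      t0 = t, t1 = t + fly_s, type = "flight",
      lat0 = points$lat[i], lon0 = points$lon[i],
      lat1 = points$lat[i + 1], lon1 = points$lon[i + 1],
      site = NA_character_, stringsAsFactors = FALSE)
    t <- t + fly_s
    if (i + 1 < n && stays_h[i + 1] > 0) {
      stay_s <- stays_h[i + 1] * 3600
      segs[[length(segs) + 1]] <- data.frame(
        t0 = t, t1 = t + stay_s, type = "stationary",
        lat0 = points$lat[i + 1], lon0 = points$lon[i + 1],
        lat1 = points$lat[i + 1], lon1 = points$lon[i + 1],
        site = points$site[i + 1], stringsAsFactors = FALSE)
      visits[[length(visits) + 1]] <- data.frame(
        season = season,
        site = ifelse(is.na(points$site[i + 1]), "stopover", points$site[i + 1]),
        kind = ifelse(is.na(points$site[i + 1]), "stopover", "staging"),
        lat = points$lat[i + 1], lon = points$lon[i + 1],
        start = t, end = t + stay_s, stringsAsFactors = FALSE)
      t <- t + stay_s
    }
  }
  list(segments = do.call(rbind, segs), distance_km = sum(d),
       visits = if (length(visits)) do.call(rbind, visits) else NULL)
}

sample_leg_points <- function(leg) {
  pts <- leg
  pts$stay_mean_d <- pmax(0.25, stats::rnorm(nrow(pts), leg$stay_mean_d, leg$stay_sd_d)) *
    (leg$stay_mean_d > 0)
  pts
}

#' Generate one animal's synthetic annual-cycle track with ground truth
#'
#' Builds a continuous true path (territory residency -> great-circle
#' migration legs at a sampled flight speed with staging stays and unplanned
#' stopovers -> next territory), then observes it through the duty cycle with
#' per-class positional error. Deterministic given `seed`.
#'
#' @param schedule A [population_schedule()].
#' @param move A [movement_config()].
#' @param seed Integer seed.
#' @param animal_id Identifier for the track.
#' @param n_years Number of consecutive annual cycles.
#' @param start_year First calendar year (default 2015).
#' @param end_margin_d Days of residency appended after the final breeding
#'   arrival (default 20).
#' @return A list with `track` (a [track()]) and `truth` (class
#'   `flyway_truth`: `events`, `legs`, `visits` tibbles).
#' @export
generate_annual_track <- function(schedule, move, seed,
                                  animal_id = paste0(schedule$name, "_01"),
                                  n_years = 1, start_year = 2015,
                                  end_margin_d = 20) {
  withr::with_seed(seed, {
    md <- schedule$mean_dates
    rate <- if (!is.null(move$stopover_rate)) move$stopover_rate else schedule$stopover_rate
    # draw the full multi-year schedule, rejecting infeasible draws
    for (attempt in 1:200) {
      ok <- TRUE
      v_mps <- min(22, max(8, stats::rnorm(1, move$flight_speed_mps[["mean"]],
                                           move$flight_speed_mps[["sd"]])))
      v_kmh <- v_mps * 3.6
      yrs <- lapply(seq_len(n_years), function(y) {
        yy <- start_year + y - 1
        list(ba = date_instant(yy, stats::rnorm(1, md$breeding_arrival[["doy"]],
                                                md$breeding_arrival[["sd"]])),
             ad = date_instant(yy, stats::rnorm(1, md$autumn_departure[["doy"]],
                                                md$autumn_departure[["sd"]])),
             wa = date_instant(yy, stats::rnorm(1, md$winter_arrival[["doy"]],
                                                md$winter_arrival[["sd"]])),
             sd = date_instant(yy + 1, stats::rnorm(1, md$spring_departure[["doy"]],
                                                    md$spring_departure[["sd"]])))
      })
      aut_d <- path_dist(rbind(as_point(schedule$breeding), schedule$autumn_leg[, c("lat", "lon")],
                               as_point(schedule$winter)))
      spr_d <- path_dist(rbind(as_point(schedule$winter), schedule$spring_leg[, c("lat", "lon")],
                               as_point(schedule$breeding)))
      for (y in seq_len(n_years)) {
        s <- yrs[[y]]
        if (as.numeric(s$ad - s$ba, units = "days") < 16) ok <- FALSE
        if (as.numeric(s$wa, units = "days") - as.numeric(s$ad, units = "days") < 0) ok <- FALSE
        if (as.numeric(s$wa - s$ad, units = "days") < aut_d / v_kmh / 24 + 2) ok <- FALSE
        ba_next <- if (y < n_years) yrs[[y + 1]]$ba else
          date_instant(start_year + n_years, md$breeding_arrival[["doy"]])
        if (as.numeric(ba_next - s$sd, units = "days") < spr_d / v_kmh / 24 + 2) ok <- FALSE
        if (as.numeric(s$sd - s$wa, units = "days") < 30) ok <- FALSE
      }
      if (ok) break
      if (attempt == 200) stop("could not draw a feasible schedule: staging stays/flights exceed season spans")
    }
    # assemble the true timeline
    segs <- list(); ev <- list(); legs <- list(); visits <- list()
    stationary_seg <- function(t0, t1, pt, site) {
      data.frame(t0 = as.numeric(t0), t1 = as.numeric(t1), type = "stationary",
                 lat0 = pt[["lat"]], lon0 = pt[["lon"]],
                 lat1 = pt[["lat"]], lon1 = pt[["lon"]],
                 site = site, stringsAsFactors = FALSE)
    }
    for (y in seq_len(n_years)) {
      s <- yrs[[y]]
      yy <- start_year + y - 1
      segs[[length(segs) + 1]] <- stationary_seg(s$ba, s$ad, schedule$breeding, "breeding")
      aut_pts <- rbind(leg_row(schedule$breeding[["lat"]], schedule$breeding[["lon"]]),
                       sample_leg_points(schedule$autumn_leg),
                       leg_row(schedule$winter[["lat"]], schedule$winter[["lon"]]))
      aut <- build_leg(aut_pts, s$ad, s$wa, v_kmh,
                       stats::rpois(1, rate[["autumn"]]), move$stopover_stay_mean_d,
                       "autumn")
      segs[[length(segs) + 1]] <- aut$segments
      ba_next <- if (y < n_years) yrs[[y + 1]]$ba else NULL
      if (is.null(ba_next)) {
        ba_next_draw <- date_instant(yy + 1, stats::rnorm(1, md$breeding_arrival[["doy"]],
                                                          md$breeding_arrival[["sd"]]))
        # keep the final spring feasible
        min_ba <- s$sd + (path_dist(rbind(as_point(schedule$winter),
                                          schedule$spring_leg[, c("lat", "lon")],
                                          as_point(schedule$breeding))) / v_kmh + 24) * 3600
        ba_next <- max(ba_next_draw, min_ba)
      }
      segs[[length(segs) + 1]] <- stationary_seg(s$wa, s$sd, schedule$winter, "winter")
      spr_pts <- rbind(leg_row(schedule$winter[["lat"]], schedule$winter[["lon"]]),
                       sample_leg_points(schedule$spring_leg),
                       leg_row(schedule$breeding[["lat"]], schedule$breeding[["lon"]]))
      spr <- build_leg(spr_pts, s$sd, ba_next, v_kmh,
                       stats::rpois(1, rate[["spring"]]), move$stopover_stay_mean_d,
                       "spring")
      segs[[length(segs) + 1]] <- spr$segments
      ev[[length(ev) + 1]] <- data.frame(
        year = yy,
        kind = c("autumn_departure", "winter_arrival", "winter_departure",
                 "breeding_arrival"),
        time = as.POSIXct(c(s$ad, s$wa, s$sd, ba_next), tz = "UTC"),
        stringsAsFactors = FALSE)
      legs[[length(legs) + 1]] <- data.frame(
        year = yy, season = c("autumn", "spring"),
        depart = as.POSIXct(c(s$ad, s$sd), tz = "UTC"),
        arrive = as.POSIXct(c(s$wa, ba_next), tz = "UTC"),
        distance_km = c(aut$distance_km, spr$distance_km),
        stringsAsFactors = FALSE)
      for (lv in list(aut$visits, spr$visits)) {
        if (!is.null(lv)) {
          lv$year <- yy
          visits[[length(visits) + 1]] <- lv
        }
      }
      if (y == n_years) {
        segs[[length(segs) + 1]] <- stationary_seg(
          ba_next, ba_next + end_margin_d * 86400, schedule$breeding, "breeding")
      }
    }
    timeline <- do.call(rbind, segs)
    truth <- structure(list(
      events = tibble::as_tibble(do.call(rbind, ev)),
      legs = tibble::as_tibble(do.call(rbind, legs)),
      visits = tibble::as_tibble(do.call(rbind, visits))
    ), class = "flyway_truth")
    if (!is.null(truth$visits) && nrow(truth$visits)) {
      truth$visits$start <- as.POSIXct(truth$visits$start, origin = "1970-01-01", tz = "UTC")
      truth$visits$end <- as.POSIXct(truth$visits$end, origin = "1970-01-01", tz = "UTC")
    }
    trk <- observe_timeline(timeline, move, animal_id)
    list(track = trk, truth = truth)
  })
}

as_point <- function(p) tibble::tibble(lat = p[["lat"]], lon = p[["lon"]])

path_dist <- function(pts) {
  n <- nrow(pts)
  sum(great_circle_km(pts$lat[-n], pts$lon[-n], pts$lat[-1], pts$lon[-1]))
}

# True position at time t (seconds since epoch) from the timeline.
timeline_position <- function(timeline, t) {
  i <- findInterval(t, timeline$t0)
  i <- pmin(pmax(i, 1), nrow(timeline))
  lat <- numeric(length(t)); lon <- numeric(length(t))
  for (k in seq_along(t)) {
    seg <- timeline[i[k], ]
    if (seg$type == "stationary" || seg$t1 == seg$t0) {
      lat[k] <- seg$lat0; lon[k] <- seg$lon0
    } else {
      f <- (t[k] - seg$t0) / (seg$t1 - seg$t0)
      p <- gc_interpolate(seg$lat0, seg$lon0, seg$lat1, seg$lon1, min(1, max(0, f)))
      lat[k] <- p[1, "lat"]; lon[k] <- p[1, "lon"]
    }
  }
  cbind(lat = lat, lon = lon)
}

# Observe a timeline through the duty cycle with wander and class error.
observe_timeline <- function(timeline, move, animal_id) {
  t_start <- timeline$t0[1]
  t_end <- timeline$t1[nrow(timeline)]
  off_s <- move$duty_cycle[["off_h"]] * 3600
  on_s <- move$duty_cycle[["on_h"]] * 3600
  cycle_s <- off_s + on_s
  n_cycles <- ceiling((t_end - t_start) / cycle_s)
  times <- numeric(0)
  for (k in seq_len(n_cycles)) {
    w0 <- t_start + (k - 1) * cycle_s + off_s
    w1 <- min(w0 + on_s, t_end)
    if (w0 >= t_end) break
    n_fix <- if (identical(move$fixes_per_on$dispersion, "fixed")) {
      round(move$fixes_per_on$mean)
    } else {
      min(move$fixes_per_on$max,
          1 + stats::rpois(1, max(0, move$fixes_per_on$mean - 1)))
    }
    tt <- if (move$fix_spacing == "regular") {
      w0 + (seq_len(n_fix) - 1) * (w1 - w0) / n_fix
    } else {
      sort(stats::runif(n_fix, w0, w1))
    }
    times <- c(times, tt)
  }
  times <- round(times)
  times <- times[!duplicated(times)]
  if (!length(times)) stop("duty cycle produced no fixes")
  pos <- timeline_position(timeline, times)
  # Within-territory/staging wander: independent per-fix draws from a
  # central-place commuting mixture — the bird is either near its roost/nest
  # or out at foraging range. The displacement distribution has its
  # mean + 2 SD point (~1.5 r) well above the maximum displacement (r), so
  # territory fixes never trip the breakout rule: departures are abrupt, with
  # no false starts.
  seg_idx <- pmin(pmax(findInterval(times, timeline$t0), 1), nrow(timeline))
  is_stat <- timeline$type[seg_idx] == "stationary"
  out_trip <- stats::runif(length(times)) < 0.65
  r <- move$territory_radius_km *
    ifelse(out_trip, stats::runif(length(times), 0.92, 1),
           0.05 * sqrt(stats::runif(length(times))))
  th <- stats::runif(length(times), 0, 2 * pi)
  dlat_w <- ifelse(is_stat, r * cos(th) / 111.195, 0)
  dlon_w <- ifelse(is_stat, r * sin(th) / (111.195 * cos(pos[, "lat"] * pi / 180)), 0)
  lc <- sample(names(move$lc_mix), length(times), replace = TRUE,
               prob = move$lc_mix)
  err_km <- move$lc_error_m[lc] / 1000 * move$error_scale
  ex <- stats::rnorm(length(times), 0, err_km / sqrt(2))
  ey <- stats::rnorm(length(times), 0, err_km / sqrt(2))
  lat <- pos[, "lat"] + dlat_w + ey / 111.195
  lon <- pos[, "lon"] + dlon_w + ex / (111.195 * cos(pos[, "lat"] * pi / 180))
  fixes <- tibble::tibble(
    timestamp = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
    lat = round(pmin(90, pmax(-90, lat)), 6),
    lon = round(lon, 6),
    lc = lc,
    error_radius_m = unname(move$lc_error_m[lc])
  )
  track(animal_id, fixes,
        duty_cycle = list(off_h = move$duty_cycle[["off_h"]],
                          on_h = move$duty_cycle[["on_h"]]))
}

#' Generate a cohort of synthetic animals
#'
#' Draws `n` independent animals around the schedule means; reproducible per
#' seed (animal `i` uses derived seed `seed + 131 * i`).
#'
#' @inheritParams generate_annual_track
#' @param n Number of animals (>= 0).
#' @return A list with `tracks` (named list of tracks) and `truth` (named
#'   list of truth logs).
#' @export
generate_cohort <- function(n, schedule, move, seed, n_years = 1,
                            start_year = 2015) {
  stopifnot(n >= 0)
  tracks <- list(); truth <- list()
  ids <- sprintf("%s_%02d", schedule$name, seq_len(n))
  for (i in seq_len(n)) {
    g <- generate_annual_track(schedule, move, seed = seed + 131L * i,
                               animal_id = ids[i], n_years = n_years,
                               start_year = start_year)
    tracks[[ids[i]]] <- g$track
    truth[[ids[i]]] <- g$truth
  }
  list(tracks = tracks, truth = truth)
}
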