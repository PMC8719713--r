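# Delineating the annual cycle: territory centroids, breakout departures and
# arrivals (mean + 2 SD displacement rule), flight-speed event-time
# interpolation, stationary periods, and the four-season partition.

#' Fit a territory model (centroid + displacement statistics)
#'
#' The centroid is the arithmetic mean latitude and the circular mean
#' longitude; displacement statistics are over great-circle distances from
#' each fix to the centroid. Departures and arrivals are declared when a fix
#' exceeds `mean_disp_km + 2 * sd_disp_km` from the centroid.
#'
#' @param fixes A data frame of fixes (`lat`, `lon` columns), at least 3 rows.
#' @return A list of class `flyway_territory` with `centroid` (named lat/lon),
#'   `mean_disp_km`, `sd_disp_km`, `n_fixes`.
#' @export
fit_territory_model <- function(fixes) {
  if (nrow(fixes) < 3) stop("territory model needs at least 3 fixes")
  centroid <- c(lat = mean(fixes$lat), lon = circular_mean_lon(fixes$lon))
  disp <- great_circle_km(fixes$lat, fixes$lon, centroid["lat"], centroid["lon"])
  structure(list(centroid = centroid,
                 mean_disp_km = mean(disp),
                 sd_disp_km = stats::sd(disp),
                 n_fixes = nrow(fixes)),
            class = "flyway_territory")
}

territory_threshold_km <- function(model) {
  model$mean_disp_km + 2 * model$sd_disp_km
}

new_event <- function(kind, season, observed_fix, event_time, interpolated) {
  structure(list(kind = kind, season = season, observed_fix = observed_fix,
                 event_time = event_time, interpolated = interpolated),
            class = "flyway_event")
}

#' Detect the first breakout movement from a territory
#'
#' Scans fixes after `from_time` for the first fix whose displacement from the
#' territory centroid exceeds the mean + 2 SD threshold, confirmed either by a
#' net displacement beyond `confirm_km`, or by the next fix also exceeding the
#' threshold while gaining at least `confirm_gain_km` of displacement
#' (sustained outward movement). The confirmation guard makes a single noisy
#' outlier followed by a return (a "false start") a non-event, and keeps
#' threshold-grazing territory commutes from ever registering as departures.
#'
#' @param trk A [track()] (quality-filtered).
#' @param model A [fit_territory_model()] result.
#' @param from_time POSIXct; only fixes strictly after this instant are
#'   scanned.
#' @param kind `"departure"` or `"arrival"` label for the returned event.
#' @param confirm_km Net displacement accepted in place of a confirming next
#'   fix (default 100 km).
#' @param confirm_gain_km Minimum displacement gained by the confirming next
#'   fix (default 5 km).
#' @return A `flyway_event` (with `event_time` set to the observed fix time,
#'   not yet interpolated), or `NULL` if no breakout occurs.
#' @export
detect_breakout <- function(trk, model, from_time, kind = "departure",
                            confirm_km = 100, confirm_gain_km = 5) {
  fx <- trk$fixes[trk$fixes$timestamp > from_time, , drop = FALSE]
  if (!nrow(fx)) return(NULL)
  thr <- territory_threshold_km(model)
  disp <- great_circle_km(fx$lat, fx$lon, model$centroid["lat"], model$centroid["lon"])
  beyond <- disp > thr
  for (i in which(beyond)) {
    confirmed <- disp[i] > confirm_km ||
      (i < nrow(fx) && beyond[i + 1] && disp[i + 1] >= disp[i] + confirm_gain_km)
    if (confirmed) {
      return(new_event(kind, NA_character_, fx[i, , drop = FALSE],
                       fx$timestamp[i], interpolated = FALSE))
    }
  }
  NULL
}

#' Interpolate an event time with the flight-speed rule
#'
#' The apparent speed between the event's observed fix and the adjacent fix is
#' compared with `mean_speed - 2 * sd_speed`. A slower apparent speed implies
#' the transition happened inside an observation gap, and the event time is
#' offset from the in-flight fix by great-circle distance divided by the mean
#' flight speed; otherwise the observed time stands.
#'
#' For a departure the observed fix is the breakout (first in-flight) fix and
#' `neighbor_fix` the last pre-departure fix: the event time is moved earlier.
#' For an arrival the observed fix is the first on-territory fix and
#' `neighbor_fix` the last in-flight fix: the event time is
#' `neighbor + distance / mean_speed`.
#'
#' @param event A `flyway_event`.
#' @param neighbor_fix A one-row fix data frame adjacent to the event fix.
#' @param mean_speed_mps,sd_speed_mps Population mean flight speed and its
#'   between-measurement SD (defaults 14.7 and 2.01 m/s, i.e. threshold
#'   10.68 m/s).
#' @return The event with `event_time` and `interpolated` updated.
#' @export
interpolate_event_time <- function(event, neighbor_fix,
                                   mean_speed_mps = 14.7, sd_speed_mps = 2.01) {
  ofix <- event$observed_fix
  d_km <- great_circle_km(ofix$lat, ofix$lon, neighbor_fix$lat, neighbor_fix$lon)
  dt_s <- abs(as.numeric(ofix$timestamp) - as.numeric(neighbor_fix$timestamp))
  if (dt_s == 0) {
    if (d_km > 0) stop("zero time separation with nonzero distance")
    return(event)
  }
  v_mps <- d_km * 1000 / dt_s
  threshold <- mean_speed_mps - 2 * sd_speed_mps
  if (v_mps < threshold) {
    offset_s <- d_km * 1000 / mean_speed_mps
    event$event_time <- if (event$kind == "departure") {
      ofix$timestamp - offset_s
    } else {
      neighbor_fix$timestamp + offset_s
    }
    event$interpolated <- TRUE
  } else {
    event$event_time <- if (event$kind == "departure") {
      ofix$timestamp
    } else {
      # still at flight speed across the gap: the arrival coincides with the
      # first on-territory fix
      ofix$timestamp
    }
    event$interpolated <- FALSE
  }
  event
}

#' Detect stationary periods along a track
#'
#' Maximal runs of consecutive fixes whose segment displacements are
#' site-scale (segment speed below `max_speed_kmh`, or a hop shorter than
#' `max_radius_km` — closely spaced fixes inside a site imply high apparent
#' speeds from positional error alone) and which remain within
#' `max_radius_km` of the running run centroid, kept when they span at least
#' `min_duration_h`. Runs are separated by flight fixes; local
#' roosting/foraging commutes within the radius stay in one run.
#'
#' @param trk A quality-filtered [track()].
#' @param max_speed_kmh Segment-speed ceiling within a run (default 5 km/h).
#' @param max_radius_km Radius around the run centroid (default 25 km).
#' @param min_duration_h Minimum run span to report (default 6 h).
#' @return A tibble with one row per stationary period: `animal_id`, `start`,
#'   `end`, `lat`, `lon` (centroid), `n_fixes`, `duration_d`.
#' @export
detect_stationary_periods <- function(trk, max_speed_kmh = 5,
                                      max_radius_km = 25, min_duration_h = 6) {
  fx <- trk$fixes
  empty <- tibble::tibble(animal_id = character(), start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"), lat = numeric(),
                          lon = numeric(), n_fixes = integer(), duration_d = numeric())
  n <- nrow(fx)
  if (n < 2) return(empty)
  d <- great_circle_km(fx$lat[-n], fx$lon[-n], fx$lat[-1], fx$lon[-1])
  dt_h <- diff(as.numeric(fx$timestamp)) / 3600
  slow <- (d / dt_h < max_speed_kmh) | (d < max_radius_km)
  runs <- list()
  i <- 1
  while (i <= n) {
    j <- i
    lat_sum <- fx$lat[i]; lon_sum <- fx$lon[i]
    while (j < n && slow[j]) {
      # candidate extension j+1; check it stays within the radius of the
      # running centroid
      c_lat <- lat_sum / (j - i + 1)
      c_lon <- lon_sum / (j - i + 1)
      if (great_circle_km(fx$lat[j + 1], fx$lon[j + 1], c_lat, c_lon) > max_radius_km) break
      j <- j + 1
      lat_sum <- lat_sum + fx$lat[j]; lon_sum <- lon_sum + fx$lon[j]
    }
    if (j > i) {
      runs[[length(runs) + 1]] <- c(i, j)
    }
    i <- j + 1
  }
  if (!length(runs)) return(empty)
  rows <- lapply(runs, function(r) {
    idx <- r[1]:r[2]
    span_h <- (as.numeric(fx$timestamp[r[2]]) - as.numeric(fx$timestamp[r[1]])) / 3600
    if (span_h < min_duration_h) return(NULL)
    tibble::tibble(animal_id = trk$animal_id,
                   start = fx$timestamp[r[1]], end = fx$timestamp[r[2]],
                   lat = mean(fx$lat[idx]), lon = circular_mean_lon(fx$lon[idx]),
                   n_fixes = length(idx), duration_d = span_h / 24)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Partition an animal-year into the four seasons
#'
#' Given the four ordered transition events (breeding departure, winter
#' arrival, winter departure, breeding arrival), returns season initiation
#' instants and durations in fractional days: autumn = [breeding departure,
#' winter arrival), winter = [winter arrival, winter departure), spring =
#' [winter departure, breeding arrival), breeding = the remainder of the
#' tracked span.
#'
#' @param events A list with elements `autumn_departure`, `winter_arrival`,
#'   `winter_departure`, `breeding_arrival`, each a `flyway_event` or POSIXct.
#' @param animal_id,population,year Optional labels.
#' @return A one-row tibble with initiation times and `*_duration_d` columns.
#' @export
delineate_seasons <- function(events, animal_id = NA_character_,
                              population = NA_character_, year = NA_integer_) {
  get_t <- function(e) {
    if (is.null(e)) return(as.POSIXct(NA, tz = "UTC"))
    if (inherits(e, "flyway_event")) e$event_time else e
  }
  t_ad <- get_t(events$autumn_departure)
  t_wa <- get_t(events$winter_arrival)
  t_wd <- get_t(events$winter_departure)
  t_ba <- get_t(events$breeding_arrival)
  ts <- c(autumn_departure = t_ad, winter_arrival = t_wa,
          winter_departure = t_wd, breeding_arrival = t_ba)
  ok <- !is.na(ts)
  if (sum(ok) >= 2) {
    tv <- ts[ok]
    if (any(diff(as.numeric(tv)) <= 0)) {
      bad <- which(diff(as.numeric(tv)) <= 0)[1]
      stop("events out of order: ", names(tv)[bad], " >= ", names(tv)[bad + 1])
    }
  }
  days <- function(a, b) (as.numeric(b) - as.numeric(a)) / 86400
  tibble::tibble(
    animal_id = animal_id, population = population, year = year,
    autumn_departure = t_ad, winter_arrival = t_wa,
    winter_departure = t_wd, breeding_arrival = t_ba,
    autumn_duration_d = days(t_ad, t_wa),
    winter_duration_d = days(t_wa, t_wd),
    spring_duration_d = days(t_wd, t_ba)
  )
}

#' Segment one annual-cycle track into transition events and seasons
#'
#' End-to-end segmentation: stationary periods are detected, periods at least
#' `min_territory_d` long are taken as breeding/winter territories, a
#' territory model is fitted on the first `territory_window_d` days of each
#' territory, departures are found by forward breakout scan and arrivals by
#' the first fix entering the next territory, and every event time is refined
#' with the flight-speed interpolation rule.
#'
#' @param trk A quality-filtered [track()] spanning (at least) breeding ->
#'   winter -> breeding.
#' @param territory_hints Optional data frame (`lat`, `lon`) of known breeding
#'   and winter territory regions (deployment knowledge, as in a field study
#'   where capture sites are known): stationary periods within
#'   `hint_radius_km` of a hint count as territories regardless of length.
#'   Without hints, only the duration rule applies, which cannot separate a
#'   short breeding residency from a long staging stay.
#' @param hint_radius_km Radius for matching periods to hints (default 120 km).
#' @param min_territory_d Minimum stationary-period length to call a territory
#'   (default 45 d; staging stays are shorter, winters and breeding residencies
#'   longer).
#' @param territory_window_d Days of residency used to fit each territory
#'   model (default 14).
#' @param mean_speed_mps,sd_speed_mps Flight-speed parameters for
#'   [interpolate_event_time()].
#' @param stationary_args List of overrides for [detect_stationary_periods()].
#' @return A list with `events` (named list of `flyway_event`s per transition,
#'   in chronological order), `cycles` (tibble from [delineate_seasons()], one
#'   row per tracked year), `territories`, and `stationary_periods`.
#' @export
segment_annual_cycle <- function(trk, territory_hints = NULL,
                                 hint_radius_km = 120,
                                 min_territory_d = 45,
                                 territory_window_d = 14,
                                 mean_speed_mps = 14.7, sd_speed_mps = 2.01,
                                 stationary_args = list()) {
  periods <- do.call(detect_stationary_periods, c(list(trk), stationary_args))
  if (!is.null(territory_hints) && nrow(periods)) {
    # deployment knowledge available: a territory is a stationary period in a
    # known breeding/winter region (duration alone cannot separate a short
    # breeding residency from a long staging stay)
    is_terr <- rep(FALSE, nrow(periods))
    for (h in seq_len(nrow(territory_hints))) {
      is_terr <- is_terr |
        great_circle_km(periods$lat, periods$lon,
                        territory_hints$lat[h], territory_hints$lon[h]) <= hint_radius_km
    }
  } else {
    is_terr <- periods$duration_d >= min_territory_d
  }
  terr <- periods[is_terr, , drop = FALSE]
  fx <- trk$fixes
  events <- list()
  if (nrow(terr) >= 2) {
    for (k in seq_len(nrow(terr) - 1)) {
      # departure from territory k; the model window never extends past the
      # stationary period itself
      win_end <- min(terr$start[k] + territory_window_d * 86400, terr$end[k])
      model_fx <- fx[fx$timestamp >= terr$start[k] & fx$timestamp <= win_end, ]
      if (nrow(model_fx) < 3) next
      model <- fit_territory_model(model_fx)
      dep <- detect_breakout(trk, model, from_time = win_end, kind = "departure")
      if (!is.null(dep)) {
        prev_idx <- max(which(fx$timestamp < dep$observed_fix$timestamp))
        dep <- interpolate_event_time(dep, fx[prev_idx, , drop = FALSE],
                                      mean_speed_mps, sd_speed_mps)
      }
      # arrival into territory k + 1: observed fix is the first fix of that
      # stationary period, the neighbour the last in-flight fix before it
      arr_idx <- which(fx$timestamp == terr$start[k + 1])[1]
      arr <- NULL
      if (!is.na(arr_idx) && arr_idx > 1) {
        arr <- new_event("arrival", NA_character_,
                         fx[arr_idx, , drop = FALSE], fx$timestamp[arr_idx],
                         interpolated = FALSE)
        arr <- interpolate_event_time(arr, fx[arr_idx - 1, , drop = FALSE],
                                      mean_speed_mps, sd_speed_mps)
      }
      events[[length(events) + 1]] <- list(departure = dep, arrival = arr,
                                           from = k, to = k + 1)
    }
  }
  # label alternating seasons: territory 1 is the starting (breeding) one
  cycles <- NULL
  if (length(events) >= 2) {
    n_cycles <- length(events) %/% 2
    rows <- lapply(seq_len(n_cycles), function(cyc) {
      aut <- events[[2 * cyc - 1]]; spr <- events[[2 * cyc]]
      delineate_seasons(list(
        autumn_departure = aut$departure, winter_arrival = aut$arrival,
        winter_departure = spr$departure, breeding_arrival = spr$arrival
      ), animal_id = trk$animal_id, year = cyc)
    })
    cycles <- do.call(rbind, rows)
  }
  list(events = events, cycles = cycles, territories = terr,
       stationary_periods = periods)
}
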