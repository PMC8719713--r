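# End-to-end orchestration: simulate (or read) -> filter -> segment ->
# interpolate -> metrics -> classify -> tables, with a reproducibility
# manifest. Every stage is also callable on its own.

#' Pipeline run configuration
#'
#' Fully serializable; a run is reproducible from its config alone (the seed
#' is part of it).
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Integer seed for all randomness.
#' @param presets Character vector of [preset_schedule()] names to simulate
#'   (ignored when `input` is given).
#' @param n_per_population Animals per simulated population.
#' @param input Optional path to a delimited telemetry table to analyse
#'   instead of simulating.
#' @param population_map Optional data frame (`animal_id`, `population`) used
#'   with `input`.
#' @param move A [movement_config()] for simulation.
#' @param allowed_classes Location classes retained by the quality filter.
#' @param interpolate Fit the CTCRW and interpolate each migration leg
#'   (default TRUE; FALSE measures distance along the raw fix polyline).
#' @param dt_min CTCRW prediction interval (minutes).
#' @param link_km Site-clustering linkage distance (km).
#' @param criteria A [site_criteria()].
#' @return A list of class `flyway_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            presets = c("mackenzie_delta", "hudson_bay"),
                            n_per_population = 5,
                            input = NULL, population_map = NULL,
                            move = movement_config(),
                            allowed_classes = c("LC3", "LC2", "LC1"),
                            interpolate = TRUE, dt_min = 15,
                            link_km = 250, criteria = site_criteria()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), presets = presets,
                 n_per_population = n_per_population, input = input,
                 population_map = population_map, move = move,
                 allowed_classes = allowed_classes, interpolate = interpolate,
                 dt_min = dt_min, link_km = link_km, criteria = criteria),
            class = "flyway_config")
}

# Extract the fixes of one migration leg (departure..arrival, inclusive of
# the flanking event fixes) as a track.
leg_track <- function(trk, t_dep, t_arr, pad_h = 6) {
  fx <- trk$fixes[trk$fixes$timestamp >= t_dep - pad_h * 3600 &
                    trk$fixes$timestamp <= t_arr + pad_h * 3600, , drop = FALSE]
  track(trk$animal_id, fx, duty_cycle = trk$duty_cycle)
}

#' Measure one migration leg, interpolating across duty-cycle gaps
#'
#' Fits the CTCRW to the leg's fixes, predicts the smoothed pathway on a
#' regular grid, and summarises distance (along the interpolated pathway),
#' duration and migration speed.
#'
#' @param trk The animal's (quality-filtered) [track()].
#' @param departure,arrival `flyway_event`s or POSIXct instants bounding the
#'   leg.
#' @param season Label carried into the result.
#' @param interpolate If FALSE, measure along the raw fix polyline instead.
#' @param dt_min Prediction interval in minutes.
#' @param init CTCRW starting parameters.
#' @return A list: the [summarize_leg()] result plus `path`.
#' @export
measure_leg <- function(trk, departure, arrival, season = NA_character_,
                        interpolate = TRUE, dt_min = 15,
                        init = ctcrw_params()) {
  t0 <- if (inherits(departure, "flyway_event")) departure$event_time else departure
  t1 <- if (inherits(arrival, "flyway_event")) arrival$event_time else arrival
  lt <- leg_track(trk, t0, t1)
  if (interpolate && nrow(lt$fixes) >= 8) {
    fit <- fit_ctcrw(lt, init = init)
    path <- predict_path(lt, fit$params, dt_min = dt_min)
  } else {
    path <- tibble::tibble(time = lt$fixes$timestamp, lat = lt$fixes$lat,
                           lon = lt$fixes$lon, position_sd_km = NA_real_)
    attr(path, "animal_id") <- trk$animal_id
  }
  # clip the path to the event interval so staging wander outside it never
  # contributes
  keep <- path$time >= t0 & path$time <= t1
  path_clipped <- path[keep, , drop = FALSE]
  if (nrow(path_clipped) < 2) path_clipped <- path
  # migration length excludes local movements at stopover/staging sites
  stops <- detect_stationary_periods(lt)
  leg <- summarize_leg(t0, t1, path_clipped, animal_id = trk$animal_id,
                       season = season, exclude_intervals = stops)
  leg$path <- path_clipped
  leg
}

#' Run the full annual-cycle pipeline
#'
#' Executes simulate/read -> quality filter -> segmentation -> (optional)
#' CTCRW interpolation -> migration metrics -> site clustering and
#' classification -> summary tables, writing `tracks.csv`, `events.csv`,
#' `stationary_periods.csv`, `annual_cycle.csv`, `migration.csv`,
#' `phenology.csv`, `sites.csv`, `comparisons.csv`, `paths.geojson` and
#' `run_manifest.json` under `config$out_dir`. Idempotent given the same
#' config and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the artifact
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "flyway_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hints_by_pop <- list()
  if (is.null(config$input)) {
    tracks <- list(); populations <- character()
    for (i in seq_along(config$presets)) {
      sch <- preset_schedule(config$presets[i])
      coh <- generate_cohort(config$n_per_population, sch, config$move,
                             seed = config$seed + 5000L * (i - 1L))
      tracks <- c(tracks, coh$tracks)
      populations <- c(populations,
                       stats::setNames(rep(sch$name, length(coh$tracks)),
                                       names(coh$tracks)))
      hints_by_pop[[sch$name]] <- tibble::tibble(
        lat = c(sch$breeding[["lat"]], sch$winter[["lat"]]),
        lon = c(sch$breeding[["lon"]], sch$winter[["lon"]]))
    }
  } else {
    if (!file.exists(config$input)) {
      stop("input file not found: ", config$input)
    }
    tracks <- read_tracks(config$input)
    populations <- if (!is.null(config$population_map)) {
      stats::setNames(config$population_map$population,
                      config$population_map$animal_id)
    } else {
      stats::setNames(rep("all", length(tracks)), names(tracks))
    }
  }
  if (!length(tracks)) stop("no tracks to analyse")
  qf <- quality_filter(allowed_classes = config$allowed_classes)
  filtered <- lapply(tracks, filter_quality, cfg = qf)
  write_tracks(filtered, file.path(config$out_dir, "tracks.csv"))

  events_rows <- list(); cycles_rows <- list(); periods_rows <- list()
  legs_rows <- list(); paths <- list(); visit_rows <- list(); itin_rows <- list()
  for (id in names(filtered)) {
    trk <- filtered[[id]]
    pop <- unname(populations[[id]])
    hints <- hints_by_pop[[pop]]
    seg <- segment_annual_cycle(trk, territory_hints = hints)
    if (!is.null(seg$cycles) && nrow(seg$cycles)) {
      seg$cycles$population <- pop
      cycles_rows[[id]] <- seg$cycles
    }
    periods_rows[[id]] <- seg$stationary_periods
    for (pair in seg$events) {
      for (role in c("departure", "arrival")) {
        e <- pair[[role]]
        if (is.null(e)) next
        events_rows[[length(events_rows) + 1]] <- tibble::tibble(
          animal_id = id, population = pop, kind = e$kind,
          observed_time = e$observed_fix$timestamp,
          event_time = e$event_time, interpolated = e$interpolated)
      }
    }
    # migration legs per cycle
    if (!is.null(seg$cycles) && nrow(seg$cycles)) {
      for (r in seq_len(nrow(seg$cycles))) {
        cyc <- seg$cycles[r, ]
        for (s in c("autumn", "spring")) {
          t0 <- if (s == "autumn") cyc$autumn_departure else cyc$winter_departure
          t1 <- if (s == "autumn") cyc$winter_arrival else cyc$breeding_arrival
          if (is.na(t0) || is.na(t1)) next
          leg <- try(measure_leg(trk, t0, t1, season = s,
                                 interpolate = config$interpolate,
                                 dt_min = config$dt_min), silent = TRUE)
          if (inherits(leg, "try-error")) next
          legs_rows[[length(legs_rows) + 1]] <- tibble::tibble(
            animal_id = id, population = pop, season = s,
            departure = t0, arrival = t1,
            distance_km = leg$distance_km, duration_d = leg$duration_d,
            speed_kmd = leg$speed_kmd)
          paths[[paste(id, s, cyc$year, sep = "_")]] <- leg$path
        }
      }
    }
    # itinerary (all stops) and migration visits (non-territory stops)
    sp <- seg$stationary_periods
    if (nrow(sp)) {
      itin_rows[[id]] <- sp
      is_terr <- sp$start %in% seg$territories$start
      visit_rows[[id]] <- sp[!is_terr, , drop = FALSE]
    }
  }
  events <- if (length(events_rows)) do.call(rbind, events_rows) else
    tibble::tibble(animal_id = character(), population = character(),
                   kind = character(), observed_time = as.POSIXct(character(), tz = "UTC"),
                   event_time = as.POSIXct(character(), tz = "UTC"),
                   interpolated = logical())
  cycles <- if (length(cycles_rows)) do.call(rbind, cycles_rows) else NULL
  periods <- if (length(periods_rows)) do.call(rbind, periods_rows) else NULL
  legs <- if (length(legs_rows)) do.call(rbind, legs_rows) else NULL
  visits <- if (length(visit_rows)) do.call(rbind, visit_rows) else NULL
  itinerary <- if (length(itin_rows)) do.call(rbind, itin_rows) else NULL

  sites <- NULL
  if (!is.null(visits) && nrow(visits)) {
    visits <- cluster_visits(visits, link_km = config$link_km)
    sites <- classify_sites(visits, itinerary = itinerary,
                            criteria = config$criteria,
                            n_population = length(filtered))
    sites <- associate_stopovers(visits, sites)
  }
  tables <- build_tables(cycles = cycles, legs = legs, sites = sites)

  write_table(events, file.path(config$out_dir, "events.csv"))
  if (!is.null(periods)) write_table(periods, file.path(config$out_dir, "stationary_periods.csv"))
  if (!is.null(cycles)) write_table(cycles, file.path(config$out_dir, "annual_cycle.csv"))
  if (!is.null(legs)) write_table(legs, file.path(config$out_dir, "migration.csv"))
  write_table(tables$phenology, file.path(config$out_dir, "phenology.csv"))
  write_table(tables$sites, file.path(config$out_dir, "sites.csv"))
  write_table(tables$comparisons, file.path(config$out_dir, "comparisons.csv"))
  if (length(paths)) write_paths_geojson(paths, file.path(config$out_dir, "paths.geojson"))

  artifacts <- list.files(config$out_dir, pattern = "\\.(csv|geojson)$")
  cfg_json <- as.character(jsonlite::serializeJSON(config))
  cfg_file <- file.path(config$out_dir, "run_config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    package = "flyway",
    version = as.character(utils::packageVersion("flyway")),
    seed = config$seed,
    config_file = basename(cfg_file),
    config_md5 = unname(tools::md5sum(cfg_file)),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(tracks = filtered, events = events, cycles = cycles,
                 periods = periods, legs = legs, visits = visits,
                 sites = sites, tables = tables, manifest = manifest))
}
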