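# Reading, validating, filtering and writing ARGOS-style telemetry tables.

#' ARGOS location-class levels, best to worst
#' @export
LC_LEVELS <- c("LC3", "LC2", "LC1", "LC0", "LCA", "LCB", "LCZ")

#' Construct a telemetry track
#'
#' A track is the time-ordered sequence of satellite fixes for one animal,
#' together with its transmitter duty-cycle metadata.
#'
#' @param animal_id Character scalar identifying the animal.
#' @param fixes A data frame with columns `timestamp` (POSIXct, UTC), `lat`,
#'   `lon` (decimal degrees), `lc` (one of [LC_LEVELS]) and optionally
#'   `error_radius_m`.
#' @param duty_cycle Optional list with elements `off_h` and `on_h` (hours).
#' @param transmitter_mass_g Optional transmitter mass.
#' @return An object of class `flyway_track`.
#' @export
track <- function(animal_id, fixes, duty_cycle = NULL, transmitter_mass_g = NULL) {
  fixes <- tibble::as_tibble(fixes)
  if (!"error_radius_m" %in% names(fixes)) fixes$error_radius_m <- NA_real_
  required <- c("timestamp", "lat", "lon", "lc")
  missing_cols <- setdiff(required, names(fixes))
  if (length(missing_cols)) {
    stop("fixes is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(fixes)) {
    if (any(abs(fixes$lat) > 90)) stop("latitude out of [-90, 90]")
    bad_lc <- setdiff(unique(as.character(fixes$lc)), LC_LEVELS)
    if (length(bad_lc)) stop("unknown location class: ", paste(bad_lc, collapse = ", "))
    if (any(!is.na(fixes$error_radius_m) & fixes$error_radius_m < 0)) {
      stop("error_radius_m must be non-negative")
    }
    fixes$lon <- normalize_lon(fixes$lon)
    fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
    if (anyDuplicated(fixes$timestamp)) {
      fixes <- dedupe_fixes(fixes)
    }
  }
  fixes$lc <- factor(as.character(fixes$lc), levels = LC_LEVELS)
  structure(
    list(animal_id = animal_id,
         fixes = fixes[, c("timestamp", "lat", "lon", "lc", "error_radius_m")],
         duty_cycle = duty_cycle,
         transmitter_mass_g = transmitter_mass_g),
    class = "flyway_track"
  )
}

#' @export
print.flyway_track <- function(x, ...) {
  dc <- if (is.null(x$duty_cycle)) "none" else
    sprintf("%g h off / %g h on", x$duty_cycle$off_h, x$duty_cycle$on_h)
  cat(sprintf("<flyway_track> %s: %d fixes, duty cycle %s\n",
              x$animal_id, nrow(x$fixes), dc))
  if (nrow(x$fixes)) {
    cat(sprintf("  span %s .. %s UTC\n",
                format(min(x$fixes$timestamp), tz = "UTC"),
                format(max(x$fixes$timestamp), tz = "UTC")))
  }
  invisible(x)
}

# Collapse duplicate (animal, timestamp) rows: keep the best location class,
# then the first occurrence. Gives a deterministic canonical form.
dedupe_fixes <- function(fixes) {
  rank <- match(as.character(fixes$lc), LC_LEVELS)
  ord <- order(fixes$timestamp, rank, seq_len(nrow(fixes)))
  fixes <- fixes[ord, , drop = FALSE]
  fixes[!duplicated(fixes$timestamp), , drop = FALSE]
}

#' Column dialect for delimited telemetry tables
#'
#' Maps the canonical fix fields onto the column names of a particular export
#' format. The default matches this package's own writer.
#'
#' @param animal_id,timestamp,lat,lon,lc,error_radius_m Column names in the
#'   source table; `error_radius_m` may be `NULL` if absent.
#' @param sep Field separator.
#' @param lc_map Optional named character vector translating location-class
#'   tokens in the file (names) to [LC_LEVELS] values, e.g. `c("3" = "LC3")`.
#' @return A list of class `flyway_dialect`.
#' @export
telemetry_dialect <- function(animal_id = "animal_id", timestamp = "timestamp",
                              lat = "lat", lon = "lon", lc = "lc",
                              error_radius_m = "error_radius_m",
                              sep = ",", lc_map = NULL) {
  structure(list(animal_id = animal_id, timestamp = timestamp, lat = lat,
                 lon = lon, lc = lc, error_radius_m = error_radius_m,
                 sep = sep, lc_map = lc_map),
            class = "flyway_dialect")
}

parse_utc <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y/%m/%d %H:%M:%OS",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  out
}

#' Read ARGOS-style telemetry into tracks
#'
#' Reads a delimited text table of satellite fixes, validates it, and returns
#' one [track()] per animal with time-sorted fixes. Duplicate
#' (animal, timestamp) rows are collapsed keeping the best location class.
#'
#' @param source Path to a delimited text file (or a connection).
#' @param dialect A [telemetry_dialect()] describing the columns.
#' @return A named list of `flyway_track` objects (possibly empty), sorted by
#'   animal id.
#' @export
read_tracks <- function(source, dialect = telemetry_dialect()) {
  raw <- utils::read.table(source, header = TRUE, sep = dialect$sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) return(structure(list(), names = character()))
  need <- c(dialect$animal_id, dialect$timestamp, dialect$lat, dialect$lon, dialect$lc)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("input is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ts <- parse_utc(raw[[dialect$timestamp]])
  if (anyNA(ts)) {
    stop("unparseable timestamp at row ", which(is.na(ts))[1], ": ",
         raw[[dialect$timestamp]][which(is.na(ts))[1]])
  }
  lat <- suppressWarnings(as.numeric(raw[[dialect$lat]]))
  lon <- suppressWarnings(as.numeric(raw[[dialect$lon]]))
  if (anyNA(lat) || anyNA(lon)) {
    bad <- which(is.na(lat) | is.na(lon))[1]
    stop("unparseable coordinate at row ", bad)
  }
  lc <- as.character(raw[[dialect$lc]])
  if (!is.null(dialect$lc_map)) {
    mapped <- unname(dialect$lc_map[lc])
    lc <- ifelse(is.na(mapped), lc, mapped)
  }
  bad_lc <- setdiff(unique(lc), LC_LEVELS)
  if (length(bad_lc)) {
    stop("unknown location-class token: ", paste(bad_lc, collapse = ", "))
  }
  err <- if (!is.null(dialect$error_radius_m) &&
             dialect$error_radius_m %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[dialect$error_radius_m]]))
  } else NA_real_
  fixes <- tibble::tibble(
    animal_id = as.character(raw[[dialect$animal_id]]),
    timestamp = ts, lat = lat, lon = lon, lc = lc, error_radius_m = err
  )
  ids <- sort(unique(fixes$animal_id))
  out <- lapply(ids, function(id) {
    track(id, fixes[fixes$animal_id == id,
                    c("timestamp", "lat", "lon", "lc", "error_radius_m")])
  })
  names(out) <- ids
  out
}

#' Quality-filter configuration
#'
#' @param allowed_classes Location classes to retain; the default keeps the
#'   Doppler classes with a stated accuracy bound (LC1-LC3).
#' @param max_speed_mps Optional plausibility cap (m/s) for spike removal: a
#'   fix is dropped when the segment speed to BOTH neighbours exceeds the cap.
#'   Off by default.
#' @return A list of class `flyway_quality_filter`.
#' @export
quality_filter <- function(allowed_classes = c("LC3", "LC2", "LC1"),
                           max_speed_mps = NULL) {
  allowed_classes <- match.arg(allowed_classes, LC_LEVELS, several.ok = TRUE)
  if (!length(allowed_classes)) stop("allowed_classes must be non-empty")
  structure(list(allowed_classes = allowed_classes, max_speed_mps = max_speed_mps),
            class = "flyway_quality_filter")
}

#' Filter a track by location class (and optionally speed spikes)
#'
#' Retains only fixes whose location class is in `cfg$allowed_classes`; if
#' `cfg$max_speed_mps` is set, iteratively removes fixes implying a segment
#' speed above the cap to both temporal neighbours. Idempotent; never reorders.
#'
#' @param trk A [track()].
#' @param cfg A [quality_filter()].
#' @return The filtered track (possibly with zero fixes).
#' @export
filter_quality <- function(trk, cfg = quality_filter()) {
  stopifnot(inherits(trk, "flyway_track"))
  fx <- trk$fixes
  fx <- fx[as.character(fx$lc) %in% cfg$allowed_classes, , drop = FALSE]
  if (!is.null(cfg$max_speed_mps)) {
    repeat {
      n <- nrow(fx)
      if (n < 3) break
      d_prev <- great_circle_km(fx$lat[-n], fx$lon[-n], fx$lat[-1], fx$lon[-1])
      dt_h <- diff(as.numeric(fx$timestamp)) / 3600
      v_mps <- (d_prev * 1000) / (dt_h * 3600)
      # speed of segment i links fix i and fix i+1
      spike <- c(FALSE, v_mps[-(n - 1)] > cfg$max_speed_mps, FALSE) &
        c(FALSE, v_mps[-1] > cfg$max_speed_mps, FALSE)
      if (!any(spike)) break
      fx <- fx[!spike, , drop = FALSE]
    }
  }
  trk$fixes <- fx
  trk
}

#' Write tracks to a delimited text file
#'
#' Writes the canonical column layout (`animal_id, timestamp, lat, lon, lc,
#' error_radius_m`) with ISO-8601 UTC timestamps. Coordinates are written with
#' six decimals (about 0.1 m), which defines the canonical form on which
#' `read_tracks(write_tracks(x))` is the identity.
#'
#' @param tracks A list of [track()] objects (or a single track).
#' @param sink Output file path.
#' @export
write_tracks <- function(tracks, sink) {
  if (inherits(tracks, "flyway_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    fx <- tr$fixes
    data.frame(
      animal_id = rep(tr$animal_id, nrow(fx)),
      timestamp = format(fx$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      lat = sprintf("%.6f", fx$lat),
      lon = sprintf("%.6f", fx$lon),
      lc = as.character(fx$lc),
      error_radius_m = ifelse(is.na(fx$error_radius_m), "",
                              sprintf("%.1f", fx$error_radius_m)),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(animal_id = character(), timestamp = character(),
               lat = character(), lon = character(), lc = character(),
               error_radius_m = character())
  }
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Write a derived table as CSV
#'
#' Thin deterministic CSV writer used for all pipeline output tables.
#' @param rows A data frame.
#' @param sink Output file path.
#' @export
write_table <- function(rows, sink) {
  utils::write.csv(as.data.frame(rows), sink, row.names = FALSE)
  invisible(NULL)
}

#' Write interpolated paths as GeoJSON
#'
#' One RFC 7946 `LineString` feature per path, coordinates in lon-lat order,
#' rounded to six decimals. Bit-stable for identical inputs.
#'
#' @param paths A single interpolated path (see [predict_path()]) or a list of
#'   them; each needs `lat`, `lon` columns and an `animal_id` attribute or
#'   element.
#' @param sink Output file path.
#' @export
write_paths_geojson <- function(paths, sink) {
  if (is.data.frame(paths)) paths <- list(paths)
  features <- lapply(paths, function(p) {
    id <- attr(p, "animal_id")
    if (is.null(id)) id <- "unknown"
    coords <- lapply(seq_len(nrow(p)), function(i) {
      c(round(p$lon[i], 6), round(p$lat[i], 6))
    })
    list(type = "Feature",
         properties = list(animal_id = id),
         geometry = list(type = "LineString", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, sink, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
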