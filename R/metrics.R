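# Migration metrics, phenology summaries and the statistical comparisons.

#' Length of a path along its great-circle segments
#'
#' Sum of consecutive haversine segment lengths. This is how migration length
#' is measured along an interpolated pathway.
#'
#' @param path A data frame with `lat` and `lon` columns (ordered along the
#'   path), or a matrix with columns lat, lon.
#' @param exclude_intervals Optional data frame with `start`/`end` POSIXct
#'   columns (and `lat`/`lon` site centroids); the path must then carry a
#'   `time` column. Segments falling inside an interval are replaced by the
#'   great-circle step from the interval's entry position to its exit
#'   position, so local movements at stopover and staging sites do not
#'   contribute to migration length.
#' @return Length in km (0, with a warning, for a single-point path).
#' @export
path_length_km <- function(path, exclude_intervals = NULL) {
  lat <- as.numeric(path[, "lat", drop = TRUE])
  lon <- as.numeric(path[, "lon", drop = TRUE])
  n <- length(lat)
  if (n < 2) {
    warning("path has fewer than 2 positions; length is 0")
    return(0)
  }
  seg_len <- great_circle_km(lat[-n], lon[-n], lat[-1], lon[-1])
  if (is.null(exclude_intervals) || !nrow(exclude_intervals)) {
    return(sum(seg_len))
  }
  tm <- as.numeric(path$time)
  mid <- (tm[-n] + tm[-1]) / 2
  inside <- rep(FALSE, n - 1)
  extra <- 0
  for (k in seq_len(nrow(exclude_intervals))) {
    t0 <- as.numeric(exclude_intervals$start[k])
    t1 <- as.numeric(exclude_intervals$end[k])
    hit <- mid >= t0 & mid <= t1
    if (any(hit)) {
      i0 <- min(which(hit)); i1 <- max(which(hit)) + 1
      extra <- extra + great_circle_km(lat[i0], lon[i0], lat[i1], lon[i1])
    }
    inside <- inside | hit
  }
  sum(seg_len[!inside]) + extra
}

#' Summarise a migration leg
#'
#' Distance is the along-path length of the interpolated pathway, duration the
#' elapsed time between departure and arrival events (stops included), and
#' migration speed their ratio in km/d.
#'
#' @param departure,arrival Transition events (see [detect_breakout()]) or
#'   POSIXct instants.
#' @param path The interpolated path for the leg (`lat`, `lon` columns).
#' @param animal_id,season Optional labels carried through to the result.
#' @param exclude_intervals Stationary intervals passed to
#'   [path_length_km()] so local movements at stops do not count as migration
#'   length.
#' @return A list of class `flyway_leg` with `distance_km`, `duration_d`,
#'   `speed_kmd`.
#' @export
summarize_leg <- function(departure, arrival, path, animal_id = NA_character_,
                          season = NA_character_, exclude_intervals = NULL) {
  t0 <- if (inherits(departure, "flyway_event")) departure$event_time else departure
  t1 <- if (inherits(arrival, "flyway_event")) arrival$event_time else arrival
  if (as.numeric(t1) <= as.numeric(t0)) {
    stop("arrival (", format(t1), ") is not after departure (", format(t0), ")")
  }
  distance_km <- path_length_km(path, exclude_intervals = exclude_intervals)
  duration_d <- (as.numeric(t1) - as.numeric(t0)) / 86400
  structure(list(animal_id = animal_id, season = season,
                 departure = t0, arrival = t1,
                 distance_km = distance_km, duration_d = duration_d,
                 speed_kmd = distance_km / duration_d),
            class = "flyway_leg")
}

#' Group summary (mean and standard error)
#'
#' @param x Numeric values (one per animal-season; repeat seasons from one
#'   animal are treated as independent samples).
#' @param n_individuals Number of distinct animals contributing.
#' @return A list with `n_individuals`, `n_seasons`, `mean`, `se`.
#' @export
group_summary <- function(x, n_individuals = NA_integer_) {
  x <- x[!is.na(x)]
  list(n_individuals = n_individuals, n_seasons = length(x),
       mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}

#' Two-tailed two-sample t-test
#'
#' Pooled-variance Student's t by default (df = n1 + n2 - 2), Welch optional.
#' Accepts either raw samples or printed-style summaries
#' (`list(mean=, se=, n=)`); pooled variances are back-computed from the SEs.
#'
#' @param g1,g2 Numeric vectors, or lists/`group_summary()` results with
#'   elements `mean`, `se` and `n` (or `n_seasons`).
#' @param method `"pooled"` or `"welch"`.
#' @return A list of class `flyway_comparison` with `t_statistic`, `df`,
#'   `p_two_tailed`, `method`.
#' @export
two_sample_t <- function(g1, g2, method = c("pooled", "welch")) {
  method <- match.arg(method)
  as_summ <- function(g) {
    if (is.numeric(g)) {
      if (length(g) < 2) stop("raw samples need n >= 2")
      list(mean = mean(g), se = stats::sd(g) / sqrt(length(g)), n = length(g))
    } else {
      n <- if (!is.null(g$n)) g$n else g$n_seasons
      list(mean = g$mean, se = g$se, n = n)
    }
  }
  a <- as_summ(g1); b <- as_summ(g2)
  if (method == "pooled") {
    s1sq <- a$se^2 * a$n; s2sq <- b$se^2 * b$n
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * s1sq + (b$n - 1) * s2sq) / df
    se_diff <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se_diff <- sqrt(a$se^2 + b$se^2)
    df <- se_diff^4 / (a$se^4 / (a$n - 1) + b$se^4 / (b$n - 1))
  }
  if (se_diff == 0) {
    t_stat <- if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
  } else {
    t_stat <- (a$mean - b$mean) / se_diff
  }
  structure(list(t_statistic = t_stat, df = df,
                 p_two_tailed = 2 * stats::pt(-abs(t_stat), df),
                 method = method),
            class = "flyway_comparison")
}

#' Bonferroni correction
#'
#' `p_adj = min(1, p * family_size)`; the family defaults to the number of
#' p-values supplied.
#'
#' @param p_values Numeric vector of p-values.
#' @param family_size Size of the test family (>= `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (family_size < length(p_values)) {
    stop("family_size must be at least the number of p-values")
  }
  stats::p.adjust(p_values, method = "bonferroni", n = family_size)
}

# Month-name parser kept locale-independent on purpose.
.month_names <- c("january", "february", "march", "april", "may", "june",
                  "july", "august", "september", "october", "november",
                  "december")

#' Parse a printed day-month date ("7 July") into a Date
#'
#' @param x Character vector like `"7 July"` or `"04 Jul"`.
#' @param year Calendar year to anchor the date in (default 2015, an arbitrary
#'   non-leap reference year).
#' @return A `Date` vector.
#' @export
parse_day_month <- function(x, year = 2015) {
  parts <- strsplit(trimws(x), "\\s+")
  out <- vapply(parts, function(p) {
    if (length(p) != 2) return(NA_real_)
    day <- suppressWarnings(as.integer(p[1]))
    m <- pmatch(tolower(p[2]), .month_names)
    if (is.na(day) || is.na(m)) return(NA_real_)
    as.numeric(as.Date(sprintf("%d-%02d-%02d", year, m, day)))
  }, numeric(1))
  if (anyNA(out)) stop("unparseable date: ", x[which(is.na(out))[1]])
  as.Date(out, origin = "1970-01-01")
}

#' Difference between two calendar dates in days
#'
#' @param d1,d2 `Date`s (or strings accepted by [parse_day_month()]).
#' @return `d2 - d1` in whole days.
#' @export
date_diff <- function(d1, d2) {
  if (is.character(d1)) d1 <- parse_day_month(d1)
  if (is.character(d2)) d2 <- parse_day_month(d2)
  as.numeric(round(as.numeric(d2) - as.numeric(d1)))
}

#' Mean and standard error of a set of calendar dates
#'
#' Dates are reduced to a linear day axis; to keep the mean unambiguous the
#' dates must fall within a 180-day window (one season).
#'
#' @param dates A `Date` or POSIXct vector (or printed strings).
#' @param n_individuals Optional count of distinct animals.
#' @return A [group_summary()]-style list plus `mean_date` (a `Date`).
#' @export
date_stats <- function(dates, n_individuals = NA_integer_) {
  if (is.character(dates)) dates <- parse_day_month(dates)
  x <- as.numeric(as.Date(dates, tz = "UTC"))
  if (!length(x)) stop("no dates supplied")
  if (diff(range(x)) > 180) {
    stop("dates span more than 180 days; seasonal mean is ambiguous")
  }
  out <- group_summary(x, n_individuals)
  out$mean_date <- as.Date(round(out$mean), origin = "1970-01-01")
  out
}

#' Build phenology, migration and site summary tables
#'
#' Collates pipeline outputs into the population-by-season summary layout used
#' for reporting: mean +/- SE with n (individuals) and x (seasons).
#'
#' @param cycles A data frame of annual-cycle rows (see
#'   [delineate_seasons()]), with columns `animal_id`, `population`, `year`,
#'   and per-season initiation times/durations.
#' @param legs A data frame of migration-leg summaries with columns
#'   `animal_id`, `population`, `season`, `distance_km`, `duration_d`,
#'   `speed_kmd`.
#' @param sites A data frame of classified sites (see [classify_sites()]), or
#'   `NULL`.
#' @return A list with elements `phenology`, `migration`, `sites`,
#'   `comparisons` (tibbles; empty inputs give header-only tables).
#' @export
build_tables <- function(cycles = NULL, legs = NULL, sites = NULL) {
  phen <- tibble::tibble(population = character(), season = character(),
                         n_individuals = integer(), n_seasons = integer(),
                         mean_date = as.Date(character()), se_d = numeric())
  # season initiation events: spring begins at winter departure
  season_cols <- c(breeding = "breeding_arrival", autumn = "autumn_departure",
                   winter = "winter_arrival", spring = "winter_departure")
  if (!is.null(cycles) && nrow(cycles)) {
    for (pop in sort(unique(cycles$population))) {
      sub <- cycles[cycles$population == pop, , drop = FALSE]
      for (s in names(season_cols)) {
        col <- season_cols[[s]]
        if (!col %in% names(sub)) next
        v <- sub[[col]][!is.na(sub[[col]])]
        if (!length(v)) next
        st <- date_stats(as.Date(as.POSIXct(v, origin = "1970-01-01", tz = "UTC")),
                         n_individuals = length(unique(sub$animal_id[!is.na(sub[[col]])])))
        phen <- rbind(phen, tibble::tibble(
          population = pop, season = s,
          n_individuals = st$n_individuals, n_seasons = st$n_seasons,
          mean_date = st$mean_date, se_d = st$se))
      }
    }
  }
  mig <- tibble::tibble(population = character(), season = character(),
                        n_individuals = integer(), n_seasons = integer(),
                        mean_distance_km = numeric(), se_distance_km = numeric(),
                        mean_duration_d = numeric(), se_duration_d = numeric(),
                        mean_speed_kmd = numeric(), se_speed_kmd = numeric())
  if (!is.null(legs) && nrow(legs)) {
    for (pop in sort(unique(legs$population))) {
      for (s in sort(unique(legs$season))) {
        sub <- legs[legs$population == pop & legs$season == s, , drop = FALSE]
        if (!nrow(sub)) next
        se <- function(v) stats::sd(v) / sqrt(length(v))
        mig <- rbind(mig, tibble::tibble(
          population = pop, season = s,
          n_individuals = length(unique(sub$animal_id)), n_seasons = nrow(sub),
          mean_distance_km = mean(sub$distance_km), se_distance_km = se(sub$distance_km),
          mean_duration_d = mean(sub$duration_d), se_duration_d = se(sub$duration_d),
          mean_speed_kmd = mean(sub$speed_kmd), se_speed_kmd = se(sub$speed_kmd)))
      }
    }
  }
  comparisons <- tibble::tibble(metric = character(), group1 = character(),
                                group2 = character(), t = numeric(), df = numeric(),
                                p = numeric(), p_bonferroni = numeric())
  if (nrow(phen)) {
    pops <- sort(unique(phen$population))
    if (length(pops) == 2 && !is.null(cycles)) {
      rows <- list()
      for (s in names(season_cols)) {
        col <- season_cols[[s]]
        v1 <- cycles[[col]][cycles$population == pops[1]]
        v2 <- cycles[[col]][cycles$population == pops[2]]
        v1 <- as.numeric(v1[!is.na(v1)]) / 86400
        v2 <- as.numeric(v2[!is.na(v2)]) / 86400
        if (length(v1) >= 2 && length(v2) >= 2) {
          ct <- two_sample_t(v1, v2)
          rows[[s]] <- tibble::tibble(
            metric = paste0(s, "_initiation"), group1 = pops[1], group2 = pops[2],
            t = ct$t_statistic, df = ct$df, p = ct$p_two_tailed,
            p_bonferroni = NA_real_)
        }
      }
      if (length(rows)) {
        comparisons <- do.call(rbind, c(list(comparisons), rows))
        comparisons$p_bonferroni <- bonferroni(comparisons$p)
      }
    }
  }
  sites_tbl <- if (is.null(sites)) {
    tibble::tibble(site_id = integer(), lat = numeric(), lon = numeric(),
                   label = character(), n_individuals = integer(),
                   n_years = integer(), median_stay_d = numeric(),
                   next_leg_km = numeric())
  } else tibble::as_tibble(sites)
  list(phenology = phen, migration = mig, sites = sites_tbl,
       comparisons = comparisons)
}
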