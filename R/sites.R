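# Clustering stationary periods into geographic sites and applying the
# staging-vs-stopover criteria, upstream association and between-year fidelity.

#' Cluster stationary-period visits into geographic sites
#'
#' Single-linkage agglomeration over great-circle distances between visit
#' centroids, cut at `link_km`. Site ids are assigned deterministically by the
#' lexicographic (lat, lon) order of the cluster centroids, so the result is
#' invariant to input permutation.
#'
#' @param periods A tibble of stationary periods (see
#'   [detect_stationary_periods()]), non-empty.
#' @param link_km Linkage cut height in km (default 250; staging areas are
#'   regional).
#' @return The input tibble with a `site_id` column, plus a `sites` attribute
#'   summarising each cluster (centroid, n visits).
#' @export
cluster_visits <- function(periods, link_km = 250) {
  if (!nrow(periods)) stop("no stationary periods to cluster")
  n <- nrow(periods)
  if (n == 1) {
    cl <- 1L
  } else {
    dm <- geosphere::distm(cbind(periods$lon, periods$lat),
                           fun = function(a, b) geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM))
    hc <- stats::hclust(stats::as.dist(dm), method = "single")
    cl <- stats::cutree(hc, h = link_km)
  }
  cents <- t(vapply(sort(unique(cl)), function(k) {
    c(lat = mean(periods$lat[cl == k]), lon = circular_mean_lon(periods$lon[cl == k]))
  }, c(lat = 0, lon = 0)))
  ord <- order(round(cents[, "lat"], 9), round(cents[, "lon"], 9))
  relabel <- integer(length(ord)); relabel[ord] <- seq_along(ord)
  out <- periods
  out$site_id <- relabel[cl]
  sites <- tibble::tibble(site_id = seq_along(ord),
                          lat = as.numeric(cents[ord, "lat"]),
                          lon = as.numeric(cents[ord, "lon"]),
                          n_visits = as.integer(table(out$site_id)))
  attr(out, "sites") <- sites
  out
}

#' Classification thresholds for staging areas vs stopovers
#'
#' Operationalizes the staging-area criteria: long stays (weeks), a long
#' onward flight (> 1,000 km), and annual reuse by the population. The
#' resource-density criterion is unobservable from telemetry and is not part
#' of the classifier.
#'
#' @param min_staging_stay_d Minimum median stay for staging (default 7 d).
#' @param min_next_leg_km Minimum onward-flight distance for staging
#'   (default 1000 km).
#' @param min_population_fraction Minimum fraction of tracked animals using
#'   the site (default 0.2), accepted in place of multi-year reuse.
#' @param min_reuse_years Minimum distinct years of use (default 2).
#' @param max_stopover_stay_d Maximum median stay for a stopover (default 7 d).
#' @return A list of class `flyway_site_criteria`.
#' @export
site_criteria <- function(min_staging_stay_d = 7, min_next_leg_km = 1000,
                          min_population_fraction = 0.2, min_reuse_years = 2,
                          max_stopover_stay_d = 7) {
  structure(list(min_staging_stay_d = min_staging_stay_d,
                 min_next_leg_km = min_next_leg_km,
                 min_population_fraction = min_population_fraction,
                 min_reuse_years = min_reuse_years,
                 max_stopover_stay_d = max_stopover_stay_d),
            class = "flyway_site_criteria")
}

# Distance from each visit to the next destination its animal moved to. The
# itinerary is the full time-ordered list of an animal's stops (visits plus
# territories); when NULL the visits themselves serve as the itinerary.
next_leg_distances <- function(visits, itinerary = NULL) {
  if (is.null(itinerary)) itinerary <- visits
  out <- rep(NA_real_, nrow(visits))
  for (k in seq_len(nrow(visits))) {
    later <- itinerary[itinerary$animal_id == visits$animal_id[k] &
                         as.numeric(itinerary$start) > as.numeric(visits$start[k]), ,
                       drop = FALSE]
    if (nrow(later)) {
      j <- which.min(as.numeric(later$start))
      out[k] <- great_circle_km(visits$lat[k], visits$lon[k],
                                later$lat[j], later$lon[j])
    }
  }
  out
}

#' Classify clustered sites as staging areas or stopovers
#'
#' A site is a **staging area** when its median stay is at least
#' `min_staging_stay_d`, its onward flight exceeds `min_next_leg_km`, and it
#' is reused (at least `min_reuse_years` years, or at least
#' `min_population_fraction` of the tracked animals). Otherwise it is a
#' **stopover** if the median stay is at most `max_stopover_stay_d`, else
#' `unclassified`.
#'
#' @param visits Clustered visits from [cluster_visits()]; needs `animal_id`,
#'   `start`, `end`, `duration_d`, `lat`, `lon`, `site_id`.
#' @param itinerary Optional tibble (`animal_id`, `lat`, `lon`, `start`) of
#'   every stop in each animal's journey, including breeding/winter
#'   territories, used to measure the onward ("next destination") leg of each
#'   visit. Defaults to the visits themselves. Visitors absent from a supplied
#'   itinerary cause an error naming the animal.
#' @param criteria A [site_criteria()].
#' @param n_population Total number of tracked animals (defaults to the number
#'   of distinct animals in `visits`).
#' @return A tibble with one row per site: centroid, `label`,
#'   `n_individuals`, `n_years`, `median_stay_d`, `next_leg_km`.
#' @export
classify_sites <- function(visits, itinerary = NULL,
                           criteria = site_criteria(),
                           n_population = length(unique(visits$animal_id))) {
  if (!"site_id" %in% names(visits)) stop("visits must be clustered first")
  if (!is.null(itinerary)) {
    missing_it <- setdiff(unique(visits$animal_id), itinerary$animal_id)
    if (length(missing_it)) {
      stop("no itinerary for animal(s): ", paste(missing_it, collapse = ", "))
    }
  }
  visits$next_leg_km <- next_leg_distances(visits, itinerary)
  years <- as.integer(format(visits$start, "%Y", tz = "UTC"))
  rows <- lapply(sort(unique(visits$site_id)), function(sid) {
    sub <- visits[visits$site_id == sid, , drop = FALSE]
    med_stay <- stats::median(sub$duration_d)
    nl <- stats::median(sub$next_leg_km, na.rm = TRUE)
    n_ind <- length(unique(sub$animal_id))
    n_yr <- length(unique(years[visits$site_id == sid]))
    reused <- (n_yr >= criteria$min_reuse_years) ||
      (n_ind / n_population >= criteria$min_population_fraction)
    label <- if (!is.na(nl) && med_stay >= criteria$min_staging_stay_d &&
                 nl > criteria$min_next_leg_km && reused) {
      "staging"
    } else if (med_stay <= criteria$max_stopover_stay_d) {
      "stopover"
    } else {
      "unclassified"
    }
    tibble::tibble(site_id = sid,
                   lat = mean(sub$lat), lon = circular_mean_lon(sub$lon),
                   label = label, n_individuals = n_ind, n_years = n_yr,
                   median_stay_d = med_stay, next_leg_km = nl)
  })
  do.call(rbind, rows)
}

#' Associate stopovers with their upstream staging area
#'
#' Each stopover site is mapped to the staging site its visitors most recently
#' left: per visit, the latest preceding staging visit by the same animal;
#' site-level assignment by majority vote across visits, ties broken by the
#' earliest staging site id. Stopovers with no upstream staging visit in any
#' itinerary are flagged as origin-associated.
#'
#' @param visits Clustered visits (with `site_id`).
#' @param sites Classified sites from [classify_sites()].
#' @return `sites` with `upstream_site` (integer, NA for origin-flagged
#'   stopovers and for staging sites) and `origin_flagged` columns.
#' @export
associate_stopovers <- function(visits, sites) {
  staging_ids <- sites$site_id[sites$label == "staging"]
  upstream <- rep(NA_integer_, nrow(sites))
  origin <- rep(FALSE, nrow(sites))
  for (r in which(sites$label == "stopover")) {
    sid <- sites$site_id[r]
    votes <- integer(0)
    sub <- visits[visits$site_id == sid, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      prior <- visits[visits$animal_id == sub$animal_id[k] &
                        visits$start < sub$start[k] &
                        visits$site_id %in% staging_ids, , drop = FALSE]
      if (nrow(prior)) {
        votes <- c(votes, prior$site_id[which.max(as.numeric(prior$start))])
      }
    }
    if (length(votes)) {
      tab <- table(votes)
      best <- as.integer(names(tab)[tab == max(tab)])
      upstream[r] <- min(best)
    } else {
      origin[r] <- TRUE
    }
  }
  sites$upstream_site <- upstream
  sites$origin_flagged <- origin
  sites
}

#' Between-year fidelity to staging areas
#'
#' Over all (animal, staging site, year) use events for which the animal was
#' also tracked through the same season the following year, the event is
#' consistent when the site was used again that following year (an overflight
#' of a previously used site counts as inconsistent). Undefined (NA, with a
#' message) when no repeat-year events exist.
#'
#' @param use_events A tibble with columns `animal_id`, `site_id`, `season`,
#'   `year` (one row per staging use event).
#' @param coverage A tibble with columns `animal_id`, `season`, `year` listing
#'   the animal-season-years actually tracked; defaults to the events
#'   themselves (every used year assumed tracked).
#' @return A list with `proportion`, `n_consistent`, `n_events`.
#' @export
site_fidelity <- function(use_events, coverage = NULL) {
  if (is.null(coverage)) {
    coverage <- unique(use_events[, c("animal_id", "season", "year")])
  }
  tracked <- function(id, season, yr) {
    any(coverage$animal_id == id & coverage$season == season & coverage$year == yr)
  }
  n_events <- 0L; n_consistent <- 0L
  for (k in seq_len(nrow(use_events))) {
    ev <- use_events[k, ]
    if (!tracked(ev$animal_id, ev$season, ev$year + 1)) next
    n_events <- n_events + 1L
    reused <- any(use_events$animal_id == ev$animal_id &
                    use_events$site_id == ev$site_id &
                    use_events$season == ev$season &
                    use_events$year == ev$year + 1)
    if (reused) n_consistent <- n_consistent + 1L
  }
  if (n_events == 0L) {
    message("no repeat-year staging events; fidelity is undefined")
    return(list(proportion = NA_real_, n_consistent = 0L, n_events = 0L))
  }
  list(proportion = n_consistent / n_events,
       n_consistent = n_consistent, n_events = n_events)
}
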