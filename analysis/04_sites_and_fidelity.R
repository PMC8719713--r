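#!/usr/bin/env Rscript
# Cluster stationary periods into geographic sites, classify staging areas vs
# stopovers, and associate each stopover with its upstream staging area.
#
# Input:  results/tracks.csv
# Output: results/stationary_periods.csv, results/sites.csv

suppressPackageStartupMessages(library(flyway))

tracks <- read_tracks("results/tracks.csv")
population_of <- function(id) sub("_[0-9]+$", "", id)

periods <- list(); visits <- list()
for (id in names(tracks)) {
  sch <- preset_schedule(population_of(id))
  hints <- tibble::tibble(lat = c(sch$breeding[["lat"]], sch$winter[["lat"]]),
                          lon = c(sch$breeding[["lon"]], sch$winter[["lon"]]))
  trk <- filter_quality(tracks[[id]])
  seg <- segment_annual_cycle(trk, territory_hints = hints)
  sp <- seg$stationary_periods
  periods[[id]] <- sp
  visits[[id]] <- sp[!(sp$start %in% seg$territories$start), , drop = FALSE]
}
periods <- do.call(rbind, periods)
visits <- do.call(rbind, visits)

visits <- cluster_visits(visits, link_km = 250)
sites <- classify_sites(visits, itinerary = periods,
                        n_population = length(tracks))
sites <- associate_stopovers(visits, sites)

write_table(periods, "results/stationary_periods.csv")
write_table(sites, "results/sites.csv")

message(sprintf("%d stationary periods -> %d sites: %d staging, %d stopover, %d unclassified",
                nrow(periods), nrow(sites), sum(sites$label == "staging"),
                sum(sites$label == "stopover"), sum(sites$label == "unclassified")))
for (r in which(sites$label == "staging")) {
  s <- sites[r, ]
  message(sprintf("  staging site %d at (%.1f, %.1f): median stay %.1f d, next leg %.0f km, %d birds",
                  s$site_id, s$lat, s$lon, s$median_stay_d, s$next_leg_km,
                  s$n_individuals))
}
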