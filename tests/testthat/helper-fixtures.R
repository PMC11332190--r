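# Shared fixture builders. Everything is generated in code at test time.

utc <- function(s) as.POSIXct(s, tz = "UTC")

# Detections of one species at one station, at given minute offsets.
det_at_minutes <- function(minutes, counts = rep(1L, length(minutes)),
                           station = "st1", species = "sp1",
                           origin = utc("2021-01-01 00:00:00")) {
  data.frame(station_id = station, timestamp = origin + minutes * 60,
             species_id = species, count = counts, stringsAsFactors = FALSE)
}

station_row <- function(id = "st1", community = "C01", days = 30,
                        start = utc("2021-01-01 00:00:00")) {
  data.frame(station_id = id, community = community, x = 0, y = 0,
             deploy_start = start, deploy_end = start + days * 86400,
             stringsAsFactors = FALSE)
}

# Minimal trait table with one species per mandatory group.
tiny_traits <- function() {
  data.frame(
    species_id = c("sp1", "sp2", "sp3", "sp4", "sp5"),
    taxon_group = c("rodent", "ungulate", "ungulate", "primate", "bird"),
    body_mass_kg = c(2.5, 4.5, 15, 7, 2),
    duiker_class = c("none", "blue", "other_duiker", "none", "none"),
    mean_group_size = c(1.5, 1.2, 1.5, 4, 1.3),
    excluded = FALSE, stringsAsFactors = FALSE)
}

# A small but non-degenerate scenario for pipeline tests.
small_scenario <- function(seed = 1, ...) {
  scenario_config(n_communities = 3, n_stations_per_site = 6,
                  days_per_station = 30, n_trips_per_community = 15,
                  mean_trip_hours = 4, gps_fraction = 0.5, seed = seed, ...)
}

# Straight out-and-back track at constant speed, metric coordinates.
line_track <- function(n = 41, step_m = 50, fix_s = 30,
                       t0 = utc("2021-01-01 06:00:00")) {
  m <- (n + 1) %/% 2
  x <- c(seq(0, by = step_m, length.out = m),
         rev(seq(0, by = step_m, length.out = m))[-1])
  data.frame(t = t0 + (seq_len(n) - 1) * fix_s, x = x[seq_len(n)], y = 0)
}

# An abundance_matrix object built directly from a numeric matrix.
ab_from_matrix <- function(N, community) {
  structure(list(N = N, days = setNames(rep(30, nrow(N)), rownames(N)),
                 community = setNames(community, rownames(N))),
            class = "abundance_matrix")
}
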