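#' Collapse camera-trap triggers into independent detection events
#'
#' Successive triggers of the same species at the same station are merged
#' into one independent detection event unless separated from the previous
#' trigger by at least `window_minutes` (a rolling gap-to-previous-detection
#' rule; a gap of exactly the window starts a new event). An event's
#' abundance contribution is the maximum individual count over its triggers.
#'
#' @param detections data.frame with `station_id`, `timestamp` (POSIXct),
#'   `species_id`, `count`.
#' @param window_minutes independence window in minutes, default 30.
#' @return data.frame of events: `station_id`, `species_id`, `event_start`,
#'   `max_individuals`, `n_triggers`.
#' @examples
#' d <- data.frame(station_id = "a",
#'                 timestamp = as.POSIXct("2021-01-01", tz = "UTC") +
#'                             c(0, 10, 45) * 60,
#'                 species_id = "sp1", count = c(1, 3, 2))
#' collapse_events(d)  # two events, starts at minutes 0 and 45
#' @export
collapse_events <- function(detections, window_minutes = 30) {
  if (window_minutes <= 0) stopf("window_minutes must be positive")
  need <- c("station_id", "timestamp", "species_id", "count")
  if (!all(need %in% names(detections)))
    stopf("detections must have columns %s", paste(need, collapse = ", "))
  if (nrow(detections) == 0)
    return(data.frame(station_id = character(), species_id = character(),
                      event_start = as.POSIXct(character(), tz = "UTC"),
                      max_individuals = integer(), n_triggers = integer()))
  d <- detections[order(detections$station_id, detections$species_id,
                        detections$timestamp), ]
  grp <- paste(d$station_id, d$species_id, sep = "\r")
  new_grp <- c(TRUE, grp[-1] != grp[-nrow(d)])
  gap_s <- c(Inf, as.numeric(d$timestamp[-1]) - as.numeric(d$timestamp[-nrow(d)]))
  new_event <- new_grp | gap_s >= window_minutes * 60
  eid <- cumsum(new_event)
  first <- which(new_event)
  out <- data.frame(
    station_id = d$station_id[first],
    species_id = d$species_id[first],
    event_start = d$timestamp[first],
    max_individuals = as.integer(tapply(d$count, eid, max)),
    n_triggers = as.integer(tabulate(eid)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Functioning days of camera-trap stations
#'
#' Effort is taken from deployment metadata: `(deploy_end - deploy_start)`
#' in days. Stations below `min_days` functioning days are flagged for
#' exclusion (surveys deploy for a minimum of a month; very short windows
#' produce unstable daily rates).
#'
#' @param stations data.frame with `station_id`, `deploy_start`, `deploy_end`.
#' @param min_days exclusion threshold in days, default 7.
#' @return named numeric vector of functioning days (NA for excluded
#'   stations, with a warning naming them).
#' @export
functioning_days <- function(stations, min_days = 7) {
  days <- as.numeric(difftime(stations$deploy_end, stations$deploy_start,
                              units = "days"))
  names(days) <- stations$station_id
  bad <- !is.finite(days) | days < min_days
  if (any(bad)) {
    warnf("excluding %d station(s) with < %g functioning days: %s",
          sum(bad), min_days, paste(stations$station_id[bad], collapse = ", "))
    days[bad] <- NA_real_
  }
  days
}

#' Site-level mean group size per species
#'
#' The mean, over all independent events of a species at all stations of a
#' site, of the maximum individual count per event. Accounts for gregarious
#' species when weighting daily detection rates. Species with no events at
#' a site fall back to a weight of 1 (only relevant for reporting, since
#' their rate there is 0 anyway).
#'
#' @param events events from [collapse_events()].
#' @param site_of named character vector mapping station_id to site.
#' @return data.frame `site`, `species_id`, `mean_group_size`.
#' @export
site_group_size <- function(events, site_of) {
  unknown <- setdiff(unique(events$station_id), names(site_of))
  if (length(unknown))
    stopf("stations without a site mapping: %s", paste(unknown, collapse = ", "))
  site <- site_of[events$station_id]
  agg <- aggregate(events$max_individuals,
                   by = list(site = site, species_id = events$species_id),
                   FUN = mean)
  names(agg)[3] <- "mean_group_size"
  agg[order(agg$site, agg$species_id), ]
}

#' Group-size-weighted daily detection rate matrix
#'
#' Builds the abundance matrix whose entry for species k at station i is the
#' daily detection rate (independent events of k at i divided by the
#' station's functioning days) weighted by the site-level mean group size of
#' k, accounting for gregarious species. Species flagged `excluded` in the
#' trait table are dropped before counting; stations with too few
#' functioning days are dropped with a warning.
#'
#' @param events events from [collapse_events()].
#' @param stations station metadata (with `community` used as the site).
#' @param traits species trait table; rows with `excluded = TRUE` dropped.
#' @param min_days passed to [functioning_days()].
#' @return an object of class `"abundance_matrix"`: list with `N` (stations
#'   x species matrix of weighted daily rates), `days` (named vector),
#'   `community` (named vector per station).
#' @examples
#' # 6 events in 30 days at one station, site group size 2 -> N = 0.4
#' @export
abundance_matrix <- function(events, stations, traits, min_days = 7) {
  keep_sp <- traits$species_id[!traits$excluded]
  ev <- events[events$species_id %in% keep_sp, , drop = FALSE]
  days <- suppressWarnings(functioning_days(stations, min_days))
  bad <- names(days)[is.na(days)]
  if (length(bad))
    warnf("dropping %d station(s) below the functioning-days threshold", length(bad))
  st <- stations[!stations$station_id %in% bad, , drop = FALSE]
  days <- days[st$station_id]
  ev <- ev[ev$station_id %in% st$station_id, , drop = FALSE]

  site_of <- setNames(st$community, st$station_id)
  sp <- sort(unique(keep_sp))
  N <- matrix(0, nrow = nrow(st), ncol = length(sp),
              dimnames = list(st$station_id, sp))
  if (nrow(ev)) {
    gs <- site_group_size(ev, site_of)
    cnt <- table(factor(ev$station_id, levels = st$station_id),
                 factor(ev$species_id, levels = sp))
    N <- matrix(as.numeric(cnt), nrow = nrow(st),
                dimnames = list(st$station_id, sp)) / days[st$station_id]
    w <- matrix(1, nrow(N), ncol(N), dimnames = dimnames(N))
    # expand site-level weights to every station of that site
    for (r in seq_len(nrow(gs))) {
      rows <- which(site_of[rownames(N)] == gs$site[r])
      w[rows, match(gs$species_id[r], sp)] <- gs$mean_group_size[r]
    }
    N <- N * w
  }
  structure(list(N = N, days = days,
                 community = setNames(st$community, st$station_id)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("Abundance matrix: %d stations x %d species (%d site(s))\n",
              nrow(x$N), ncol(x$N), length(unique(x$community))))
  invisible(x)
}

#' Filter rare species and species-poor stations to a fixpoint
#'
#' Dissimilarity analyses are sensitive to extremely rare species and to
#' species-poor assemblages, so only species detected by at least
#' `min_stations_per_species` stations and stations detecting at least
#' `min_species_per_station` species are retained. Because removing a
#' station can push a species below its threshold (and vice versa), both
#' removals are iterated to a fixpoint; the result satisfies both criteria
#' simultaneously and is invariant under re-application. Presence is judged
#' on a strictly positive rate.
#'
#' @param mat an `"abundance_matrix"`.
#' @param min_stations_per_species,min_species_per_station thresholds,
#'   default 3 each.
#' @return the filtered `"abundance_matrix"`.
#' @export
apply_filters <- function(mat, min_stations_per_species = 3,
                          min_species_per_station = 3) {
  N <- mat$N
  repeat {
    sp_keep <- colSums(N > 0) >= min_stations_per_species
    N2 <- N[, sp_keep, drop = FALSE]
    st_keep <- rowSums(N2 > 0) >= min_species_per_station
    N2 <- N2[st_keep, , drop = FALSE]
    if (nrow(N2) == 0 || ncol(N2) == 0) {
      last <- if (ncol(N2) > 0) "species" else "stations"
      stopf("filtering emptied the matrix (last surviving dimension: %s)", last)
    }
    if (identical(dim(N2), dim(N))) break
    N <- N2
  }
  structure(list(N = N, days = mat$days[rownames(N)],
                 community = mat$community[rownames(N)]),
            class = "abundance_matrix")
}
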