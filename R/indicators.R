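# The 33 community-level offtake and pressure indicators, their names and
# their hypothesized direction of change along the degradation gradient.
indicator_meta <- function() {
  data.frame(
    id = sprintf("I%02d", 1:33),
    name = c("pct_kills_gun", "pct_kills_snare", "pct_kills_night",
             "pct_kills_day", "mean_gun_trip_h", "mean_gun_trip_km",
             "pct_gun_trip_hours_night",
             "pct_rodents", "pct_ungulates", "pct_primates", "pct_birds",
             "blue_duiker_pct_offtake", "mean_body_mass_offtake_kg",
             "pct_unsuccessful_trips", "pct_strict_gun_trips",
             "pct_strict_trap_trips", "annual_extraction_kg_km2_y",
             "cpue_all_kg_trip", "cpue_all_kg_h", "cpue_all_kg_km",
             "cpue_rodent_kg_trip", "cpue_rodent_kg_h", "cpue_rodent_kg_km",
             "cpue_ungulate_kg_trip", "cpue_ungulate_kg_h", "cpue_ungulate_kg_km",
             "cpue_primate_kg_trip", "cpue_primate_kg_h", "cpue_primate_kg_km",
             "cpue_bird_kg_trip", "cpue_bird_kg_h", "cpue_bird_kg_km",
             "pct_pieces_traded"),
    expected_trend = c("up", "down", "up", "down", "up", "up", "up",
                       "up", "down", "down", "up", "up", "down",
                       "up", "up", "down", "up",
                       "down", "down", "down",
                       "up", "up", "up",
                       "down", "down", "down",
                       "down", "down", "down",
                       "up", "up", "up",
                       "up"),
    stringsAsFactors = FALSE)
}

#' Compute the 33 hunting offtake and pressure indicators per community
#'
#' Indicators cover four families: hunting method (share of kills by gun,
#' wire snare; kills at night and by day; gun-trip duration, distance and
#' night-activity share), catch composition (shares of rodents, ungulates,
#' primates and birds; BlueDuiker%; mean body mass of the offtake), hunter
#' returns (unsuccessful, strict-gun and strict-trap trip shares; annual
#' extraction rate in kg/km^2/y; biomass per trip, hour and kilometre for
#' all species and per group) and wild-meat use (share of kills traded).
#' Exactly 33 slots are always emitted per community; indicators that
#' cannot be computed carry `NA` with a reason code rather than a zero, so
#' the downstream correlation screen can drop them explicitly.
#'
#' The night window is 18:00-06:00 local time (equatorial sites have
#' near-constant day length). Kill-level mass prefers the recorded carcass
#' weight and falls back to reference body mass. Kilometre-based CPUE uses
#' biomass harvested on GPS-tracked trips over the kilometres walked on
#' those trips. The annual extraction rate scales total harvested biomass
#' to a year using the community's monitored span and divides by its
#' hunting-territory area.
#'
#' @param trips data.frame with `trip_id`, `community`, `depart`, `return`,
#'   `methods_used` (comma-separated subset of gun/snare/hand).
#' @param kills data.frame with `trip_id`, `community`, `species_id`,
#'   `method`, `kill_time`, `weight_kg`, `traded`.
#' @param tracks optional data.frame with `trip_id`, `t`, `x`, `y`.
#' @param traits species trait table.
#' @param territory_area_km2 named vector of community territory areas, or
#'   `NULL` when territories were not estimated.
#' @param monitoring_days named per-community monitored spans in days;
#'   default is the span from first departure to last return per community.
#' @param night numeric `c(start, end)` hours of the night window.
#' @return object of class `"indicator_table"`: long data.frame with
#'   `community`, `id`, `name`, `value`, `reason`.
#' @export
compute_indicators <- function(trips, kills, tracks = NULL, traits,
                               territory_area_km2 = NULL,
                               monitoring_days = NULL,
                               night = c(18, 6)) {
  bad <- setdiff(kills$trip_id, trips$trip_id)
  if (length(bad)) stopf("kills reference unknown trips: %s",
                         paste(utils::head(bad, 5), collapse = ", "))
  miss <- setdiff(kills$species_id, traits$species_id)
  if (length(miss)) stopf("kills of species missing from traits: %s",
                          paste(miss, collapse = ", "))
  meta <- indicator_meta()
  rows <- lapply(sort(unique(trips$community)), function(cm) {
    ind <- community_indicators(
      trips[trips$community == cm, , drop = FALSE],
      kills[kills$community == cm, , drop = FALSE],
      tracks = if (!is.null(tracks)) tracks[tracks$trip_id %in%
        trips$trip_id[trips$community == cm], , drop = FALSE],
      traits = traits,
      area_km2 = if (!is.null(territory_area_km2)) territory_area_km2[[cm]],
      mon_days = if (!is.null(monitoring_days)) monitoring_days[[cm]],
      night = night)
    data.frame(community = cm, meta[, c("id", "name")],
               value = ind$value, reason = ind$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("indicator_table", "data.frame"))
}

community_indicators <- function(trips, kills, tracks, traits, area_km2,
                                 mon_days, night) {
  v <- setNames(rep(NA_real_, 33), sprintf("I%02d", 1:33))
  reason <- setNames(rep(NA_character_, 33), names(v))
  miss <- function(id, why) reason[id] <<- why

  nt <- nrow(trips); nk <- nrow(kills)
  trip_h <- as.numeric(difftime(trips$return, trips$depart, units = "hours"))
  kills_per_trip <- table(factor(kills$trip_id, levels = trips$trip_id))
  grp <- traits$taxon_group[match(kills$species_id, traits$species_id)]
  mass <- ifelse(!is.na(kills$weight_kg), kills$weight_kg,
                 traits$body_mass_kg[match(kills$species_id, traits$species_id)])

  if (nk > 0) {
    v["I01"] <- 100 * mean(kills$method == "gun")
    v["I02"] <- 100 * mean(kills$method == "snare")
    kt_known <- !is.na(kills$kill_time)
    if (any(kt_known)) {
      hh <- as.integer(format(kills$kill_time[kt_known], "%H", tz = "UTC"))
      at_night <- is_night_hour(hh, night[1], night[2])
      v["I03"] <- 100 * mean(at_night)
      v["I04"] <- 100 * mean(!at_night)
    } else { miss("I03", "no kill times"); miss("I04", "no kill times") }
    v["I08"] <- 100 * mean(grp == "rodent")
    v["I09"] <- 100 * mean(grp == "ungulate")
    v["I10"] <- 100 * mean(grp == "primate")
    v["I11"] <- 100 * mean(grp == "bird")
    dk <- traits$duiker_class[match(kills$species_id, traits$species_id)]
    if (any(dk != "none")) v["I12"] <- suppressWarnings(blue_duiker_pct(dk))
    else miss("I12", "no duikers harvested")
    v["I13"] <- mean(mass)
    v["I33"] <- 100 * mean(kills$traded)
  } else {
    for (id in c("I01", "I02", "I03", "I04", "I08", "I09", "I10", "I11",
                 "I12", "I13", "I33")) miss(id, "no kills")
  }

  # gun hunting trips: any trip whose declared methods include the gun
  is_gun <- grepl("gun", trips$methods_used, fixed = TRUE)
  if (any(is_gun)) {
    v["I05"] <- mean(trip_h[is_gun])
    gun_tracks <- if (!is.null(tracks) && nrow(tracks) > 0)
      tracks[tracks$trip_id %in% trips$trip_id[is_gun], , drop = FALSE]
    if (!is.null(gun_tracks) && nrow(gun_tracks) > 0) {
      lens <- vapply(split(gun_tracks, gun_tracks$trip_id),
                     function(tr) track_stats(tr)[["length_km"]], numeric(1))
      v["I06"] <- mean(lens)
      hh <- as.integer(format(gun_tracks$t, "%H", tz = "UTC"))
      v["I07"] <- 100 * mean(is_night_hour(hh, night[1], night[2]))
    } else {
      miss("I06", "no tracked gun trips")
      nh <- sum(mapply(night_hours, trips$depart[is_gun], trips$return[is_gun],
                       MoreArgs = list(night_start = night[1], night_end = night[2])))
      v["I07"] <- 100 * nh / sum(trip_h[is_gun])
    }
  } else { for (id in c("I05", "I06", "I07")) miss(id, "no gun trips") }

  if (nt > 0) {
    v["I14"] <- 100 * mean(kills_per_trip == 0)
    v["I15"] <- 100 * mean(trips$methods_used == "gun")
    v["I16"] <- 100 * mean(trips$methods_used == "snare")
  } else { for (id in c("I14", "I15", "I16")) miss(id, "no trips") }

  total_kg <- sum(mass)
  mon <- mon_days %||%
    as.numeric(difftime(max(trips$return), min(trips$depart), units = "days"))
  if (!is.null(area_km2) && is.finite(area_km2) && area_km2 > 0 &&
      is.finite(mon) && mon > 0) {
    v["I17"] <- total_kg * (365 / mon) / area_km2
  } else miss("I17", if (is.null(area_km2) || !is.finite(area_km2))
    "no territory area" else "zero territory area or monitoring span")

  # CPUE family: group biomass over the same community-wide denominators,
  # so per-group values sum exactly to the all-species value
  tracked_ids <- if (!is.null(tracks) && nrow(tracks) > 0) unique(tracks$trip_id)
  total_km <- if (!is.null(tracked_ids))
    sum(vapply(split(tracks, tracks$trip_id),
               function(tr) track_stats(tr)[["length_km"]], numeric(1)))
  kg_groups <- c(all = total_kg,
                 rodent = sum(mass[grp == "rodent"]),
                 ungulate = sum(mass[grp == "ungulate"]),
                 primate = sum(mass[grp == "primate"]),
                 bird = sum(mass[grp == "bird"]))
  kg_tracked <- if (!is.null(tracked_ids)) {
    on_track <- kills$trip_id %in% tracked_ids
    c(all = sum(mass[on_track]),
      rodent = sum(mass[on_track & grp == "rodent"]),
      ungulate = sum(mass[on_track & grp == "ungulate"]),
      primate = sum(mass[on_track & grp == "primate"]),
      bird = sum(mass[on_track & grp == "bird"]))
  }
  slots <- list(all = c("I18", "I19", "I20"), rodent = c("I21", "I22", "I23"),
                ungulate = c("I24", "I25", "I26"),
                primate = c("I27", "I28", "I29"), bird = c("I30", "I31", "I32"))
  for (g in names(slots)) {
    ids <- slots[[g]]
    if (nt > 0) {
      v[ids[1]] <- kg_groups[[g]] / nt
      v[ids[2]] <- kg_groups[[g]] / sum(trip_h)
    } else { miss(ids[1], "no trips"); miss(ids[2], "no trips") }
    if (!is.null(tracked_ids) && total_km > 0)
      v[ids[3]] <- kg_tracked[[g]] / total_km
    else miss(ids[3], "no tracked trips")
  }
  list(value = unname(v), reason = unname(reason))
}

#' Ratio of rodent to ungulate kills
#'
#' The headline composite of the two strongest degradation indicators
#' (percent rodents and percent ungulates in the offtake): the count of
#' rodent kills over the count of ungulate kills. Rises along the
#' degradation gradient from well under 0.1 to above 1.
#'
#' @param kills kill records with `species_id`.
#' @param traits species trait table.
#' @return nonnegative ratio; `NA` (with warning) when no ungulate kills.
#' @export
rodents_ungulates_ratio <- function(kills, traits) {
  grp <- traits$taxon_group[match(kills$species_id, traits$species_id)]
  n_ung <- sum(grp == "ungulate")
  if (n_ung == 0) {
    warnf("no ungulate kills; rodents:ungulates ratio undefined")
    return(NA_real_)
  }
  sum(grp == "rodent") / n_ung
}

#' Offtake species richness at a standard number of hunting trips
#'
#' Trip-based rarefaction of the harvested species list: same analytic
#' interpolation as [rarefied_richness()] with hunting trips as sampling
#' units, standardising richness comparisons across communities with
#' unequal monitoring (default 500 recorded trips).
#'
#' @param kills kill records with `trip_id`, `species_id`.
#' @param trips trip records (defines the unit list, including zero-kill trips).
#' @param n_trips_target target number of trips, default 500.
#' @return expected species count; observed richness (flagged) when the
#'   target exceeds the recorded trips.
#' @export
offtake_species_accumulation <- function(kills, trips, n_trips_target = 500) {
  sp <- sort(unique(kills$species_id))
  inc <- matrix(FALSE, nrow(trips), length(sp),
                dimnames = list(trips$trip_id, sp))
  if (nrow(kills))
    inc[cbind(match(kills$trip_id, trips$trip_id),
              match(kills$species_id, sp))] <- TRUE
  rarefied_richness(inc, n_trips_target)
}

#' @export
print.indicator_table <- function(x, digits = 3, ...) {
  wide <- stats::reshape(as.data.frame(x)[, c("community", "id", "value")],
                         idvar = "community", timevar = "id",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  cat(sprintf("Offtake indicators: %d communities x 33 indicators (%d missing slots)\n",
              length(unique(x$community)), sum(is.na(x$value))))
  print(utils::head(wide[, 1:min(8, ncol(wide))], 10), digits = digits,
        row.names = FALSE)
  invisible(x)
}
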