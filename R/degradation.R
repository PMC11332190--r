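#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|a_k - b_k|) / sum(a_k + b_k)` over a shared species ordering:
#' 0 for identical assemblages, 1 for disjoint supports. Used here on
#' group-size-weighted daily detection rates, so a community station's
#' dissimilarity from a reference station measures faunal degradation.
#'
#' @param a,b nonnegative abundance vectors on the same species ordering.
#' @return dissimilarity in `[0, 1]`, or `NA` (with a warning) when both
#'   vectors are all zero.
#' @examples
#' bray_curtis(c(2, 1), c(1, 3))  # 3/7
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stopf("vectors must share one species ordering")
  if (any(a < 0 | b < 0)) stopf("abundances must be nonnegative")
  denom <- sum(a + b)
  if (denom == 0) {
    warnf("both assemblages empty; Bray-Curtis undefined, pair skipped")
    return(NA_real_)
  }
  sum(abs(a - b)) / denom
}

# All pairwise BC values between rows of A (n_a x S) and rows of B (n_b x S).
bc_cross <- function(A, B) {
  out <- matrix(NA_real_, nrow(A), nrow(B),
                dimnames = list(rownames(A), rownames(B)))
  for (j in seq_len(nrow(B))) {
    b <- B[j, ]
    num <- rowSums(abs(sweep(A, 2, b)))
    den <- rowSums(A) + sum(b)
    out[, j] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

# Align two abundance matrices on the union of their species, zero-filling.
align_species <- function(A, B) {
  sp <- sort(union(colnames(A), colnames(B)))
  pad <- function(M) {
    out <- matrix(0, nrow(M), length(sp), dimnames = list(rownames(M), sp))
    out[, colnames(M)] <- M
    out
  }
  list(A = pad(A), B = pad(B))
}

#' Per-community faunal degradation scores
#'
#' Scores every pair of one community station and one reference station with
#' the Bray-Curtis dissimilarity of their weighted daily detection rates
#' (on the union species set, zero-filling absences), then summarises each
#' community by the median of its pairs. Communities are ranked by ascending
#' median (least degraded first). With 301 retained hunted stations and 38
#' reference stations this emits 11,438 pair values.
#'
#' @param hunted an `"abundance_matrix"` of the hunted-community stations
#'   (its `community` field defines the grouping).
#' @param reference an `"abundance_matrix"` of the reference-site stations.
#' @return object of class `"degradation_scores"`: data.frame with
#'   `community`, `median_bc`, `n_pairs`, `rank`; attribute `"pairs"` holds
#'   the full per-community vectors of pair values.
#' @export
pairwise_degradation <- function(hunted, reference) {
  stopifnot(inherits(hunted, "abundance_matrix"),
            inherits(reference, "abundance_matrix"))
  al <- align_species(hunted$N, reference$N)
  comms <- unique(hunted$community)
  pairs <- list(); rows <- list()
  for (cm in comms) {
    A <- al$A[hunted$community == cm, , drop = FALSE]
    if (nrow(A) == 0) {
      rows[[cm]] <- data.frame(community = cm, median_bc = NA_real_,
                               n_pairs = 0L, stringsAsFactors = FALSE)
      pairs[[cm]] <- numeric(0)
      next
    }
    bc <- bc_cross(A, al$B)
    v <- as.numeric(bc)
    pairs[[cm]] <- v
    rows[[cm]] <- data.frame(community = cm,
                             median_bc = median(v, na.rm = TRUE),
                             n_pairs = length(v), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$rank <- rank(out$median_bc, ties.method = "first", na.last = "keep")
  out <- out[order(out$median_bc), ]
  rownames(out) <- NULL
  structure(out, pairs = pairs, class = c("degradation_scores", "data.frame"))
}

#' @export
print.degradation_scores <- function(x, digits = 3, ...) {
  cat("Faunal degradation (median Bray-Curtis vs reference), least degraded first:\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Detection-event composition by major species group
#'
#' Shares of independent detection events per site over the groups
#' rodents, ungulates, carnivores, apes, terrestrial birds and other
#' species (monkeys and remaining taxa fold into "other").
#'
#' @param events events from [collapse_events()].
#' @param stations station metadata giving each station's site.
#' @param traits species trait table.
#' @return data.frame site x group shares; shares sum to 1 per site.
#' @export
composition_proportions <- function(events, stations, traits) {
  grp <- traits$taxon_group[match(events$species_id, traits$species_id)]
  shown <- c("rodent", "ungulate", "carnivore", "ape", "bird")
  grp <- ifelse(grp %in% shown, grp, "other")
  site <- stations$community[match(events$station_id, stations$station_id)]
  tab <- table(factor(site), factor(grp, levels = c(shown, "other")))
  prop <- prop.table(tab, margin = 1)
  as.data.frame.matrix(prop)
}

#' Mean body mass of camera-trap detection events
#'
#' Event-weighted mean of reference body masses over all detection events
#' (each independent event counts once regardless of group size; an
#' individual-weighted variant multiplies each event by its maximum
#' individual count).
#'
#' @param events events from [collapse_events()].
#' @param traits species trait table with `body_mass_kg`.
#' @param weight_by_individuals if `TRUE`, weight each event by
#'   `max_individuals`.
#' @return mean body mass in kg.
#' @export
ct_mean_body_mass <- function(events, traits, weight_by_individuals = FALSE) {
  m <- traits$body_mass_kg[match(events$species_id, traits$species_id)]
  if (anyNA(m))
    stopf("missing body mass for species: %s",
          paste(unique(events$species_id[is.na(m)]), collapse = ", "))
  if (weight_by_individuals)
    weighted.mean(m, events$max_individuals)
  else mean(m)
}

#' Blue duikers as a percentage of all duikers
#'
#' `100 * blue / (blue + other duikers)`; a dual index that rises with
#' hunting pressure because medium and large duikers are less resistant
#' than the small blue duiker.
#'
#' @param duiker_class character vector of per-record duiker classes
#'   (`"blue"`, `"other_duiker"`, `"none"`), or a named numeric count
#'   vector with elements `blue` and `other_duiker`.
#' @return percentage in `[0, 100]`, or `NA` (with warning) when no duiker
#'   records are present.
#' @export
blue_duiker_pct <- function(duiker_class) {
  if (is.numeric(duiker_class)) {
    blue <- duiker_class[["blue"]]; other <- duiker_class[["other_duiker"]]
  } else {
    blue <- sum(duiker_class == "blue")
    other <- sum(duiker_class == "other_duiker")
  }
  if (blue + other == 0) {
    warnf("no duiker records; BlueDuiker%% undefined")
    return(NA_real_)
  }
  100 * blue / (blue + other)
}

#' Rarefied species richness at a standard sampling effort
#'
#' Analytic sample-based rarefaction (interpolation) on incidence data:
#' the expected richness in `t` of `T` sampling units is
#' `sum_k [1 - choose(T - T_k, t) / choose(T, t)]` where `T_k` is the
#' number of units in which species k was detected. Units here are
#' camera-days (one station-day) or hunting trips. If the target effort
#' exceeds the observed effort the observed richness is returned with an
#' attribute `extrapolated = TRUE`; no extrapolation is attempted.
#'
#' @param incidence units x species matrix (logical or 0/1) of detections.
#' @param target_effort target number of units (default 1000 camera-days);
#'   rounded to a whole unit.
#' @return expected species count (numeric).
#' @export
rarefied_richness <- function(incidence, target_effort = 1000) {
  inc <- (as.matrix(incidence) > 0)
  Tn <- nrow(inc)
  Tk <- colSums(inc)
  Tk <- Tk[Tk > 0]
  t <- round(target_effort)
  if (t < 1) stopf("target_effort must be at least one unit")
  if (t >= Tn)
    return(structure(length(Tk), flagged = t > Tn, extrapolated = t > Tn))
  es <- sum(1 - exp(lchoose(Tn - Tk, t) - lchoose(Tn, t)))
  es
}

#' Build a station-day incidence matrix from detection events
#'
#' One row per functioning station-day, one column per species; used as the
#' sampling-unit mapping for [rarefied_richness()] on camera-trap data.
#'
#' @param events events from [collapse_events()].
#' @param stations station metadata with deployment windows.
#' @return logical matrix (station-days x species).
#' @export
incidence_by_station_day <- function(events, stations) {
  days <- pmax(1, round(as.numeric(difftime(stations$deploy_end,
                                            stations$deploy_start, units = "days"))))
  unit_station <- rep(stations$station_id, days)
  unit_day <- unlist(lapply(days, seq_len))
  unit_id <- paste(unit_station, unit_day, sep = ".d")
  start_of <- setNames(stations$deploy_start, stations$station_id)
  ev_day <- 1 + floor(as.numeric(difftime(events$event_start,
                                          start_of[events$station_id],
                                          units = "days")))
  ev_unit <- paste(events$station_id, ev_day, sep = ".d")
  sp <- sort(unique(events$species_id))
  inc <- matrix(FALSE, length(unit_id), length(sp),
                dimnames = list(unit_id, sp))
  ok <- ev_unit %in% unit_id
  inc[cbind(match(ev_unit[ok], unit_id), match(events$species_id[ok], sp))] <- TRUE
  inc
}
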