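#' Fit the full offtake-indicator degradation screen
#'
#' The package's central fitting function. From raw camera-trap triggers,
#' station metadata, hunting trips/kills (and optionally GPS tracks) it:
#' collapses triggers into 30-minute independent detection events; builds
#' the group-size-weighted daily detection rate matrix and filters rare
#' species / species-poor stations to a fixpoint on the pooled matrix (so
#' both sides of every pair satisfy the criteria); scores every
#' (community station, reference station) pair with the Bray-Curtis
#' dissimilarity and summarises communities by their median; estimates
#' per-hunter movement-based kernel utilization distributions and stacks
#' their 0.95 isopleths into community territory areas (when tracks are
#' supplied); computes the 33 offtake indicators; and correlates each
#' indicator with the degradation medians under a Bonferroni adjustment.
#'
#' @param detections camera-trap trigger records (`station_id`,
#'   `timestamp`, `species_id`, `count`).
#' @param stations station metadata (`station_id`, `community`, `x`, `y`,
#'   `deploy_start`, `deploy_end`); the reference grid's community must
#'   equal `reference`.
#' @param trips,kills,tracks hunting records as in [compute_indicators()];
#'   `tracks` may be `NULL` (km-based CPUE and territory areas are then
#'   reported missing).
#' @param traits species trait table.
#' @param reference community label of the reference site (default
#'   `"REFERENCE"`).
#' @param window_minutes event-independence window (default 30).
#' @param min_days functioning-days threshold for stations (default 7).
#' @param min_stations_per_species,min_species_per_station abundance-matrix
#'   filters (default 3 each).
#' @param night night window hours (default `c(18, 6)`).
#' @param m Bonferroni multiplier (default 33).
#' @param level isopleth level for territories (default 0.95).
#' @param ud_cell_m UD raster cell in metres (default 50).
#' @param compute_territory estimate hunter UDs and territory areas;
#'   defaults to `TRUE` when tracks are supplied. Quadratic in track length,
#'   so the dominant cost on large track sets.
#' @return object of class `"hunt_screen"` with components `events`,
#'   `abundance` (filtered pooled matrix), `scores`
#'   (`"degradation_scores"`), `territories` (named areas, km^2),
#'   `indicators` (`"indicator_table"`), `screen` (`"indicator_screen"`)
#'   and the call.
#' @seealso [collapse_events()], [pairwise_degradation()],
#'   [compute_indicators()], [screen_indicators()]
#' @examples
#' sc <- scenario_config(n_communities = 3, n_stations_per_site = 6,
#'                       days_per_station = 30, n_trips_per_community = 15,
#'                       mean_trip_hours = 4, gps_fraction = 0, seed = 42)
#' traits <- make_species_pool(12, seed = 42)
#' ct <- simulate_camera_traps(sc, traits)
#' h <- simulate_hunts(sc, traits)
#' fit <- hunt_screen(ct$detections, ct$stations, h$trips, h$kills,
#'                    tracks = NULL, traits = traits)
#' fit
#' @export
hunt_screen <- function(detections, stations, trips, kills, tracks = NULL,
                        traits, reference = "REFERENCE",
                        window_minutes = 30, min_days = 7,
                        min_stations_per_species = 3,
                        min_species_per_station = 3,
                        night = c(18, 6), m = 33, level = 0.95,
                        ud_cell_m = 50,
                        compute_territory = !is.null(tracks)) {
  if (!reference %in% stations$community)
    stopf("no stations belong to the reference site '%s'", reference)
  events <- collapse_events(detections, window_minutes)
  ab <- abundance_matrix(events, stations, traits, min_days = min_days)
  ab <- apply_filters(ab, min_stations_per_species, min_species_per_station)
  is_ref <- ab$community == reference
  split_ab <- function(sel) structure(
    list(N = ab$N[sel, , drop = FALSE], days = ab$days[sel],
         community = ab$community[sel]), class = "abundance_matrix")
  scores <- pairwise_degradation(split_ab(!is_ref), split_ab(is_ref))

  territories <- NULL
  if (compute_territory && !is.null(tracks) && nrow(tracks) > 0) {
    territories <- vapply(split(tracks, tracks$community), function(tc) {
      uds <- lapply(split(tc, tc$hunter_id), function(th) {
        # pool a hunter's trips into one UD via time-weighted bursts
        th <- th[order(th$t), ]
        mbkde_ud(th, cell_m = ud_cell_m)
      })
      community_territory(uds, level = level)$area_km2
    }, numeric(1))
  }

  indicators <- compute_indicators(trips, kills, tracks, traits,
                                   territory_area_km2 = territories,
                                   night = night)
  screen <- screen_indicators(indicators, scores, m = m)
  structure(list(events = events, abundance = ab, scores = scores,
                 territories = territories, indicators = indicators,
                 screen = screen, reference = reference,
                 call = match.call()),
            class = "hunt_screen")
}

#' @export
print.hunt_screen <- function(x, digits = 3, ...) {
  cat("Offtake-indicator screen against camera-trap faunal degradation\n\n")
  print(x$scores, digits = digits)
  cat("\n")
  print(x$screen, digits = digits, max_rows = 7)
  invisible(x)
}

#' @export
summary.hunt_screen <- function(object, ...) {
  rep <- screen_report(object$screen, object$indicators)
  structure(list(report = rep, abundance = object$abundance,
                 territories = object$territories,
                 n_events = nrow(object$events)),
            class = "summary.hunt_screen")
}

#' @export
print.summary.hunt_screen <- function(x, digits = 3, ...) {
  cat(sprintf("Events: %d | retained stations: %d | retained species: %d\n",
              x$n_events, nrow(x$abundance$N), ncol(x$abundance$N)))
  cat("\nCommunities (ascending degradation):\n")
  print(x$report$communities, digits = digits, row.names = FALSE)
  if (!is.null(x$territories)) {
    cat("\nTerritory areas (km^2):\n")
    print(round(x$territories, 2))
  }
  cat("\nIndicator screen:\n")
  cols <- c("id", "name", "n", "r", "p", "p_bonferroni",
            "significant_adjusted", "direction_matches")
  print(x$report$indicators[, cols], digits = digits, row.names = FALSE)
  invisible(x)
}

#' Indicator correlations from a fitted screen
#'
#' @param object a `"hunt_screen"`.
#' @param ... unused.
#' @return named vector of Pearson correlations (indicator id -> r),
#'   in screen ranking order.
#' @export
coef.hunt_screen <- function(object, ...) {
  setNames(object$screen$r, object$screen$id)
}

#' Plot a fitted indicator screen
#'
#' Scatter of the top-ranked indicator (or a chosen one) against the
#' community median degradation, with the least-squares line.
#'
#' @param x a `"hunt_screen"`.
#' @param indicator indicator id, default the largest `|r|`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hunt_screen <- function(x, indicator = x$screen$id[1], ...) {
  med <- setNames(x$scores$median_bc, x$scores$community)
  sub <- x$indicators[x$indicators$id == indicator, ]
  val <- setNames(sub$value, sub$community)[names(med)]
  row <- x$screen[x$screen$id == indicator, ]
  graphics::plot(med, val, xlab = "median Bray-Curtis degradation",
                 ylab = row$name,
                 main = sprintf("%s: r = %.2f, p = %.3g", indicator,
                                row$r, row$p), ...)
  ok <- is.finite(med) & is.finite(val)
  if (sum(ok) >= 3) graphics::abline(stats::lm(val[ok] ~ med[ok]), lty = 2)
  invisible(x)
}
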