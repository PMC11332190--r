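#' Simulate camera-trap trigger records along a defaunation gradient
#'
#' Lays out one systematic camera-trap grid per community (one station per
#' 2 km^2) plus a reference grid, then draws, for every station and species,
#' a Poisson number of independent encounters with mean
#' `days * base_rate_k * exp(slope[group(k)] * d)` where `d` is the
#' community's degradation level. Each encounter is expanded into 1-3 video
#' triggers less than 30 minutes apart — so downstream event collapsing is
#' exercised and its removal measurable — and each trigger carries an
#' individual count of `1 + Poisson(mean_group_size - 1)`.
#'
#' @param scenario a [scenario_config()].
#' @param traits species trait table from [make_species_pool()].
#' @return list with `detections` (station_id, timestamp, species_id, count)
#'   and `stations` (station_id, community, x, y, deploy_start, deploy_end).
#' @examples
#' sc <- scenario_config(n_communities = 2, n_stations_per_site = 4,
#'                       days_per_station = 20, seed = 1)
#' ct <- simulate_camera_traps(sc, make_species_pool(8, 1))
#' head(ct$detections)
#' @export
simulate_camera_traps <- function(scenario, traits) {
  sc <- validate_scenario(scenario)
  set.seed(substream(sc$seed, 2))
  villages <- village_points(sc)
  t0 <- as.POSIXct("2021-06-15 00:00:00", tz = "UTC")

  stations <- do.call(rbind, lapply(seq_len(nrow(villages)), function(i) {
    v <- villages[i, ]
    n <- if (v$community == "REFERENCE") sc$n_reference_stations else sc$n_stations_per_site
    ncol_grid <- ceiling(sqrt(n))
    idx <- seq_len(n) - 1
    spacing <- sqrt(2e6)  # one CT every 2 km^2
    data.frame(station_id = sprintf("%s_ct%03d", v$community, seq_len(n)),
               community = v$community,
               x = v$x + (idx %% ncol_grid) * spacing,
               y = v$y + 1000 + (idx %/% ncol_grid) * spacing,
               deploy_start = t0,
               deploy_end = t0 + sc$days_per_station * 86400,
               stringsAsFactors = FALSE)
  }))
  rownames(stations) <- NULL

  det <- vector("list", nrow(villages))
  for (i in seq_len(nrow(villages))) {
    v <- villages[i, ]
    st <- stations[stations$community == v$community, ]
    rates <- species_rates(sc, traits, v$degradation)
    grid <- expand.grid(station = st$station_id, species = traits$species_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lambda <- sc$days_per_station * rates[grid$species]
    n_enc <- rpois(nrow(grid), lambda)
    keep <- n_enc > 0
    if (!any(keep)) { det[[i]] <- NULL; next }
    enc_station <- rep(grid$station[keep], n_enc[keep])
    enc_species <- rep(grid$species[keep], n_enc[keep])
    n_total_enc <- length(enc_station)
    enc_t0 <- t0 + runif(n_total_enc, 0, sc$days_per_station * 86400 - 1800)

    # expand each encounter to 1-3 triggers with < 30 min consecutive gaps
    n_trig <- sample.int(3, n_total_enc, replace = TRUE)
    row_enc <- rep(seq_len(n_total_enc), n_trig)
    within <- sequence(n_trig)
    gaps <- runif(length(row_enc), 60, 540)
    gaps[within == 1] <- 0
    cs <- cumsum(gaps)
    first_of <- cumsum(c(1, n_trig[-n_total_enc]))
    offset <- cs - rep(cs[first_of], n_trig)

    gs <- traits$mean_group_size[match(enc_species[row_enc], traits$species_id)]
    det[[i]] <- data.frame(
      station_id = enc_station[row_enc],
      timestamp = enc_t0[row_enc] + offset,
      species_id = enc_species[row_enc],
      count = 1L + rpois(length(row_enc), gs - 1),
      stringsAsFactors = FALSE)
  }
  detections <- do.call(rbind, det)
  detections <- detections[order(detections$station_id, detections$species_id,
                                 detections$timestamp), ]
  rownames(detections) <- NULL
  list(detections = detections, stations = stations)
}
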