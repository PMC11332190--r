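#' Simulate hunting trips, kills and GPS tracks
#'
#' Draws, per community, hunting trips with log-normal durations around the
#' configured mean, Poisson kill counts, kill species multinomial in
#' `rate_k(d) * catchability_k` (so the offtake composition tracks local
#' abundance along the degradation gradient), kill weights as reference body
#' mass times a `lognormal(0, 0.1)` factor, a traded flag Bernoulli in the
#' community's trade probability
#' `clamp(trade_base + trade_slope * d + e_c)` — where `e_c` is a
#' community-level normal perturbation capturing market-access and
#' socioeconomic differences between villages — per-kill methods from the
#' gun/snare/hand mixture, and gun kill times drawn at night with the
#' configured night fraction. A configurable share of trips carries a GPS
#' track: an out-and-back correlated random walk at the fix interval,
#' starting and ending exactly at the community's village point.
#'
#' For tracked trips the return time is set to the track's last fix so trip
#' duration and trace agree.
#'
#' @inheritParams simulate_camera_traps
#' @return list with data.frames `trips` (trip_id, hunter_id, community,
#'   depart, return, methods_used, tracked), `kills` (kill_id, trip_id,
#'   community, species_id, method, kill_time, weight_kg, traded),
#'   `tracks` (trip_id, hunter_id, community, t, x, y) and `communities`
#'   (community, degradation, trade_p: the realized per-community trade
#'   probability).
#' @examples
#' sc <- scenario_config(n_communities = 2, n_trips_per_community = 5,
#'                       mean_trip_hours = 3, seed = 1)
#' h <- simulate_hunts(sc, make_species_pool(8, 1))
#' nrow(h$trips)
#' @export
simulate_hunts <- function(scenario, traits) {
  sc <- validate_scenario(scenario)
  set.seed(substream(sc$seed, 3))
  villages <- village_points(sc)
  villages <- villages[villages$community != "REFERENCE", ]
  t0 <- as.POSIXct("2021-06-15 00:00:00", tz = "UTC")
  catch <- sc$catchability %||% setNames(rep(1, nrow(traits)), traits$species_id)

  trips_l <- list(); kills_l <- list(); tracks_l <- list()
  kill_counter <- 0L
  # community-level trade probabilities: gradient effect plus village noise
  trade_p_all <- clamp01(sc$trade_base + sc$trade_slope * villages$degradation +
                           rnorm(nrow(villages), 0, sc$trade_site_sd))
  # community-level yield multipliers: villages differ in returns per trip
  yield_all <- sc$trip_yield * rlnorm(nrow(villages), 0, sc$yield_site_sd)
  for (i in seq_len(nrow(villages))) {
    v <- villages[i, ]
    trade_p <- trade_p_all[i]
    n <- sc$n_trips_per_community
    hunters <- sprintf("%s_h%02d", v$community, seq_len(sc$n_hunters_per_community))
    trip_id <- sprintf("%s_t%04d", v$community, seq_len(n))
    hunter <- sample(hunters, n, replace = TRUE)
    depart <- t0 + round(runif(n, 0, 364 * 86400) / 60) * 60
    dur_h <- rlnorm(n, meanlog = log(sc$mean_trip_hours) - 0.125, sdlog = 0.5)
    tracked <- runif(n) < sc$gps_fraction

    # GPS tracks: out-leg correlated random walk retraced home
    for (j in which(tracked)) {
      n_fix <- max(5, round(dur_h[j] * 3600 / sc$fix_interval_s) + 1)
      m <- ceiling((n_fix + 1) / 2)
      step_mean <- sc$walk_speed_kmh / 3.6 * sc$fix_interval_s
      heading <- runif(1, 0, 2 * pi) + cumsum(rnorm(m - 1, 0, 0.35))
      step <- rgamma(m - 1, shape = 4, scale = step_mean / 4)
      xs <- v$x + c(0, cumsum(step * cos(heading)))
      ys <- v$y + c(0, cumsum(step * sin(heading)))
      xs <- c(xs, rev(xs[-m])); ys <- c(ys, rev(ys[-m]))
      nf <- length(xs)
      dur_h[j] <- (nf - 1) * sc$fix_interval_s / 3600
      tracks_l[[length(tracks_l) + 1L]] <- data.frame(
        trip_id = trip_id[j], hunter_id = hunter[j], community = v$community,
        t = depart[j] + (seq_len(nf) - 1) * sc$fix_interval_s,
        x = xs, y = ys, stringsAsFactors = FALSE)
    }
    ret <- depart + dur_h * 3600

    n_kills <- rpois(n, yield_all[i])
    rates <- species_rates(sc, traits, v$degradation)
    p_sp <- rates * catch[traits$species_id]
    p_sp <- p_sp / sum(p_sp)
    methods_used <- character(n)
    for (j in seq_len(n)) {
      if (n_kills[j] == 0) {
        methods_used[j] <- sample(names(sc$method_mix), 1, prob = sc$method_mix)
        next
      }
      sp <- sample(traits$species_id, n_kills[j], replace = TRUE, prob = p_sp)
      meth <- sample(names(sc$method_mix), n_kills[j], replace = TRUE,
                     prob = sc$method_mix)
      methods_used[j] <- paste(sort(unique(meth)), collapse = ",")
      want_night <- meth == "gun" & runif(n_kills[j]) < sc$gun_night_fraction
      kt <- depart[j] + runif(n_kills[j]) * (as.numeric(ret[j]) - as.numeric(depart[j]))
      for (k in seq_len(n_kills[j])) {
        cand <- depart[j] + runif(40) * (as.numeric(ret[j]) - as.numeric(depart[j]))
        hh <- as.integer(format(cand, "%H", tz = "UTC"))
        ok <- if (want_night[k]) is_night_hour(hh) else !is_night_hour(hh)
        if (any(ok)) kt[k] <- cand[which(ok)[1]]
      }
      mass <- traits$body_mass_kg[match(sp, traits$species_id)]
      kills_l[[length(kills_l) + 1L]] <- data.frame(
        kill_id = sprintf("k%06d", kill_counter + seq_len(n_kills[j])),
        trip_id = trip_id[j], community = v$community,
        species_id = sp, method = meth, kill_time = kt,
        weight_kg = mass * rlnorm(n_kills[j], 0, 0.1),
        traded = runif(n_kills[j]) < trade_p,
        stringsAsFactors = FALSE)
      kill_counter <- kill_counter + n_kills[j]
    }
    trips_l[[i]] <- data.frame(trip_id = trip_id, hunter_id = hunter,
                               community = v$community, depart = depart,
                               return = ret, methods_used = methods_used,
                               tracked = tracked, stringsAsFactors = FALSE)
  }
  empty_kills <- data.frame(kill_id = character(), trip_id = character(),
                            community = character(), species_id = character(),
                            method = character(),
                            kill_time = as.POSIXct(character(), tz = "UTC"),
                            weight_kg = numeric(), traded = logical(),
                            stringsAsFactors = FALSE)
  list(trips = do.call(rbind, trips_l),
       kills = if (length(kills_l)) do.call(rbind, kills_l) else empty_kills,
       tracks = if (length(tracks_l)) do.call(rbind, tracks_l) else NULL,
       communities = data.frame(community = villages$community,
                                degradation = villages$degradation,
                                trade_p = trade_p_all,
                                stringsAsFactors = FALSE))
}
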