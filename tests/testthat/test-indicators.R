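# Hand-built one-community fixtures with known answers.

mk_trip <- function(id, dur_h = 12, methods = "gun", community = "C01",
                    depart = utc("2021-03-01 06:00:00")) {
  data.frame(trip_id = id, hunter_id = "h1", community = community,
             depart = depart, return = depart + dur_h * 3600,
             methods_used = methods, tracked = FALSE, stringsAsFactors = FALSE)
}

mk_kill <- function(id, trip, species, method = "gun", weight = NA_real_,
                    traded = FALSE, time = utc("2021-03-01 12:00:00"),
                    community = "C01") {
  data.frame(kill_id = id, trip_id = trip, community = community,
             species_id = species, method = method, kill_time = time,
             weight_kg = weight, traded = traded, stringsAsFactors = FALSE)
}

test_that("indicator table always carries exactly 33 slots per community", {
  trips <- rbind(mk_trip("t1"), mk_trip("t2", community = "C02"))
  kills <- mk_kill("k1", "t1", "sp1")
  ind <- compute_indicators(trips, kills, traits = tiny_traits())
  expect_s3_class(ind, "indicator_table")
  expect_equal(as.integer(table(ind$community)), c(33L, 33L))
  expect_equal(ind$id[1:33], sprintf("I%02d", 1:33))
  # missing slots carry reasons, not zeros
  expect_true(all(!is.na(ind$reason[is.na(ind$value)])))
  pct <- grepl("^pct", ind$name) & !is.na(ind$value)
  expect_true(all(ind$value[pct] >= 0 & ind$value[pct] <= 100))
})

test_that("catch composition percentages and the rodents:ungulates ratio", {
  trips <- mk_trip("t1")
  kills <- rbind(
    do.call(rbind, lapply(1:5, function(i) mk_kill(paste0("r", i), "t1", "sp1"))),
    do.call(rbind, lapply(1:20, function(i) mk_kill(paste0("u", i), "t1", "sp3"))))
  ind <- compute_indicators(trips, kills, traits = tiny_traits())
  v <- setNames(ind$value, ind$id)
  expect_equal(v[["I08"]], 20)
  expect_equal(v[["I09"]], 80)
  expect_equal(rodents_ungulates_ratio(kills, tiny_traits()), 0.25)
  expect_equal(rodents_ungulates_ratio(kills, tiny_traits()),
               v[["I08"]] / v[["I09"]])
  only_u <- kills[6:15, ]
  expect_equal(rodents_ungulates_ratio(only_u, tiny_traits()), 0)
  only_r <- kills[1:5, ]
  expect_warning(rr <- rodents_ungulates_ratio(only_r, tiny_traits()), "undefined")
  expect_true(is.na(rr))
})

test_that("CPUE: one 12-h trip, 6 kg harvested, 4 km walked", {
  trips <- mk_trip("t1", dur_h = 12)
  kills <- rbind(mk_kill("k1", "t1", "sp1", weight = 2),
                 mk_kill("k2", "t1", "sp3", weight = 4))
  track <- line_track(n = 21, step_m = 200)  # 20 segments x 200 m = 4 km
  track$trip_id <- "t1"
  ind <- compute_indicators(trips, kills, tracks = track, traits = tiny_traits())
  v <- setNames(ind$value, ind$id)
  expect_equal(v[["I18"]], 6)    # kg per trip
  expect_equal(v[["I19"]], 0.5)  # kg per hour
  expect_equal(v[["I20"]], 1.5)  # kg per km
  # per-group masses land in the right slots
  expect_equal(v[["I21"]], 2)    # rodent kg / trip
  expect_equal(v[["I24"]], 4)    # ungulate kg / trip
})

test_that("method, day/night and success partitions close", {
  depart <- utc("2021-03-01 06:00:00")
  trips <- rbind(mk_trip("t1", methods = "gun"),
                 mk_trip("t2", methods = "snare"),
                 mk_trip("t3", methods = "gun,snare"),
                 mk_trip("t4", methods = "gun"))
  kills <- rbind(
    mk_kill("k1", "t1", "sp1", method = "gun", time = depart + 15 * 3600),  # 21:00
    mk_kill("k2", "t2", "sp3", method = "snare", time = depart + 2 * 3600), # 08:00
    mk_kill("k3", "t3", "sp4", method = "hand", time = depart + 4 * 3600))
  ind <- compute_indicators(trips, kills, traits = tiny_traits())
  v <- setNames(ind$value, ind$id)
  expect_equal(v[["I01"]] + v[["I02"]], 100 * 2 / 3)  # + hand = 100
  expect_equal(v[["I03"]] + v[["I04"]], 100)
  expect_equal(v[["I03"]], 100 / 3)
  expect_equal(v[["I14"]], 25)                         # t4 unsuccessful
  expect_equal(v[["I15"]], 50)                         # t1, t4 strict gun
  expect_equal(v[["I16"]], 25)                         # t2 strict trap
  expect_lte(v[["I15"]] + v[["I16"]], 100)
})

test_that("trade, extraction rate and mass fallback", {
  trips <- mk_trip("t1", dur_h = 24)
  kills <- rbind(mk_kill("k1", "t1", "sp3", weight = 10, traded = TRUE),
                 mk_kill("k2", "t1", "sp1", traded = TRUE))  # falls back to 2.5 kg
  ind <- compute_indicators(trips, kills, traits = tiny_traits(),
                            territory_area_km2 = c(C01 = 25),
                            monitoring_days = c(C01 = 365))
  v <- setNames(ind$value, ind$id)
  expect_equal(v[["I33"]], 100)
  expect_equal(v[["I13"]], (10 + 2.5) / 2)
  expect_equal(v[["I17"]], 12.5 * 1 / 25)
  # zero area -> missing with reason
  ind0 <- compute_indicators(trips, kills, traits = tiny_traits(),
                             territory_area_km2 = c(C01 = 0))
  expect_true(is.na(ind0$value[ind0$id == "I17"]))
  expect_match(ind0$reason[ind0$id == "I17"], "territory")
})

test_that("per-group CPUE decomposes the all-species CPUE", {
  sc <- small_scenario(seed = 13)
  h <- simulate_hunts(sc, tiny_traits())
  ind <- compute_indicators(h$trips, h$kills, tracks = h$tracks,
                            traits = tiny_traits())
  for (cm in unique(ind$community)) {
    v <- setNames(ind$value[ind$community == cm], ind$id[ind$community == cm])
    for (off in 0:2) {  # trip, hour, km denominators
      groups <- v[sprintf("I%02d", c(21, 24, 27, 30) + off)]
      total <- v[[sprintf("I%02d", 18 + off)]]
      if (!is.na(total) && !anyNA(groups))
        expect_lte(sum(groups), total + 1e-9)
    }
    # with the 5-species pool every kill is in a named group: sums are exact
    v5 <- v[sprintf("I%02d", c(21, 24, 27, 30))]
    if (!anyNA(v5)) expect_equal(sum(v5), v[["I18"]], tolerance = 1e-9)
  }
})

test_that("percent traded recovers the generative trade fraction", {
  tr <- tiny_traits()
  sc <- scenario_config(n_communities = 2, degradation_levels = c(0.2, 0.8),
                        n_trips_per_community = 150, trip_yield = 3,
                        mean_trip_hours = 3, gps_fraction = 0, seed = 17)
  h <- simulate_hunts(sc, tr)
  ind <- compute_indicators(h$trips, h$kills, traits = tr)
  for (i in 1:2) {
    cm <- sprintf("C%02d", i)
    p <- h$communities$trade_p[h$communities$community == cm]
    n <- sum(h$kills$community == cm)
    i33 <- ind$value[ind$community == cm & ind$id == "I33"]
    expect_lt(abs(i33 - 100 * p), 3 * 100 * sqrt(p * (1 - p) / n))
  }
})

test_that("offtake species accumulation matches a resampling oracle", {
  set.seed(19)
  trips <- do.call(rbind, lapply(1:12, function(i) mk_trip(paste0("t", i))))
  kills <- do.call(rbind, lapply(1:40, function(i)
    mk_kill(paste0("k", i), sample(trips$trip_id, 1),
            sample(tiny_traits()$species_id, 1))))
  target <- 5
  es <- offtake_species_accumulation(kills, trips, target)
  mc <- mean(replicate(10000, {
    sub <- sample(trips$trip_id, target)
    length(unique(kills$species_id[kills$trip_id %in% sub]))
  }))
  expect_lt(abs(es - mc), 0.05)
  # endpoints
  expect_equal(as.numeric(offtake_species_accumulation(kills, trips, 12)),
               length(unique(kills$species_id)))
})

test_that("kills referencing unknown trips or species are rejected", {
  trips <- mk_trip("t1")
  expect_error(compute_indicators(trips, mk_kill("k1", "zz", "sp1"),
                                  traits = tiny_traits()), "unknown trips")
  expect_error(compute_indicators(trips, mk_kill("k1", "t1", "spX"),
                                  traits = tiny_traits()), "missing from traits")
})
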