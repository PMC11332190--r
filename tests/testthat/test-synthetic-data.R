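test_that("species pool is reproducible, covers mandatory groups, rejects tiny pools", {
  a <- make_species_pool(12, seed = 1)
  b <- make_species_pool(12, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, make_species_pool(12, seed = 2)))

  expect_true(any(a$duiker_class == "blue"))
  expect_true(all(c("rodent", "ungulate", "primate", "bird") %in% a$taxon_group))
  expect_true(all(a$body_mass_kg > 0))
  expect_true(all(a$mean_group_size >= 1))
  expect_true(all(a$taxon_group[a$duiker_class != "none"] == "ungulate"))
  expect_error(make_species_pool(5), "too small")
})

test_that("ungulates are heavier than rodents in the bulk of seeds", {
  heavier <- vapply(1:100, function(s) {
    p <- make_species_pool(30, seed = s)
    median(p$body_mass_kg[p$taxon_group == "ungulate"]) >
      median(p$body_mass_kg[p$taxon_group == "rodent"])
  }, logical(1))
  expect_gte(sum(heavier), 95)
})

test_that("camera-trap simulator reproduces base rates at degradation zero", {
  sc <- scenario_config(n_communities = 1, degradation_levels = 0,
                        n_stations_per_site = 50, n_reference_stations = 4,
                        days_per_station = 30, seed = 7)
  traits <- tiny_traits()
  base <- c(sp1 = 0.08, sp2 = 0.25, sp3 = 0.25, sp4 = 0.05, sp5 = 0.08)
  ct <- simulate_camera_traps(sc, traits)
  det <- ct$detections[grepl("^C01", ct$detections$station_id), ]
  ev <- collapse_events(det)
  effort <- 50 * 30
  for (sp in names(base)) {
    rate_hat <- sum(ev$species_id == sp) / effort
    se <- sqrt(base[[sp]] / effort)  # Poisson Monte-Carlo SE of the mean rate
    expect_lt(abs(rate_hat - base[[sp]]), 3 * se + 0.05 * base[[sp]])
  }
})

test_that("rodent share of detections rises along the gradient", {
  traits <- tiny_traits()
  share <- vapply(c(0, 0.5, 1), function(d) {
    sc <- scenario_config(n_communities = 1, degradation_levels = d,
                          n_stations_per_site = 30, n_reference_stations = 4,
                          days_per_station = 30, seed = 11)
    det <- simulate_camera_traps(sc, traits)$detections
    det <- det[grepl("^C01", det$station_id), ]
    mean(det$species_id == "sp1")
  }, numeric(1))
  expect_true(all(diff(share) > 0))
})

test_that("fixed seeds give identical detection and hunt streams", {
  sc <- small_scenario(seed = 5)
  tr <- tiny_traits()
  expect_identical(simulate_camera_traps(sc, tr), simulate_camera_traps(sc, tr))
  h1 <- simulate_hunts(sc, tr)
  h2 <- simulate_hunts(sc, tr)
  expect_identical(h1, h2)
  # and identical GPX bytes
  f1 <- tempfile(fileext = ".gpx"); f2 <- tempfile(fileext = ".gpx")
  write_gpx(h1$tracks, f1); write_gpx(h2$tracks, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero yield makes every trip unsuccessful", {
  sc <- small_scenario(seed = 3, trip_yield = 0)
  h <- simulate_hunts(sc, tiny_traits())
  expect_equal(nrow(h$kills), 0)
  ind <- compute_indicators(h$trips, h$kills, traits = tiny_traits())
  i14 <- ind$value[ind$id == "I14"]
  expect_true(all(i14 == 100))
})

test_that("doubling a species' catchability raises its share of kills", {
  tr <- tiny_traits()
  base_catch <- setNames(rep(1, 5), tr$species_id)
  boosted <- base_catch; boosted["sp4"] <- 2
  share <- function(catch) {
    sc <- scenario_config(n_communities = 2, degradation_levels = c(0.3, 0.3),
                          n_trips_per_community = 400, trip_yield = 12.5,
                          mean_trip_hours = 2, gps_fraction = 0,
                          catchability = catch, seed = 21)
    k <- simulate_hunts(sc, tr)$kills
    mean(k$species_id == "sp4")
  }
  s1 <- share(base_catch); s2 <- share(boosted)
  expect_gt(s2, s1 * 1.5)  # multinomial ratio roughly doubles
})

test_that("kill composition follows the normalized rate x catchability law", {
  tr <- tiny_traits()
  d <- 0.4
  sc <- scenario_config(n_communities = 1, degradation_levels = d,
                        n_trips_per_community = 800, trip_yield = 12.5,
                        mean_trip_hours = 2, gps_fraction = 0, seed = 31)
  k <- simulate_hunts(sc, tr)$kills
  base <- c(sp1 = 0.08, sp2 = 0.25, sp3 = 0.25, sp4 = 0.05, sp5 = 0.08)
  slope <- c(rodent = 1.5, ungulate = -1.5, primate = -0.6, bird = 0.4)
  p <- base * exp(slope[tr$taxon_group] * d)
  p <- p / sum(p)
  obs <- table(factor(k$species_id, levels = tr$species_id))
  expect_gte(sum(obs), 9000)
  gof <- chisq.test(obs, p = p)
  expect_gt(gof$p.value, 0.001)   # goodness-of-fit non-rejection
})

test_that("tracks are regular, closed at the village and time-ordered", {
  sc <- small_scenario(seed = 9)
  h <- simulate_hunts(sc, tiny_traits())
  for (id in head(unique(h$tracks$trip_id), 5)) {
    tr <- h$tracks[h$tracks$trip_id == id, ]
    expect_true(all(diff(as.numeric(tr$t)) == sc$fix_interval_s))
    d_end <- sqrt((tr$x[1] - tr$x[nrow(tr)])^2 + (tr$y[1] - tr$y[nrow(tr)])^2)
    expect_lt(d_end, 1)
    # first fix is the village point itself
    vil <- huntmon:::village_points(sc)
    com <- h$trips$community[match(id, h$trips$trip_id)]
    v <- vil[vil$community == com, ]
    expect_lt(sqrt((tr$x[1] - v$x)^2 + (tr$y[1] - v$y)^2), 1)
  }
})

test_that("scenario validation rejects bad configurations", {
  expect_error(scenario_config(degradation_levels = c(0.2, 1.4),
                               n_communities = 2), "\\[0, 1\\]")
  expect_error(scenario_config(n_communities = 2,
                               degradation_levels = 0.5), "one entry per")
  expect_error(scenario_config(catchability = c(sp1 = -1)), "positive")
})
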