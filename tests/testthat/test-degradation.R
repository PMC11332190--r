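test_that("Bray-Curtis matches hand-computed values and boundary cases", {
  expect_equal(bray_curtis(c(2, 1), c(1, 3)), 3 / 7)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_warning(v <- bray_curtis(c(0, 0), c(0, 0)), "undefined")
  expect_true(is.na(v))
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "ordering")
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "nonnegative")
})

test_that("Bray-Curtis is symmetric, bounded and scale-invariant", {
  set.seed(1)
  for (i in 1:50) {
    a <- rexp(8); b <- rexp(8) * rbinom(8, 1, 0.7)
    expect_equal(bray_curtis(a, b), bray_curtis(b, a))
    expect_gte(bray_curtis(a, b), 0)
    expect_lte(bray_curtis(a, b), 1)
    s <- runif(1, 0.1, 10)
    expect_equal(bray_curtis(a * s, b * s), bray_curtis(a, b))
  }
})

test_that("Bray-Curtis agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(2)
  M <- matrix(rexp(40), 5, 8)
  d_pkg <- sapply(2:5, function(i) bray_curtis(M[1, ], M[i, ]))
  d_veg <- as.matrix(vegan::vegdist(M, "bray"))[1, 2:5]
  expect_equal(d_pkg, unname(d_veg))
})

test_that("pairwise degradation equals a brute-force double loop", {
  set.seed(3)
  for (rep in 1:5) {
    nh <- sample(3:20, 1); nr <- sample(2:20, 1); S <- sample(4:10, 1)
    H <- matrix(rexp(nh * S) * rbinom(nh * S, 1, 0.8), nh, S,
                dimnames = list(paste0("h", 1:nh), paste0("sp", 1:S)))
    R <- matrix(rexp(nr * S) * rbinom(nr * S, 1, 0.8), nr, S,
                dimnames = list(paste0("r", 1:nr), paste0("sp", 1:S)))
    comm <- setNames(sample(c("A", "B"), nh, replace = TRUE), rownames(H))
    scores <- pairwise_degradation(
      ab_from_matrix(H, comm),
      ab_from_matrix(R, setNames(rep("REFERENCE", nr), rownames(R))))
    # independent oracle: direct formula in an explicit double loop
    for (cm in unique(comm)) {
      vals <- c()
      for (i in which(comm == cm)) for (j in 1:nr)
        vals <- c(vals, sum(abs(H[i, ] - R[j, ])) / sum(H[i, ] + R[j, ]))
      expect_equal(scores$median_bc[scores$community == cm], median(vals))
      expect_equal(scores$n_pairs[scores$community == cm], length(vals))
    }
  }
})

test_that("degradation scores count pairs and handle identical assemblages", {
  H <- matrix(c(1, 2, 0, 3, 1, 1), 3, 2, byrow = TRUE,
              dimnames = list(paste0("h", 1:3), c("sp1", "sp2")))
  R <- H[1:2, ]; rownames(R) <- c("r1", "r2")
  sc <- pairwise_degradation(
    ab_from_matrix(H, setNames(rep("A", 3), rownames(H))),
    ab_from_matrix(R, setNames(rep("REFERENCE", 2), rownames(R))))
  expect_equal(sc$n_pairs, 6L)
  # stations identical to every reference station score median 0
  Rsame <- matrix(rep(c(1, 2), each = 2), 2, 2,
                  dimnames = list(c("r1", "r2"), c("sp1", "sp2")))
  sc0 <- pairwise_degradation(
    ab_from_matrix(Rsame, setNames(rep("A", 2), rownames(Rsame))),
    ab_from_matrix(Rsame, setNames(rep("REFERENCE", 2), rownames(Rsame))))
  expect_equal(sc0$median_bc, 0)
})

test_that("species alignment zero-fills the union set", {
  H <- matrix(1, 1, 2, dimnames = list("h1", c("sp1", "sp2")))
  R <- matrix(1, 1, 2, dimnames = list("r1", c("sp2", "sp3")))
  sc <- pairwise_degradation(
    ab_from_matrix(H, c(h1 = "A")),
    ab_from_matrix(R, c(r1 = "REFERENCE")))
  # |1-0| + |1-1| + |0-1| over 1+0 + 1+1 + 0+1 = 2/4
  expect_equal(sc$median_bc, 0.5)
})

test_that("composition proportions sum to one with monkeys folded to other", {
  ev <- data.frame(station_id = "st1", species_id = c("sp1", "sp1", "sp1", "sp3"),
                   event_start = utc("2021-01-01"), max_individuals = 1L)
  p <- composition_proportions(ev, station_row(), tiny_traits())
  expect_equal(p$rodent, 0.75)
  expect_equal(p$ungulate, 0.25)
  expect_equal(sum(p[1, ]), 1)
  ev2 <- data.frame(station_id = "st1", species_id = "sp4",
                    event_start = utc("2021-01-01"), max_individuals = 1L)
  p2 <- composition_proportions(ev2, station_row(), tiny_traits())
  expect_equal(p2$other, 1)
})

test_that("CT mean body mass is event-weighted with an individual option", {
  ev <- data.frame(station_id = "st1", species_id = c("sp5", "sp4"),
                   event_start = utc("2021-01-01"), max_individuals = c(1L, 3L))
  expect_equal(ct_mean_body_mass(ev, tiny_traits()), (2 + 7) / 2)
  expect_equal(ct_mean_body_mass(ev, tiny_traits(), weight_by_individuals = TRUE),
               (2 * 1 + 7 * 3) / 4)
  expect_equal(ct_mean_body_mass(ev[c(2, 1), ], tiny_traits()),
               ct_mean_body_mass(ev, tiny_traits()))
  ev$species_id[1] <- "zz"
  expect_error(ct_mean_body_mass(ev, tiny_traits()), "zz")
})

test_that("BlueDuiker% covers all count configurations", {
  expect_equal(blue_duiker_pct(c(blue = 5, other_duiker = 15)), 25)
  expect_equal(blue_duiker_pct(c(blue = 0, other_duiker = 10)), 0)
  expect_equal(blue_duiker_pct(c(blue = 10, other_duiker = 0)), 100)
  expect_equal(blue_duiker_pct(rep(c("blue", "other_duiker", "none"), c(1, 3, 6))), 25)
  expect_warning(v <- blue_duiker_pct(c(blue = 0, other_duiker = 0)), "undefined")
  expect_true(is.na(v))
})

test_that("rarefaction endpoints are exact and t = 1 is the mean unit richness", {
  set.seed(4)
  inc <- matrix(rbinom(200, 1, 0.25), 20, 10)
  obs <- sum(colSums(inc) > 0)
  expect_equal(as.numeric(rarefied_richness(inc, 20)), obs)
  expect_equal(rarefied_richness(inc, 1), mean(rowSums(inc)))
  over <- rarefied_richness(inc, 50)
  expect_equal(as.numeric(over), obs)
  expect_true(attr(over, "extrapolated"))
})

test_that("analytic rarefaction matches Monte-Carlo subsampling", {
  set.seed(5)
  inc <- matrix(rbinom(10 * 12, 1, runif(12, 0.05, 0.6)), 10, 12, byrow = TRUE)
  t <- 4
  es <- rarefied_richness(inc, t)
  mc <- mean(replicate(10000, {
    sub <- inc[sample(10, t), , drop = FALSE]
    sum(colSums(sub) > 0)
  }))
  expect_lt(abs(es - mc), 0.05)
})

test_that("rarefaction is monotone and concave in effort", {
  set.seed(6)
  inc <- matrix(rbinom(30 * 15, 1, 0.15), 30, 15)
  es <- vapply(1:30, function(t) as.numeric(rarefied_richness(inc, t)), numeric(1))
  expect_true(all(diff(es) >= -1e-12))
  expect_true(all(diff(diff(es)) <= 1e-12))
})

test_that("station-day incidence maps events onto camera-days", {
  d <- det_at_minutes(c(10, 60 * 25), species = "sp1")  # day 1 and day 2
  ev <- collapse_events(d)
  inc <- incidence_by_station_day(ev, station_row(days = 5))
  expect_equal(dim(inc), c(5L, 1L))
  expect_equal(unname(colSums(inc)), 2)
})
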