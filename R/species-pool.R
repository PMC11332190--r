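#' Generate a synthetic species trait pool
#'
#' Draws a reproducible species pool covering the taxon groups a tropical
#' forest camera-trap survey detects. The pool always contains at least one
#' rodent, a blue-duiker analogue plus one other duiker (ungulates), one
#' primate and one terrestrial bird; remaining slots are filled across all
#' groups. Body masses are log-normal with taxon-group offsets so ungulates
#' are heavier than rodents in expectation; mean group sizes exceed 1 for
#' the gregarious groups. One non-mandatory primate, when present, is
#' flagged `excluded` to emulate analysis-level exclusions of species whose
#' range only partially overlaps a study area.
#'
#' @param n_species total species, at least 6.
#' @param seed integer seed; fixed seed gives an identical table.
#' @return data.frame with columns `species_id`, `taxon_group`,
#'   `body_mass_kg`, `duiker_class`, `mean_group_size`, `excluded`.
#' @examples
#' pool <- make_species_pool(12, seed = 1)
#' table(pool$taxon_group)
#' @export
make_species_pool <- function(n_species, seed = 1L) {
  if (n_species < 6)
    stopf("n_species = %d too small: need >= 6 to cover rodent, two ungulates (incl. a blue duiker), primate and bird", n_species)
  set.seed(substream(seed, 1))

  groups <- c("rodent", "ungulate", "ungulate", "primate", "bird")
  extra <- n_species - length(groups)
  all_groups <- c("rodent", "ungulate", "primate", "bird", "carnivore", "ape", "other")
  probs <- c(0.24, 0.24, 0.14, 0.14, 0.10, 0.04, 0.10)
  if (extra > 0)
    groups <- c(groups, sample(all_groups, extra, replace = TRUE, prob = probs))

  # log-mass centres per group (kg); sdlog keeps groups overlapping but ordered
  mu <- c(rodent = log(2.5), ungulate = log(15), primate = log(7),
          bird = log(2), carnivore = log(8), ape = log(35), other = log(5))
  mass <- rlnorm(n_species, meanlog = mu[groups], sdlog = 0.45)

  duiker <- rep("none", n_species)
  ung <- which(groups == "ungulate")
  duiker[ung[1]] <- "blue"           # blue-duiker analogue, small
  mass[ung[1]] <- rlnorm(1, log(4.5), 0.1)
  if (length(ung) > 1) {
    duiker[ung[2]] <- "other_duiker" # Cephalophus-type medium duiker
    for (j in ung[-(1:2)]) if (runif(1) < 0.5) duiker[j] <- "other_duiker"
  }

  gs_rate <- c(rodent = 2, ungulate = 2, primate = 0.5, bird = 2,
               carnivore = 4, ape = 0.7, other = 3)
  group_size <- 1 + rexp(n_species, rate = gs_rate[groups])

  excluded <- rep(FALSE, n_species)
  extra_primates <- which(groups == "primate")
  extra_primates <- extra_primates[extra_primates > 5]
  if (length(extra_primates) > 0) excluded[extra_primates[1]] <- TRUE

  data.frame(species_id = sprintf("sp%02d", seq_len(n_species)),
             taxon_group = groups,
             body_mass_kg = mass,
             duiker_class = duiker,
             mean_group_size = group_size,
             excluded = excluded,
             stringsAsFactors = FALSE)
}
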