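test_that("Dirichlet calibration has the closed form and correct domain", {
  expect_equal(dirichlet_concentration_for_he(0.6, 5), 0.6)
  expect_equal(dirichlet_concentration_for_he(0.5, 3), 0.5 / (3 * 0.5 - 1))
  # alpha -> 0 as target He -> 0
  expect_lt(dirichlet_concentration_for_he(1e-4, 5), 1e-3)
  expect_error(dirichlet_concentration_for_he(0.8, 5),
               class = "hescale_domain_error")
  expect_error(dirichlet_concentration_for_he(0.5, 2),
               class = "hescale_domain_error")
})

test_that("Dirichlet draws are simplex points with the calibrated mean He", {
  set.seed(2)
  draws <- replicate(4000, simulate_locus_frequencies(0.6, 5))
  expect_equal(unname(colSums(draws)), rep(1, 4000), tolerance = 1e-12)
  expect_true(all(draws >= 0))
  mean_he <- mean(1 - colSums(draws^2))
  expect_equal(mean_he, 0.6, tolerance = 0.01)
})

test_that("HWE genotype sampling is deterministic under a seed", {
  f <- list(L1 = c(0.5, 0.3, 0.2), L2 = c(0.9, 0.1))
  set.seed(77)
  g1 <- simulate_population_genotypes(f, 50)
  set.seed(77)
  g2 <- simulate_population_genotypes(f, 50)
  expect_equal(g1, g2)
  # monomorphic locus: every call homozygous for the mapped fragment length
  g3 <- simulate_population_genotypes(list(L = 1), 10)
  expect_true(all(g3$allele1 == 102L & g3$allele2 == 102L))
})

test_that("simulated meta-datasets are valid and fully seed-deterministic", {
  cfg <- synthetic_config(n_populations = 15L, n_loci = 6L,
                          individuals_per_pop = c(6L, 8L), seed = 42)
  sim1 <- suppressWarnings(simulate_meta(cfg))
  sim2 <- suppressWarnings(simulate_meta(cfg))
  expect_equal(sim1$meta$summaries, sim2$meta$summaries)
  expect_equal(sim1$truth, sim2$truth)
  expect_equal(sim1$genotypes$calls, sim2$genotypes$calls)

  # data-model invariants on every cell
  s <- sim1$meta$summaries
  expect_true(all(s$M >= 1 / s$K - 1e-12 & s$M <= 1))
  expect_true(all(s$H >= 1 / s$K - 1e-12 & s$H <= 1))
  expect_equal(s$He + s$H, rep(1, nrow(s)))
  expect_true(all(abs(sim1$meta$populations$latitude) <= 90))
})

test_that("generated cell He tracks the truth-table targets", {
  cfg <- synthetic_config(n_populations = 30L, seed = 9,
                          kit_assignment = "all")
  sim <- suppressWarnings(simulate_meta(cfg))
  joined <- merge(sim$meta$summaries, sim$truth, by = c("population_id", "locus"))
  # per-cell He is noisy; the mean deviation from target must be small
  expect_lt(abs(mean(joined$He - joined$target_he)), 0.03)
})

test_that("a planted gradient is recoverable from scaled He (shared kit)", {
  # with one shared kit and no offsets, both raw and scaled per-population
  # means must recover the planted negative monotone trend; the raw signal
  # is stronger because scaling adds the bounds-conditioning noise
  rs <- vapply(1:6, function(s) {
    cfg <- synthetic_config(
      seed = s, kit_assignment = "all",
      kits = list(list(id = "shared", loci = 1:20, K = 8L, he_offset = 0))
    )
    sim <- suppressWarnings(simulate_meta(cfg))
    sc <- suppressWarnings(scaled_he(sim$meta))
    pops <- sim$meta$populations
    ph <- sc$populations[match(pops$population_id, sc$populations$population_id), ]
    c(raw = gradient_analysis(pops, ph$mean_raw_he)$r_s[3],
      scl = gradient_analysis(pops, ph$mean_scaled_he)$r_s[3])
  }, numeric(2))
  expect_true(all(rs["raw", ] <= -0.4))
  expect_true(all(rs["scl", ] < 0))
  expect_lte(mean(rs["scl", ]), -0.25)
})

test_that("truth targets track the distance-decay oracle of the generator", {
  # large-n oracle of the truth model itself: the Spearman correlation of
  # base_he - slope * d / 1000 + Normal(0, noise_sd) with d, for uniform
  # placement in the default window, is about -0.82 (noise_sd = 0.02 against
  # a ~0.03 SD gradient signal); an 85-population draw must sit near it
  set.seed(1)
  n <- 50000
  lon <- runif(n, -5, 25)
  lat <- runif(n, 40, 55)
  d <- haversine_km(lat, lon, 46.05, 14.5)
  oracle <- cor(0.70 - 0.08 * d / 1000 + rnorm(n, 0, 0.02), d,
                method = "spearman")
  expect_lt(oracle, -0.75)

  cfg <- synthetic_config(seed = 4, kit_assignment = "all")
  sim <- suppressWarnings(simulate_meta(cfg))
  tr <- sim$truth
  off <- ifelse(tr$kit == "high", 0.05, -0.05)
  per_pop <- tapply(tr$target_he - off, tr$population_id, mean)
  dist <- tapply(tr$distance_km, tr$population_id, mean)
  r <- spearman_correlation(as.numeric(per_pop), as.numeric(dist))$r_s
  expect_lt(r, 0)
  expect_lt(abs(r - oracle), 0.15)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(), "mandatory")
  expect_error(
    synthetic_config(seed = 1, base_he = 0.9),
    class = "hescale_config_error"
  )
  expect_error(
    synthetic_config(seed = 1, kits = list(
      list(id = "a", loci = 1:10, K = 4L, he_offset = 0)
    )),
    class = "hescale_config_error"
  )
})
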