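# Fixtures built in code: small genotype tables, files, and an independent
# haversine oracle used to cross-check the geosphere-backed implementation.

write_genepop_fixture <- function(path) {
  writeLines(c(
    "Two-population toy dataset",
    "locusA",
    "locusB",
    "POP",
    "ind1 , 0101 0102",
    "ind2 , 0102 0202",
    "ind3 , 0101 0000",
    "POP",
    "ind1 , 0202 0101",
    "ind2 , 0102 0102",
    "ind3 , 0201 0202"
  ), path)
  path
}

write_long_fixture <- function(path) {
  df <- data.frame(
    study_id = "s1",
    population_id = rep(c("p1", "p2"), each = 4),
    individual_id = rep(c("i1", "i2"), each = 2, times = 2),
    latitude = rep(c(45, 50), each = 4),
    longitude = rep(c(10, 12), each = 4),
    locus = rep(c("locusA", "locusB"), times = 4),
    allele1 = c(100, 120, 100, 120, 102, 120, 102, 122),
    allele2 = c(100, 122, 102, 120, 102, 122, 100, NA)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

# tiny genotype table built directly (2 pops x 2 loci, known frequencies)
toy_genotypes <- function() {
  pops <- tibble::tibble(
    study_id = "s1",
    population_id = c("p1", "p2"),
    latitude = c(45, 50),
    longitude = c(10, 12),
    n_individuals = c(2L, 2L)
  )
  calls <- tibble::tibble(
    study_id = "s1",
    population_id = rep(c("p1", "p2"), each = 4),
    individual_id = rep(c("i1", "i2"), each = 2, times = 2),
    locus = rep(c("locusA", "locusB"), times = 4),
    allele1 = c(100L, 120L, 100L, 120L, 102L, 120L, 102L, 122L),
    allele2 = c(100L, 122L, 102L, 120L, 102L, 122L, 100L, 122L)
  )
  genotype_table(pops, calls, c("locusA", "locusB"))
}

# meta-dataset with hand-chosen frequencies (for scaling oracles)
freq_meta <- function(freq_df, pops = NULL) {
  freq_df <- tibble::as_tibble(freq_df)
  if (!"study_id" %in% names(freq_df)) freq_df$study_id <- "s1"
  if (!"gene_copies" %in% names(freq_df)) freq_df$gene_copies <- 40L
  summ <- locus_population_summary(freq_df)
  if (is.null(pops)) {
    ids <- unique(freq_df$population_id)
    pops <- tibble::tibble(
      study_id = "s1", population_id = ids,
      latitude = seq(44, 54, length.out = length(ids)),
      longitude = seq(8, 20, length.out = length(ids)),
      n_individuals = 20L
    )
  }
  structure(
    list(populations = pops, summaries = summ, frequencies = freq_df,
         loci = sort(unique(summ$locus)), studies = unique(pops$study_id)),
    class = "meta_dataset"
  )
}

# independent haversine (pure R, textbook formula) as an oracle
oracle_haversine_km <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# quick scaled-He pipeline on a simulation: per-population means + gradient
sim_gradient <- function(seed, kit_assignment, k_mode = "study") {
  sim <- suppressWarnings(
    simulate_meta(synthetic_config(seed = seed, kit_assignment = kit_assignment))
  )
  sc <- suppressWarnings(scaled_he(sim$meta, k_mode = k_mode))
  pops <- sim$meta$populations
  ph <- sc$populations[match(pops$population_id, sc$populations$population_id), ]
  list(
    sim = sim, scaled = sc, pops = pops, per_pop = ph,
    raw = gradient_analysis(pops, ph$mean_raw_he),
    scl = gradient_analysis(pops, ph$mean_scaled_he)
  )
}
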