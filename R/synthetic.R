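#' Configuration for the synthetic range-expansion generator
#'
#' Describes a multi-population microsatellite meta-dataset with a planted
#' diversity gradient: populations scattered uniformly over a lon/lat
#' window, per-population target He declining linearly with great-circle
#' distance from an origin, genotypes drawn under Hardy-Weinberg
#' proportions from Dirichlet-calibrated allele frequencies, and locus
#' "kits" of differing polymorphism that can be assigned by region to
#' inject ascertainment (discovery) bias.
#'
#' Defaults emulate a range-wide beech survey: 85 populations of 10-20
#' diploid individuals typed at 20 loci over a European window, He about
#' 0.70 at the origin declining by 0.08 per 1000 km with population-level
#' jitter of 0.02. The default kits split the panel into a low-polymorphism
#' half (K = 4 alleles, target He offset -0.05) and a high-polymorphism
#' half (K = 12, +0.05) — a separation large enough to drive a raw-He bias
#' while staying inside a realistic He band.
#'
#' @param n_populations Number of populations (default 85).
#' @param individuals_per_pop Integer range `c(min, max)`; per-population
#'   sizes drawn uniformly (default `c(10, 20)`).
#' @param n_loci Number of loci (default 20).
#' @param lon_window,lat_window Sampling window in degrees (defaults
#'   `c(-5, 25)`, `c(40, 55)`).
#' @param origin Numeric `c(lat, lon)` of the gradient origin (default
#'   [default_origin()]).
#' @param base_he Target He at the origin (default 0.70).
#' @param slope He loss per 1000 km of distance from origin (default 0.08).
#' @param noise_sd SD of the population-level He jitter (default 0.02).
#' @param kits List of kits, each `list(id =, loci =, K =, he_offset =)`
#'   where `loci` are locus indices; defaults to a low/high pair covering
#'   the panel in halves.
#' @param kit_assignment `"all"` (every population typed with every kit),
#'   `"random"` (each population typed with one kit at random), or
#'   `"by_distance"` (populations beyond the median distance get the
#'   highest-K kit — the bias injection).
#' @param seed Integer seed (mandatory).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_populations = 85L,
                             individuals_per_pop = c(10L, 20L),
                             n_loci = 20L,
                             lon_window = c(-5, 25),
                             lat_window = c(40, 55),
                             origin = default_origin(),
                             base_he = 0.70,
                             slope = 0.08,
                             noise_sd = 0.02,
                             kits = NULL,
                             kit_assignment = c("all", "random", "by_distance"),
                             seed) {
  kit_assignment <- match.arg(kit_assignment)
  if (missing(seed)) stop_config("`seed` is mandatory")
  if (is.null(kits)) {
    half <- floor(n_loci / 2)
    kits <- list(
      list(id = "low", loci = seq_len(half), K = 4L, he_offset = -0.05),
      list(id = "high", loci = seq(half + 1L, n_loci), K = 12L,
           he_offset = 0.05)
    )
  }
  covered <- sort(unlist(lapply(kits, `[[`, "loci")))
  if (!identical(covered, seq_len(n_loci))) {
    stop_config("kits must cover every locus index exactly once")
  }
  for (k in kits) {
    if (k$K < 2L) stop_config("each kit needs K >= 2")
    if (base_he + k$he_offset >= 1 - 1 / k$K) {
      stop_config(sprintf(
        "base_he + offset (%g) unreachable with K = %d alleles",
        base_he + k$he_offset, k$K
      ))
    }
  }
  if (slope < 0) stop_config("slope must be >= 0")
  if (n_populations < 1L || n_loci < 1L) {
    stop_config("need at least 1 population and 1 locus")
  }
  if (individuals_per_pop[1] < 1L ||
        individuals_per_pop[2] < individuals_per_pop[1]) {
    stop_config("individuals_per_pop must be a valid range")
  }
  structure(
    list(
      n_populations = as.integer(n_populations),
      individuals_per_pop = as.integer(individuals_per_pop),
      n_loci = as.integer(n_loci),
      lon_window = lon_window, lat_window = lat_window,
      origin = origin, base_he = base_he, slope = slope,
      noise_sd = noise_sd, kits = kits,
      kit_assignment = kit_assignment, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Dirichlet concentration matching a target expected heterozygosity
#'
#' For a symmetric Dirichlet(alpha, ..., alpha) of length K, the expected
#' homozygosity of a draw is \eqn{E[\sum p^2] = (\alpha + 1)/(K\alpha + 1)},
#' so the concentration whose expected He equals `target_he` is
#' \deqn{\alpha = \frac{He}{K(1 - He) - 1}.}
#' He at or above `1 - 1/K` is unreachable with K alleles and is a domain
#' error.
#'
#' @param target_he Target expected heterozygosity, in `(0, 1 - 1/K)`.
#' @param K Number of alleles (>= 2).
#' @return The concentration alpha (> 0).
#' @examples
#' dirichlet_concentration_for_he(0.6, 5) # 0.6
#' @export
dirichlet_concentration_for_he <- function(target_he, K) {
  if (K < 2L) stop_domain("K must be >= 2")
  if (target_he <= 0 || target_he >= 1 - 1 / K) {
    stop_domain(sprintf(
      "target He must lie in (0, 1 - 1/K) = (0, %g) for K = %d",
      1 - 1 / K, K
    ))
  }
  target_he / (K * (1 - target_he) - 1)
}

#' Draw one allele-frequency vector from a symmetric Dirichlet
#'
#' Standard gamma-normalization construction; uses the current RNG state,
#' so callers control determinism by seeding.
#'
#' @param alpha Concentration (> 0).
#' @param K Number of alleles (>= 2).
#' @return Numeric vector of length K summing to 1.
#' @export
simulate_locus_frequencies <- function(alpha, K) {
  if (alpha <= 0) stop_domain("alpha must be > 0")
  if (K < 2L) stop_domain("K must be >= 2")
  g <- rgamma(K, shape = alpha, rate = 1)
  while (sum(g) == 0) g <- rgamma(K, shape = alpha, rate = 1) # pathological alpha
  g / sum(g)
}

#' Simulate diploid genotypes under Hardy-Weinberg proportions
#'
#' Each genotype is two independent draws from the locus frequency vector;
#' allele index k is mapped to a plausible fragment length `100 + 2k`.
#'
#' @param freqs List of frequency vectors, one per locus (names used as
#'   locus names, else `locus01`, ...).
#' @param n_individuals Number of diploid individuals.
#' @return Tibble of calls: `individual_id`, `locus`, `allele1`, `allele2`.
#' @export
simulate_population_genotypes <- function(freqs, n_individuals) {
  if (n_individuals < 1L) stop_domain("need n_individuals >= 1")
  if (!is.list(freqs)) freqs <- list(freqs)
  loci <- names(freqs)
  if (is.null(loci)) loci <- sprintf("locus%02d", seq_along(freqs))
  rows <- purrr::map2(freqs, loci, function(p, nm) {
    draws <- sample.int(length(p), 2L * n_individuals, replace = TRUE,
                        prob = p)
    a1 <- 100L + 2L * draws[seq_len(n_individuals)]
    a2 <- 100L + 2L * draws[n_individuals + seq_len(n_individuals)]
    tibble::tibble(
      individual_id = sprintf("ind%04d", seq_len(n_individuals)),
      locus = nm, allele1 = a1, allele2 = a2
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a meta-dataset with a planted diversity gradient
#'
#' Populations are placed uniformly in the window; population j's target He
#' at a locus belonging to kit k is
#' `clip(base_he + he_offset_k - slope * d_j / 1000 + jitter_j, 0.01,
#' 1 - 1/K_k - 0.01)` with one `Normal(0, noise_sd)` jitter per population
#' and `d_j` the distance from the origin in km. Allele frequencies come
#' from the Dirichlet calibration ([dirichlet_concentration_for_he()]) and
#' genotypes from HWE sampling. With `kit_assignment = "by_distance"` the
#' populations beyond the median distance are typed with the highest-K kit
#' only — the ascertainment-bias injection mirrored by the validation
#' scenarios.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `meta` (a `meta_dataset`), `truth` (tibble:
#'   `population_id`, `distance_km`, `locus`, `kit`, `target_he`),
#'   `genotypes` (a [genotype_table()]).
#' @export
simulate_meta <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_local_seed(cfg$seed, {
    np <- cfg$n_populations
    pop_ids <- sprintf("pop%03d", seq_len(np))
    lon <- runif(np, cfg$lon_window[1], cfg$lon_window[2])
    lat <- runif(np, cfg$lat_window[1], cfg$lat_window[2])
    d_km <- haversine_km(lat, lon, cfg$origin[1], cfg$origin[2])
    n_ind <- sample(
      seq(cfg$individuals_per_pop[1], cfg$individuals_per_pop[2]),
      np, replace = TRUE
    )
    jitter <- rnorm(np, 0, cfg$noise_sd)

    kit_ids <- vapply(cfg$kits, `[[`, character(1), "id")
    locus_names <- sprintf("locus%02d", seq_len(cfg$n_loci))
    locus_kit <- character(cfg$n_loci)
    for (k in cfg$kits) locus_kit[k$loci] <- k$id
    kit_K <- setNames(
      vapply(cfg$kits, function(k) as.integer(k$K), integer(1)), kit_ids
    )
    kit_off <- setNames(
      vapply(cfg$kits, function(k) as.numeric(k$he_offset), numeric(1)),
      kit_ids
    )

    pop_kits <- switch(cfg$kit_assignment,
      all = replicate(np, kit_ids, simplify = FALSE),
      random = as.list(sample(kit_ids, np, replace = TRUE)),
      by_distance = {
        high_kit <- kit_ids[which.max(kit_K)]
        other <- kit_ids[kit_ids != high_kit]
        lapply(d_km, function(d) {
          if (d > median(d_km)) high_kit else other[which.min(kit_K[other])]
        })
      }
    )

    truth_rows <- vector("list", np)
    call_rows <- vector("list", np)
    n_clipped <- 0L
    for (j in seq_len(np)) {
      loci_j <- which(locus_kit %in% pop_kits[[j]])
      freqs <- vector("list", length(loci_j))
      targets <- numeric(length(loci_j))
      for (ii in seq_along(loci_j)) {
        l <- loci_j[ii]
        kid <- locus_kit[l]
        K <- kit_K[[kid]]
        raw_target <- cfg$base_he + kit_off[[kid]] -
          cfg$slope * d_km[j] / 1000 + jitter[j]
        target <- min(max(raw_target, 0.01), 1 - 1 / K - 0.01)
        if (target != raw_target) n_clipped <- n_clipped + 1L
        targets[ii] <- target
        alpha <- dirichlet_concentration_for_he(target, K)
        freqs[[ii]] <- simulate_locus_frequencies(alpha, K)
      }
      names(freqs) <- locus_names[loci_j]
      calls <- simulate_population_genotypes(freqs, n_ind[j])
      calls$study_id <- "synthetic"
      calls$population_id <- pop_ids[j]
      call_rows[[j]] <- calls
      truth_rows[[j]] <- tibble::tibble(
        population_id = pop_ids[j],
        distance_km = d_km[j],
        locus = locus_names[loci_j],
        kit = locus_kit[loci_j],
        target_he = targets
      )
    }
    if (n_clipped > 0L) {
      warn(sprintf("%d target He value(s) clipped into (0.01, 1 - 1/K - 0.01)",
                   n_clipped))
    }
    pops <- tibble::tibble(
      study_id = "synthetic", population_id = pop_ids,
      latitude = lat, longitude = lon, n_individuals = n_ind
    )
    calls <- dplyr::bind_rows(call_rows)[
      , c("study_id", "population_id", "individual_id", "locus",
          "allele1", "allele2")
    ]
    g <- genotype_table(pops, calls, locus_names)
    meta <- merge_studies(list(study_dataset(g)))
    list(meta = meta, truth = dplyr::bind_rows(truth_rows), genotypes = g)
  })
}

#' Write the synthetic outputs as plain-text files
#'
#' Writes the long-format genotype file, the population table, and the
#' truth table under a path stem.
#'
#' @param sim Result of [simulate_meta()].
#' @param stem Output path stem.
#' @return Character vector of paths, invisibly.
#' @export
write_synthetic <- function(sim, stem) {
  p1 <- paste0(stem, "_genotypes.tsv")
  p2 <- paste0(stem, "_populations.tsv")
  p3 <- paste0(stem, "_truth.tsv")
  write_long_genotypes(sim$genotypes, p1)
  readr::write_tsv(sim$meta$populations, p2, progress = FALSE)
  readr::write_tsv(sim$truth, p3, progress = FALSE)
  invisible(c(p1, p2, p3))
}
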