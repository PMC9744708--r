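#' Split populations into two geographic or random groups
#'
#' Coordinate axes use a median split: group A is the southern (latitude) or
#' western (longitude) half, with populations exactly at the median assigned
#' to A; the median maximizes balance and is the natural reading of a
#' two-group geographic split. The random axis assigns a seeded uniform
#' shuffle balanced to `ceiling(n/2)` / `floor(n/2)`.
#'
#' @param pops Tibble with columns `population_id`, `latitude`, `longitude`.
#' @param axis `"latitude"`, `"longitude"`, or `"random"`.
#' @param seed Integer seed (required for `axis = "random"`).
#' @return Tibble with columns `population_id`, `group` (`"A"` / `"B"`);
#'   attributes `axis`, `threshold` (NA for random), `seed`.
#' @export
split_populations <- function(pops, axis = c("latitude", "longitude", "random"),
                              seed = NULL) {
  axis <- match.arg(axis)
  pops <- tibble::as_tibble(pops)
  if (nrow(pops) < 2L) stop_domain("need at least 2 populations")
  threshold <- NA_real_
  if (axis == "random") {
    if (is.null(seed)) stop_config("random split requires a seed")
    n <- nrow(pops)
    ord <- with_local_seed(seed, sample.int(n))
    group <- rep("B", n)
    group[ord[seq_len(ceiling(n / 2))]] <- "A"
  } else {
    coord <- pops[[axis]]
    if (any(is.na(coord))) stop_data("missing coordinates for split axis")
    if (length(unique(coord)) == 1L) {
      stop_domain("all populations share the split coordinate")
    }
    threshold <- median(coord)
    group <- ifelse(coord <= threshold, "A", "B")
    if (!all(c("A", "B") %in% group)) {
      stop_domain("median split left one group empty (heavy ties at median)")
    }
  }
  out <- tibble::tibble(population_id = pops$population_id, group = group)
  attr(out, "axis") <- axis
  attr(out, "threshold") <- threshold
  attr(out, "seed") <- if (axis == "random") as.integer(seed) else NA_integer_
  out
}

#' Partition loci into low- and high-polymorphism halves
#'
#' Ranks loci by their global mean He across all populations — He, not
#' allele count, is the quantity whose cross-panel bias is under study — and
#' assigns the top `floor(n/2)` to the `"high"` group (odd counts place the
#' middle locus in `"low"`). Ties are broken by larger global allele count,
#' then lexicographic locus name. `mode = "random"` shuffles loci into
#' balanced halves under a seed instead.
#'
#' @param meta A `meta_dataset`.
#' @param mode `"polymorphism"` (default) or `"random"`.
#' @param seed Integer seed (required for `mode = "random"`).
#' @return Tibble with columns `locus`, `group` (`"low"` / `"high"`),
#'   `ranking_stat` (global mean He; NA in random mode); attributes `mode`,
#'   `seed`.
#' @export
rank_loci_by_polymorphism <- function(meta, mode = c("polymorphism", "random"),
                                      seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(meta, "meta_dataset"))
  summ <- meta$summaries
  stats_tbl <- summ |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      ranking_stat = mean(.data$He),
      allele_count = max(.data$K),
      .groups = "drop"
    )
  if (!is.null(meta$frequencies)) {
    global_k <- meta$frequencies |>
      dplyr::distinct(.data$locus, .data$allele) |>
      dplyr::count(.data$locus, name = "allele_count_global")
    stats_tbl <- stats_tbl |>
      dplyr::left_join(global_k, by = "locus") |>
      dplyr::mutate(
        allele_count = dplyr::coalesce(.data$allele_count_global, .data$allele_count)
      ) |>
      dplyr::select(-"allele_count_global")
  }
  n <- nrow(stats_tbl)
  if (mode == "random") {
    if (is.null(seed)) stop_config("random locus partition requires a seed")
    ord <- with_local_seed(seed, sample.int(n))
    group <- rep("low", n)
    group[ord[seq_len(floor(n / 2))]] <- "high"
    out <- tibble::tibble(
      locus = stats_tbl$locus, group = group, ranking_stat = NA_real_
    )
  } else {
    ord <- order(
      -stats_tbl$ranking_stat, -stats_tbl$allele_count, stats_tbl$locus
    )
    group <- rep("low", n)
    group[ord[seq_len(floor(n / 2))]] <- "high"
    out <- tibble::tibble(
      locus = stats_tbl$locus, group = group,
      ranking_stat = stats_tbl$ranking_stat
    )
  }
  attr(out, "mode") <- mode
  attr(out, "seed") <- if (mode == "random") as.integer(seed) else NA_integer_
  out
}

#' Restrict each population group to its assigned locus group and recompute
#'
#' The core of the bias-injection experiments: population group A keeps only
#' its paired locus group's cells (likewise B), then raw mean He and mean
#' scaled He are recomputed on the restricted cells. Scaling bounds are
#' per-cell functions of that cell's K and M, so restriction leaves the
#' bounds themselves unchanged — only the averaging set changes.
#'
#' @param meta A `meta_dataset`.
#' @param split Population split from [split_populations()], or `NULL` for
#'   no restriction (complete dataset).
#' @param partition Locus partition from [rank_loci_by_polymorphism()], or
#'   `NULL` for no restriction.
#' @param pairing Named character vector mapping population group to locus
#'   group, default `c(A = "low", B = "high")`.
#' @param degenerate_policy,k_mode Passed to [scaled_he()]. Study-wide K
#'   (the default `k_mode`) is computed from the full study's frequencies:
#'   restricting populations to a scenario does not redefine a locus's
#'   allele count.
#' @return Tibble with columns `population_id`, `group`, `mean_raw_he`,
#'   `mean_scaled_he`, `n_loci_used`, `n_loci_degenerate`.
#' @export
apply_scenario <- function(meta, split = NULL, partition = NULL,
                           pairing = c(A = "low", B = "high"),
                           degenerate_policy = "exclude", k_mode = "study") {
  stopifnot(inherits(meta, "meta_dataset"))
  summ <- meta$summaries
  if (is.null(split)) {
    split <- tibble::tibble(
      population_id = unique(meta$populations$population_id),
      group = "A"
    )
    if (is.null(partition)) pairing <- c(A = "all")
  }
  summ <- summ |>
    dplyr::inner_join(split, by = "population_id")
  if (!is.null(partition)) {
    summ <- summ |>
      dplyr::inner_join(
        partition[, c("locus", "group")], by = "locus",
        suffix = c("", "_locus")
      ) |>
      dplyr::filter(.data$group_locus == unname(pairing[.data$group])) |>
      dplyr::select(-"group_locus")
  }
  lost <- setdiff(split$population_id, summ$population_id)
  restricted <- structure(
    list(summaries = summ, frequencies = meta$frequencies),
    class = "meta_dataset"
  )
  res <- scaled_he(restricted, degenerate_policy = degenerate_policy,
                   k_mode = k_mode)
  out <- res$populations |>
    dplyr::left_join(split, by = "population_id") |>
    dplyr::select(
      "population_id", "group", "mean_raw_he", "mean_scaled_he",
      "n_loci_used", "n_loci_degenerate"
    )
  if (length(lost) > 0L) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      population_id = lost,
      group = split$group[match(lost, split$population_id)],
      mean_raw_he = NA_real_, mean_scaled_he = NA_real_,
      n_loci_used = 0L, n_loci_degenerate = 0L
    ))
  }
  out
}

#' Run the full grid of bias-injection scenarios
#'
#' Executes seven scenarios — the complete dataset, then the cross of
#' population splits (north-south, west-east, random) with locus partitions
#' (random, by polymorphism) — and reports Spearman correlations of raw and
#' scaled mean He against latitude, longitude, and distance from the origin
#' for each. In polymorphism scenarios the more-polymorphic locus half goes
#' to the southern (north-south), eastern (west-east), or B (random) group,
#' mirroring the discovery-bias construction being probed.
#'
#' @param meta A `meta_dataset` with population coordinates.
#' @param origin Numeric `c(lat, lon)` (default [default_origin()]).
#' @param seed Integer master seed for the random split and random locus
#'   partitions (sub-seeds derived deterministically).
#' @param degenerate_policy,k_mode Passed to [scaled_he()].
#' @return Tibble (class `scenario_report`) with columns `scenario`,
#'   `correlate`, `metric` (`raw` / `scaled`), `r_s`, `p`, `n`; attribute
#'   `seed`.
#' @export
run_bias_scenarios <- function(meta, origin = default_origin(), seed = 1L,
                               degenerate_policy = "exclude",
                               k_mode = "study") {
  stopifnot(inherits(meta, "meta_dataset"))
  pops <- meta$populations
  seed <- as.integer(seed)

  lp_poly <- rank_loci_by_polymorphism(meta, mode = "polymorphism")
  lp_rand <- rank_loci_by_polymorphism(meta, mode = "random", seed = seed + 1L)
  splits <- list(
    north_south = split_populations(pops, "latitude"),
    west_east = split_populations(pops, "longitude"),
    random = split_populations(pops, "random", seed = seed + 2L)
  )
  # A is the south/west half; the south (NS) and east (WE) sides get the
  # high-polymorphism loci, as does the arbitrary B side of the random split
  pairings <- list(
    north_south = c(A = "high", B = "low"),
    west_east = c(A = "low", B = "high"),
    random = c(A = "low", B = "high")
  )

  scenarios <- list(complete = list(split = NULL, partition = NULL,
                                    pairing = c(A = "all")))
  for (sp in names(splits)) {
    scenarios[[paste0(sp, "_loci_random")]] <- list(
      split = splits[[sp]], partition = lp_rand, pairing = pairings[[sp]]
    )
    scenarios[[paste0(sp, "_loci_polymorphism")]] <- list(
      split = splits[[sp]], partition = lp_poly, pairing = pairings[[sp]]
    )
  }

  rows <- purrr::imap(scenarios, function(sc, nm) {
    per_pop <- apply_scenario(
      meta, split = sc$split, partition = sc$partition, pairing = sc$pairing,
      degenerate_policy = degenerate_policy, k_mode = k_mode
    )
    per_pop <- per_pop[match(pops$population_id, per_pop$population_id), ]
    raw <- gradient_analysis(pops, per_pop$mean_raw_he, origin, "raw")
    scl <- gradient_analysis(pops, per_pop$mean_scaled_he, origin, "scaled")
    dplyr::bind_rows(raw, scl) |>
      dplyr::mutate(scenario = nm, .before = 1L) |>
      dplyr::select("scenario", "correlate", "metric", "r_s", "p", "n")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "origin") <- origin
  class(out) <- c("scenario_report", class(out))
  out
}
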