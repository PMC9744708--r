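#' Theoretical bounds of homozygosity given K and M
#'
#' For a locus with at most `K` alleles whose most frequent allele has
#' frequency `M`, homozygosity \eqn{H = \sum p^2} is constrained to a closed
#' interval:
#' \deqn{h_{min} = \frac{K M^2 - 2M + 1}{K - 1}}
#' \deqn{h_{max} = 1 - M(\lceil M^{-1}\rceil - 1)(2 - \lceil M^{-1}\rceil M)}
#' The lower bound is attained when the remaining probability mass is spread
#' evenly over the other `K - 1` alleles; the upper bound when as many alleles
#' as possible sit at frequency `M`. These bounds are the basis of the min-max
#' scaling of He: they describe how much of the apparent heterozygosity range
#' is fixed by panel polymorphism (K, M) rather than by the population.
#'
#' When the interval collapses (`K <= 2`, `M = 1`, or `M = 1/K`) the cell is
#' flagged degenerate: the data carry no information about where H sits inside
#' its theoretical range.
#'
#' @param K Integer vector of allele counts (>= 1).
#' @param M Numeric vector of most-frequent-allele frequencies, each in
#'   `[1/K, 1]`. Recycled against `K`.
#' @param eps Degeneracy threshold on `h_max - h_min` (default `1e-12`).
#' @return A tibble with columns `K`, `M`, `h_min`, `h_max`, `ceil_inv_M`,
#'   `degenerate`.
#' @examples
#' theoretical_h_bounds(3, 0.5) # h_min = 0.375, h_max = 0.5
#' @export
theoretical_h_bounds <- function(K, M, eps = 1e-12) {
  n <- max(length(K), length(M))
  K <- rep_len(as.integer(K), n)
  M <- rep_len(as.numeric(M), n)
  if (any(is.na(K)) || any(is.na(M))) {
    stop_domain("K and M must be non-missing")
  }
  if (any(K < 1L)) stop_domain("K must be >= 1")
  bad <- K >= 2L & (M < 1 / K - 1e-9 | M > 1 + 1e-9)
  if (any(bad)) {
    stop_domain(sprintf(
      "M outside [1/K, 1] for %d cell(s); first offender K=%d, M=%g",
      sum(bad), K[which(bad)[1]], M[which(bad)[1]]
    ))
  }

  # smallest integer >= 1/M, with a fuzz so exact reciprocals on the grid
  # (e.g. M = 0.2) do not tip over to the next integer
  cim <- as.integer(ceiling(1 / M - 1e-9))

  h_min <- ifelse(K == 1L, 1, (K * M^2 - 2 * M + 1) / pmax(K - 1, 1L))
  h_max <- ifelse(K == 1L, 1, 1 - M * (cim - 1) * (2 - cim * M))

  # floating-point slop can leave h_max a few ulp under h_min in degenerate
  # configurations; clamp (a genuine inversion would exceed eps by far)
  flip <- h_max < h_min & (h_min - h_max) < 1e-9
  h_max[flip] <- h_min[flip]

  tibble::tibble(
    K = K, M = M,
    h_min = h_min, h_max = h_max,
    ceil_inv_M = ifelse(K == 1L, 1L, cim),
    degenerate = (h_max - h_min) <= eps
  )
}

#' Min-max scale homozygosity within its theoretical bounds
#'
#' Maps observed homozygosity `H` onto `[0, 1]` relative to the theoretical
#' interval for its `(K, M)` cell:
#' \deqn{H_{scaled} = \frac{H - h_{min}}{h_{max} - h_{min}}}
#' and reports `scaled_he = 1 - h_scaled`, the standardized expected
#' heterozygosity. Degenerate cells yield `NA` (flagged, not an error):
#' with `K <= 2`, `M = 1` or `M = 1/K`, H is fully determined by `(K, M)` and
#' has no within-interval position.
#'
#' @param H Numeric vector of homozygosities (`sum(p^2)`).
#' @param bounds A tibble as returned by [theoretical_h_bounds()], one row per
#'   element of `H` (or a single row, recycled).
#' @param tol Tolerance for H falling outside its bounds before it is treated
#'   as a data error rather than rounding noise (default `1e-9`); within
#'   tolerance H is clipped into range.
#' @return A tibble with columns `H`, `h_scaled`, `scaled_he`, `degenerate`.
#' @examples
#' b <- theoretical_h_bounds(3, 0.4) # bounds [0.34, 0.36]
#' scale_cell(0.36, b) # h_scaled = 1, scaled_he = 0
#' @export
scale_cell <- function(H, bounds, tol = 1e-9) {
  n <- max(length(H), nrow(bounds))
  H <- rep_len(as.numeric(H), n)
  if (nrow(bounds) == 1L && n > 1L) {
    bounds <- bounds[rep(1L, n), ]
  }
  if (nrow(bounds) != n) {
    stop_data("`bounds` must have one row per H value")
  }
  out_of_range <- !bounds$degenerate &
    (H < bounds$h_min - tol | H > bounds$h_max + tol)
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop_data(sprintf(
      paste0(
        "H outside theoretical bounds for %d cell(s); first offender ",
        "H=%.10g with bounds [%.10g, %.10g] (K=%d, M=%g) - K, M and H were ",
        "likely computed from inconsistent frequencies"
      ),
      sum(out_of_range), H[i], bounds$h_min[i], bounds$h_max[i],
      bounds$K[i], bounds$M[i]
    ))
  }
  Hc <- pmin(pmax(H, bounds$h_min), bounds$h_max)
  width <- bounds$h_max - bounds$h_min
  h_scaled <- ifelse(bounds$degenerate, NA_real_, (Hc - bounds$h_min) / width)
  h_scaled <- pmin(pmax(h_scaled, 0), 1)
  tibble::tibble(
    H = H,
    h_scaled = h_scaled,
    scaled_he = 1 - h_scaled,
    degenerate = bounds$degenerate
  )
}

#' Scaled expected heterozygosity for every cell of a meta-dataset
#'
#' Applies [theoretical_h_bounds()] and [scale_cell()] to every
#' (population, locus) cell of a meta-dataset and averages scaled He per
#' population. M and H come from the cell's observed frequencies
#' ([locus_population_summary()] derives them jointly, so they are always
#' mutually consistent). The bound theorem's K is the locus's allele count:
#' by default (`k_mode = "study"`) the number of distinct alleles observed
#' for that locus across the whole study, the most faithful available
#' estimate of "at most K alleles". The per-cell observed allele count
#' (`k_mode = "cell"`) is also available but is a downward-biased,
#' sample-size-dependent estimate at typical population sizes (10-20
#' individuals); conditioning the bounds on it re-injects sampling noise
#' and flattens the scaled statistic's response to true diversity.
#'
#' Cells whose theoretical interval collapses (all `K <= 2` cells, monomorphic
#' cells, and `M = 1/K` cells) carry no scalable signal. Under the default
#' `degenerate_policy = "exclude"` they are dropped from the per-population
#' average (imputing any constant would re-inject panel-composition signal —
#' the artifact scaling removes); `"midpoint"` assigns them `scaled_he = 0.5`
#' instead. Low-polymorphism loci are retained, never filtered.
#'
#' @param meta A `meta_dataset` (see [merge_studies()]) or a plain summary
#'   tibble with columns `population_id`, `locus`, `K`, `M`, `H`, `He`.
#' @param degenerate_policy `"exclude"` (default) or `"midpoint"`.
#' @param k_mode `"study"` (default): the bound theorem's K is the
#'   study-wide allele count for the locus — distinct alleles across all the
#'   study's populations when frequencies are attached, else the maximum
#'   per-cell K; `"cell"`: the per-cell observed allele count.
#' @param eps,tol Passed to [theoretical_h_bounds()] / [scale_cell()].
#' @return A list of class `scaled_he_result` with elements `cells` (tibble:
#'   `study_id`, `population_id`, `locus`, `K`, `M`, `H`, `He`, `h_min`,
#'   `h_max`, `h_scaled`, `scaled_he`, `degenerate`) and `populations`
#'   (tibble: `population_id`, `mean_raw_he`, `mean_scaled_he`,
#'   `n_loci_used`, `n_loci_degenerate`).
#' @export
scaled_he <- function(meta, degenerate_policy = c("exclude", "midpoint"),
                      k_mode = c("study", "cell"), eps = 1e-12, tol = 1e-9) {
  degenerate_policy <- match.arg(degenerate_policy)
  k_mode <- match.arg(k_mode)
  is_meta <- inherits(meta, "meta_dataset") ||
    (is.list(meta) && !is.data.frame(meta) && !is.null(meta$summaries))
  summ <- if (is_meta) meta$summaries else tibble::as_tibble(meta)
  freqs <- if (is_meta) meta$frequencies else NULL
  req <- c("population_id", "locus", "K", "M", "H", "He")
  if (!all(req %in% names(summ))) {
    stop_data(paste0(
      "summaries must contain columns: ", paste(req, collapse = ", ")
    ))
  }
  if (!"study_id" %in% names(summ)) summ$study_id <- NA_character_

  K_eff <- summ$K
  if (k_mode == "study") {
    if (!is.null(freqs)) {
      study_k <- freqs |>
        dplyr::distinct(.data$study_id, .data$locus, .data$allele) |>
        dplyr::count(.data$study_id, .data$locus, name = "K_study")
      K_eff <- summ |>
        dplyr::left_join(study_k, by = c("study_id", "locus")) |>
        dplyr::pull(.data$K_study)
    } else {
      K_eff <- summ |>
        dplyr::group_by(.data$study_id, .data$locus) |>
        dplyr::mutate(.K_study = max(.data$K)) |>
        dplyr::ungroup() |>
        dplyr::pull(.data$.K_study)
    }
    K_eff[is.na(K_eff)] <- summ$K[is.na(K_eff)]
    K_eff <- pmax(K_eff, summ$K) # a cell can never exceed its study's count
  }

  b <- theoretical_h_bounds(K_eff, summ$M, eps = eps)
  sc <- scale_cell(summ$H, b, tol = tol)
  if (degenerate_policy == "midpoint") {
    sc$h_scaled[sc$degenerate] <- 0.5
    sc$scaled_he[sc$degenerate] <- 0.5
  }

  cells <- tibble::tibble(
    study_id = summ$study_id,
    population_id = summ$population_id,
    locus = summ$locus,
    K = summ$K, M = summ$M, H = summ$H, He = summ$He,
    h_min = b$h_min, h_max = b$h_max,
    h_scaled = sc$h_scaled, scaled_he = sc$scaled_he,
    degenerate = sc$degenerate
  )

  pops <- cells |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(
      mean_raw_he = mean(.data$He[!is.na(.data$scaled_he)]),
      mean_scaled_he = mean(.data$scaled_he[!is.na(.data$scaled_he)]),
      n_loci_used = sum(!is.na(.data$scaled_he)),
      n_loci_degenerate = sum(.data$degenerate),
      .groups = "drop"
    )
  pops$mean_raw_he[pops$n_loci_used == 0L] <- NA_real_
  pops$mean_scaled_he[pops$n_loci_used == 0L] <- NA_real_
  if (any(pops$n_loci_used == 0L)) {
    warn(sprintf(
      "%d population(s) have only degenerate cells; mean scaled He is NA",
      sum(pops$n_loci_used == 0L)
    ))
  }

  structure(
    list(cells = cells, populations = pops,
         degenerate_policy = degenerate_policy, k_mode = k_mode),
    class = "scaled_he_result"
  )
}

#' Exhaustively enumerate H over a discrete frequency simplex
#'
#' Brute-force verification companion to [theoretical_h_bounds()]: enumerates
#' every frequency vector on a `1/step` grid of length `K` (entries >= 0,
#' i.e. at most K alleles, the bound theorem's premise) with maximum entry
#' exactly `m/step`, computes H for each, and reports the
#' observed extremes together with the count of vectors whose H falls outside
#' `[lo - slack, hi + slack]`. The enumeration is independent of the bound
#' formulas, so it can serve as their oracle.
#'
#' @param K Number of alleles (positive entries).
#' @param m Integer numerator of the maximum frequency (`M = m/step`).
#' @param step Grid resolution denominator (default 100, i.e. 0.01 steps).
#' @param lo,hi Interval to check H values against (defaults `-Inf`/`Inf`
#'   disable the check).
#' @param slack Slack applied to the interval check (default `1e-9`).
#' @return Named numeric vector: `h_min`, `h_max` (observed extremes over the
#'   enumeration; `Inf`/`-Inf` when no admissible vector exists), `n`
#'   (vectors enumerated), `n_violations`.
#' @export
enumerate_h_given_m <- function(K, m, step = 100L, lo = -Inf, hi = Inf,
                                slack = 1e-9) {
  .enumerate_h_range_cpp(as.integer(K), as.integer(m), as.integer(step),
                         as.numeric(lo), as.numeric(hi), as.numeric(slack))
}
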