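#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean radius).
#' A spherical model is adequate here: interpolation weights and gradient
#' correlations operate at continental scale where the ellipsoidal
#' correction (< 0.5%) is immaterial.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized,
#'   recycled).
#' @return Numeric vector of distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  if (any(abs(p1[, 2]) > 90 | abs(p2[, 2]) > 90 |
            abs(p1[, 1]) > 180 | abs(p2[, 1]) > 180)) {
    stop_domain("coordinates outside WGS84 ranges")
  }
  as.numeric(geosphere::distHaversine(p1, p2, r = 6371.0088))
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' `r_s` is the Pearson correlation of average ranks. The two-sided p-value
#' uses the t approximation with `n - 2` degrees of freedom for `n >= 10`,
#' exact enumeration over all `n!` permutations for `n <= 8`, and seeded
#' Monte-Carlo permutation (1e5 draws) in between — at those sizes the t
#' approximation is unreliable and full enumeration still cheap or
#' approximable.
#'
#' Pairs with a missing value in either argument are dropped. If either
#' variable has zero rank variance the correlation is undefined: the result
#' carries `NA` with a warning rather than an error, so gradient scans over
#' many metrics degrade gracefully.
#'
#' @param x,y Numeric vectors of equal length.
#' @param mc_seed Seed for the Monte-Carlo branch (default 20260101).
#' @return A tibble with columns `r_s`, `p`, `n`, `method`.
#' @export
spearman_correlation <- function(x, y, mc_seed = 20260101L) {
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_domain("need at least 3 complete pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warn("zero rank variance; Spearman correlation undefined")
    return(tibble::tibble(
      r_s = NA_real_, p = NA_real_, n = n, method = NA_character_
    ))
  }
  r_s <- cor(rx, ry)

  if (n >= 10L) {
    tstat <- r_s * sqrt((n - 2) / max(1 - r_s^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  } else if (n <= 8L) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1L, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(r_perm) >= abs(r_s) - 1e-12)
    method <- "exact-permutation"
  } else {
    r_perm <- with_local_seed(mc_seed, {
      vapply(seq_len(1e5), function(i) cor(rx, sample(ry)), numeric(1))
    })
    p <- mean(abs(r_perm) >= abs(r_s) - 1e-12)
    method <- "mc-permutation"
  }
  tibble::tibble(r_s = r_s, p = min(p, 1), n = n, method = method)
}

# All n! permutations of 1..n as a matrix (rows). Used only for n <= 8.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on `groups - 1`
#' degrees of freedom (delegating to [stats::kruskal.test()]); the
#' all-observations-equal edge case is defined as `H = 0`, `p = 1`.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return A tibble with columns `H_stat`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_domain("need at least 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop_domain("groups must be non-empty")
  }
  pooled <- unlist(groups, use.names = FALSE)
  df <- length(groups) - 1L
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(H_stat = 0, df = df, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  tibble::tibble(
    H_stat = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value
  )
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise mean-rank comparisons after a Kruskal-Wallis test. For groups a,
#' b with pooled mean ranks \eqn{\bar R_a, \bar R_b}:
#' \deqn{z = (\bar R_a - \bar R_b) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_a} +
#'   \frac{1}{n_b}\right)}}
#' with the tie term summed over tied groups in the pooled sample. Adjusted
#' p-values are `min(1, p * C(k, 2))`.
#'
#' @param groups List of >= 2 non-empty numeric vectors; names used as group
#'   labels when present.
#' @return A tibble with columns `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_domain("need at least 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop_domain("groups must be non-empty")
  }
  k <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)
  sizes <- vapply(groups, length, integer(1))
  idx_end <- cumsum(sizes)
  idx_start <- idx_end - sizes + 1L
  mean_ranks <- vapply(seq_len(k), function(i) {
    mean(rk[idx_start[i]:idx_end[i]])
  }, numeric(1))
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(k, 2L)
  n_pairs <- ncol(pairs)
  z <- p <- numeric(n_pairs)
  for (c_i in seq_len(n_pairs)) {
    a <- pairs[1L, c_i]
    b <- pairs[2L, c_i]
    se <- sqrt(var_base * (1 / sizes[a] + 1 / sizes[b]))
    z[c_i] <- if (se == 0) 0 else (mean_ranks[a] - mean_ranks[b]) / se
    p[c_i] <- 2 * pnorm(-abs(z[c_i]))
  }
  tibble::tibble(
    group1 = labels[pairs[1L, ]],
    group2 = labels[pairs[2L, ]],
    z = z, p = p,
    p_adjusted = pmin(1, p * n_pairs)
  )
}

#' Geographic gradient analysis of a per-population metric
#'
#' Correlates a per-population metric against latitude, longitude, and
#' great-circle distance from a hypothesized origin (Spearman). Under a
#' post-glacial range expansion from the origin, genetic diversity is
#' expected to decrease with distance; latitude and longitude correlations
#' test the corresponding south-to-north and west-to-east readings of that
#' gradient. Populations lacking the metric are dropped pairwise.
#'
#' @param pops Tibble with columns `population_id`, `latitude`, `longitude`.
#' @param metric Numeric vector, one value per row of `pops` (NA allowed).
#' @param origin Numeric `c(lat, lon)` of the hypothesized expansion origin
#'   (default [default_origin()]).
#' @param metric_name Label recorded in the report (default "metric").
#' @return A tibble (class `gradient_report`) with columns `metric`,
#'   `correlate` (`latitude` / `longitude` / `distance_from_origin`), `r_s`,
#'   `p`, `n`, `method`; the origin is attached as attribute `origin`.
#' @export
gradient_analysis <- function(pops, metric, origin = default_origin(),
                              metric_name = "metric") {
  pops <- tibble::as_tibble(pops)
  req <- c("population_id", "latitude", "longitude")
  if (!all(req %in% names(pops))) {
    stop_data(paste0("pops must contain columns: ", paste(req, collapse = ", ")))
  }
  if (length(metric) != nrow(pops)) {
    stop_data("metric must have one value per population")
  }
  if (sum(!is.na(metric)) < 3L) {
    stop_domain("need at least 3 populations with a metric value")
  }
  dist_km <- haversine_km(
    pops$latitude, pops$longitude, origin[1], origin[2]
  )
  correlates <- list(
    latitude = pops$latitude,
    longitude = pops$longitude,
    distance_from_origin = dist_km
  )
  rows <- purrr::imap(correlates, function(v, nm) {
    res <- spearman_correlation(metric, v)
    tibble::tibble(
      metric = metric_name, correlate = nm,
      r_s = res$r_s, p = res$p, n = res$n, method = res$method
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "origin") <- origin
  class(out) <- c("gradient_report", class(out))
  out
}

#' Default hypothesized expansion origin
#'
#' The Slovenian region of the eastern Alps, a proposed main source area for
#' the post-glacial recolonization of central and northern Europe by beech.
#' No exact coordinates are canonical; this default (46.05 N, 14.5 E) is a
#' documented, overridable convention.
#'
#' @return Numeric `c(lat, lon)`.
#' @export
default_origin <- function() {
  c(lat = 46.05, lon = 14.5)
}
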