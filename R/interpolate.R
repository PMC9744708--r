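#' Grid specification for surface interpolation
#'
#' @param bbox Numeric `c(lat_min, lat_max, lon_min, lon_max)`, or `NULL` to
#'   derive from the data extent padded by 1 degree.
#' @param cell_size Cell edge in degrees (default 0.5).
#' @param block Block-discretization factor b: each cell's value averages
#'   b x b regularly spaced sub-point predictions (default 2, i.e. a 2 x 2
#'   block average).
#' @param power Inverse-distance weighting exponent (default 5).
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(bbox = NULL, cell_size = 0.5, block = 2L, power = 5) {
  if (!is.null(bbox)) {
    if (length(bbox) != 4L || bbox[1] >= bbox[2] || bbox[3] >= bbox[4]) {
      stop_config("bbox must be c(lat_min, lat_max, lon_min, lon_max)")
    }
  }
  if (cell_size <= 0) stop_config("cell_size must be > 0")
  if (block < 1L) stop_config("block must be >= 1")
  if (power <= 0) stop_config("idw power must be > 0")
  structure(
    list(bbox = bbox, cell_size = cell_size, block = as.integer(block),
         power = power),
    class = "grid_spec"
  )
}

#' Inverse-distance-weighted prediction at query points
#'
#' Prediction is the d^(-power)-weighted mean of the observations, with d
#' the great-circle distance in km — so weights are isotropic in ground
#' distance rather than degrees. A query within 1e-9 km of a data point
#' returns that point's value exactly (ties among exact hits: their mean),
#' making the interpolator exact at data sites for any power.
#'
#' @param lat,lon Numeric vectors: data point coordinates.
#' @param values Numeric vector of observations at the data points.
#' @param query_lat,query_lon Numeric vectors of query coordinates
#'   (equal length).
#' @param power IDW exponent (default 5).
#' @return Numeric vector of predictions, one per query.
#' @export
idw_predict <- function(lat, lon, values, query_lat, query_lon, power = 5) {
  n <- length(values)
  if (n == 0L) stop_domain("need at least 1 data point")
  if (length(lat) != n || length(lon) != n) {
    stop_data("lat, lon and values must have equal length")
  }
  if (any(!is.finite(values))) stop_data("values must be finite")
  nq <- max(length(query_lat), length(query_lon))
  query_lat <- rep_len(query_lat, nq)
  query_lon <- rep_len(query_lon, nq)
  # one vectorized distance call for all (data point, query) pairs
  D <- matrix(
    haversine_km(
      rep(query_lat, each = n), rep(query_lon, each = n),
      rep(lat, times = nq), rep(lon, times = nq)
    ),
    nrow = n, ncol = nq
  )
  W <- D^(-power)
  out <- colSums(W * values) / colSums(W)
  hit_cols <- which(colSums(D < 1e-9) > 0)
  for (q in hit_cols) {
    out[q] <- mean(values[D[, q] < 1e-9])
  }
  out
}

#' Interpolate a surface over a regular grid
#'
#' Each grid cell's value is the mean of IDW predictions at `block x block`
#' regularly spaced sub-points inside the cell (a block average); with
#' `block = 1` the cell value is the prediction at its center. Fully
#' deterministic.
#'
#' @param lat,lon,values Data points and observations.
#' @param spec A [grid_spec()].
#' @return A tibble of class `idw_surface` with columns `lat`, `lon` (cell
#'   centers), `value`, `masked` (all `FALSE`; see [mask_surface()]);
#'   attribute `spec`.
#' @export
interpolate_surface <- function(lat, lon, values, spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 0L) stop_domain("need at least 1 data point")
  bbox <- spec$bbox
  if (is.null(bbox)) {
    bbox <- c(min(lat) - 1, max(lat) + 1, min(lon) - 1, max(lon) + 1)
  }
  cs <- spec$cell_size
  lat_centers <- seq(bbox[1] + cs / 2, bbox[2], by = cs)
  lon_centers <- seq(bbox[3] + cs / 2, bbox[4], by = cs)
  if (length(lat_centers) == 0L || length(lon_centers) == 0L) {
    stop_domain("empty grid: bbox smaller than one cell")
  }
  grid <- expand.grid(lat = lat_centers, lon = lon_centers,
                      KEEP.OUT.ATTRS = FALSE)
  b <- spec$block
  # sub-point offsets relative to the cell center, fractions of the cell edge
  off <- ((seq_len(b) - 0.5) / b - 0.5) * cs
  acc <- numeric(nrow(grid))
  for (oy in off) {
    for (ox in off) {
      acc <- acc + idw_predict(
        lat, lon, values, grid$lat + oy, grid$lon + ox, spec$power
      )
    }
  }
  out <- tibble::tibble(
    lat = grid$lat, lon = grid$lon,
    value = acc / (b * b), masked = FALSE
  )
  attr(out, "spec") <- spec
  class(out) <- c("idw_surface", class(out))
  out
}

#' Mask a surface to a polygon
#'
#' Flags cells whose centers fall outside the polygon(s). Rings follow
#' GeoJSON semantics: closed lon/lat rings combined under the even-odd rule
#' (holes are additional rings); a center exactly on a ring edge counts as
#' inside.
#'
#' @param surface An `idw_surface`.
#' @param rings A list of closed rings, each a 2-column matrix of
#'   (lon, lat); or the result of [read_geojson_rings()].
#' @return The surface with its `masked` column updated.
#' @export
mask_surface <- function(surface, rings) {
  stopifnot(inherits(surface, "idw_surface"))
  if (is.matrix(rings)) rings <- list(rings)
  for (r in rings) {
    if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 4L) {
      stop_parse("each ring must be a matrix of (lon, lat) with >= 4 rows")
    }
    if (any(r[1L, ] != r[nrow(r), ])) {
      stop_parse("ring is not closed (first and last vertex differ)")
    }
  }
  inside <- vapply(seq_len(nrow(surface)), function(i) {
    point_in_rings(surface$lon[i], surface$lat[i], rings)
  }, logical(1))
  surface$masked <- !inside
  surface
}

# Even-odd point-in-polygon over a set of rings; points on any edge are
# inside. Plain ray casting in lon/lat coordinates.
point_in_rings <- function(x, y, rings) {
  crossings <- 0L
  for (ring in rings) {
    n <- nrow(ring) - 1L
    for (i in seq_len(n)) {
      x1 <- ring[i, 1]; y1 <- ring[i, 2]
      x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
      # on-segment check (boundary-inclusive rule)
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-12 &&
            x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
            y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12) {
        return(TRUE)
      }
      if ((y1 > y) != (y2 > y)) {
        x_int <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < x_int) crossings <- crossings + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

#' Read polygon rings from a GeoJSON file
#'
#' Accepts a Polygon or MultiPolygon geometry, a Feature, or a
#' FeatureCollection; returns all rings flattened to a list of (lon, lat)
#' matrices suitable for [mask_surface()].
#'
#' @param path Path to a GeoJSON file.
#' @return List of closed ring matrices.
#' @export
read_geojson_rings <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- list()
  collect <- function(node) {
    if (is.null(node$type)) stop_parse("GeoJSON node without a type")
    switch(node$type,
      FeatureCollection = lapply(node$features, collect),
      Feature = collect(node$geometry),
      Polygon = geoms[[length(geoms) + 1L]] <<- node$coordinates,
      MultiPolygon = for (poly in node$coordinates) {
        geoms[[length(geoms) + 1L]] <<- poly
      },
      stop_parse(sprintf("unsupported GeoJSON type '%s'", node$type))
    )
    invisible(NULL)
  }
  collect(gj)
  rings <- list()
  for (poly in geoms) {
    for (ring in poly) {
      m <- do.call(rbind, lapply(ring, function(pt) {
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
      }))
      rings[[length(rings) + 1L]] <- m
    }
  }
  if (length(rings) == 0L) stop_parse("no polygon rings found in GeoJSON")
  rings
}

#' Leave-one-out cross-validation of the IDW interpolator
#'
#' Predicts each observation from all others and reports residuals and
#' RMSE. Data points whose coordinates coincide with the held-out point
#' (within 1e-9 km) are excluded from its donor set too, so duplicated
#' stations cannot leak the held-out value into its own prediction.
#'
#' @param lat,lon,values Data points and observations (>= 3).
#' @param power IDW exponent (default 5).
#' @return A list of class `loo_cv_report`: `predicted`, `residuals`
#'   (observed minus predicted), `rmse`.
#' @export
loo_cross_validate <- function(lat, lon, values, power = 5) {
  n <- length(values)
  if (n < 3L) stop_domain("need at least 3 points")
  predicted <- numeric(n)
  for (i in seq_len(n)) {
    d <- haversine_km(lat[i], lon[i], lat, lon)
    donors <- which(d > 1e-9)
    if (length(donors) == 0L) {
      stop_data("a point has no donors: all points are co-located")
    }
    predicted[i] <- idw_predict(
      lat[donors], lon[donors], values[donors], lat[i], lon[i], power
    )
  }
  residuals <- values - predicted
  structure(
    list(predicted = predicted, residuals = residuals,
         rmse = sqrt(mean(residuals^2))),
    class = "loo_cv_report"
  )
}

#' @export
print.loo_cv_report <- function(x, ...) {
  cat(sprintf("<loo_cv_report> n = %d, RMSE = %.6g\n",
              length(x$residuals), x$rmse))
  invisible(x)
}

#' Jackknife confidence intervals for an interpolated surface
#'
#' For each grid cell, computes the full-data surface value and the n
#' delete-one surface values, forms jackknife pseudo-values
#' \eqn{\theta_i = n s_{full} - (n-1) s_{-i}}, and reports the
#' half-width of the t-based confidence interval
#' \eqn{t_{1-\alpha/2, n-1}\, sd(\theta)/\sqrt{n}} per cell.
#'
#' @param lat,lon,values Data points and observations (>= 3).
#' @param spec A [grid_spec()].
#' @param conf Confidence level (default 0.95).
#' @return The full-data surface tibble with an added `ci_half_width`
#'   column.
#' @export
jackknife_intervals <- function(lat, lon, values, spec = grid_spec(),
                                conf = 0.95) {
  n <- length(values)
  if (n < 3L) stop_domain("need at least 3 points")
  full <- interpolate_surface(lat, lon, values, spec)
  # delete-one surfaces share the full surface's grid
  spec_fixed <- spec
  if (is.null(spec_fixed$bbox)) {
    spec_fixed$bbox <- c(min(lat) - 1, max(lat) + 1, min(lon) - 1, max(lon) + 1)
  }
  pseudo <- matrix(0, nrow = nrow(full), ncol = n)
  for (i in seq_len(n)) {
    s_i <- interpolate_surface(lat[-i], lon[-i], values[-i], spec_fixed)
    pseudo[, i] <- n * full$value - (n - 1) * s_i$value
  }
  theta_sd <- apply(pseudo, 1L, sd)
  tcrit <- qt(1 - (1 - conf) / 2, df = n - 1)
  full$ci_half_width <- tcrit * theta_sd / sqrt(n)
  full
}

#' Write a surface as a delimited grid table
#'
#' Columns `lat`, `lon`, `value`, `masked` and, when present,
#' `ci_half_width`.
#'
#' @param surface An `idw_surface`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  readr::write_tsv(tibble::as_tibble(surface), path, progress = FALSE)
  invisible(path)
}
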