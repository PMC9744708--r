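test_that("IDW is exact at data sites and symmetric between equidistant points", {
  lat <- c(45, 47)
  lon <- c(10, 10)
  v <- c(0.57, 0.80)
  expect_equal(idw_predict(lat, lon, v, 45, 10), 0.57)
  # midpoint on the same meridian: equidistant, any power
  for (p in c(1, 2, 5, 20)) {
    expect_equal(idw_predict(lat, lon, c(0.4, 0.6), 46, 10, power = p), 0.5)
  }
})

test_that("two-point worked example: d ratio 2 at power 5 gives 32/33", {
  # place the query on a meridian, data points 100 and 200 km away
  km_per_deg <- haversine_km(0, 0, 1, 0)
  lat <- c(100, -200) / km_per_deg
  lon <- c(0, 0)
  pred <- idw_predict(lat, lon, c(1, 0), 0, 0, power = 5)
  expect_equal(pred, 32 / 33, tolerance = 1e-12)
})

test_that("IDW predictions are convex and permutation-invariant", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    lat <- runif(n, 40, 55)
    lon <- runif(n, -5, 25)
    v <- runif(n)
    q <- c(runif(1, 40, 55), runif(1, -5, 25))
    pred <- idw_predict(lat, lon, v, q[1], q[2])
    expect_gte(pred, min(v) - 1e-12)
    expect_lte(pred, max(v) + 1e-12)
    perm <- sample(n)
    expect_equal(idw_predict(lat[perm], lon[perm], v[perm], q[1], q[2]), pred)
  }
})

test_that("high power localizes predictions to the nearest point", {
  lat <- c(44, 50)
  lon <- c(8, 20)
  v <- c(0.2, 0.9)
  near_first <- idw_predict(lat, lon, v, 44.5, 9, power = 50)
  expect_equal(near_first, 0.2, tolerance = 1e-6)
})

test_that("block-averaged surfaces compose from sub-point predictions", {
  lat <- c(45, 46, 47)
  lon <- c(10, 11, 12)
  v <- c(0.3, 0.5, 0.8)
  spec1 <- grid_spec(bbox = c(45, 47, 10, 12), cell_size = 1, block = 1L)
  s1 <- interpolate_surface(lat, lon, v, spec1)
  # block = 1: cell value is the center prediction
  expect_equal(
    s1$value,
    idw_predict(lat, lon, v, s1$lat, s1$lon, 5)
  )
  # block = 2: mean of the four quarter-point predictions
  spec2 <- grid_spec(bbox = c(45, 47, 10, 12), cell_size = 1, block = 2L)
  s2 <- interpolate_surface(lat, lon, v, spec2)
  for (i in seq_len(nrow(s2))) {
    offs <- c(-0.25, 0.25)
    sub <- expand.grid(dy = offs, dx = offs)
    manual <- mean(idw_predict(
      lat, lon, v, s2$lat[i] + sub$dy, s2$lon[i] + sub$dx, 5
    ))
    expect_equal(s2$value[i], manual, tolerance = 1e-12)
  }
  # constant field interpolates to the constant everywhere
  sc <- interpolate_surface(lat, lon, rep(0.6, 3), spec2)
  expect_equal(sc$value, rep(0.6, nrow(sc)))
})

test_that("polygon masking flags centers outside, boundary counts inside", {
  ring <- cbind(c(10, 12, 12, 10, 10), c(45, 45, 47, 47, 45)) # lon, lat
  surf <- tibble::tibble(
    lat = c(46, 48, 45), lon = c(11, 11, 11), value = 1, masked = FALSE
  )
  class(surf) <- c("idw_surface", class(surf))
  m <- mask_surface(surf, list(ring))
  expect_equal(m$masked, c(FALSE, TRUE, FALSE)) # on-edge point unmasked

  open_ring <- ring[1:4, ]
  expect_error(mask_surface(surf, list(open_ring)),
               class = "hescale_parse_error")
})

test_that("GeoJSON polygons load as rings and drive masking", {
  p <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Polygon",
    coordinates = list(list(
      list(10, 45), list(12, 45), list(12, 47), list(10, 47), list(10, 45)
    ))
  ), auto_unbox = TRUE), p)
  rings <- read_geojson_rings(p)
  expect_length(rings, 1L)
  expect_equal(nrow(rings[[1]]), 5L)
})

test_that("LOO cross-validation matches a hand-computed 3-point oracle", {
  lat <- c(45, 46, 47.5)
  lon <- c(10, 11.5, 10.5)
  v <- c(0.4, 0.6, 0.7)
  cv <- loo_cross_validate(lat, lon, v, power = 5)
  # manual hold-out prediction for each point from the other two
  for (i in 1:3) {
    d <- oracle_haversine_km(lat[i], lon[i], lat[-i], lon[-i])
    w <- d^-5
    manual <- sum(w * v[-i]) / sum(w)
    expect_equal(cv$predicted[i], manual, tolerance = 1e-6)
  }
  expect_equal(cv$rmse, sqrt(mean((v - cv$predicted)^2)), tolerance = 1e-12)

  # constant field: zero residuals
  cv0 <- loo_cross_validate(lat, lon, rep(0.5, 3))
  expect_equal(cv0$rmse, 0)
})

test_that("LOO RMSE grows with the noise level on a smooth field", {
  set.seed(99)
  n <- 40
  lat <- runif(n, 42, 52)
  lon <- runif(n, 0, 20)
  base <- 0.7 - 0.02 * (lat - 42)
  rmses <- vapply(c(0.01, 0.05, 0.1), function(s) {
    loo_cross_validate(lat, lon, base + rnorm(n, 0, s))$rmse
  }, numeric(1))
  expect_true(all(diff(rmses) > 0))
})

test_that("jackknife intervals vanish on constant fields and stay nonnegative", {
  lat <- c(45, 46, 47, 48)
  lon <- c(10, 12, 11, 13)
  spec <- grid_spec(bbox = c(45, 48, 10, 13), cell_size = 1, block = 1L)
  s0 <- jackknife_intervals(lat, lon, rep(0.5, 4), spec)
  expect_equal(s0$ci_half_width, rep(0, nrow(s0)))

  s1 <- jackknife_intervals(lat, lon, c(0.4, 0.5, 0.6, 0.7), spec)
  expect_true(all(s1$ci_half_width >= 0))
})

test_that("uncertainty is larger far from the data than at the data", {
  set.seed(12)
  n <- 12
  lat <- runif(n, 44, 47)
  lon <- runif(n, 8, 12)
  v <- 0.7 - 0.05 * (lat - 44) + rnorm(n, 0, 0.02)
  spec <- grid_spec(bbox = c(43, 52, 7, 13), cell_size = 1, block = 1L)
  s <- jackknife_intervals(lat, lon, v, spec)
  near <- s$lat <= 47
  far <- s$lat >= 50
  expect_gt(mean(s$ci_half_width[far]), 0)
  expect_gt(mean(s$ci_half_width[near]), 0)
  # far cells: delete-one surfaces move more where no point anchors them
  expect_false(mean(s$ci_half_width[near]) > mean(s$ci_half_width[far]) * 5)
})
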