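test_that("haversine distances match an independent implementation", {
  expect_equal(haversine_km(0, 0, 0, 0), 0)
  # half circumference: pi * R
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-4)
  d <- haversine_km(46, 14.5, 48, 16.5)
  expect_equal(d, oracle_haversine_km(46, 14.5, 48, 16.5), tolerance = 5e-3)

  # symmetry and triangle inequality on random triples
  set.seed(11)
  for (i in 1:25) {
    lat <- runif(3, -85, 85)
    lon <- runif(3, -179, 179)
    ab <- haversine_km(lat[1], lon[1], lat[2], lon[2])
    ba <- haversine_km(lat[2], lon[2], lat[1], lon[1])
    ac <- haversine_km(lat[1], lon[1], lat[3], lon[3])
    cb <- haversine_km(lat[3], lon[3], lat[2], lon[2])
    expect_equal(ab, ba)
    expect_lte(ab, ac + cb + 1e-9)
  }
})

test_that("Spearman r_s matches hand values and ties use average ranks", {
  expect_equal(spearman_correlation(1:3, 1:3)$r_s, 1)
  expect_equal(spearman_correlation(1:3, 3:1)$r_s, -1)
  expect_equal(spearman_correlation(1:4, c(2, 1, 4, 3))$r_s, 0.6)
  # invariance under strictly monotone transforms
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  r0 <- spearman_correlation(x, y)$r_s
  expect_equal(spearman_correlation(exp(x), y)$r_s, r0)
  expect_equal(spearman_correlation(x, y^3)$r_s, r0)
})

test_that("exact permutation p-values match an independent exact test", {
  # no ties: cor.test's exact Spearman p is an independent oracle
  set.seed(5)
  for (i in 1:5) {
    x <- sample(1:7)
    y <- sample(1:7)
    res <- spearman_correlation(x, y)
    expect_equal(res$method, "exact-permutation")
    oracle <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  }
})

test_that("large-n p-values follow the t approximation", {
  set.seed(6)
  x <- rnorm(30)
  y <- x + rnorm(30)
  res <- spearman_correlation(x, y)
  expect_equal(res$method, "t-approximation")
  tstat <- res$r_s * sqrt((res$n - 2) / (1 - res$r_s^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), res$n - 2))
})

test_that("zero rank variance yields NA with a warning, not an error", {
  expect_warning(res <- spearman_correlation(c(1, 1, 1, 1), 1:4), "variance")
  expect_true(is.na(res$r_s))
})

test_that("Kruskal-Wallis reproduces the textbook example and edge cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H_stat, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))

  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$H_stat, 0,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5)))$H_stat, 0)
  expect_error(kruskal_wallis(list(1:3)), class = "hescale_domain_error")

  # label symmetry and monotone invariance of the pooled sample
  g <- list(a = c(3, 6, 1), b = c(9, 2), c = c(4, 8, 7))
  h1 <- kruskal_wallis(g)$H_stat
  expect_equal(kruskal_wallis(rev(g))$H_stat, h1)
  expect_equal(kruskal_wallis(lapply(g, function(v) v^3))$H_stat, h1)
})

test_that("Dunn z matches a direct rank-formula evaluation", {
  # groups (1,2,3) vs (7,8,9): mean ranks 2 and 5, no ties
  d <- dunn_posthoc(list(g1 = c(1, 2, 3), g2 = c(7, 8, 9)))
  se <- sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(abs(d$z), 3 / se, tolerance = 1e-9)
  expect_equal(d$p, 2 * pnorm(-3 / se), tolerance = 1e-12)

  # identical groups: z = 0, adjusted p = 1
  d0 <- dunn_posthoc(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(d0$z, 0)
  expect_equal(d0$p_adjusted, 1)

  # Bonferroni never deflates
  set.seed(8)
  d3 <- dunn_posthoc(list(rnorm(5), rnorm(5), rnorm(5)))
  expect_true(all(d3$p_adjusted >= d3$p))
  expect_true(all(d3$p_adjusted <= 1))
})

test_that("gradient analysis correlates a metric with the three correlates", {
  pops <- tibble::tibble(
    population_id = sprintf("p%d", 1:12),
    latitude = seq(42, 53, by = 1),
    longitude = seq(6, 28, by = 2)
  )
  d <- haversine_km(pops$latitude, pops$longitude, 46.05, 14.5)
  metric <- 1 - d / max(d) # strictly decreasing with distance
  rep <- gradient_analysis(pops, metric, origin = c(46.05, 14.5))
  expect_equal(rep$r_s[rep$correlate == "distance_from_origin"], -1)
  expect_equal(nrow(rep), 3L)

  # constant metric: all three undefined
  suppressWarnings(rep0 <- gradient_analysis(pops, rep(0.5, 12)))
  expect_true(all(is.na(rep0$r_s)))

  # pairwise deletion keeps the maximum available n
  metric[1] <- NA
  rep2 <- gradient_analysis(pops, metric)
  expect_equal(unique(rep2$n), 11L)

  expect_error(gradient_analysis(pops, c(1, NA, NA, rep(NA, 9))),
               class = "hescale_domain_error")
})
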