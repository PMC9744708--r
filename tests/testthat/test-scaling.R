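test_that("worked bound examples match formula and enumeration", {
  b <- theoretical_h_bounds(3, 0.5)
  expect_equal(b$h_min, 0.375)
  expect_equal(b$h_max, 0.5)
  expect_equal(b$ceil_inv_M, 2L)
  expect_false(b$degenerate)

  # K = 3, M = 0.4: h_min attained by (0.4, 0.3, 0.3), h_max by (0.4, 0.4, 0.2)
  b2 <- theoretical_h_bounds(3, 0.4)
  expect_equal(b2$h_min, 0.34)
  expect_equal(b2$h_max, 0.36)
  expect_equal(b2$ceil_inv_M, 3L)
  e <- enumerate_h_given_m(3, 40)
  expect_equal(unname(e["h_min"]), 0.34, tolerance = 1e-12)
  expect_equal(unname(e["h_max"]), 0.36, tolerance = 1e-12)
})

test_that("degenerate configurations collapse the interval exactly", {
  # K = 2: H fully determined by M
  for (M in c(0.5, 0.6, 0.75, 0.9)) {
    b <- theoretical_h_bounds(2, M)
    expect_equal(b$h_min, M^2 + (1 - M)^2)
    expect_equal(b$h_max, b$h_min)
    expect_true(b$degenerate)
  }
  # monomorphic and equifrequent endpoints
  expect_true(theoretical_h_bounds(5, 1)$degenerate)
  expect_equal(theoretical_h_bounds(5, 1)$h_min, 1)
  b_eq <- theoretical_h_bounds(4, 0.25)
  expect_true(b_eq$degenerate)
  expect_equal(b_eq$h_min, 0.25, tolerance = 1e-12)
  # K = 1 short-circuits to (1, 1)
  b1 <- theoretical_h_bounds(1, 1)
  expect_equal(c(b1$h_min, b1$h_max), c(1, 1))
})

test_that("M outside [1/K, 1] is a domain error", {
  expect_error(theoretical_h_bounds(3, 0.2), class = "hescale_domain_error")
  expect_error(theoretical_h_bounds(3, 1.2), class = "hescale_domain_error")
})

test_that("scaling maps bounds to endpoints and interior cells linearly", {
  b <- theoretical_h_bounds(3, 0.4)
  s <- scale_cell(c(0.34, 0.345, 0.36), b[rep(1, 3), ])
  expect_equal(s$h_scaled, c(0, 0.25, 1), tolerance = 1e-9)
  expect_equal(s$scaled_he, c(1, 0.75, 0), tolerance = 1e-9)
  # monotone response: scaled He strictly decreases in H
  hs <- scale_cell(seq(0.34, 0.36, by = 0.005), b[rep(1, 5), ])$scaled_he
  expect_true(all(diff(hs) < 0))
})

test_that("out-of-bounds H errors; marginal excursions clip; degenerate absent", {
  b <- theoretical_h_bounds(3, 0.4)
  expect_error(scale_cell(0.40, b), class = "hescale_data_error")
  near <- scale_cell(0.36 + 1e-10, b)
  expect_equal(near$h_scaled, 1)
  bd <- theoretical_h_bounds(2, 0.6)
  sd_ <- scale_cell(0.52, bd)
  expect_true(is.na(sd_$h_scaled) && is.na(sd_$scaled_he))
  expect_true(sd_$degenerate)
})

test_that("bounds hold over a sampled (K, M) grid with enumeration attainment", {
  # small in-suite sweep; the full K in 2..8 x 0.01-grid sweep runs in the
  # acceptance tests
  for (K in c(3L, 5L)) {
    for (m in seq(ceiling(100 / K), 99, by = 7)) {
      b <- theoretical_h_bounds(K, m / 100)
      e <- enumerate_h_given_m(K, m, lo = b$h_min, hi = b$h_max)
      if (e[["n"]] == 0) next
      expect_equal(unname(e[["n_violations"]]), 0)
      expect_lt(e[["h_min"]] - b$h_min, 0.03)
      expect_lt(b$h_max - e[["h_max"]], 0.03)
    }
  }
})

test_that("per-population averaging excludes degenerate cells by default", {
  f <- tibble::tibble(
    population_id = "p1",
    locus = c("A", "A", "A", "B", "B", "B", "C", "C"),
    allele = c(1, 2, 3, 1, 2, 3, 1, 2),
    frequency = c(0.4, 0.3, 0.3, 0.4, 0.4, 0.2, 0.6, 0.4)
  )
  m <- freq_meta(f)
  res <- suppressWarnings(scaled_he(m, k_mode = "cell"))
  cells <- res$cells[order(res$cells$locus), ]
  # locus A: H = 0.34 -> scaled He 1; locus B: H = 0.36 -> 0; locus C: K=2
  expect_equal(cells$scaled_he[1:2], c(1, 0), tolerance = 1e-9)
  expect_true(cells$degenerate[3])
  expect_equal(res$populations$mean_scaled_he, 0.5, tolerance = 1e-9)
  expect_equal(res$populations$n_loci_used, 2L)
  expect_equal(res$populations$n_loci_degenerate, 1L)

  mid <- suppressWarnings(scaled_he(m, degenerate_policy = "midpoint",
                                    k_mode = "cell"))
  expect_equal(mid$populations$n_loci_used, 3L)
  expect_equal(mid$populations$mean_scaled_he, mean(c(1, 0, 0.5)),
               tolerance = 1e-9)
})

test_that("all-degenerate populations yield NA means with a warning", {
  f <- tibble::tibble(
    population_id = "p1", locus = c("A", "A"),
    allele = c(1, 2), frequency = c(0.7, 0.3)
  )
  expect_warning(res <- scaled_he(freq_meta(f)), "degenerate")
  expect_true(is.na(res$populations$mean_scaled_he))
  expect_equal(res$populations$n_loci_degenerate, 1L)
})

test_that("study-wide K widens bounds relative to per-cell K", {
  # population p2 observes only 2 of the locus's 3 study-wide alleles
  f <- tibble::tibble(
    population_id = c("p1", "p1", "p1", "p2", "p2"),
    locus = "A",
    allele = c(1, 2, 3, 1, 2),
    frequency = c(0.4, 0.3, 0.3, 0.6, 0.4)
  )
  m <- freq_meta(f)
  cell_mode <- suppressWarnings(scaled_he(m, k_mode = "cell"))
  study_mode <- scaled_he(m, k_mode = "study")
  p2_cell <- cell_mode$cells[cell_mode$cells$population_id == "p2", ]
  p2_study <- study_mode$cells[study_mode$cells$population_id == "p2", ]
  expect_true(p2_cell$degenerate)     # K = 2 per cell
  expect_false(p2_study$degenerate)   # K = 3 study-wide
  expect_equal(p2_study$h_min, (3 * 0.36 - 1.2 + 1) / 2)
})
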