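test_that("stack generation is deterministic and validates its spec", {
  spec <- landscape_spec(20, 20, 10, c("a", "b"), c(0, 50), seed = 7)
  s1 <- generate_predictor_stack(spec)
  s2 <- generate_predictor_stack(spec)
  expect_identical(s1$layers, s2$layers)
  expect_true(all(vapply(s1$layers, function(m) all(is.finite(m)), logical(1))))
  expect_error(landscape_spec(1, 2, 10, "a", 0, seed = 1), "4 cells")
  expect_error(landscape_spec(10, 10, 10, c("a", "a"), 0, seed = 1), "unique")
  expect_error(landscape_spec(10, 10, -1, "a", 0, seed = 1), "positive")
})

test_that("autocorrelation length controls lag-1 Moran's I", {
  # white noise: Moran's I near 0 (Monte-Carlo error at 40x40 is small)
  m0 <- make_stack(40, "a", autocorr = 0, seed = 3)$layers$a
  expect_lt(abs(oracle_moran_i(m0)), 0.06)
  # smoothing induces strong positive autocorrelation
  m1 <- make_stack(40, "a", autocorr = 30, seed = 3)$layers$a
  expect_gt(oracle_moran_i(m1), 0.5)
  # larger length => strictly larger mean I over 20 replicate seeds
  mean_i <- function(len) mean(vapply(1:20, function(s)
    oracle_moran_i(make_stack(25, "a", autocorr = len, seed = s)$layers$a),
    numeric(1)))
  expect_lt(mean_i(0), mean_i(20))
  expect_lt(mean_i(20), mean_i(50))
})

test_that("true_suitability matches the logistic formula", {
  st <- make_stack(10, c("x", "y"), seed = 2)
  flat <- true_suitability(st, true_niche(0, c(x = 0, y = 0)))
  expect_equal(as.vector(flat), rep(0.5, 100))
  # large intercept drives suitability monotonically towards 1
  s_lo <- true_suitability(st, true_niche(5, c(x = 1)))
  s_hi <- true_suitability(st, true_niche(20, c(x = 1)))
  expect_true(all(s_hi > s_lo))
  expect_true(all(s_hi > 0.999))
  # hand-evaluated 3x3 case with linear + quadratic terms
  a <- matrix(c(-1, 0, 1, 2, -2, 0.5, 1.5, -0.5, 0), 3, 3)
  b <- matrix(seq(-0.8, 0.8, length.out = 9), 3, 3)
  st3 <- raw_stack(a = a, b = b)
  niche <- true_niche(0.3, c(a = 1.2, b = -0.7), c(a = -0.4))
  want <- plogis(0.3 + 1.2 * a - 0.7 * b - 0.4 * a^2)
  expect_equal(unclass(true_suitability(st3, niche)), want,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(true_suitability(st3, true_niche(0, c(zz = 1))), "unknown")
})

test_that("occurrence sampling follows the suitability x bias law", {
  st <- make_stack(10, "a", seed = 5)
  uni <- grid_map(matrix(1, 10, 10), st)
  occ <- sample_occurrences(uni, uni, 5000, seed = 9, dirty_fraction = 0)
  expect_equal(nrow(occ), 5000)
  counts <- table(factor(locate_cells(st, occ$lon, occ$lat)$row, levels = 1:10),
                  factor(locate_cells(st, occ$lon, occ$lat)$col, levels = 1:10))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
  # zero suitability over half the grid -> zero records there
  half <- uni; half[, 1:5] <- 0
  occ2 <- sample_occurrences(half, uni, 500, seed = 9, dirty_fraction = 0)
  expect_true(all(locate_cells(st, occ2$lon, occ2$lat)$col > 5))
  # exact count contract and determinism
  occ3a <- sample_occurrences(uni, uni, 100, seed = 4)
  occ3b <- sample_occurrences(uni, uni, 100, seed = 4)
  expect_equal(nrow(occ3a), 100)
  expect_identical(occ3a, occ3b)
  expect_error(sample_occurrences(grid_map(matrix(0, 10, 10), st), uni, 5,
                                  seed = 1), "zero")
})

test_that("empirical cell frequencies converge to normalised suitability x bias", {
  st <- make_stack(6, "a", seed = 11)
  suit <- grid_map(matrix(runif(36), 6, 6), st)
  bias <- grid_map(matrix(runif(36), 6, 6), st)
  occ <- sample_occurrences(suit, bias, 10000, seed = 2, dirty_fraction = 0)
  loc <- locate_cells(st, occ$lon, occ$lat)
  counts <- as.vector(table(factor((loc$col - 1) * 6 + loc$row, levels = 1:36)))
  p <- as.vector(suit * bias); p <- p / sum(p)
  expect_gt(suppressWarnings(chisq.test(counts, p = p))$p.value, 0.01)
})

test_that("dirty records exercise every cleaning rule", {
  st <- make_stack(30, "a", autocorr = 50, seed = 13)
  uni <- grid_map(matrix(1, 30, 30), st)
  occ <- sample_occurrences(uni, uni, 300, seed = 21, dirty_fraction = 0.2)
  expect_gt(sum(occ$coord_uncertainty_m > 5000, na.rm = TRUE), 0)
  expect_gt(sum(is.na(occ$year)), 0)
  expect_gt(sum(occ$year < 1970, na.rm = TRUE), 0)
  expect_gt(sum(occ$is_fossil), 0)
  expect_gt(sum(occ$is_absence_record), 0)
})

test_that("analogue sightings track the bias surface only", {
  st <- make_stack(10, "a", seed = 5)
  uni <- grid_map(matrix(1, 10, 10), st)
  a1 <- generate_analogue_sightings(uni, 5000, seed = 3)
  loc <- locate_cells(st, a1$lon, a1$lat)
  counts <- table(factor((loc$col - 1) * 10 + loc$row, levels = 1:100))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
  # concentrated bias puts every point into that cell
  onecell <- matrix(0, 10, 10); onecell[4, 7] <- 1
  a2 <- generate_analogue_sightings(grid_map(onecell, st), 50, seed = 3)
  loc2 <- locate_cells(st, a2$lon, a2$lat)
  expect_true(all(loc2$row == 4 & loc2$col == 7))
  expect_identical(a2, generate_analogue_sightings(grid_map(onecell, st), 50,
                                                   seed = 3))
})

test_that("shift_climate applies factor * x + delta per layer", {
  st <- make_stack(8, c("p", "q"), seed = 6)
  expect_identical(shift_climate(st, scenario_shift())$layers, st$layers)
  sh <- shift_climate(st, scenario_shift(additive_delta = c(p = 2)))
  expect_equal(mean(sh$layers$p), mean(st$layers$p) + 2, tolerance = 1e-12)
  expect_identical(sh$layers$q, st$layers$q)
  # hand-written 2x2 arithmetic check
  m <- matrix(c(0, 1, -2, 3), 2, 2)
  st2 <- raw_stack(z = m)
  out <- shift_climate(st2, scenario_shift(additive_delta = c(z = -1),
                                           multiplicative_factor = c(z = 2)))
  expect_equal(out$layers$z, 2 * m - 1, tolerance = 1e-14)
  expect_error(shift_climate(st2, scenario_shift(additive_delta = c(nope = 1))),
               "unknown")
})
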