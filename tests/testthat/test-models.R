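test_that("bioclim_score implements the percentile envelope", {
  ref <- matrix(1:10, ncol = 1)
  expect_equal(bioclim_score(ref, 0.5), 0)       # below envelope minimum
  expect_equal(bioclim_score(ref, 11), 0)        # above envelope maximum
  expect_equal(bioclim_score(ref, 5), 1)         # p = 0.5 at the median
  expect_equal(bioclim_score(ref, 2), 0.4)       # p = 0.2 -> 2 * 0.2
  # multi-variable: overall score is the minimum over variables
  ref2 <- cbind(1:10, 1:10)
  expect_equal(bioclim_score(ref2, c(5, 2)), 0.4)
  expect_error(bioclim_score(ref[1:4, , drop = FALSE], 5), "at least 5")
  # vectorised predictor agrees with the scalar definition
  newX <- matrix(seq(0, 11, 0.5), ncol = 1)
  got <- rangecast:::bioclim_predict_matrix(ref, newX)
  want <- vapply(newX[, 1], function(x) bioclim_score(ref, x), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("fit_all produces the full roster x repeats grid, reproducibly", {
  tb <- random_table(120, 3, seed = 1)
  mods <- fit_all(tb, roster = c("glm", "cta"), n_repeats = 2, seed = 5)
  expect_length(mods, 4)
  expect_equal(vapply(mods, function(m) m$algorithm, character(1)),
               c("glm", "cta", "glm", "cta"))
  # (seed, repeat) fully determines splits and scores
  mods2 <- fit_all(tb, roster = c("glm", "cta"), n_repeats = 2, seed = 5)
  expect_identical(lapply(mods, function(m) m$calib_idx),
                   lapply(mods2, function(m) m$calib_idx))
  expect_identical(lapply(mods, function(m) m$scores),
                   lapply(mods2, function(m) m$scores))
  # calibration and holdout are disjoint and sized by calib_fraction
  expect_length(intersect(mods[[1]]$calib_idx, mods[[1]]$holdout_idx), 0)
  expect_equal(length(mods[[1]]$calib_idx), 84)
  # learner failure is recorded, not fatal
  register_algorithm("boom",
    fit = function(data, seed) stop("deliberate"),
    predict = function(state, newdata) rep(0.5, nrow(newdata)))
  mods3 <- fit_all(tb, roster = c("glm", "boom"), n_repeats = 1, seed = 5)
  expect_null(mods3[[2]]$scores)
  expect_match(mods3[[2]]$error, "deliberate")
})

test_that("every default learner emits suitabilities in [0, 1]", {
  st <- make_stack(40, c("bio13", "bio15"), autocorr = 60, seed = 21)
  suit <- true_suitability(st, true_niche(-1, c(bio13 = 3, bio15 = -2)))
  uni <- grid_map(matrix(1, 40, 40), st)
  pres <- sample_occurrences(suit, uni, 120, seed = 3, dirty_fraction = 0)
  k <- fit_env_kernel(pres, st, seed = 1)
  pa <- sample_pseudoabsences(k, uni, st, pres, 10, seed = 4)
  tb <- scale_centre(sample_table(st, pres, pa))$table
  mods <- suppressWarnings(fit_all(tb, n_repeats = 1, seed = 9))
  expect_length(mods, 9)
  newd <- tb[setdiff(names(tb), "label")]
  for (m in mods) {
    expect_null(m$error, info = m$algorithm)
    p <- predict_suitability(m, newd)
    expect_true(all(p >= 0 & p <= 1), info = m$algorithm)
  }
})

test_that("a strongly separable synthetic table yields median holdout TSS >= 0.7", {
  # the generator's default study conditions, at reduced extent
  sc <- synthetic_config(n_rows = 120, n_cols = 120, n_presences = 350,
                         n_analogues = 1200)
  st <- generate_predictor_stack(landscape_spec(
    sc$n_rows, sc$n_cols, sc$cell_size_km, sc$layer_names,
    sc$autocorr_length_km, seed = 31))
  suit <- true_suitability(st, sc$niche)
  bias <- generate_bias_surface(st, sc$bias_autocorr_km, sc$bias_strength,
                                seed = 32)
  pres <- thin(clean(sample_occurrences(suit, bias, sc$n_presences,
                                        seed = 33))$occ, 30, seed = 34)
  k <- fit_env_kernel(pres, st, seed = 35)
  bs <- build_bias_surface(generate_analogue_sightings(bias, sc$n_analogues,
                                                       seed = 36), st, 30)
  pa <- sample_pseudoabsences(k, bs, st, pres, 30, seed = 37)
  tb <- scale_centre(sample_table(st, pres, pa))$table
  mods <- suppressWarnings(fit_all(tb, n_repeats = 2, seed = 38))
  tss <- vapply(mods, function(m) m$scores$TSS, numeric(1))
  expect_gte(median(tss), 0.7)
})

test_that("permutation importance reflects what a model actually uses", {
  tb <- random_table(400, 3, seed = 7)
  # a learner that uses only v1 (logistic in the standardized column)
  register_algorithm("only_v1",
    fit = function(data, seed) list(),
    predict = function(state, newdata) plogis(newdata$v1))
  m <- fit_all(tb, roster = "only_v1", n_repeats = 1, seed = 2)[[1]]
  imp <- permutation_importance(m, tb, n_shuffles = 5, seed = 3)
  expect_equal(unname(imp[c("v2", "v3")]), c(0, 0))   # untouched variables
  expect_gt(imp[["v1"]], 0.8)                          # ~ 1 - cor(p, perm(p))
  # constant-output model: all importances 0, flagged degenerate
  register_algorithm("const0.4",
    fit = function(data, seed) list(),
    predict = function(state, newdata) rep(0.4, nrow(newdata)))
  mc <- fit_all(tb, roster = "const0.4", n_repeats = 1, seed = 2)[[1]]
  impc <- permutation_importance(mc, tb, seed = 3)
  expect_true(all(impc == 0))
  expect_true(isTRUE(attr(impc, "degenerate")))
})
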