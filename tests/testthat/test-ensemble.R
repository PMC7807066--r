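test_that("gates keep exactly the models passing all three thresholds", {
  m_lo_tss <- fake_model(tss = 0.69, auc_ = 0.95, kappa = 0.8, value = 0.3)
  m_ok <- fake_model(tss = 0.75, auc_ = 0.92, kappa = 0.71, value = 0.5)
  m_lo_auc <- fake_model(tss = 0.8, auc_ = 0.89, kappa = 0.8, value = 0.6)
  sel <- select_members(list(m_lo_tss, m_ok, m_lo_auc))
  expect_equal(sel$report$pass, c(FALSE, TRUE, FALSE))
  expect_match(sel$report$reason[1], "TSS")
  expect_match(sel$report$reason[3], "AUC")
  expect_length(sel$members, 1)
  # boundary values are inclusive
  m_edge <- fake_model(tss = 0.7, auc_ = 0.9, kappa = 0.7, value = 0.4)
  expect_true(select_members(list(m_edge))$report$pass)
  # all models failing leaves an empty set; ensembling it is fatal
  sel2 <- select_members(list(m_lo_tss))
  expect_length(sel2$members, 0)
  expect_error(ensemble_model(sel2$members), "empty ensemble")
  # raising any gate never adds members
  pool <- list(m_lo_tss, m_ok, m_lo_auc, m_edge)
  base_pass <- select_members(pool)$report$pass
  for (g in list(c(0.75, 0.9, 0.7), c(0.7, 0.95, 0.7), c(0.7, 0.9, 0.75)))
    expect_true(all(select_members(pool, g[1], g[2], g[3])$report$pass <= base_pass))
})

test_that("ensemble weighting is TSS-proportional and bounded by members", {
  st <- make_stack(6, c("v1", "v2"), seed = 3)
  newd <- as.data.frame(stack_values(st))
  m1 <- fake_model(tss = 0.9, value = 0.6, id = "c6")
  m2 <- fake_model(tss = 0.45, value = 0.3, id = "c3")
  # single member: ensemble == member
  e1 <- ensemble_model(list(m1))
  expect_equal(e1$weights, 1)
  expect_equal(ensemble_predict_table(e1, newd), rep(0.6, 36))
  # equal TSS: arithmetic mean
  m3 <- fake_model(tss = 0.9, value = 0.2, id = "c2")
  e2 <- ensemble_model(list(m1, m3))
  expect_equal(ensemble_predict_table(e2, newd), rep(0.4, 36))
  # hand-computed weighted average: 0.9/1.35*0.6 + 0.45/1.35*0.3 = 0.5
  e3 <- ensemble_model(list(m1, m2))
  expect_equal(sum(e3$weights), 1, tolerance = 1e-12)
  expect_equal(ensemble_predict_table(e3, newd), rep(0.5, 36),
               tolerance = 1e-12)
  # weights sum to 1 and predictions stay inside the member envelope
  withr::with_seed(4, {
    ms <- lapply(runif(5, 0.3, 0.95), function(t)
      fake_model(tss = t, value = runif(1), id = paste0("r", round(t, 5))))
  })
  e4 <- ensemble_model(ms)
  expect_equal(sum(e4$weights), 1, tolerance = 1e-12)
  pred <- ensemble_predict_table(e4, newd)
  vals <- vapply(ms, function(m) m$state$value, numeric(1))
  expect_true(all(pred >= min(vals) - 1e-12 & pred <= max(vals) + 1e-12))
})

test_that("projection standardises scenario stacks with fitting-era parameters", {
  # fit a GLM on standardized values, then project onto the raw stack
  st <- make_stack(20, c("v1", "v2"), autocorr = 40, seed = 8)
  tb_raw <- as.data.frame(stack_values(st))
  withr::with_seed(1,
    tb_raw$label <- rbinom(nrow(tb_raw), 1, plogis(2 * tb_raw$v1)))
  std <- scale_centre(tb_raw)
  mods <- fit_all(std$table, roster = "glm", n_repeats = 1, seed = 2)
  ens <- ensemble_model(mods, std$params)
  map <- ensemble_predict(ens, st)
  # cell-wise equality with a direct standardized-table prediction
  want <- predict_suitability(mods[[1]],
                              apply_standardization(tb_raw, std$params))
  expect_equal(as.vector(map), want, tolerance = 1e-12)
  expect_error(ensemble_predict(ens, make_stack(5, "zz", seed = 1)), "missing")
})

test_that("uncertainty map is the member coefficient of variation", {
  st <- make_stack(5, c("v1", "v2"), seed = 2)
  m1 <- fake_model(tss = 0.8, value = 0.2, id = "u2")
  m2 <- fake_model(tss = 0.8, value = 0.6, id = "u6")
  expect_error(uncertainty_map(ensemble_model(list(m1)), st), "2 members")
  cv <- uncertainty_map(ensemble_model(list(m1, m2)), st)
  expect_equal(as.vector(cv), rep(sd(c(0.2, 0.6)) / 0.4, 25), tolerance = 1e-12)
  # identical members: CV 0; CV is scale-invariant
  cv0 <- uncertainty_map(ensemble_model(list(m1, fake_model(0.8, value = 0.2,
                                                            id = "u2b"))), st)
  expect_true(all(cv0 == 0))
  m1h <- fake_model(tss = 0.8, value = 0.1, id = "h1")
  m2h <- fake_model(tss = 0.8, value = 0.3, id = "h3")
  cvh <- uncertainty_map(ensemble_model(list(m1h, m2h)), st)
  expect_equal(as.vector(cvh), as.vector(cv), tolerance = 1e-12)
})

test_that("binarization and range change follow the cell-count definitions", {
  st <- make_stack(5, "a", seed = 1)
  m <- grid_map(seq(0, 1, length.out = 25), st)
  expect_true(all(binarize(m, 0)$presence))
  expect_false(any(binarize(m, 1.0000)$presence[m < 1]))
  hand <- grid_map(matrix(c(0.2, 0.5, 0.9, 0.4, 0.5, 0.1, 0.8, 0.3, 0.6), 3, 3),
                   raw_stack(a = matrix(0, 3, 3)))
  expect_equal(binarize(hand, 0.5)$presence,
               matrix(c(F, T, T, F, T, F, T, F, T), 3, 3))
  expect_error(binarize(m, 1.5), "threshold")

  mk <- function(n_pres, overlap_with = NULL, total = 400) {
    v <- rep(FALSE, total)
    if (is.null(overlap_with)) v[seq_len(n_pres)] <- TRUE
    else v[overlap_with] <- TRUE
    structure(list(presence = matrix(v, 20, 20), threshold = 0.5,
                   label = "x", cell_size_km = 10),
              class = "binary_range_map")
  }
  cur <- mk(100)
  same <- range_change(cur, cur)
  expect_equal(same$pct_change_unlimited, 0)
  expect_equal(same$pct_change_no_dispersal, 0)
  # current 100, other 180 with overlap 90: +80% / -10%
  oth <- mk(NA, overlap_with = c(1:90, 101:190))
  rc <- range_change(cur, oth)
  expect_equal(rc$cells_current, 100)
  expect_equal(rc$cells_other, 180)
  expect_equal(rc$cells_overlap, 90)
  expect_equal(rc$pct_change_unlimited, 80)
  expect_equal(rc$pct_change_no_dispersal, -10)
  expect_equal(sum(rc$gain_loss_map == "gain"), 90)
  expect_equal(sum(rc$gain_loss_map == "loss"), 10)
  expect_equal(sum(rc$gain_loss_map == "stable"), 90)
  # disjoint range: no-dispersal change is -100%
  dis <- mk(NA, overlap_with = 201:300)
  expect_equal(range_change(cur, dis)$pct_change_no_dispersal, -100)
  expect_error(range_change(mk(0), cur), "empty")
  # invariant: no-dispersal change never exceeds unlimited change
  for (s in 1:10) {
    withr::with_seed(s, {
      a <- mk(NA, overlap_with = sample(400, 150))
      b <- mk(NA, overlap_with = sample(400, sample(50:350, 1)))
    })
    r <- range_change(a, b)
    expect_lte(r$pct_change_no_dispersal, r$pct_change_unlimited)
    expect_lte(r$cells_overlap, min(r$cells_current, r$cells_other))
  }
})
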