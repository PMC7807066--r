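test_that("confusion counts follow the >=-threshold convention", {
  s <- c(0.1, 0.4, 0.6, 0.9); l <- c(0, 0, 1, 1)
  all_pres <- confusion(s, l, 0)
  expect_equal(all_pres$FN + all_pres$TN, 0)
  none <- confusion(s, l, 0.95)
  expect_equal(none$TP + none$FP, 0)
  # 10-point hand-counted instance (score == threshold counts as presence)
  s10 <- c(0.05, 0.2, 0.5, 0.5, 0.55, 0.6, 0.7, 0.8, 0.9, 0.95)
  l10 <- c(0, 0, 0, 1, 0, 1, 0, 1, 1, 1)
  cc <- confusion(s10, l10, 0.5)
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = 5, FP = 3, TN = 2, FN = 0))
  expect_error(confusion(s10, l10[-1], 0.5), "mismatch")
})

test_that("TSS and Kappa agree with first-principles formulas", {
  perfect <- tss_kappa(confusion(c(0.1, 0.9), c(0, 1), 0.5))
  expect_equal(perfect[c("sensitivity", "specificity", "TSS", "Kappa")],
               list(sensitivity = 1, specificity = 1, TSS = 1, Kappa = 1))
  all_pres <- tss_kappa(confusion(c(0.6, 0.7), c(0, 1), 0))
  expect_equal(all_pres$TSS, 0)
  expect_equal(all_pres$sensitivity, 1)
  expect_equal(all_pres$specificity, 0)
  # TP=45 FN=5 TN=40 FP=10: p_o = 0.85, p_e = 0.5
  m <- tss_kappa(structure(list(TP = 45, FP = 10, TN = 40, FN = 5),
                           class = "confusion_counts"))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$TSS, 0.7, tolerance = 1e-14)
  expect_equal(m$Kappa, 0.7, tolerance = 1e-14)
  # random tables against the oracle
  for (s in 1:20) {
    cc <- withr::with_seed(s, as.list(setNames(sample(1:30, 4, TRUE),
                                               c("TP", "FP", "TN", "FN"))))
    got <- tss_kappa(structure(cc, class = "confusion_counts"))
    want <- oracle_metrics(cc$TP, cc$FP, cc$TN, cc$FN)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("TSS is prevalence-invariant under presence duplication", {
  s <- c(0.2, 0.3, 0.55, 0.6, 0.8, 0.9); l <- c(0, 0, 1, 0, 1, 1)
  t1 <- tss_kappa(confusion(s, l, 0.5))$TSS
  s2 <- c(s, s[l == 1]); l2 <- c(l, l[l == 1])
  expect_equal(tss_kappa(confusion(s2, l2, 0.5))$TSS, t1, tolerance = 1e-14)
})

test_that("AUC equals the pair-counting estimate, ties at one half", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.8, 0.9, 0.1, 0.2), c(0, 0, 1, 1)), 0)
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 3 / 4)
  for (s in 1:10) {
    withr::with_seed(s, {
      sc <- sample(seq(0, 1, 0.1), 40, replace = TRUE)  # many ties
      lb <- rbinom(40, 1, 0.5)
    })
    if (length(unique(lb)) < 2) next
    expect_equal(auc(sc, lb), oracle_auc(sc, lb), tolerance = 1e-12)
  }
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("max-TSS threshold matches the exhaustive sweep with smallest-tie rule", {
  # perfectly separated: the smallest optimal candidate is the lowest
  # presence score
  s <- c(0.1, 0.2, 0.7, 0.9); l <- c(0, 0, 1, 1)
  got <- max_tss_threshold(s, l)
  expect_equal(got$threshold, 0.7)
  expect_equal(got$TSS, 1)
  # hand-written 8-point instance vs exhaustive oracle
  s8 <- c(0.15, 0.3, 0.35, 0.5, 0.55, 0.62, 0.8, 0.85)
  l8 <- c(0, 0, 1, 0, 1, 1, 0, 1)
  expect_equal(max_tss_threshold(s8, l8), oracle_max_tss(s8, l8))
  # candidate-set invariance: duplicating every point (so each score value
  # appears twice) leaves the returned threshold unchanged
  expect_equal(max_tss_threshold(c(s8, s8), c(l8, l8)),
               max_tss_threshold(s8, l8))
  # random instances up to n = 200
  for (s in 1:10) {
    withr::with_seed(s, {
      sc <- round(runif(200), 2)
      lb <- rbinom(200, 1, plogis(3 * (sc - 0.5)))
    })
    if (length(unique(lb)) < 2) next
    expect_equal(max_tss_threshold(sc, lb), oracle_max_tss(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("Boyce index is +1/-1 for monotone P/E and ~0 for random placement", {
  # calibrated predictions: presences pile up at high suitability
  withr::with_seed(1, {
    bg <- runif(5000)
    pres <- bg[rbinom(5000, 1, bg) == 1]
  })
  expect_gt(boyce(bg, pres), 0.9)
  # anti-calibrated
  withr::with_seed(2, {
    pres_bad <- bg[rbinom(5000, 1, 1 - bg) == 1]
  })
  expect_lt(boyce(bg, pres_bad), -0.9)
  # presences drawn uniformly from the background (n = 5000): index ~ 0.
  # With ~10 effectively independent windows (width = range/10) the null
  # sd of a Spearman coefficient is ~1/3, so individual draws scatter
  # widely; the 20-seed mean must sit near zero and no systematic sign
  # may appear.
  idx <- vapply(1:20, function(s) {
    p <- withr::with_seed(s, sample(bg, 5000, replace = TRUE))
    boyce(bg, p)
  }, numeric(1))
  expect_lt(abs(mean(idx)), 0.2)
  expect_lt(median(abs(idx)), 0.35)
  expect_error(boyce(rep(0.5, 10), rep(0.5, 4)), "degenerate")
})

test_that("evaluate_scores ties the metrics together at the max-TSS threshold", {
  withr::with_seed(3, {
    sc <- runif(100)
    lb <- rbinom(100, 1, plogis(4 * (sc - 0.5)))
  })
  ev <- evaluate_scores(sc, lb)
  expect_equal(ev$TSS, ev$sensitivity + ev$specificity - 1, tolerance = 1e-12)
  expect_equal(ev$threshold, oracle_max_tss(sc, lb)$threshold)
  expect_equal(ev$AUC, oracle_auc(sc, lb), tolerance = 1e-12)
})
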