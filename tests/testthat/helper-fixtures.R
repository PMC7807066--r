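# Small in-code fixtures shared across test files.

make_stack <- function(n = 30, layers = c("bio13", "bio15"), autocorr = 0,
                       cell = 10, seed = 1) {
  generate_predictor_stack(
    landscape_spec(n, n, cell, layers, autocorr, seed = seed))
}

# A hand-buildable stack from explicit matrices.
raw_stack <- function(..., cell = 1) {
  predictor_stack(list(...), cell_size_km = cell)
}

# Random planar occurrence set on [0, extent]^2.
random_occurrences <- function(n, extent = 500, seed = 1) {
  withr::with_seed(seed, occurrence_set(
    lon = runif(n, 0, extent), lat = runif(n, 0, extent),
    year = sample(1980:2020, n, replace = TRUE),
    coord_uncertainty_m = runif(n, 0, 4000), source = "fixture"))
}

# Random sample table with p predictors and a weakly informative label.
random_table <- function(n = 60, p = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(rnorm(n * p), n))
    names(X) <- paste0("v", seq_len(p))
    X$label <- rbinom(n, 1, plogis(X$v1))
    X
  })
}

# A fake scored model for gate/ensemble tests: predicts a fixed constant.
fake_model <- function(tss, auc_ = 0.95, kappa = tss, value = 0.5,
                       id = paste0("const", signif(value, 3))) {
  register_algorithm(id,
    fit = function(data, seed) list(value = value),
    predict = function(state, newdata) rep(state$value, nrow(newdata)))
  m <- list(algorithm = id, run = 1L, state = list(value = value),
            calib_idx = 1:2, holdout_idx = 3:4, seed = 1L,
            scores = structure(list(AUC = auc_, threshold = 0.5,
                                    sensitivity = NA, specificity = NA,
                                    TSS = tss, Kappa = kappa),
                               class = "evaluation_scores"),
            error = NULL)
  class(m) <- "fitted_model"
  m
}
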