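## Algorithm registry -------------------------------------------------------
## Every learner is registered under a short id with a `fit(data, seed)` and
## a `predict(state, newdata)` function. All learners consume a data frame
## with a binary `label` column plus (standardised) predictor columns, and
## emit suitabilities in [0, 1].

.algo_registry <- new.env(parent = emptyenv())

#' Register a suitability learner
#'
#' @param id short algorithm id.
#' @param fit function `(data, seed) -> state`; `data` has a 0/1 `label`
#'   column, remaining columns are predictors.
#' @param predict function `(state, newdata) -> suitability in [0, 1]`.
#' @export
register_algorithm <- function(id, fit, predict) {
  assign(id, list(fit = fit, predict = predict), envir = .algo_registry)
  invisible(id)
}

#' List registered algorithm ids
#' @return character vector.
#' @export
registered_algorithms <- function() sort(ls(.algo_registry))

get_algorithm <- function(id) {
  if (!exists(id, envir = .algo_registry, inherits = FALSE))
    stop("algorithm '", id, "' is not registered")
  get(id, envir = .algo_registry, inherits = FALSE)
}

#' Default nine-algorithm roster
#'
#' Climate envelope (`bioclim`), logistic GLM with quadratic terms (`glm`),
#' smooth additive logistic model (`gam`), classification tree (`cta`),
#' random forest (`rf`), gradient-boosted trees (`gbm`), single-hidden-layer
#' neural net (`ann`), linear discriminant analysis (`fda` slot), and
#' adaptive regression splines (`mars`). A tenth slot is open to any
#' user-registered learner via [register_algorithm()].
#'
#' @return character vector of 9 algorithm ids.
#' @export
default_roster <- function() {
  c("bioclim", "glm", "gam", "cta", "rf", "gbm", "ann", "fda", "mars")
}

split_xy <- function(data) {
  vars <- setdiff(names(data), c("label", "weight"))
  list(X = as.matrix(data[vars]), y = data$label, vars = vars)
}

clamp01 <- function(p) pmin(1, pmax(0, as.numeric(p)))

## ---- BIOCLIM climate envelope (in-house) ---------------------------------

#' BIOCLIM climate-envelope score
#'
#' Classic percentile envelope: per variable, `p` is the empirical fraction
#' of presence values at or below `x`; the per-variable score is
#' `2 * min(p, 1 - p)` (0 outside the presence min-max) and the overall
#' score is the minimum over variables, so a site scores 1 only at the
#' per-variable medians of the presence envelope.
#'
#' @param presence_env matrix of presence-row predictor values (>= 5 rows).
#' @param x predictor vector (same column order).
#' @return suitability in `[0, 1]`.
#' @export
bioclim_score <- function(presence_env, x) {
  presence_env <- as.matrix(presence_env)
  if (nrow(presence_env) < 5) stop("need at least 5 presence rows")
  s <- vapply(seq_len(ncol(presence_env)), function(j) {
    ref <- presence_env[, j]
    if (x[j] < min(ref) || x[j] > max(ref)) return(0)
    p <- mean(ref <= x[j])
    2 * min(p, 1 - p)
  }, numeric(1))
  min(s)
}

bioclim_predict_matrix <- function(ref, newX) {
  score <- matrix(0, nrow(newX), ncol(newX))
  for (j in seq_len(ncol(ref))) {
    r <- sort(ref[, j])
    n <- length(r)
    p <- findInterval(newX[, j], r) / n   # fraction of ref <= x
    sj <- 2 * pmin(p, 1 - p)
    sj[newX[, j] < r[1] | newX[, j] > r[n]] <- 0
    score[, j] <- sj
  }
  apply(score, 1L, min)
}

## ---- in-house adaptive regression splines --------------------------------
## Forward selection of reflected hinge pairs max(0, x - t) / max(0, t - x)
## by least-squares screening, then a binomial GLM on the selected basis.

mars_build_basis <- function(X, terms) {
  B <- matrix(1, nrow(X), 1)
  for (tm in terms) {
    h <- X[, tm$var] - tm$knot
    B <- cbind(B, if (tm$dir > 0) pmax(0, h) else pmax(0, -h))
  }
  B
}

mars_fit <- function(data, seed, max_pairs = 8, knot_probs = seq(0.1, 0.9, 0.1)) {
  xy <- split_xy(data)
  X <- xy$X; y <- xy$y
  terms <- list()
  B <- matrix(1, nrow(X), 1)
  rss <- sum((y - mean(y))^2)
  for (step in seq_len(max_pairs)) {
    best <- NULL
    for (v in seq_len(ncol(X))) {
      for (t in unique(stats::quantile(X[, v], knot_probs, names = FALSE))) {
        h1 <- pmax(0, X[, v] - t); h2 <- pmax(0, t - X[, v])
        fit <- stats::lm.fit(cbind(B, h1, h2), y)
        r <- sum(fit$residuals^2)
        if (is.null(best) || r < best$rss) best <- list(var = v, knot = t, rss = r)
      }
    }
    if (is.null(best) || (rss - best$rss) / rss < 1e-4) break
    terms <- c(terms, list(list(var = best$var, knot = best$knot, dir = 1),
                           list(var = best$var, knot = best$knot, dir = -1)))
    B <- mars_build_basis(X, terms)
    rss <- best$rss
  }
  gfit <- suppressWarnings(stats::glm.fit(B, y, family = stats::binomial()))
  coef <- gfit$coefficients
  coef[is.na(coef)] <- 0
  list(terms = terms, coef = coef, vars = xy$vars)
}

mars_predict <- function(state, newdata) {
  X <- as.matrix(newdata[state$vars])
  B <- mars_build_basis(X, state$terms)
  clamp01(stats::plogis(drop(B %*% state$coef)))
}

## ---- default roster registrations ----------------------------------------

register_algorithm("bioclim",
  fit = function(data, seed) {
    xy <- split_xy(data)
    ref <- xy$X[xy$y == 1, , drop = FALSE]
    if (nrow(ref) < 5) stop("need at least 5 presence rows")
    list(ref = ref, vars = xy$vars)
  },
  predict = function(state, newdata)
    bioclim_predict_matrix(state$ref, as.matrix(newdata[state$vars])))

register_algorithm("glm",
  fit = function(data, seed) {
    vars <- setdiff(names(data), c("label", "weight"))
    rhs <- paste(c(vars, sprintf("I(%s^2)", vars)), collapse = " + ")
    suppressWarnings(stats::glm(stats::as.formula(paste("label ~", rhs)),
                                data = data, family = stats::binomial()))
  },
  predict = function(state, newdata)
    clamp01(suppressWarnings(stats::predict(state, newdata, type = "response"))))

register_algorithm("gam",
  fit = function(data, seed) {
    vars <- setdiff(names(data), c("label", "weight"))
    k <- max(3, min(5, floor(nrow(data) / (2 * length(vars)))))
    rhs <- paste(sprintf("s(%s, k = %d)", vars, k), collapse = " + ")
    mgcv::gam(stats::as.formula(paste("label ~", rhs)), data = data,
              family = stats::binomial())
  },
  predict = function(state, newdata)
    clamp01(stats::predict(state, newdata, type = "response")))

register_algorithm("cta",
  fit = function(data, seed) {
    vars <- setdiff(names(data), c("label", "weight"))
    d <- data[vars]; d$label <- factor(data$label, levels = c(0, 1))
    with_seed(seed, rpart::rpart(label ~ ., data = d, method = "class",
                                 control = rpart::rpart.control(cp = 0.005,
                                                                xval = 5)))
  },
  predict = function(state, newdata)
    clamp01(stats::predict(state, newdata, type = "prob")[, "1"]))

register_algorithm("rf",
  fit = function(data, seed) {
    xy <- split_xy(data)
    with_seed(seed, randomForest::randomForest(
      x = xy$X, y = factor(xy$y, levels = c(0, 1)), ntree = 300))
  },
  predict = function(state, newdata) {
    vars <- rownames(state$importance)
    clamp01(stats::predict(state, as.matrix(newdata[vars]), type = "prob")[, "1"])
  })

register_algorithm("gbm",
  fit = function(data, seed) {
    xy <- split_xy(data)
    fit <- xgboost::xgboost(
      x = xy$X, y = factor(xy$y, levels = c(0, 1)), nrounds = 150,
      max_depth = 3, learning_rate = 0.1, subsample = 0.8, nthreads = 1,
      verbosity = 0, seed = seed)
    list(booster = fit, vars = xy$vars)
  },
  predict = function(state, newdata)
    clamp01(stats::predict(state$booster, as.matrix(newdata[state$vars]),
                           type = "response")))

register_algorithm("ann",
  fit = function(data, seed) {
    xy <- split_xy(data)
    fit <- with_seed(seed, nnet::nnet(x = xy$X, y = xy$y, size = 5,
                                      decay = 5e-3, maxit = 250,
                                      entropy = TRUE, trace = FALSE))
    list(net = fit, vars = xy$vars)
  },
  predict = function(state, newdata)
    clamp01(stats::predict(state$net, as.matrix(newdata[state$vars]))))

register_algorithm("fda",
  fit = function(data, seed) {
    xy <- split_xy(data)
    list(lda = MASS::lda(xy$X, grouping = factor(xy$y, levels = c(0, 1))),
         vars = xy$vars)
  },
  predict = function(state, newdata)
    clamp01(stats::predict(state$lda,
                           as.matrix(newdata[state$vars]))$posterior[, "1"]))

register_algorithm("mars", fit = mars_fit, predict = mars_predict)

# Pure-noise learner (never in the default roster): predictions are
# label-independent uniform draws, deterministic in the fitting seed. Used
# to demonstrate that the evaluation gates reject uninformative models.
register_algorithm("noise",
  fit = function(data, seed) list(seed = seed),
  predict = function(state, newdata)
    with_seed(state$seed + nrow(newdata),
              stats::runif(nrow(newdata))))

## ---- fitting and scoring --------------------------------------------------

#' Predict suitability from a fitted model
#'
#' @param model a `fitted_model` from [fit_all()].
#' @param newdata data frame with the model's predictor columns (already on
#'   the standardised scale used at fitting).
#' @return suitability vector in `[0, 1]`.
#' @export
predict_suitability <- function(model, newdata) {
  alg <- get_algorithm(model$algorithm)
  clamp01(alg$predict(model$state, newdata))
}

#' Fit the full algorithm roster over repeated random splits
#'
#' For each of `n_repeats` independent random 70/30 splits, every roster
#' algorithm is fitted on the calibration rows and scored on its own
#' holdout with AUC, the max-TSS threshold, and TSS/Kappa/sensitivity/
#' specificity at that threshold. `(seed, repeat)` fully determines each
#' split; learner failures are recorded per model, not fatal.
#'
#' @param table standardised sample table with a 0/1 `label` column and
#'   both classes present.
#' @param roster character vector of registered algorithm ids.
#' @param n_repeats number of random splits (default 6).
#' @param calib_fraction calibration fraction in (0, 1) (default 0.7).
#' @param seed integer seed.
#' @return list of `fitted_model` objects (algorithm, run, state, split
#'   indices, holdout `scores`, or `error`).
#' @export
fit_all <- function(table, roster = default_roster(), n_repeats = 6,
                    calib_fraction = 0.7, seed = 1L) {
  if (calib_fraction <= 0 || calib_fraction >= 1)
    stop("calib_fraction must be in (0, 1)")
  if (length(unique(table$label)) < 2) stop("both classes must be present")
  n <- nrow(table)
  models <- list()
  for (r in seq_len(n_repeats)) {
    split_seed <- derive_seed(seed, paste0("split:", r))
    calib <- with_seed(split_seed, sample.int(n, round(calib_fraction * n)))
    both <- function(idx) length(unique(table$label[idx])) == 2
    if (!both(calib) || !both(setdiff(seq_len(n), calib))) {
      calib <- with_seed(split_seed + 1L, sample.int(n, round(calib_fraction * n)))
      if (!both(calib) || !both(setdiff(seq_len(n), calib)))
        stop("a class is absent from the split after resampling")
    }
    holdout <- setdiff(seq_len(n), calib)
    for (a in roster) {
      fit_seed <- derive_seed(seed, paste0("fit:", r, ":", a))
      m <- list(algorithm = a, run = r, calib_idx = calib,
                holdout_idx = holdout, seed = fit_seed,
                state = NULL, scores = NULL, error = NULL)
      res <- tryCatch({
        state <- get_algorithm(a)$fit(table[calib, , drop = FALSE], fit_seed)
        preds <- clamp01(get_algorithm(a)$predict(state, table[holdout, , drop = FALSE]))
        list(state = state,
             scores = evaluate_scores(preds, table$label[holdout]))
      }, error = function(e) e)
      if (inherits(res, "error")) m$error <- conditionMessage(res)
      else { m$state <- res$state; m$scores <- res$scores }
      class(m) <- "fitted_model"
      models[[length(models) + 1L]] <- m
    }
  }
  models
}

#' Permutation variable importance
#'
#' Each predictor column is permuted in turn and the model re-projected;
#' importance is one minus the Pearson correlation between the original and
#' permuted predictions (mean over `n_shuffles`, clipped to `[0, 1]`). A
#' model whose predictions have zero variance gets importance 0 everywhere,
#' flagged with attribute `degenerate`.
#'
#' @param model a `fitted_model`.
#' @param table sample table the model was fitted on (standardised scale).
#' @param n_shuffles permutations per variable (default 3).
#' @param seed integer seed.
#' @return named numeric vector of importances in `[0, 1]`.
#' @export
permutation_importance <- function(model, table, n_shuffles = 3, seed = 1L) {
  vars <- setdiff(names(table), c("label", "weight"))
  p0 <- predict_suitability(model, table)
  if (stats::sd(p0) == 0) {
    out <- stats::setNames(rep(0, length(vars)), vars)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  imp <- vapply(vars, function(v) {
    cors <- vapply(seq_len(n_shuffles), function(s) {
      perm <- with_seed(derive_seed(seed, paste0("perm:", v, ":", s)),
                        sample.int(nrow(table)))
      tb <- table
      tb[[v]] <- tb[[v]][perm]
      pp <- predict_suitability(model, tb)
      if (stats::sd(pp) == 0) 0 else stats::cor(p0, pp)
    }, numeric(1))
    mean(1 - cors)
  }, numeric(1))
  pmin(pmax(imp, 0), 1)
}
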