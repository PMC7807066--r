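#' Specification of a synthetic landscape
#'
#' Defines the grid and the per-layer spatial autocorrelation of a synthetic
#' environmental substrate. Layers are realised as Gaussian white noise
#' convolved with a Gaussian kernel whose standard deviation is
#' `autocorr_length_km`, then standardised to mean 0 / sd 1, giving simple
#' controllable spatial autocorrelation on a planar equal-area grid.
#'
#' @param n_rows,n_cols positive cell counts (`n_rows * n_cols >= 4`).
#' @param cell_size_km positive cell edge length.
#' @param layer_names unique, non-empty predictor names.
#' @param autocorr_length_km nonnegative correlation length, recycled per
#'   layer.
#' @param seed integer seed; regeneration with the same spec is bit-identical.
#' @return object of class `landscape_spec`.
#' @export
landscape_spec <- function(n_rows, n_cols, cell_size_km, layer_names,
                           autocorr_length_km, seed) {
  if (n_rows < 1 || n_cols < 1 || n_rows * n_cols < 4)
    stop("grid must have at least 4 cells")
  if (cell_size_km <= 0) stop("cell_size_km must be positive")
  if (length(layer_names) == 0 || anyDuplicated(layer_names))
    stop("layer_names must be non-empty and unique")
  if (any(autocorr_length_km < 0)) stop("autocorr_length_km must be >= 0")
  autocorr <- rep_len(as.numeric(autocorr_length_km), length(layer_names))
  names(autocorr) <- layer_names
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size_km = as.numeric(cell_size_km),
                 layer_names = as.character(layer_names),
                 autocorr_length_km = autocorr, seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Generate a synthetic predictor stack
#'
#' One spatially autocorrelated standardised layer per name. Deterministic
#' in `spec` (each layer draws from its own derived seed).
#'
#' @param spec a [landscape_spec()].
#' @return a [predictor_stack()].
#' @export
generate_predictor_stack <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  layers <- lapply(seq_along(spec$layer_names), function(i) {
    nm <- spec$layer_names[i]
    z <- with_seed(derive_seed(spec$seed, paste0("layer:", nm)),
                   matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                          spec$n_rows, spec$n_cols))
    sigma <- spec$autocorr_length_km[[nm]] / spec$cell_size_km
    z <- smooth_gaussian_grid(z, sigma)
    (z - mean(z)) / stats::sd(z)
  })
  names(layers) <- spec$layer_names
  predictor_stack(layers, spec$cell_size_km, seed = spec$seed)
}

#' Define a true (generating) niche
#'
#' Ground truth for parameter-recovery tests: per-cell suitability is
#' `plogis(intercept + sum(coef * x) + sum(quad * x^2))`.
#'
#' @param intercept real intercept on the logit scale.
#' @param coefficients named numeric vector of linear terms.
#' @param quadratic_coefficients optional named numeric vector of quadratic
#'   terms.
#' @return object of class `true_niche`.
#' @export
true_niche <- function(intercept, coefficients,
                       quadratic_coefficients = NULL) {
  if (length(coefficients) && is.null(names(coefficients)))
    stop("coefficients must be named by predictor")
  if (length(quadratic_coefficients) && is.null(names(quadratic_coefficients)))
    stop("quadratic_coefficients must be named by predictor")
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 quadratic_coefficients = quadratic_coefficients),
            class = "true_niche")
}

#' Evaluate the true suitability surface
#'
#' @param stack a [predictor_stack()].
#' @param niche a [true_niche()]; every referenced predictor must exist in
#'   the stack.
#' @return suitability grid matrix in (0, 1), co-registered with `stack`.
#' @export
true_suitability <- function(stack, niche) {
  used <- union(names(niche$coefficients), names(niche$quadratic_coefficients))
  missing <- setdiff(used, names(stack$layers))
  if (length(missing))
    stop("unknown predictor name(s): ", paste(missing, collapse = ", "))
  eta <- matrix(niche$intercept, stack$n_rows, stack$n_cols)
  for (nm in names(niche$coefficients))
    eta <- eta + niche$coefficients[[nm]] * stack$layers[[nm]]
  for (nm in names(niche$quadratic_coefficients))
    eta <- eta + niche$quadratic_coefficients[[nm]] * stack$layers[[nm]]^2
  grid_map(stats::plogis(eta), stack)
}

#' Generate a smooth observation-bias surface
#'
#' Emulates spatially uneven sampling effort (roads, towns): an
#' autocorrelated Gaussian field is exponentiated and rescaled to a maximum
#' of 1, so effort is positive everywhere but concentrated in patches.
#'
#' @param stack reference [predictor_stack()] (geometry only).
#' @param autocorr_length_km correlation length of the effort field.
#' @param strength log-scale contrast; 0 gives a uniform surface.
#' @param seed integer seed.
#' @return bias grid matrix in (0, 1], co-registered with `stack`.
#' @export
generate_bias_surface <- function(stack, autocorr_length_km, strength = 1.5,
                                  seed = 1L) {
  z <- with_seed(derive_seed(seed, "bias-surface"),
                 matrix(stats::rnorm(n_cells(stack)), stack$n_rows, stack$n_cols))
  z <- smooth_gaussian_grid(z, autocorr_length_km / stack$cell_size_km)
  z <- (z - mean(z)) / stats::sd(z)
  b <- exp(strength * z)
  grid_map(b / max(b), stack)
}

# Draw n cells (column-major indices) with probability proportional to w.
sample_cells <- function(w, n) {
  if (all(w <= 0) || !any(is.finite(w)))
    stop("selection weights are identically zero")
  w[!is.finite(w)] <- 0
  sample.int(length(w), n, replace = TRUE, prob = w)
}

# Uniform jitter of cell indices into planar point coordinates.
jitter_points_in_cells <- function(cells, n_rows, cs) {
  row <- (cells - 1L) %% n_rows + 1L
  col <- (cells - 1L) %/% n_rows + 1L
  list(x = (col - 1L + stats::runif(length(cells))) * cs,
       y = (n_rows - row + stats::runif(length(cells))) * cs)
}

#' Sample occurrence records from a known suitability surface
#'
#' Emulates opportunistic presence-only sightings: cells are drawn with
#' probability proportional to `suitability * bias`, then points are
#' jittered uniformly within their cell. A configurable fraction of records
#' deliberately violates the cleaning rules (uncertainty > 5 km, missing
#' year, pre-1970 year, fossil flags, absence flags, far outliers) to
#' exercise the cleaner.
#'
#' @param suit suitability grid matrix (values in `[0, 1]`).
#' @param bias co-registered bias grid matrix.
#' @param n number of records to draw (returned exactly).
#' @param seed integer seed.
#' @param dirty_fraction fraction of records made to violate a cleaning
#'   rule (default 0.1, split evenly among the rule types).
#' @return an [occurrence_set()] with planar-km coordinates.
#' @export
sample_occurrences <- function(suit, bias, n, seed, dirty_fraction = 0.1) {
  stopifnot_coregistered(suit, bias)
  if (n < 1) stop("n must be >= 1")
  cs <- attr(suit, "cell_size_km")
  n_rows <- nrow(suit)
  with_seed(seed, {
    w <- as.vector(suit) * as.vector(bias)
    cells <- sample_cells(w, n)
    pt <- jitter_points_in_cells(cells, n_rows, cs)
    occ <- occurrence_set(
      lon = pt$x, lat = pt$y,
      year = sample(1975:2020, n, replace = TRUE),
      coord_uncertainty_m = stats::runif(n, 0, 3000),
      is_fossil = FALSE, is_absence_record = FALSE,
      source = "synthetic")
    n_dirty <- round(dirty_fraction * n)
    if (n_dirty > 0) {
      idx <- sample.int(n, n_dirty)
      kinds <- rep_len(c("uncertainty", "no_year", "old_year",
                         "fossil", "absence", "outlier"), n_dirty)
      for (k in seq_len(n_dirty)) {
        i <- idx[k]
        switch(kinds[k],
          uncertainty = { occ$coord_uncertainty_m[i] <- stats::runif(1, 5001, 25000) },
          no_year = { occ$year[i] <- NA_integer_ },
          old_year = { occ$year[i] <- sample(1900:1969, 1) },
          fossil = { occ$is_fossil[i] <- TRUE },
          absence = { occ$is_absence_record[i] <- TRUE },
          outlier = {
            # push the point to the grid corner farthest from the record
            # centroid, where it is usually > 30 km from everything else
            cx <- mean(occ$lon[-i]); cy <- mean(occ$lat[-i])
            xmax <- ncol(suit) * cs; ymax <- n_rows * cs
            occ$lon[i] <- if (cx > xmax / 2) stats::runif(1, 0, cs) else stats::runif(1, xmax - cs, xmax)
            occ$lat[i] <- if (cy > ymax / 2) stats::runif(1, 0, cs) else stats::runif(1, ymax - cs, ymax)
          })
      }
      attr(occ, "dirty_index") <- sort(idx)
    }
    occ
  })
}

#' Sample analogue-species sightings from the bias surface alone
#'
#' Points whose cell probability is proportional to observation effort only
#' (niche-independent); used downstream to estimate the sampling-bias layer.
#'
#' @param bias bias grid matrix (nonnegative, not all zero).
#' @param n number of sightings.
#' @param seed integer seed.
#' @return an [occurrence_set()] with clean metadata.
#' @export
generate_analogue_sightings <- function(bias, n, seed) {
  if (n < 1) stop("n must be >= 1")
  cs <- attr(bias, "cell_size_km")
  with_seed(seed, {
    cells <- sample_cells(as.vector(bias), n)
    pt <- jitter_points_in_cells(cells, nrow(bias), cs)
    occurrence_set(pt$x, pt$y,
                   year = sample(1990:2020, n, replace = TRUE),
                   coord_uncertainty_m = stats::runif(n, 0, 3000),
                   source = "analogue")
  })
}

#' Define a climate-scenario shift
#'
#' A parametric stand-in for past/future scenario grids: each named layer is
#' transformed cell-wise as `factor * x + delta`.
#'
#' @param additive_delta named numeric vector of offsets.
#' @param multiplicative_factor named numeric vector of positive factors.
#' @return object of class `scenario_shift`.
#' @export
scenario_shift <- function(additive_delta = numeric(),
                           multiplicative_factor = numeric()) {
  if (length(additive_delta) && is.null(names(additive_delta)))
    stop("additive_delta must be named")
  if (length(multiplicative_factor)) {
    if (is.null(names(multiplicative_factor)))
      stop("multiplicative_factor must be named")
    if (any(multiplicative_factor <= 0))
      stop("multiplicative factors must be positive")
  }
  structure(list(additive_delta = additive_delta,
                 multiplicative_factor = multiplicative_factor),
            class = "scenario_shift")
}

#' Apply a scenario shift to a predictor stack
#'
#' @param stack a [predictor_stack()].
#' @param shift a [scenario_shift()]; every referenced layer must exist.
#' @return a new `predictor_stack` on the same grid; unnamed layers pass
#'   through unchanged.
#' @export
shift_climate <- function(stack, shift) {
  stopifnot(inherits(shift, "scenario_shift"))
  touched <- union(names(shift$additive_delta), names(shift$multiplicative_factor))
  missing <- setdiff(touched, names(stack$layers))
  if (length(missing))
    stop("unknown layer name(s): ", paste(missing, collapse = ", "))
  layers <- stack$layers
  for (nm in touched) {
    f <- if (nm %in% names(shift$multiplicative_factor))
      shift$multiplicative_factor[[nm]] else 1
    d <- if (nm %in% names(shift$additive_delta))
      shift$additive_delta[[nm]] else 0
    layers[[nm]] <- f * layers[[nm]] + d
  }
  predictor_stack(layers, stack$cell_size_km, seed = stack$seed)
}
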