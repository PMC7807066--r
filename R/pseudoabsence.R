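#' Estimate a sampling-effort (bias) surface by point-density analysis
#'
#' Gaussian kernel density of analogue-species sightings evaluated at cell
#' centres (points are binned to cells, then convolved with a Gaussian of
#' the requested bandwidth; reflection padding conserves mass), rescaled to
#' a maximum of 1. The pre-normalisation density (points per km^2) is kept
#' in the `"density"` attribute; its cell sum times cell area recovers the
#' point count.
#'
#' @param analogue_points an [occurrence_set()] (planar km).
#' @param grid reference [predictor_stack()].
#' @param bandwidth_km positive kernel standard deviation.
#' @return bias grid matrix in `[0, 1]`, co-registered with `grid`.
#' @export
build_bias_surface <- function(analogue_points, grid, bandwidth_km) {
  if (nrow(analogue_points) == 0) stop("empty point set")
  if (bandwidth_km <= 0) stop("bandwidth must be positive")
  loc <- locate_cells(grid, analogue_points$lon, analogue_points$lat)
  ok <- !is.na(loc$row)
  counts <- matrix(0, grid$n_rows, grid$n_cols)
  tab <- table(factor(loc$row[ok], levels = seq_len(grid$n_rows)),
               factor(loc$col[ok], levels = seq_len(grid$n_cols)))
  counts[] <- as.numeric(tab)
  sm <- smooth_gaussian_grid(counts, bandwidth_km / grid$cell_size_km)
  sm[sm < 0] <- 0  # tiny negative ringing from the linear filter
  dens <- sm / grid$cell_size_km^2
  out <- grid_map(sm / max(sm), grid)
  attr(out, "density") <- dens
  out
}

#' Fit a presence density kernel in principal-component space
#'
#' Principal components are fitted on the standardised predictor values of
#' the full grid; the presence records are projected into that space and a
#' product-Gaussian kernel density with per-component Scott's-rule
#' bandwidths is placed on their scores. Used to define "environments that
#' look like presences", whose complement steers pseudo-absence placement.
#'
#' @param presences an [occurrence_set()] with at least 10 records on the
#'   grid.
#' @param stack a [predictor_stack()]; constant layers are an error.
#' @param n_components number of components to retain; default: smallest
#'   count explaining >= 95% of variance.
#' @param seed integer seed (kept for provenance; the fit is deterministic).
#' @return object of class `env_kernel` with the component transform,
#'   bandwidths, reference scores and the kernel density evaluated over the
#'   full grid (`grid_density`).
#' @export
fit_env_kernel <- function(presences, stack, n_components = NULL, seed = 1L) {
  if (nrow(presences) < 10) stop("need at least 10 presences")
  X <- stack_values(stack)
  sds <- apply(X, 2L, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("constant predictor layer (zero variance): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  means <- colMeans(X)
  Z <- sweep(sweep(X, 2L, means), 2L, sds, "/")
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  var_expl <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- if (is.null(n_components)) which(var_expl >= 0.95)[1] else as.integer(n_components)
  if (k < 1 || k > ncol(X)) stop("retained components out of range")
  pres_env <- extract(stack, presences)
  P <- as.matrix(pres_env[, colnames(X), drop = FALSE])
  Pz <- sweep(sweep(P, 2L, means), 2L, sds, "/")
  scores <- Pz %*% pca$rotation[, seq_len(k), drop = FALSE]
  n <- nrow(scores)
  bw <- apply(scores, 2L, stats::sd) * n^(-1 / (k + 4))
  bw[bw <= 0 | !is.finite(bw)] <- 1e-6
  kern <- structure(list(means = means, sds = sds,
                         rotation = pca$rotation[, seq_len(k), drop = FALSE],
                         n_components = k, bandwidths = bw,
                         reference_scores = scores, seed = seed),
                    class = "env_kernel")
  grid_scores <- Z %*% kern$rotation
  kern$grid_density <- grid_map(env_kernel_density(kern, grid_scores), stack)
  kern
}

#' Evaluate an environmental kernel density
#'
#' @param kernel an `env_kernel` from [fit_env_kernel()].
#' @param x either a matrix of component scores (columns = retained
#'   components) or a data frame of raw predictor values to be projected.
#' @return nonnegative density values, one per row of `x`.
#' @export
env_kernel_density <- function(kernel, x) {
  if (is.data.frame(x)) {
    X <- as.matrix(x[, names(kernel$means), drop = FALSE])
    x <- sweep(sweep(X, 2L, kernel$means), 2L, kernel$sds, "/") %*% kernel$rotation
  }
  ref <- kernel$reference_scores
  h <- kernel$bandwidths
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(ref))) {
    lk <- 1
    for (j in seq_len(ncol(ref)))
      lk <- lk * stats::dnorm(x[, j], ref[i, j], h[j])
    out <- out + lk
  }
  out / nrow(ref)
}

#' Sample pseudo-absences at a 1:1 ratio with presences
#'
#' Cell weight is the complement of the normalised presence-kernel density,
#' `(1 - d / max(d))`, multiplied by the sampling-effort bias layer, so
#' pseudo-absences concentrate in environments unlike presences but mirror
#' observation effort. Candidates are drawn sequentially by weight and
#' rejected if closer than `min_dist_km` to any presence or already-accepted
#' pseudo-absence; after `50 * n` rejections the requested count is declared
#' infeasible and the achievable set is returned with a warning.
#'
#' @param kernel an `env_kernel` fitted on the presences.
#' @param bias bias grid matrix co-registered with `stack`.
#' @param stack the [predictor_stack()].
#' @param presences the presence [occurrence_set()].
#' @param min_dist_km minimum spacing (default 30 km).
#' @param seed integer seed.
#' @return `occurrence_set` of pseudo-absences (source
#'   `"pseudoabsence"`), with attribute `requested` = presence count.
#' @export
sample_pseudoabsences <- function(kernel, bias, stack, presences,
                                  min_dist_km = 30, seed = 1L) {
  stopifnot_coregistered(bias, stack)
  n <- nrow(presences)
  if (n < 1) stop("need at least one presence")
  d <- as.vector(kernel$grid_density)
  w <- (1 - d / max(d)) * as.vector(bias)
  w[!is.finite(w) | w < 0] <- 0
  nodata <- rowSums(!is.finite(stack_values(stack))) > 0
  w[nodata] <- 0
  if (all(w == 0)) stop("selection weights are identically zero")
  cs <- stack$cell_size_km
  with_seed(seed, {
    px <- presences$lon; py <- presences$lat
    ax <- numeric(0); ay <- numeric(0)
    rejections <- 0L
    while (length(ax) < n && rejections < 50L * n) {
      cell <- sample_cells(w, 1L)
      pt <- jitter_points_in_cells(cell, stack$n_rows, cs)
      d_pres <- sqrt((pt$x - px)^2 + (pt$y - py)^2)
      d_pa <- if (length(ax)) sqrt((pt$x - ax)^2 + (pt$y - ay)^2) else Inf
      if (min(d_pres) >= min_dist_km && min(d_pa) >= min_dist_km) {
        ax <- c(ax, pt$x); ay <- c(ay, pt$y)
      } else rejections <- rejections + 1L
    }
    if (length(ax) < n)
      warning(sprintf(
        "spacing constraint infeasible: placed %d of %d pseudo-absences",
        length(ax), n))
    out <- occurrence_set(ax, ay, year = NA_integer_,
                          coord_uncertainty_m = 0,
                          source = "pseudoabsence")
    attr(out, "requested") <- n
    out
  })
}
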