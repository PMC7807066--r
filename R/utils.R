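## Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so every generator is a pure function of its
# arguments.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Derive a stage seed from the global pipeline seed
#'
#' Deterministic, documented derivation: the global seed is combined with a
#' hash of the stage label so any stage can be re-run in isolation with
#' identical results. Result is always a positive 32-bit integer.
#'
#' @param seed global integer seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483629 + 1)
}

# Separable Gaussian smoothing with reflection padding (mass-conserving up
# to kernel truncation at 4 sigma). sigma is in cell units.
smooth_gaussian_grid <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_cells))
  k <- stats::dnorm(seq(-r, r), sd = sigma_cells)
  k <- k / sum(k)
  pad_reflect <- function(v, r) {
    n <- length(v)
    ri <- pmin(r, n - 1L)
    c(v[seq(ri + 1L, 2L)], v, v[seq(n - 1L, n - ri)])
  }
  conv1 <- function(v) {
    n <- length(v)
    ri <- min(r, n - 1L)
    kk <- if (ri < r) { k2 <- stats::dnorm(seq(-ri, ri), sd = sigma_cells); k2 / sum(k2) } else k
    p <- pad_reflect(v, ri)
    out <- stats::filter(p, kk, sides = 2)
    as.numeric(out[(ri + 1L):(ri + n)])
  }
  m <- apply(m, 2L, conv1)
  t(apply(m, 1L, conv1))
}

# Euclidean distance in km between two planar point sets (matrices/data
# frames with x, y columns).
planar_dist_km <- function(a, b) {
  sqrt(outer(a[[1]], b[[1]], "-")^2 + outer(a[[2]], b[[2]], "-")^2)
}

#' Great-circle distance via the haversine formula
#'
#' Spherical Earth of radius 6371.0088 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees; vectors recycle.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}
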