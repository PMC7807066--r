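# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: direct double sums, exhaustive sweeps, O(n^2) loops.

# Lag-1 (rook-neighbour) Moran's I by the direct double sum.
oracle_moran_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; w_sum <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          num <- num + z[i, j] * z[ii, jj]
          w_sum <- w_sum + 1
        }
      }
    }
  }
  (length(m) / w_sum) * num / sum(z^2)
}

# AUC by explicit pair counting, ties counted one half.
oracle_auc <- function(scores, labels) {
  p <- scores[labels == 1]; a <- scores[labels == 0]
  tot <- 0
  for (x in p) for (y in a)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(p) * length(a))
}

# Metrics from first principles on a 2x2 table.
oracle_metrics <- function(TP, FP, TN, FN) {
  n <- TP + FP + TN + FN
  sens <- TP / (TP + FN); spec <- TN / (TN + FP)
  p_o <- (TP + TN) / n
  p_yes <- ((TP + FP) / n) * ((TP + FN) / n)
  p_no <- ((FN + TN) / n) * ((FP + TN) / n)
  p_e <- p_yes + p_no
  list(sensitivity = sens, specificity = spec, TSS = sens + spec - 1,
       Kappa = if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e))
}

# VIF via the inverse-correlation-matrix identity.
oracle_vif <- function(X) {
  v <- diag(solve(stats::cor(X)))
  stats::setNames(as.numeric(v), colnames(X))
}

# Exhaustive max-TSS sweep over unique observed scores, smallest winner.
oracle_max_tss <- function(scores, labels) {
  best_t <- NA; best_tss <- -Inf
  for (t in sort(unique(scores))) {
    TP <- sum(scores >= t & labels == 1); FN <- sum(scores < t & labels == 1)
    TN <- sum(scores < t & labels == 0); FP <- sum(scores >= t & labels == 0)
    tss <- TP / (TP + FN) + TN / (TN + FP) - 1
    if (tss > best_tss) { best_tss <- tss; best_t <- t }
  }
  list(threshold = best_t, TSS = best_tss)
}

# MESS similarity straight from the piecewise formula (strict less-than).
oracle_mess <- function(reference, p) {
  rmin <- min(reference); rmax <- max(reference)
  f <- 100 * sum(reference < p) / length(reference)
  if (f == 0) (p - rmin) / (rmax - rmin) * 100
  else if (f <= 50) 2 * f
  else if (f < 100) 2 * (100 - f)
  else (rmax - p) / (rmax - rmin) * 100
}

# Greedy thinning re-implemented independently (same seeded ordering
# contract: a permutation drawn with sample.int under the seed).
oracle_thin <- function(points, min_dist_km, seed) {
  n <- nrow(points)
  ord <- withr::with_seed(as.integer(seed), sample.int(n))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      d <- sqrt((points$lon[i] - points$lon[k])^2 +
                (points$lat[i] - points$lat[k])^2)
      if (d < min_dist_km) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# All-pairs nearest neighbour (planar).
oracle_nn_km <- function(points) {
  n <- nrow(points)
  nn <- rep(Inf, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    d <- sqrt((points$lon[i] - points$lon[j])^2 +
              (points$lat[i] - points$lat[j])^2)
    if (d < nn[i]) nn[i] <- d
  }
  nn
}

min_pairwise_km <- function(occ) {
  d <- sqrt(outer(occ$lon, occ$lon, "-")^2 + outer(occ$lat, occ$lat, "-")^2)
  diag(d) <- Inf
  min(d)
}
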