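#' Confusion counts at a threshold
#'
#' The `>=`-threshold convention is fixed package-wide: a score equal to the
#' threshold predicts presence.
#'
#' @param scores suitability vector in `[0, 1]`.
#' @param labels 0/1 vector of the same length.
#' @param threshold classification threshold.
#' @return list with `TP`, `FP`, `TN`, `FN` (class `confusion_counts`).
#' @export
confusion <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) stop("length mismatch")
  pred <- scores >= threshold
  structure(list(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, TSS and Kappa from confusion counts
#'
#' `TSS = sensitivity + specificity - 1`; Kappa is the chance-corrected
#' agreement `(p_o - p_e) / (1 - p_e)` with `p_e` from the marginals.
#'
#' @param counts a [confusion()] result (both classes must be represented).
#' @return named list: `sensitivity`, `specificity`, `TSS`, `Kappa`.
#' @export
tss_kappa <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (TP + FN == 0 || TN + FP == 0) stop("a class is empty")
  n <- TP + FP + TN + FN
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  p_o <- (TP + TN) / n
  p_e <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  list(sensitivity = sens, specificity = spec,
       TSS = sens + spec - 1, Kappa = kappa)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate: the fraction of presence-absence
#' pairs ranked correctly, ties counted one half.
#'
#' @param scores suitability vector.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximising the TSS
#'
#' Sweeps the candidate set of unique observed score values; ties are broken
#' by the smallest optimal candidate. Adding duplicates of existing scores
#' never changes the result.
#'
#' @param scores suitability vector.
#' @param labels 0/1 vector; both classes must be present.
#' @return list with `threshold` and `TSS`.
#' @export
max_tss_threshold <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  cand <- sort(unique(scores))
  # at threshold t: sens = P(score >= t | 1), spec = P(score < t | 0)
  tss <- vapply(cand, function(t)
    sum(scores >= t & labels == 1) / n1 +
    sum(scores < t & labels == 0) / n0 - 1, numeric(1))
  best <- which.max(tss)  # first index, i.e. smallest optimal candidate
  list(threshold = cand[best], TSS = tss[best])
}

#' Continuous Boyce index
#'
#' Overlapping windows span the observed suitability range; per window,
#' `P` is the fraction of presences and `E` the fraction of background
#' cells falling inside. The index is the Spearman rank correlation of
#' `P/E` against the window midpoint, skipping windows with `E = 0`.
#' +1 indicates perfect monotone calibration, 0 a prediction no better
#' than random placement of the presences.
#'
#' @param suitability_background suitability over the evaluation cells.
#' @param suitability_at_presences suitability at the presence points.
#' @param n_windows number of overlapping windows (default 101).
#' @param window_width window width; default one tenth of the observed
#'   suitability range.
#' @return Boyce index in `[-1, 1]`.
#' @export
boyce <- function(suitability_background, suitability_at_presences,
                  n_windows = 101, window_width = NULL) {
  rng <- range(suitability_background, suitability_at_presences, na.rm = TRUE)
  if (diff(rng) <= 0) stop("degenerate suitability range")
  w <- if (is.null(window_width)) diff(rng) / 10 else window_width
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_windows)
  P <- vapply(mids, function(m)
    mean(suitability_at_presences >= m - w / 2 &
         suitability_at_presences <= m + w / 2), numeric(1))
  E <- vapply(mids, function(m)
    mean(suitability_background >= m - w / 2 &
         suitability_background <= m + w / 2), numeric(1))
  use <- E > 0
  if (sum(use) < 2) stop("fewer than 2 usable windows")
  suppressWarnings(stats::cor(P[use] / E[use], mids[use], method = "spearman"))
}

#' Score predictions against 0/1 labels
#'
#' Convenience wrapper used on every holdout: AUC, the max-TSS threshold,
#' and sensitivity/specificity/TSS/Kappa at that threshold.
#'
#' @param scores suitability vector.
#' @param labels 0/1 vector.
#' @return named list of class `evaluation_scores`.
#' @export
evaluate_scores <- function(scores, labels) {
  th <- max_tss_threshold(scores, labels)
  m <- tss_kappa(confusion(scores, labels, th$threshold))
  structure(list(AUC = auc(scores, labels), threshold = th$threshold,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 TSS = m$TSS, Kappa = m$Kappa),
            class = "evaluation_scores")
}
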