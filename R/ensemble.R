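#' Gate candidate models on evaluation thresholds
#'
#' Keeps exactly the models meeting all three inclusive gates
#' (TSS >= `tss_min`, AUC >= `auc_min`, Kappa >= `kappa_min`); models that
#' failed to fit are excluded with their error as the reason.
#'
#' @param models list of `fitted_model`s from [fit_all()].
#' @param tss_min,auc_min,kappa_min inclusion gates (defaults 0.7/0.9/0.7).
#' @return list with `members` (surviving models) and `report` (data frame:
#'   algorithm, run, scores, `pass`, `reason`). An empty survivor set is
#'   reported, not fatal here; ensembling it is.
#' @export
select_members <- function(models, tss_min = 0.7, auc_min = 0.9,
                           kappa_min = 0.7) {
  rows <- lapply(models, function(m) {
    if (is.null(m$scores)) {
      data.frame(algorithm = m$algorithm, run = m$run, AUC = NA_real_,
                 TSS = NA_real_, Kappa = NA_real_, pass = FALSE,
                 reason = paste("fit error:", m$error),
                 stringsAsFactors = FALSE)
    } else {
      s <- m$scores
      fails <- c(if (s$TSS < tss_min) sprintf("TSS %.3f < %.2f", s$TSS, tss_min),
                 if (s$AUC < auc_min) sprintf("AUC %.3f < %.2f", s$AUC, auc_min),
                 if (s$Kappa < kappa_min) sprintf("Kappa %.3f < %.2f", s$Kappa, kappa_min))
      data.frame(algorithm = m$algorithm, run = m$run, AUC = s$AUC,
                 TSS = s$TSS, Kappa = s$Kappa, pass = length(fails) == 0,
                 reason = if (length(fails)) paste(fails, collapse = "; ") else "",
                 stringsAsFactors = FALSE)
    }
  })
  report <- do.call(rbind, rows)
  list(members = models[report$pass], report = report)
}

#' Build a TSS-weighted ensemble
#'
#' Member weights are proportional to holdout TSS and sum to 1, so models
#' with higher skill contribute more to the consensus suitability.
#'
#' @param members non-empty list of gated `fitted_model`s.
#' @param params optional `standardization_params` carried along so
#'   projection stacks are transformed with the fitting-era means/sds.
#' @return object of class `ensemble_model`.
#' @export
ensemble_model <- function(members, params = NULL) {
  if (length(members) == 0)
    stop("empty ensemble: no model passed the inclusion gates")
  tss <- vapply(members, function(m) m$scores$TSS, numeric(1))
  if (any(tss <= 0)) stop("member TSS must be positive for weighting")
  structure(list(members = members, weights = tss / sum(tss),
                 params = params),
            class = "ensemble_model")
}

member_predictions <- function(ensemble, newdata) {
  vapply(ensemble$members, function(m) predict_suitability(m, newdata),
         numeric(nrow(newdata)))
}

#' Ensemble suitability for a table of predictor values
#'
#' @param ensemble an [ensemble_model()].
#' @param newdata data frame of predictor values on the standardised scale
#'   (or raw values if the ensemble carries standardisation parameters and
#'   `standardize = TRUE`).
#' @param standardize apply the stored fitting-era parameters first.
#' @return suitability vector; the TSS-weighted mean of member predictions.
#' @export
ensemble_predict_table <- function(ensemble, newdata, standardize = FALSE) {
  if (standardize) {
    if (is.null(ensemble$params)) stop("no standardisation parameters stored")
    newdata <- apply_standardization(newdata, ensemble$params)
  }
  P <- member_predictions(ensemble, newdata)
  drop(P %*% ensemble$weights)
}

#' Project an ensemble over a predictor stack
#'
#' The stack is standardised with the *fitting-era* parameters (never
#' refitted on the scenario), then each member predicts every cell and the
#' TSS-weighted mean is returned. Nodata cells propagate as `NA`.
#'
#' @param ensemble an [ensemble_model()] carrying standardisation
#'   parameters (or `params` given here).
#' @param stack a [predictor_stack()] containing the fitted predictor set.
#' @param params override standardisation parameters.
#' @return suitability grid matrix co-registered with `stack`.
#' @export
ensemble_predict <- function(ensemble, stack, params = ensemble$params) {
  vars <- needed_vars(ensemble, fallback = names(stack$layers))
  missing <- setdiff(vars, names(stack$layers))
  if (length(missing))
    stop("predictor(s) missing from stack: ", paste(missing, collapse = ", "))
  df <- as.data.frame(stack_values(stack))[vars]
  if (!is.null(params)) df <- apply_standardization(df, params)
  ok <- stats::complete.cases(df)
  out <- rep(NA_real_, nrow(df))
  if (any(ok))
    out[ok] <- ensemble_predict_table(ensemble, df[ok, , drop = FALSE])
  grid_map(out, stack)
}

needed_vars <- function(ensemble, fallback = NULL) {
  if (!is.null(ensemble$params)) return(names(ensemble$params$mean))
  v <- ensemble$members[[1]]$state$vars
  if (!is.null(v)) return(v)
  if (!is.null(fallback)) return(fallback)
  stop("cannot infer predictor set; supply params")
}

#' Between-member coefficient of variation map
#'
#' Cell-wise sample sd / mean of member predictions; an uncertainty surface
#' for the ensemble consensus. Cells with zero mean get CV 0 and are
#' counted in the `"n_zero_mean"` attribute.
#'
#' @param ensemble an [ensemble_model()] with >= 2 members.
#' @param stack a [predictor_stack()].
#' @return CV grid matrix.
#' @export
uncertainty_map <- function(ensemble, stack) {
  if (length(ensemble$members) < 2) stop("need at least 2 members")
  vars <- needed_vars(ensemble, fallback = names(stack$layers))
  df <- as.data.frame(stack_values(stack))[vars]
  if (!is.null(ensemble$params)) df <- apply_standardization(df, ensemble$params)
  ok <- stats::complete.cases(df)
  out <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    P <- member_predictions(ensemble, df[ok, , drop = FALSE])
    mu <- rowMeans(P)
    sdv <- apply(P, 1L, stats::sd)
    cv <- ifelse(mu == 0, 0, sdv / mu)
    out[ok] <- cv
  }
  m <- grid_map(out, stack)
  attr(m, "n_zero_mean") <- sum(out == 0 & ok[seq_along(out)], na.rm = TRUE)
  m
}

#' Binarize a suitability map
#'
#' @param map suitability grid matrix.
#' @param threshold cut-off in `[0, 1]`; a cell is "present" iff its
#'   suitability is `>=` the threshold.
#' @param label free-text scenario label for reporting.
#' @return object of class `binary_range_map` (logical grid + metadata).
#' @export
binarize <- function(map, threshold, label = "") {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  m <- map >= threshold
  structure(list(presence = m, threshold = threshold, label = label,
                 cell_size_km = attr(map, "cell_size_km")),
            class = "binary_range_map")
}

#' Range change between two binary maps under two dispersal assumptions
#'
#' Counts occupied cells (the grids are equal-area, so counts are areas).
#' Unlimited dispersal treats the whole projected range as occupied;
#' no dispersal only the overlap with the current range:
#' `pct_unlimited = (cells_other - cells_current) / cells_current * 100`,
#' `pct_no_dispersal = (overlap - cells_current) / cells_current * 100`.
#'
#' @param current,other co-registered [binarize()] outputs.
#' @return object of class `range_change_report`: cell counts, both
#'   percentage changes, and a gain/loss/stable/absent factor grid.
#' @export
range_change <- function(current, other) {
  a <- current$presence; b <- other$presence
  if (!all(dim(a) == dim(b))) stop("grids are not co-registered")
  cells_current <- sum(a, na.rm = TRUE)
  cells_other <- sum(b, na.rm = TRUE)
  overlap <- sum(a & b, na.rm = TRUE)
  if (cells_current == 0) stop("current range is empty")
  gl <- matrix("absent", nrow(a), ncol(a))
  gl[a & b] <- "stable"; gl[!a & b] <- "gain"; gl[a & !b] <- "loss"
  gl[is.na(a) | is.na(b)] <- NA
  structure(list(cells_current = cells_current, cells_other = cells_other,
                 cells_overlap = overlap,
                 pct_change_unlimited = (cells_other - cells_current) / cells_current * 100,
                 pct_change_no_dispersal = (overlap - cells_current) / cells_current * 100,
                 gain_loss_map = gl,
                 labels = c(current = current$label, other = other$label)),
            class = "range_change_report")
}

#' @export
print.range_change_report <- function(x, ...) {
  cat(sprintf(paste0("<range_change_report> %d -> %d cells (overlap %d)\n",
                     "  unlimited dispersal: %+.2f%%\n",
                     "  no dispersal:        %+.2f%%\n"),
              x$cells_current, x$cells_other, x$cells_overlap,
              x$pct_change_unlimited, x$pct_change_no_dispersal))
  invisible(x)
}
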