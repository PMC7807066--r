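#' Extract predictor values at point locations
#'
#' Each point takes the stored value of its containing cell. Points falling
#' on a nodata cell (any layer `NA`) are dropped and counted in the
#' `"n_dropped"` attribute; points outside the grid extent are an error.
#'
#' @param stack a [predictor_stack()].
#' @param points an [occurrence_set()] (planar km, on the stack's grid).
#' @return data.frame with one column per layer, attribute `n_dropped`.
#' @export
extract <- function(stack, points) {
  loc <- locate_cells(stack, points$lon, points$lat)
  if (anyNA(loc$row)) stop("point(s) outside the grid extent")
  idx <- (loc$col - 1L) * stack$n_rows + loc$row
  vals <- as.data.frame(stack_values(stack)[idx, , drop = FALSE])
  ok <- stats::complete.cases(vals)
  out <- vals[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  attr(out, "kept") <- which(ok)
  out
}

#' Assemble the model-fitting sample table
#'
#' Presences (label 1) and pseudo-absences (label 0) with their extracted
#' predictor values; the currency of all model fitting.
#'
#' @param stack a [predictor_stack()].
#' @param presences,pseudoabsences [occurrence_set()]s.
#' @return data.frame of predictor columns plus a binary `label` column.
#' @export
sample_table <- function(stack, presences, pseudoabsences) {
  p <- extract(stack, presences)
  a <- extract(stack, pseudoabsences)
  out <- rbind(p, a)
  out$label <- rep(c(1L, 0L), c(nrow(p), nrow(a)))
  rownames(out) <- NULL
  out
}

predictor_columns <- function(table) {
  setdiff(names(table), c("label", "weight"))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor `j` on all others
#' (the label column is ignored). A perfectly collinear predictor reports
#' `Inf`.
#'
#' @param table a sample table (data frame); needs >= 2 predictors and more
#'   rows than predictors.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(table) {
  vars <- predictor_columns(table)
  if (length(vars) < 2) stop("need at least 2 predictors")
  X <- as.data.frame(table[vars])
  if (nrow(X) <= length(vars)) stop("need more rows than predictors")
  vapply(vars, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v), data = X)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Stepwise VIF variable elimination
#'
#' Repeatedly removes the single predictor with the highest VIF while the
#' maximum exceeds `threshold`; the retained set's VIFs are all below or at
#' the threshold. Ties in the maximum are broken by column order.
#'
#' @param table a sample table.
#' @param threshold VIF cut-off (default 10).
#' @return object of class `vif_report`: `steps` (per-step VIF vectors),
#'   `removed` (in order), `retained`, `threshold`.
#' @export
vif_stepwise <- function(table, threshold = 10) {
  vars <- predictor_columns(table)
  work <- table[c(vars, intersect("label", names(table)))]
  steps <- list(); removed <- character(0)
  while (length(predictor_columns(work)) >= 2) {
    v <- vif(work)
    steps[[length(steps) + 1L]] <- v
    if (max(v) <= threshold) break
    worst <- names(v)[which.max(v)]
    removed <- c(removed, worst)
    work[[worst]] <- NULL
  }
  structure(list(steps = steps, removed = removed,
                 retained = predictor_columns(work),
                 threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("<vif_report> threshold %g; removed: %s; retained: %s\n",
              x$threshold,
              if (length(x$removed)) paste(x$removed, collapse = ", ") else "(none)",
              paste(x$retained, collapse = ", ")))
  invisible(x)
}

#' Scale and centre a sample table
#'
#' Standardises every predictor column to mean 0 / sd 1 and returns the
#' parameters so that projection stacks are transformed with the *fitting*
#' means and sds, never refitted on scenario data.
#'
#' @param table a sample table; constant columns are an error.
#' @return list with `table` (standardised) and `params` (class
#'   `standardization_params`: named `mean` and `sd` vectors).
#' @export
scale_centre <- function(table) {
  vars <- predictor_columns(table)
  mu <- vapply(table[vars], mean, numeric(1))
  sd_ <- vapply(table[vars], stats::sd, numeric(1))
  if (any(sd_ == 0 | !is.finite(sd_)))
    stop("constant column(s): ", paste(vars[sd_ == 0], collapse = ", "))
  out <- table
  for (v in vars) out[[v]] <- (out[[v]] - mu[[v]]) / sd_[[v]]
  params <- structure(list(mean = mu, sd = sd_),
                      class = "standardization_params")
  list(table = out, params = params)
}

#' Apply stored standardisation parameters
#'
#' @param x a sample table (data frame) or [predictor_stack()].
#' @param params `standardization_params` from [scale_centre()]. Columns or
#'   layers without stored parameters pass through unchanged.
#' @return object of the same type with standardised values.
#' @export
apply_standardization <- function(x, params) {
  stopifnot(inherits(params, "standardization_params"))
  if (inherits(x, "predictor_stack")) {
    layers <- x$layers
    for (nm in intersect(names(layers), names(params$mean)))
      layers[[nm]] <- (layers[[nm]] - params$mean[[nm]]) / params$sd[[nm]]
    predictor_stack(layers, x$cell_size_km, seed = x$seed)
  } else {
    for (nm in intersect(names(x), names(params$mean)))
      x[[nm]] <- (x[[nm]] - params$mean[[nm]]) / params$sd[[nm]]
    x
  }
}
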