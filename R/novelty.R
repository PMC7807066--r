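#' MESS similarity of a point to a reference distribution
#'
#' Multivariate-environmental-similarity building block for one variable.
#' With `f = 100 * (fraction of reference values < p)` (strict less-than):
#' `f = 0` gives `(p - min) / (max - min) * 100`; `0 < f <= 50` gives `2f`;
#' `50 < f < 100` gives `2(100 - f)`; `f = 100` gives
#' `(max - p) / (max - min) * 100`. Negative values flag novel conditions
#' outside the reference range; the maximum 100 is attained at the
#' reference median.
#'
#' @param reference non-constant numeric vector of reference values.
#' @param p value(s) to score (vectorised).
#' @return percent-scaled similarity, same length as `p`.
#' @export
mess_variable <- function(reference, p) {
  rmin <- min(reference); rmax <- max(reference)
  if (!(rmax > rmin)) stop("constant reference")
  n <- length(reference)
  ref <- sort(reference)
  # strict less-than: number of reference values < p
  f <- 100 * (findInterval(p, ref, left.open = TRUE)) / n
  out <- numeric(length(p))
  out[f == 0] <- (p[f == 0] - rmin) / (rmax - rmin) * 100
  sel <- f > 0 & f <= 50
  out[sel] <- 2 * f[sel]
  sel <- f > 50 & f < 100
  out[sel] <- 2 * (100 - f[sel])
  out[f == 100] <- (rmax - p[f == 100]) / (rmax - rmin) * 100
  out
}

#' MESS map over a predictor stack
#'
#' Evaluates [mess_variable()] for every reference predictor at every cell;
#' the aggregate layer is the cell-wise minimum over variables, so negative
#' aggregate values mark climates novel relative to the model-fitting
#' reference.
#'
#' @param reference_table sample table whose predictor columns define the
#'   reference distribution (typically the model-fitting points).
#' @param stack a [predictor_stack()] containing every reference column.
#' @return object of class `mess_map`: `layers` (named list of per-variable
#'   similarity grids), `aggregate` (cell-wise minimum grid).
#' @export
mess_map <- function(reference_table, stack) {
  vars <- predictor_columns(reference_table)
  missing <- setdiff(vars, names(stack$layers))
  if (length(missing))
    stop("predictor(s) missing from stack: ", paste(missing, collapse = ", "))
  layers <- lapply(vars, function(v)
    grid_map(mess_variable(reference_table[[v]],
                           as.vector(stack$layers[[v]])), stack))
  names(layers) <- vars
  agg <- Reduce(pmin, lapply(layers, identity))
  structure(list(layers = layers, aggregate = grid_map(agg, stack)),
            class = "mess_map")
}

#' Shift in predictor correlation structure between two stacks
#'
#' Pearson correlation of each layer pair over cells, computed per stack,
#' plus the difference; flags scenario climates whose variables co-vary
#' differently from the fitting-era climate.
#'
#' @param stack_a,stack_b [predictor_stack()]s with identical layer names.
#' @return list with correlation matrices `cor_a`, `cor_b` and
#'   `difference` (`cor_a - cor_b`).
#' @export
correlation_shift <- function(stack_a, stack_b) {
  if (!identical(sort(names(stack_a$layers)), sort(names(stack_b$layers))))
    stop("stacks must share layer names")
  A <- stack_values(stack_a)
  B <- stack_values(stack_b)[, colnames(A), drop = FALSE]
  sd_a <- apply(A, 2L, stats::sd); sd_b <- apply(B, 2L, stats::sd)
  if (any(sd_a == 0) || any(sd_b == 0)) stop("constant layer")
  ca <- stats::cor(A); cb <- stats::cor(B)
  list(cor_a = ca, cor_b = cb, difference = ca - cb)
}
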