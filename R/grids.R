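#' Co-registered stack of continuous predictor layers
#'
#' A `predictor_stack` holds one named numeric matrix per environmental
#' variable on a shared planar, equal-area grid. Row 1 is the northernmost
#' row; cell centres sit at `x = (col - 0.5) * cell_size_km`,
#' `y = (n_rows - row + 0.5) * cell_size_km`, so cell counts are areas.
#' Missing data is `NA`, never 0.
#'
#' @param layers named list of numeric matrices with identical dimensions.
#' @param cell_size_km positive cell edge length in kilometres.
#' @param seed optional integer recorded for provenance.
#' @return an object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, cell_size_km, seed = NA_integer_) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty named list of matrices")
  nms <- names(layers)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop("layer names must be present and unique")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same grid dimensions")
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L || cell_size_km <= 0)
    stop("`cell_size_km` must be a positive scalar")
  structure(
    list(layers = lapply(layers, function(m) {
      storage.mode(m) <- "double"
      m
    }),
    n_rows = unname(dims[1, 1]), n_cols = unname(dims[2, 1]),
    cell_size_km = as.numeric(cell_size_km), seed = seed),
    class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %d x %d cells (%.3g km), %d layer(s): %s\n",
              x$n_rows, x$n_cols, x$cell_size_km, length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.predictor_stack <- function(x) names(x$layers)

#' Number of cells in a stack or grid map
#' @param stack a `predictor_stack`.
#' @return integer cell count.
#' @export
n_cells <- function(stack) stack$n_rows * stack$n_cols

stopifnot_coregistered <- function(a, b) {
  da <- grid_geometry(a); db <- grid_geometry(b)
  if (!isTRUE(all.equal(da, db)))
    stop("grids are not co-registered (dimensions or cell size differ)")
  invisible(TRUE)
}

grid_geometry <- function(x) {
  if (inherits(x, "predictor_stack"))
    list(n_rows = x$n_rows, n_cols = x$n_cols, cell_size_km = x$cell_size_km)
  else if (is.matrix(x))
    list(n_rows = nrow(x), n_cols = ncol(x),
         cell_size_km = as.numeric(attr(x, "cell_size_km")))
  else stop("not a grid object")
}

#' Matrix of cell-centre coordinates
#'
#' @param stack a `predictor_stack` (or a grid matrix carrying a
#'   `cell_size_km` attribute).
#' @return data.frame with `x`, `y` (km), `row`, `col`, one row per cell in
#'   column-major cell order.
#' @export
cell_centres <- function(stack) {
  g <- grid_geometry(stack)
  cs <- g$cell_size_km
  rows <- rep(seq_len(g$n_rows), times = g$n_cols)
  cols <- rep(seq_len(g$n_cols), each = g$n_rows)
  data.frame(x = (cols - 0.5) * cs, y = (g$n_rows - rows + 0.5) * cs,
             row = rows, col = cols)
}

#' Locate points on the grid
#'
#' @param stack grid object.
#' @param x,y planar coordinates in km.
#' @return data.frame with `row`, `col` (NA outside the extent).
#' @export
locate_cells <- function(stack, x, y) {
  g <- grid_geometry(stack)
  cs <- g$cell_size_km
  col <- floor(x / cs) + 1L
  row <- g$n_rows - floor(y / cs)
  # points exactly on the top/right edge belong to the outermost cell
  col[x == g$n_cols * cs] <- g$n_cols
  row[y == g$n_rows * cs] <- 1L
  bad <- x < 0 | y < 0 | col > g$n_cols | row > g$n_rows | col < 1L | row < 1L |
    !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Flatten a stack to a cells-by-layers matrix
#'
#' @param stack a `predictor_stack`.
#' @return numeric matrix, one row per cell (column-major order), one column
#'   per layer.
#' @export
stack_values <- function(stack) {
  vapply(stack$layers, as.vector, numeric(n_cells(stack)))
}

#' Build a grid map co-registered with a stack
#'
#' @param values numeric vector in column-major cell order, or a matrix.
#' @param stack the reference `predictor_stack`.
#' @return numeric matrix with a `cell_size_km` attribute.
#' @export
grid_map <- function(values, stack) {
  m <- matrix(as.numeric(values), nrow = stack$n_rows, ncol = stack$n_cols)
  attr(m, "cell_size_km") <- stack$cell_size_km
  m
}

## ---- ESRI ASCII grid I/O -------------------------------------------------
## Plain-text raster exchange format: 6-line header then rows of cell values,
## row 1 = northernmost. NODATA cells round-trip as NA.

#' Write a grid matrix as an ESRI ASCII grid
#'
#' @param m numeric matrix (row 1 = north).
#' @param path output file path.
#' @param cell_size_km cell edge length; defaults to the matrix attribute.
#' @param xll,yll lower-left corner coordinates (km).
#' @param nodata value standing in for `NA` on disk.
#' @export
write_ascii_grid <- function(m, path, cell_size_km = attr(m, "cell_size_km"),
                             xll = 0, yll = 0, nodata = -9999) {
  if (is.null(cell_size_km)) stop("cell size unknown")
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", xll),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", cell_size_km),
           sprintf("NODATA_value %.10g", nodata))
  body <- m
  body[is.na(body)] <- nodata
  lines <- apply(body, 1L, function(r) paste(formatC(r, format = "g", digits = 9),
                                             collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any conforming tool).
#' @return numeric matrix with `cell_size_km` attribute; NODATA becomes `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2]); names(vals) <- tolower(kv[, 1])
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (nrow(m) != vals["nrows"] || ncol(m) != vals["ncols"])
    stop("malformed ASCII grid: body does not match header dimensions")
  m[m == vals["nodata_value"]] <- NA
  attr(m, "cell_size_km") <- unname(vals["cellsize"])
  m
}

#' Write a predictor stack to a directory
#'
#' One ASCII grid per layer plus a JSON sidecar (`stack.json`) recording
#' layer names, cell size and the generating seed.
#'
#' @param stack a `predictor_stack`.
#' @param dir output directory (created if needed).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$layers))
    write_ascii_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                     cell_size_km = stack$cell_size_km)
  jsonlite::write_json(
    list(layer_names = names(stack$layers),
         n_rows = stack$n_rows, n_cols = stack$n_cols,
         cell_size_km = stack$cell_size_km, seed = stack$seed),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a predictor stack written by [write_stack()]
#'
#' @param dir directory containing `stack.json` and one `.asc` per layer.
#' @return a `predictor_stack`. Layers with mismatched grids are fatal.
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  layers <- lapply(meta$layer_names, function(nm) {
    m <- read_ascii_grid(file.path(dir, paste0(nm, ".asc")))
    if (!isTRUE(all.equal(attr(m, "cell_size_km"), meta$cell_size_km)))
      stop("layer '", nm, "' cell size disagrees with sidecar")
    m
  })
  names(layers) <- meta$layer_names
  predictor_stack(layers, meta$cell_size_km,
                  seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}
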