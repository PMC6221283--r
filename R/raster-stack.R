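#' Gridded multi-layer raster stack
#'
#' A `raster_stack` holds one or more named layers sharing a single grid
#' geometry: `nrows` x `ncols` cells of size `cellsize` (decimal degrees),
#' anchored at the lower-left corner (`xmin`, `ymin`) of the lower-left
#' cell (corner registration, the ESRI ASCII `xllcorner` convention). Layers
#' are stored as numeric matrices with row 1 the northernmost row, matching
#' the on-disk layout; missing cells are `NA` internally and are written out
#' as the `nodata` sentinel.
#'
#' @param layers A named list of numeric matrices with identical dimensions,
#'   or a single matrix (which gets the name `"layer"`).
#' @param xmin,ymin Coordinates of the outer lower-left corner, degrees.
#' @param cellsize Cell edge length in degrees; must be positive.
#' @param nodata Sentinel value used when writing to disk (default -9999).
#' @return An object of class `raster_stack`.
#' @export
#' @examples
#' r <- raster_stack(list(elev = matrix(1:6, 2, 3)), xmin = 0, ymin = 40,
#'                   cellsize = 0.5)
#' r
raster_stack <- function(layers, xmin = 0, ymin = 0, cellsize = 1,
                         nodata = -9999) {
  if (is.matrix(layers)) layers <- list(layer = layers)
  if (!is.list(layers) || length(layers) == 0) {
    abort("`layers` must be a non-empty named list of matrices.")
  }
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    abort("every layer must be named.")
  }
  dims <- vapply(layers, function(m) {
    if (!is.matrix(m) || !is.numeric(m)) abort("layers must be numeric matrices.")
    dim(m)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all layers must share identical dimensions.")
  }
  check_scalar_number(cellsize, "cellsize")
  if (cellsize <= 0) abort("`cellsize` must be > 0.")
  structure(
    list(layers = layers, nrows = dims[1, 1], ncols = dims[2, 1],
         xmin = xmin, ymin = ymin, cellsize = cellsize, nodata = nodata),
    class = "raster_stack"
  )
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layer(s), %d x %d cells, cellsize %g\n",
              length(x$layers), x$nrows, x$ncols, x$cellsize))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              x$xmin, x$xmin + x$ncols * x$cellsize,
              x$ymin, x$ymin + x$nrows * x$cellsize))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

is_raster_stack <- function(x) inherits(x, "raster_stack")

same_geometry <- function(a, b, tol = 1e-9) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b)) abort("raster geometries do not match.")
  invisible(TRUE)
}

#' Extract a single layer's matrix
#'
#' @param stack A [raster_stack()].
#' @param name Layer name; defaults to the first layer.
#' @return The layer's numeric matrix (row 1 = north).
#' @export
stack_layer <- function(stack, name = NULL) {
  stopifnot(is_raster_stack(stack))
  name <- name %||% names(stack$layers)[1]
  if (!name %in% names(stack$layers)) {
    abort(sprintf("no layer named '%s'.", name))
  }
  stack$layers[[name]]
}

#' Keep a subset of layers
#'
#' @param stack A [raster_stack()].
#' @param keep Character vector of layer names to retain, in that order.
#' @return A [raster_stack()] with only the requested layers.
#' @export
select_layers <- function(stack, keep) {
  stopifnot(is_raster_stack(stack))
  missing <- setdiff(keep, names(stack$layers))
  if (length(missing) > 0) {
    abort(paste0("unknown layer(s): ", paste(missing, collapse = ", ")))
  }
  out <- stack
  out$layers <- stack$layers[keep]
  out
}

# Map cell (r, c) [1-based, row 1 = north] to its center coordinates.
cell_center_lon <- function(stack, col) stack$xmin + (col - 0.5) * stack$cellsize
cell_center_lat <- function(stack, row) {
  stack$ymin + (stack$nrows - row + 0.5) * stack$cellsize
}

# Map lon/lat to (row, col); cells are half-open [x, x + s) x [y, y + s),
# so every in-extent point belongs to exactly one cell. Out-of-extent
# points get NA.
point_to_cell <- function(stack, lon, lat) {
  col <- floor((lon - stack$xmin) / stack$cellsize) + 1
  row_from_bottom <- floor((lat - stack$ymin) / stack$cellsize) + 1
  row <- stack$nrows - row_from_bottom + 1
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1 | col > stack$ncols | row < 1 | row > stack$nrows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Tabulate a raster stack cell by cell
#'
#' Converts a stack to a long-by-cell tibble with one row per grid cell and
#' one column per layer, plus cell indices and center coordinates. This is
#' the bridge from the gridded world to the tabular one: model fitting, PCA
#' and density estimation all consume this table.
#'
#' @param x A [raster_stack()].
#' @param drop_na Drop cells where any layer is `NA` (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `lon`, `lat`, then one column
#'   per layer.
#' @export
as_tibble.raster_stack <- function(x, drop_na = TRUE, ...) {
  rows <- rep(seq_len(x$nrows), times = x$ncols)
  cols <- rep(seq_len(x$ncols), each = x$nrows)
  out <- tibble(
    row = rows, col = cols,
    lon = cell_center_lon(x, cols),
    lat = cell_center_lat(x, rows)
  )
  for (nm in names(x$layers)) out[[nm]] <- as.vector(x$layers[[nm]])
  if (drop_na) {
    keep <- stats::complete.cases(out[names(x$layers)])
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Shift every layer of a stack by a per-layer additive offset
#'
#' Models an era-to-era climate change as a uniform additive shift per
#' bioclimatic layer (e.g. a glacial cooling of -5 on annual mean
#' temperature). Geometry and `NA` (nodata) cells are preserved.
#'
#' @param stack A [raster_stack()].
#' @param offsets Named or positional numeric vector, one offset per layer.
#' @return A new [raster_stack()] with shifted values.
#' @export
#' @examples
#' r <- raster_stack(list(bio1 = matrix(10, 2, 2), bio12 = matrix(500, 2, 2)))
#' shifted <- apply_era_shift(r, c(bio1 = -5, bio12 = -100))
apply_era_shift <- function(stack, offsets) {
  stopifnot(is_raster_stack(stack))
  k <- length(stack$layers)
  if (length(offsets) != k) {
    abort(sprintf("expected %d offsets (one per layer), got %d.",
                  k, length(offsets)))
  }
  if (!is.null(names(offsets))) {
    missing <- setdiff(names(stack$layers), names(offsets))
    if (length(missing) > 0) {
      abort(paste0("offsets missing for layer(s): ",
                   paste(missing, collapse = ", ")))
    }
    offsets <- offsets[names(stack$layers)]
  }
  out <- stack
  for (i in seq_len(k)) {
    out$layers[[i]] <- stack$layers[[i]] + offsets[[i]]
  }
  out
}
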