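#' Read an ESRI ASCII grid
#'
#' Parses the `.asc` dialect: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`; case-insensitive,
#' `NODATA_value` optional) followed by `nrows` rows of `ncols` whitespace-
#' separated numbers, the first row being the northernmost. Cells equal to
#' the nodata sentinel become `NA`. Center-registered files (`xllcenter`/
#' `yllcenter`) are rejected rather than silently reinterpreted.
#'
#' @param path Path to the `.asc` file.
#' @param name Layer name for the resulting stack; defaults to the file's
#'   base name without extension.
#' @return A single-layer [raster_stack()].
#' @export
read_ascii_grid <- function(path, name = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-+0-9.eE]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  if (any(c("xllcenter", "yllcenter") %in% names(hdr))) {
    abort(paste0("center-registered ASCII grid (xllcenter/yllcenter) is not ",
                 "supported; supply corner-registered (xllcorner) files."))
  }
  required <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(required, names(hdr))
  if (length(missing) > 0) {
    abort(paste0("malformed ASCII grid header in ", path,
                 "; missing: ", paste(missing, collapse = ", ")))
  }
  nrows <- as.integer(hdr$nrows)
  ncols <- as.integer(hdr$ncols)
  body <- lines[seq(i, length.out = length(lines) - i + 1)]
  if (length(body) != nrows) {
    abort(sprintf("expected %d data rows, found %d in %s.",
                  nrows, length(body), path))
  }
  vals <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (length(v) != ncols) {
      abort(sprintf("row with %d values, expected %d columns in %s.",
                    length(v), ncols, path))
    }
    if (anyNA(v)) abort(sprintf("non-numeric cell value in %s.", path))
    v
  })
  m <- do.call(rbind, vals)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA_real_
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  raster_stack(setNames(list(m), name),
               xmin = hdr$xllcorner, ymin = hdr$yllcorner,
               cellsize = hdr$cellsize, nodata = nodata)
}

#' Write a layer as an ESRI ASCII grid
#'
#' Values are written with full double precision (17 significant digits) so
#' that a write/read round trip is exact; `NA` cells are written as the
#' stack's nodata sentinel.
#'
#' @param stack A [raster_stack()].
#' @param path Output file path.
#' @param layer Layer name to write; defaults to the first layer.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(stack, path, layer = NULL) {
  stopifnot(is_raster_stack(stack))
  m <- stack_layer(stack, layer)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.17g\nyllcorner %.17g\ncellsize %.17g\nNODATA_value %.17g\n",
    stack$ncols, stack$nrows, stack$xmin, stack$ymin, stack$cellsize,
    stack$nodata)
  writeLines(hdr, con, sep = "")
  m[is.na(m)] <- stack$nodata
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Read a directory of ASCII grids as one aligned stack
#'
#' @param dir Directory containing `.asc` files, one per layer; layer names
#'   are the file base names.
#' @param layers Optional character vector restricting (and ordering) the
#'   layers to read.
#' @return A [raster_stack()]; errors if the grids are not aligned.
#' @export
read_stack <- function(dir, layers = NULL) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no .asc files in %s", dir))
  nms <- sub("\\.asc$", "", basename(files))
  if (!is.null(layers)) {
    missing <- setdiff(layers, nms)
    if (length(missing) > 0) {
      abort(paste0("layer file(s) not found: ", paste(missing, collapse = ", ")))
    }
    files <- files[match(layers, nms)]
    nms <- layers
  }
  stacks <- lapply(files, read_ascii_grid)
  base <- stacks[[1]]
  for (s in stacks[-1]) stop_if_geometry_differs(base, s)
  raster_stack(setNames(lapply(stacks, function(s) s$layers[[1]]), nms),
               xmin = base$xmin, ymin = base$ymin,
               cellsize = base$cellsize, nodata = base$nodata)
}

#' Write every layer of a stack as ASCII grids
#'
#' @param stack A [raster_stack()].
#' @param dir Output directory (created if needed); one `<layer>.asc` per
#'   layer.
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(is_raster_stack(stack))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    write_ascii_grid(stack, file.path(dir, paste0(nm, ".asc")), layer = nm)
  }
  invisible(dir)
}
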