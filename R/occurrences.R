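#' Read an occurrence table
#'
#' Reads a CSV with columns `taxon`, `lon`, `lat` (decimal degrees). Rows
#' with a blank or non-numeric coordinate are dropped with a warning giving
#' the count; exact duplicates are retained at this stage (per-pixel
#' thinning is a separate, geometry-aware step, see [dedupe_per_pixel()]).
#'
#' @param path CSV path with header `taxon,lon,lat` (extra columns ignored).
#' @return A tibble with columns `taxon`, `lon`, `lat`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("taxon", "lon", "lat")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("occurrence file must have columns taxon,lon,lat; missing: ",
                 paste(missing, collapse = ", ")))
  }
  raw$lon <- suppressWarnings(as.numeric(raw$lon))
  raw$lat <- suppressWarnings(as.numeric(raw$lat))
  ok <- !is.na(raw$lon) & !is.na(raw$lat) & nzchar(as.character(raw$taxon)) &
    is.finite(raw$lon) & is.finite(raw$lat)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warn(sprintf("dropped %d row(s) with missing or non-numeric coordinates.",
                 n_dropped))
  }
  out <- as_tibble(raw[ok, required, drop = FALSE])
  if (nrow(out) == 0) abort(sprintf("no valid occurrence rows in %s.", path))
  out
}

#' Write an occurrence table
#'
#' @param occ Tibble with columns `taxon`, `lon`, `lat`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  write.csv(occ, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Thin occurrences to one record per raster cell
#'
#' Spatial autocorrelation control: within each taxon, keeps the first-seen
#' record in every occupied grid cell of the supplied geometry and discards
#' the rest, so the model never sees the same pixel twice. Points outside
#' the raster extent are dropped (they occupy no cell).
#'
#' @param occ Tibble with columns `lon`, `lat` and optionally `taxon`.
#' @param stack A [raster_stack()] supplying the grid geometry.
#' @return A tibble of the same shape with at most one row per (taxon, cell);
#'   input order is preserved (first-seen wins), so the result is
#'   deterministic given the input order.
#' @export
dedupe_per_pixel <- function(occ, stack) {
  stopifnot(is_raster_stack(stack))
  if (nrow(occ) == 0) return(occ)
  cell <- point_to_cell(stack, occ$lon, occ$lat)
  key <- paste(cell$row, cell$col, sep = "_")
  inside <- !is.na(cell$row)
  taxon <- if ("taxon" %in% names(occ)) occ$taxon else ""
  keep <- inside & !duplicated(paste(taxon, key, sep = "@"))
  occ[keep, , drop = FALSE]
}

#' Extract layer values at points
#'
#' Looks up, for each point, the value of the containing cell in every layer.
#' Points outside the raster extent or falling on a nodata cell are flagged,
#' never silently dropped.
#'
#' @param stack A [raster_stack()].
#' @param points Tibble with columns `lon`, `lat` (other columns carried
#'   through).
#' @return A tibble: the input columns, then `inside` (logical), `on_nodata`
#'   (logical; `NA` values in any layer), and one column per layer (`NA`
#'   where flagged).
#' @export
extract_at_points <- function(stack, points) {
  stopifnot(is_raster_stack(stack))
  if (nrow(points) == 0) abort("empty point list.")
  cell <- point_to_cell(stack, points$lon, points$lat)
  out <- as_tibble(points)
  out$inside <- !is.na(cell$row)
  idx <- cbind(cell$row, cell$col)
  vals <- lapply(stack$layers, function(m) {
    v <- rep(NA_real_, nrow(points))
    v[out$inside] <- m[idx[out$inside, , drop = FALSE]]
    v
  })
  on_nodata <- out$inside & Reduce(`|`, lapply(vals, is.na))
  out$on_nodata <- on_nodata
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  out
}
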