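#' Rectangular geographic grid
#'
#' A `chs_grid` is the raster primitive used throughout the package: a
#' rectangular matrix of cell values plus an affine transform (lower-left
#' corner, square cell size) and a NoData convention. Row 1 of the value
#' matrix is the northernmost row, matching the on-disk layout of ESRI
#' ASCII grids. NoData cells are held as `NA` in memory and serialized as
#' the `nodata` sentinel.
#'
#' @param values numeric matrix; row 1 = north.
#' @param xll,yll coordinates of the lower-left corner of the grid
#'   (degrees for geographic grids).
#' @param cellsize cell edge length (degrees, or map units for planar
#'   grids).
#' @param crs_label free-text CRS tag; `"WGS84"` (default) marks a
#'   geographic lon/lat grid, `"planar"` a projected/abstract grid.
#' @param nodata sentinel written to disk for `NA` cells.
#' @return an object of class `chs_grid`.
#' @export
grid_create <- function(values, xll, yll, cellsize, crs_label = "WGS84",
                        nodata = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("grid values must be numeric")
  if (any(!is.na(values) & values == nodata))
    stop("nodata sentinel collides with a data value")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         crs_label = crs_label, nodata = nodata),
    class = "chs_grid"
  )
}

#' @export
print.chs_grid <- function(x, ...) {
  cat(sprintf("<chs_grid> %d x %d cells, cellsize %g, origin (%g, %g), crs %s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              x$crs_label))
  v <- x$values[!is.na(x$values)]
  if (length(v)) cat(sprintf("  values: [%g, %g], %d NoData cells\n",
                             min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

grid_nrow <- function(grid) nrow(grid$values)
grid_ncol <- function(grid) ncol(grid$values)

#' Grid extent
#'
#' @param grid a `chs_grid`.
#' @return named numeric vector `xmin, xmax, ymin, ymax`.
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$xll, xmax = grid$xll + grid_ncol(grid) * grid$cellsize,
    ymin = grid$yll, ymax = grid$yll + grid_nrow(grid) * grid$cellsize)
}

#' Cell-center coordinates
#'
#' @param grid a `chs_grid`.
#' @param cells optional integer vector of cell indices (column-major over
#'   the value matrix); default all cells.
#' @return matrix with columns `lon`, `lat` (cell centers).
#' @export
grid_cell_centers <- function(grid, cells = NULL) {
  nr <- grid_nrow(grid); nc <- grid_ncol(grid)
  if (is.null(cells)) cells <- seq_len(nr * nc)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  lon <- grid$xll + (col - 0.5) * grid$cellsize
  lat <- grid$yll + (nr - row + 0.5) * grid$cellsize
  cbind(lon = lon, lat = lat)
}

#' Map points to cell indices
#'
#' Uses the half-open convention in which a cell contains its top and left
#' edges (a point exactly on a shared edge belongs to the cell for which
#' that edge is the top or left one). Points outside the extent map to
#' `NA`.
#'
#' @param grid a `chs_grid`.
#' @param lon,lat point coordinates.
#' @return integer vector of column-major cell indices (`NA` outside).
#' @export
grid_cell_index <- function(grid, lon, lat) {
  nr <- grid_nrow(grid); nc <- grid_ncol(grid)
  ytop <- grid$yll + nr * grid$cellsize
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row <- floor((ytop - lat) / grid$cellsize) + 1
  bad <- col < 1 | col > nc | row < 1 | row > nr | is.na(lon) | is.na(lat)
  idx <- (col - 1) * nr + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

same_geometry <- function(a, b, tol = 1e-9) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Multi-layer grid stack
#'
#' Bundles named, co-registered layers. Construction fails if any layer
#' disagrees with the first in shape or transform beyond 1e-9.
#'
#' @param layers named list of `chs_grid` objects.
#' @return an object of class `chs_stack`.
#' @export
stack_create <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named")
  ref <- layers[[1]]
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "chs_grid"))
      stop("layer '", nm, "' is not a chs_grid")
    if (!same_geometry(ref, layers[[nm]]))
      stop("layer '", nm, "' is not co-registered with layer '",
           names(layers)[1], "'")
  }
  structure(list(layers = layers), class = "chs_stack")
}

#' @export
print.chs_stack <- function(x, ...) {
  ref <- x$layers[[1]]
  cat(sprintf("<chs_stack> %d layers, %d x %d cells: %s\n",
              length(x$layers), nrow(ref$values), ncol(ref$values),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.chs_stack <- function(x) names(x$layers)

stack_ref <- function(stack) stack$layers[[1]]

#' Combined valid-data mask of a stack
#'
#' @param stack a `chs_stack`.
#' @return logical matrix, `TRUE` where every layer has data.
#' @export
stack_valid_mask <- function(stack) {
  m <- !is.na(stack$layers[[1]]$values)
  for (g in stack$layers[-1]) m <- m & !is.na(g$values)
  m
}

#' Extract layer values at points
#'
#' Containing-cell (nearest-cell) lookup of every stack layer at a set of
#' points, using the same cell-containment convention as
#' [grid_cell_index()].
#'
#' @param stack a `chs_stack`.
#' @param lon,lat point coordinates.
#' @return data frame with one column per layer plus `cell` (index) and
#'   `nodata` (flag: point outside the extent or on a cell where any layer
#'   lacks data).
#' @export
extract_values <- function(stack, lon, lat) {
  ref <- stack_ref(stack)
  cell <- grid_cell_index(ref, lon, lat)
  out <- data.frame(cell = cell)
  for (nm in names(stack$layers)) {
    v <- rep(NA_real_, length(cell))
    ok <- !is.na(cell)
    v[ok] <- stack$layers[[nm]]$values[cell[ok]]
    out[[nm]] <- v
  }
  out$nodata <- is.na(cell) |
    Reduce(`|`, lapply(names(stack$layers), function(nm) is.na(out[[nm]])))
  out
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param crs_label CRS tag to attach; ASCII grids carry no CRS, so a
#'   missing tag yields a warning and `"unknown"`.
#' @return a `chs_grid`.
#' @export
read_ascii_grid <- function(path, crs_label = NULL) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2]); n_hdr <- n_hdr + 1
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header: missing ", k)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (is.null(crs_label)) {
    warning("ASCII grid carries no CRS; tagging as 'unknown'")
    crs_label <- "unknown"
  }
  grid_create(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
              crs_label = crs_label, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Values are written at full double precision (`%.17g`) so a write/read
#' round-trip is lossless.
#'
#' @param grid a `chs_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid_ncol(grid)),
    sprintf("nrows %d", grid_nrow(grid)),
    sprintf("xllcorner %.17g", grid$xll),
    sprintf("yllcorner %.17g", grid$yll),
    sprintf("cellsize %.17g", grid$cellsize),
    sprintf("NODATA_value %.17g", grid$nodata)
  ), con)
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), con)
  invisible(path)
}

#' Load and validate an occurrence table
#'
#' Reads a CSV of presence points, keeps only rows with complete,
#' parseable coordinates, collapses exact-duplicate coordinate pairs, and
#' drops points outside the grid extent (count reported via `message`).
#'
#' @param path CSV with `lon`/`lat` (or `longitude`/`latitude`) columns.
#' @param grid a `chs_grid` defining the admissible extent; `NULL` skips
#'   the extent filter.
#' @return data frame with columns `species` (if present in the file),
#'   `lon`, `lat`; class `chs_occurrences`.
#' @export
load_occurrences <- function(path, grid = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if ("longitude" %in% names(df)) names(df)[names(df) == "longitude"] <- "lon"
  if ("latitude" %in% names(df)) names(df)[names(df) == "latitude"] <- "lat"
  if (!all(c("lon", "lat") %in% names(df)))
    stop("occurrence file needs lon/lat columns")
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  keep <- !is.na(lon) & !is.na(lat)
  n_bad <- sum(!keep)
  df <- df[keep, , drop = FALSE]; lon <- lon[keep]; lat <- lat[keep]
  dup <- duplicated(cbind(lon, lat))
  df <- df[!dup, , drop = FALSE]; lon <- lon[!dup]; lat <- lat[!dup]
  n_out <- 0
  if (!is.null(grid)) {
    ext <- grid_extent(grid)
    inside <- lon >= ext["xmin"] & lon < ext["xmax"] &
      lat > ext["ymin"] & lat <= ext["ymax"]
    n_out <- sum(!inside)
    df <- df[inside, , drop = FALSE]; lon <- lon[inside]; lat <- lat[inside]
  }
  if (nrow(df) == 0) stop("no valid occurrence points after cleaning")
  if (n_bad + sum(dup) + n_out > 0)
    message(sprintf(
      "occurrences: dropped %d incomplete, %d duplicate, %d out-of-extent rows",
      n_bad, sum(dup), n_out))
  out <- data.frame(
    species = if ("species" %in% names(df)) df$species else "species",
    lon = lon, lat = lat, stringsAsFactors = FALSE)
  class(out) <- c("chs_occurrences", "data.frame")
  out
}

#' Write an occurrence table
#'
#' @param occ data frame with `species`, `lon`, `lat`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[, c("species", "lon", "lat")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
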