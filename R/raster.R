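#' Georeferenced raster grid
#'
#' A minimal single-band raster container: a numeric matrix of cell values
#' (row 1 is the northernmost row), a square cell size, the coordinates of
#' the grid origin (west edge, north edge) and a CRS label. `NA` cells are
#' nodata. Cells follow the half-open convention: cell (i, j) spans
#' `[xmin + (j-1)*cs, xmin + j*cs)` in x and `(ymax - i*cs, ymax - (i-1)*cs]`
#' in y, so a point exactly on a shared edge belongs to the cell on its
#' right / below.
#'
#' @param values numeric matrix of cell values; `NA` marks nodata.
#' @param xmin x coordinate of the western grid edge.
#' @param ymax y coordinate of the northern grid edge.
#' @param cellsize cell edge length (cells are square), in CRS units.
#' @param crs free-form CRS label (e.g. `"EPSG:32632"`).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymax = nrow(values) * cellsize,
                        cellsize = 1, crs = "local") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         cellsize = as.numeric(cellsize), crs = as.character(crs)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d rows x %d cols, cellsize %g, crs %s\n",
              nrow(v), ncol(v), x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymax - nrow(v) * x$cellsize, x$ymax))
  ok <- !is.na(v)
  cat(sprintf("  cells: %d (%d nodata); range [%g, %g]\n",
              length(v), sum(!ok),
              suppressWarnings(min(v[ok])), suppressWarnings(max(v[ok]))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell index arithmetic
#'
#' `grid_rowcol` maps coordinates to (row, col) indices under the half-open
#' cell convention; points outside the grid get `NA`. `grid_xy` returns the
#' centroid coordinates of the given (row, col) pairs. `grid_centroids`
#' returns centroids of all cells (optionally only non-nodata ones).
#'
#' @param grid a [raster_grid()].
#' @param x,y coordinate vectors.
#' @return `grid_rowcol`: a two-column integer matrix `(row, col)`.
#' @export
grid_rowcol <- function(grid, x, y) {
  cs <- grid$cellsize
  col <- floor((x - grid$xmin) / cs) + 1
  row <- floor((grid$ymax - y) / cs) + 1
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  bad <- !is.finite(row) | !is.finite(col) | row < 1 | row > nr | col < 1 | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname grid_rowcol
#' @param row,col cell indices.
#' @export
grid_xy <- function(grid, row, col) {
  cs <- grid$cellsize
  cbind(x = grid$xmin + (col - 0.5) * cs,
        y = grid$ymax - (row - 0.5) * cs)
}

#' @rdname grid_rowcol
#' @param na_omit drop nodata cells.
#' @export
grid_centroids <- function(grid, na_omit = TRUE) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  idx <- which(if (na_omit) !is.na(grid$values) else rep(TRUE, nr * nc))
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  cbind(grid_xy(grid, row, col), cell = idx)
}

#' Extract raster values at point locations
#'
#' @param grid a [raster_grid()].
#' @param x,y point coordinates (same CRS as the grid).
#' @return numeric vector; `NA` for points outside the grid or on nodata.
#' @export
grid_extract <- function(grid, x, y) {
  rc <- grid_rowcol(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- grid$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south). The CRS
#' label is kept in a sidecar `<path>.prj` text file since the format has no
#' CRS slot.
#'
#' @param grid a [raster_grid()].
#' @param path file path (conventionally `.asc`).
#' @param nodata value standing in for `NA` cells on disk.
#' @return `read_asc` returns a [raster_grid()]; `write_asc` returns `path`
#'   invisibly.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  v <- grid$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymax - nrow(v) * grid$cellsize),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(grid$crs, paste0(path, ".prj"))
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) stop("ASC body size does not match header")
  v <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  prj <- paste0(path, ".prj")
  crs <- if (file.exists(prj)) readLines(prj, n = 1L) else "local"
  raster_grid(v, xmin = hdr$xllcorner,
              ymax = hdr$yllcorner + nr * hdr$cellsize,
              cellsize = hdr$cellsize, crs = crs)
}
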