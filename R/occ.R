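#' Presence records
#'
#' A thin data-frame wrapper for presence-only occurrence records with
#' columns `id`, `x`, `y`, `source`, plus a CRS label and a flag saying
#' whether the set has been deduplicated to one record per grid cell.
#'
#' @param df data frame with columns `id`, `x`, `y`, `source`.
#' @param crs CRS label of the coordinates.
#' @param gridded whether the set is already one-per-cell (see
#'   [dedup_to_grid()]).
#' @return An object of classes `occurrence_set` and `data.frame`.
#' @export
occurrence_set <- function(df, crs = "local", gridded = FALSE) {
  need <- c("id", "x", "y", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (nrow(df) > 0 && (!all(is.finite(df$x)) || !all(is.finite(df$y))))
    stop("coordinates must be finite")
  structure(df, crs = crs, gridded = gridded,
            class = c("occurrence_set", "data.frame"))
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d records, crs %s%s\n", nrow(x),
              attr(x, "crs"), if (isTRUE(attr(x, "gridded"))) ", gridded" else ""))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Read occurrence records from CSV or GeoJSON
#'
#' CSV must have columns `id,x,y,source` (missing `id`/`source` are filled).
#' GeoJSON: `Point`/`MultiPoint` features; `id` and `source` are taken from
#' feature properties when present.
#'
#' @param path file path (`.csv`, `.json` or `.geojson`).
#' @param crs CRS label to attach.
#' @export
read_occurrences <- function(path, crs = "local") {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(df$id)) df$id <- seq_len(nrow(df))
    if (is.null(df$source)) df$source <- "unknown"
    return(occurrence_set(df, crs = crs))
  }
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  rows <- list()
  for (f in feats) {
    geom <- f$geometry %||% f
    props <- f$properties %||% list()
    coords <- if (identical(geom$type, "Point")) list(geom$coordinates)
              else if (identical(geom$type, "MultiPoint")) geom$coordinates
              else stop("unsupported geometry type: ", geom$type)
    for (c0 in coords)
      rows[[length(rows) + 1L]] <- data.frame(
        id = as.character(props$id %||% (length(rows) + 1L)),
        x = as.numeric(c0[[1]]), y = as.numeric(c0[[2]]),
        source = as.character(props$source %||% "geojson"))
  }
  occurrence_set(do.call(rbind, rows), crs = crs)
}

#' Deduplicate occurrences to one record per grid cell
#'
#' Implements the standardized-sampling step: exact duplicate raw records
#' (identical coordinates and source) are collapsed, each remaining record
#' is assigned to its grid cell under the half-open cell convention, points
#' outside the grid or on nodata cells are dropped (with a message), and
#' the centroid of each occupied cell is retained as a single
#' representative record.
#'
#' @param occ an [occurrence_set()].
#' @param grid a [raster_grid()] defining the analysis grid (e.g. 1-km
#'   cells); its nodata cells are treated as outside the study area.
#' @param crs_check error if the occurrence CRS label differs from the
#'   grid's (no reprojection is attempted).
#' @return A gridded [occurrence_set()] with one record per occupied cell,
#'   located at cell centroids; `id` and `source` are taken from the first
#'   record falling in the cell.
#' @export
dedup_to_grid <- function(occ, grid, crs_check = TRUE) {
  if (crs_check && !identical(attr(occ, "crs"), grid$crs) &&
      !identical(attr(occ, "crs"), "local") && !identical(grid$crs, "local"))
    stop("CRS mismatch: occurrences are ", attr(occ, "crs"),
         " but grid is ", grid$crs, " (reproject the inputs)")
  df <- as.data.frame(occ)
  if (nrow(df) == 0)
    return(occurrence_set(df, crs = grid$crs, gridded = TRUE))
  df <- df[!duplicated(df[c("x", "y", "source")]), , drop = FALSE]
  rc <- grid_rowcol(grid, df$x, df$y)
  cell <- (rc[, 2] - 1L) * nrow(grid$values) + rc[, 1]
  inside <- !is.na(cell) & !is.na(grid$values[pmax(cell, 1L, na.rm = TRUE)])
  n_drop <- sum(!inside)
  if (n_drop > 0)
    message(n_drop, " record(s) outside the grid or on nodata cells dropped")
  df <- df[inside, , drop = FALSE]
  cell <- cell[inside]
  keep <- !duplicated(cell)
  df <- df[keep, , drop = FALSE]
  cell <- cell[keep]
  nr <- nrow(grid$values)
  xy <- grid_xy(grid, ((cell - 1L) %% nr) + 1L, ((cell - 1L) %/% nr) + 1L)
  out <- data.frame(id = df$id, x = xy[, 1], y = xy[, 2], source = df$source)
  occurrence_set(out, crs = grid$crs, gridded = TRUE)
}

# Even-odd ray casting; a point on an edge or vertex counts as inside.
# ring: 2-column matrix of vertices (closed or open).
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
  xs <- ring[, 1]; ys <- ring[, 2]
  out <- logical(length(px))
  for (i in seq_along(px)) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    on_edge <- FALSE
    j <- n
    for (k in seq_len(n)) {
      x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[k]; y2 <- ys[k]
      # boundary test: collinear and within segment bounding box
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-12 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12) {
        on_edge <- TRUE
        break
      }
      if ((y1 > y) != (y2 > y) &&
          x < x1 + (y - y1) * (x2 - x1) / (y2 - y1))
        inside <- !inside
      j <- k
    }
    out[i] <- on_edge || inside
  }
  out
}

#' Read polygons from GeoJSON
#'
#' Supports `Polygon` and `MultiPolygon` features. Interior rings (holes)
#' are honoured by even-odd counting in [protection_summary()].
#'
#' @param path GeoJSON file path.
#' @return A list of polygons; each polygon is a list of rings, each ring a
#'   2-column coordinate matrix.
#' @export
read_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  polys <- list()
  ring_mat <- function(r) do.call(rbind, lapply(r, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  for (f in feats) {
    geom <- f$geometry %||% f
    if (identical(geom$type, "Polygon")) {
      polys[[length(polys) + 1L]] <- lapply(geom$coordinates, ring_mat)
    } else if (identical(geom$type, "MultiPolygon")) {
      for (pg in geom$coordinates)
        polys[[length(polys) + 1L]] <- lapply(pg, ring_mat)
    } else stop("unsupported geometry type: ", geom$type)
  }
  polys
}

points_in_polygons <- function(px, py, polygons) {
  inside <- rep(FALSE, length(px))
  for (pg in polygons) {
    rings <- if (is.matrix(pg)) list(pg) else pg
    crossings <- rep(0L, length(px))
    for (r in rings)
      crossings <- crossings + as.integer(point_in_ring(px, py, r))
    # even-odd across rings: inside the outer ring but also inside a hole
    # (2 hits) -> outside
    inside <- inside | (crossings %% 2L == 1L)
  }
  inside
}

#' Protection status of occurrence records
#'
#' Overlays records with protected-area polygons (e.g. Natura 2000 sites)
#' and tabulates, per group and overall, how many records fall outside any
#' polygon. A point on a polygon boundary counts as protected.
#'
#' @param occ an [occurrence_set()].
#' @param polygons polygons as returned by [read_polygons()] (possibly
#'   empty: then all records are unprotected).
#' @param groups optional character vector, one group label per record
#'   (e.g. country); default puts everything in one group.
#' @return A data frame of class `protection_summary` with columns `group`,
#'   `n_total`, `n_unprotected`, `pct_unprotected` (percentage rounded to
#'   integer), ending with an `Overall` row.
#' @export
protection_summary <- function(occ, polygons = list(), groups = NULL) {
  n <- nrow(occ)
  if (is.null(groups)) groups <- rep("All", n)
  if (length(groups) != n) stop("`groups` must have one label per record")
  prot <- if (length(polygons) == 0) rep(FALSE, n)
          else points_in_polygons(occ$x, occ$y, polygons)
  tab <- function(sel, label) {
    nt <- sum(sel); nu <- sum(sel & !prot)
    data.frame(group = label, n_total = nt, n_unprotected = nu,
               pct_unprotected = ifelse(nt > 0, round(100 * nu / nt), NA))
  }
  out <- do.call(rbind, lapply(unique(groups),
                               function(g) tab(groups == g, g)))
  out <- rbind(out, tab(rep(TRUE, n), "Overall"))
  class(out) <- c("protection_summary", "data.frame")
  out
}

#' @export
print.protection_summary <- function(x, ...) {
  cat("Protection status (records outside protected areas):\n")
  df <- as.data.frame(x)
  df$pct_unprotected <- sprintf("%d%%", df$pct_unprotected)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write occurrences as CSV
#' @param occ an [occurrence_set()].
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}
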