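#' Named stack of grid-aligned predictor layers
#'
#' Holds continuous (bioclim-style, topographic) and categorical (e.g. soil
#' class) predictor layers sharing one grid geometry and one nodata mask:
#' a cell that is nodata in any layer is set to nodata in all of them.
#' Categorical layers hold integer class codes.
#'
#' @param layers named list of [raster_grid()] objects on identical geometry.
#' @param kind named character vector, `"continuous"` or `"categorical"` per
#'   layer; defaults to all continuous.
#' @return An object of class `env_stack` with elements `layers` (named list
#'   of value matrices), `kind`, and `grid` (a [raster_grid()] carrying the
#'   shared geometry and mask; its values are 1 on data cells, `NA` on
#'   nodata).
#' @export
env_stack <- function(layers, kind = NULL) {
  if (length(layers) == 0) stop("need at least one layer")
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must have unique names")
  g1 <- layers[[1]]
  for (l in layers) {
    if (!inherits(l, "raster_grid")) stop("each layer must be a raster_grid")
    if (!same_geometry(l, g1)) stop("all layers must share grid geometry")
  }
  if (is.null(kind)) kind <- stats::setNames(rep("continuous", length(layers)), nm)
  kind <- kind[nm]
  if (any(is.na(kind)) || !all(kind %in% c("continuous", "categorical")))
    stop("`kind` must map every layer to 'continuous' or 'categorical'")
  vals <- lapply(layers, `[[`, "values")
  mask <- Reduce(`|`, lapply(vals, is.na))
  vals <- lapply(vals, function(v) { v[mask] <- NA_real_; v })
  for (n in nm[kind == "categorical"]) vals[[n]] <- round(vals[[n]])
  gv <- matrix(1, nrow(g1$values), ncol(g1$values))
  gv[mask] <- NA_real_
  structure(list(layers = vals, kind = kind,
                 grid = raster_grid(gv, g1$xmin, g1$ymax, g1$cellsize, g1$crs)),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers on %d x %d grid (cellsize %g, crs %s)\n",
              length(x$layers), nrow(x$grid$values), ncol(x$grid$values),
              x$grid$cellsize, x$grid$crs))
  for (n in names(x$layers)) {
    v <- x$layers[[n]]
    cat(sprintf("  %-12s %-11s [%g, %g]\n", n, x$kind[n],
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(x)
}

layer_names <- function(stack) names(stack$layers)

#' Get one layer as a raster_grid
#' @param stack an [env_stack()].
#' @param name layer name.
#' @export
stack_layer <- function(stack, name) {
  if (!name %in% names(stack$layers)) stop("unknown layer: ", name)
  g <- stack$grid
  raster_grid(stack$layers[[name]], g$xmin, g$ymax, g$cellsize, g$crs)
}

#' Predictor values at point locations
#'
#' @param stack an [env_stack()].
#' @param x,y point coordinates, or `cells` linear cell indices.
#' @param cells optional linear cell indices into the grid matrix (column
#'   major), used instead of coordinates.
#' @return data frame with one column per layer, one row per point.
#' @export
stack_extract <- function(stack, x = NULL, y = NULL, cells = NULL) {
  if (is.null(cells)) {
    rc <- grid_rowcol(stack$grid, x, y)
    nr <- nrow(stack$grid$values)
    cells <- ifelse(is.na(rc[, 1]), NA_integer_,
                    (rc[, 2] - 1L) * nr + rc[, 1])
  }
  out <- lapply(stack$layers, function(v) {
    r <- rep(NA_real_, length(cells))
    ok <- !is.na(cells)
    r[ok] <- v[cells[ok]]
    r
  })
  as.data.frame(out)
}

#' Keep a subset of layers
#' @param stack an [env_stack()].
#' @param names layer names to keep.
#' @export
stack_subset <- function(stack, names) {
  miss <- setdiff(names, base::names(stack$layers))
  if (length(miss)) stop("unknown layer(s): ", paste(miss, collapse = ", "))
  g <- stack$grid
  layers <- lapply(names, function(n)
    raster_grid(stack$layers[[n]], g$xmin, g$ymax, g$cellsize, g$crs))
  base::names(layers) <- names
  env_stack(layers, kind = stack$kind[names])
}

#' Write every layer of a stack as ESRI ASCII grids
#'
#' One `<name>.asc` per layer plus a `manifest.csv` recording layer names,
#' kinds and file names.
#'
#' @param stack an [env_stack()].
#' @param dir output directory (created if missing).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (n in names(stack$layers)) {
    f <- file.path(dir, paste0(n, ".asc"))
    write_asc(stack_layer(stack, n), f)
    files <- c(files, basename(f))
  }
  utils::write.csv(
    data.frame(name = names(stack$layers), kind = unname(stack$kind),
               file = files),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a stack from a manifest of ASCII grids
#' @param manifest path to a `manifest.csv` written by [write_stack()], or a
#'   data frame with columns `name`, `kind`, `file` (paths relative to the
#'   manifest's directory).
#' @export
read_stack <- function(manifest) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else {
    dir <- "."
    m <- manifest
  }
  layers <- lapply(seq_len(nrow(m)), function(i) {
    p <- m$file[i]
    if (!file.exists(p)) p <- file.path(dir, m$file[i])
    read_asc(p)
  })
  names(layers) <- m$name
  env_stack(layers, kind = stats::setNames(m$kind, m$name))
}
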