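#' Resample heterogeneous source rasters onto a common study grid
#'
#' Continuous layers are resampled bilinearly (values interpolated between
#' the four surrounding source cell centers, clamped at the source edges);
#' categorical layers take the value of the source cell containing the
#' target cell center (nearest neighbour). Nodata masks of all layers are
#' unioned by [env_stack()].
#'
#' @param sources named list of [raster_grid()] objects, any geometry.
#' @param target a [raster_grid()] defining the output geometry.
#' @param kind named character vector (`"continuous"`/`"categorical"`) per
#'   source; default all continuous.
#' @return An [env_stack()] on the target geometry.
#' @export
resample_stack <- function(sources, target, kind = NULL) {
  if (is.null(kind))
    kind <- stats::setNames(rep("continuous", length(sources)), names(sources))
  ctr <- grid_centroids(target, na_omit = FALSE)
  nr <- nrow(target$values); nc <- ncol(target$values)
  layers <- lapply(names(sources), function(nm) {
    src <- sources[[nm]]
    if (is.null(src$crs) || !nzchar(src$crs))
      stop("source layer ", nm, " has no CRS")
    v <- if (kind[[nm]] == "categorical")
      grid_extract(src, ctr[, "x"], ctr[, "y"])
    else
      bilinear_sample(src, ctr[, "x"], ctr[, "y"])
    m <- matrix(NA_real_, nr, nc)
    m[ctr[, "cell"]] <- v
    m[is.na(target$values)] <- NA_real_
    raster_grid(m, target$xmin, target$ymax, target$cellsize, target$crs)
  })
  names(layers) <- names(sources)
  env_stack(layers, kind = kind)
}

# Bilinear interpolation between source cell centers; positions beyond the
# outermost centers are clamped (constant extrapolation). NA corners get
# weight 0 with renormalization; all-NA neighbourhoods give NA.
bilinear_sample <- function(src, x, y) {
  cs <- src$cellsize
  nr <- nrow(src$values); nc <- ncol(src$values)
  # fractional column/row position relative to cell centers
  fc <- (x - src$xmin) / cs + 0.5
  fr <- (src$ymax - y) / cs + 0.5
  c0 <- pmin(pmax(floor(fc), 1), nc - 1); r0 <- pmin(pmax(floor(fr), 1), nr - 1)
  if (nc == 1) c0 <- rep(1, length(x))
  if (nr == 1) r0 <- rep(1, length(y))
  tx <- pmin(pmax(fc - c0, 0), 1)
  ty <- pmin(pmax(fr - r0, 0), 1)
  c1 <- pmin(c0 + 1, nc); r1 <- pmin(r0 + 1, nr)
  v00 <- src$values[cbind(r0, c0)]; v01 <- src$values[cbind(r0, c1)]
  v10 <- src$values[cbind(r1, c0)]; v11 <- src$values[cbind(r1, c1)]
  w00 <- (1 - tx) * (1 - ty); w01 <- tx * (1 - ty)
  w10 <- (1 - tx) * ty;       w11 <- tx * ty
  W <- cbind(w00, w01, w10, w11)
  V <- cbind(v00, v01, v10, v11)
  W[is.na(V)] <- 0
  V[is.na(V)] <- 0
  tot <- rowSums(W)
  out <- rowSums(W * V) / tot
  out[tot == 0] <- NA_real_
  # points outside the source extent entirely
  outside <- x < src$xmin | x > src$xmin + nc * cs |
             y > src$ymax | y < src$ymax - nr * cs
  out[outside] <- NA_real_
  out
}

#' Iterative collinearity-driven predictor selection
#'
#' Computes the Pearson correlation matrix of the continuous layers over a
#' sample of landscape cells and, while any pair exceeds `threshold` in
#' absolute value, removes — among the variables involved in at least one
#' violating pair and not protected by `priority` — the variable with the
#' highest mean absolute correlation to the other remaining variables, then
#' recomputes and repeats. Categorical layers are exempt (Pearson
#' correlation is undefined for nominal codes) and always kept. Variance
#' inflation factors of the final set are reported as a secondary check.
#'
#' @param stack an [env_stack()].
#' @param points optional data frame with `x`, `y` sample locations; by
#'   default a fixed seeded random sample of up to `n_sample` non-nodata
#'   cells.
#' @param threshold pairwise `|r|` cut-off (default 0.7).
#' @param priority variables never removed; if two priority variables
#'   violate the threshold with each other this is an irreducible conflict
#'   and an error.
#' @param n_sample,seed size and seed of the default cell sample.
#' @param vif_warn warn if any final VIF is at or above this (default 5).
#' @return A `selection_report`: `kept` (ordered layer names, categorical
#'   last), `removed` (data frame: name, mean `|r|` at removal), `corr`
#'   (final correlation matrix), `vif` (named vector).
#' @export
correlation_select <- function(stack, points = NULL, threshold = 0.7,
                               priority = character(), n_sample = 10000,
                               seed = 1, vif_warn = 5) {
  cont <- names(stack$layers)[stack$kind == "continuous"]
  cats <- names(stack$layers)[stack$kind == "categorical"]
  if (!all(priority %in% cont))
    stop("`priority` must name continuous layers of the stack")
  vals <- sample_stack_values(stack, points, n_sample, seed)[cont]
  if (nrow(vals) < 3) stop("need at least 3 sample locations")

  keep <- cont
  removed <- data.frame(name = character(0), mean_abs_r = numeric(0))
  repeat {
    if (length(keep) < 2) break
    cm <- stats::cor(vals[keep])
    a <- abs(cm); diag(a) <- 0
    viol <- which(a > threshold, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    involved <- unique(keep[viol[, 1]])
    candidates <- setdiff(involved, priority)
    if (length(candidates) == 0) {
      pairs <- unique(t(apply(viol, 1, sort)))
      stop("irreducible conflict: priority variables violate the threshold: ",
           paste(apply(pairs, 1, function(p)
             paste(keep[p], collapse = "~")), collapse = ", "))
    }
    mean_r <- (rowSums(a) / (length(keep) - 1))[candidates]
    worst <- max(mean_r)
    pick <- sort(names(mean_r)[mean_r >= worst - 1e-12], decreasing = TRUE)[1]
    removed <- rbind(removed,
                     data.frame(name = pick, mean_abs_r = mean_r[[pick]]))
    keep <- setdiff(keep, pick)
  }
  final_corr <- if (length(keep) >= 2) stats::cor(vals[keep]) else
    diag(length(keep))
  vifs <- vif_scores(vals[keep])
  if (any(is.finite(vifs) & vifs >= vif_warn) || any(is.infinite(vifs)))
    warning("VIF at or above ", vif_warn, " for: ",
            paste(names(vifs)[vifs >= vif_warn], collapse = ", "))
  structure(list(kept = c(keep, cats), removed = removed,
                 corr = final_corr, vif = vifs, threshold = threshold,
                 priority = priority),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Collinearity selection (|r| < %g): kept %d, removed %d\n",
              x$threshold, length(x$kept), nrow(x$removed)))
  cat("  kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$removed) > 0) {
    cat("  removal order (mean |r| at removal):\n")
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("    %d. %s (%.3f)\n", i, x$removed$name[i],
                  x$removed$mean_abs_r[i]))
  }
  cat("  VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                      collapse = ", "), "\n")
  invisible(x)
}

sample_stack_values <- function(stack, points, n_sample, seed) {
  if (!is.null(points)) return(stack_extract(stack, points$x, points$y))
  cells <- which(!is.na(stack$grid$values))
  if (length(cells) > n_sample)
    cells <- with_seed(seed, sort(sample(cells, n_sample)))
  stack_extract(stack, cells = cells)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from an ordinary least-squares regression of
#' predictor `j` on all the other predictors. Perfect collinearity is
#' reported as `Inf` with a warning.
#'
#' @param values data frame of continuous predictor values (one column per
#'   predictor, one row per sample location).
#' @return Named numeric vector of VIFs (a single predictor gives VIF 1).
#' @export
vif_scores <- function(values) {
  values <- as.data.frame(values)
  p <- ncol(values)
  if (p == 0) return(stats::setNames(numeric(0), character(0)))
  if (nrow(values) < p + 2) stop("need at least `ncol + 2` sample locations")
  out <- stats::setNames(rep(1, p), names(values))
  if (p == 1) return(out)
  for (j in seq_len(p)) {
    fit <- stats::lm(values[[j]] ~ ., data = values[-j])
    r2 <- suppressWarnings(summary(fit))$r.squared  # lm warns on perfect fits
    if (r2 > 1 - 1e-10) {
      warning("perfect collinearity for ", names(values)[j])
      out[j] <- Inf
    } else out[j] <- 1 / (1 - r2)
  }
  out
}

#' Write a selection report to CSV and JSON
#' @param report a [correlation_select()] result.
#' @param dir output directory.
#' @export
write_selection_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(variable = report$kept,
                              vif = unname(report$vif[report$kept])),
                   file.path(dir, "selected_variables.csv"), row.names = FALSE)
  utils::write.csv(report$removed, file.path(dir, "removed_variables.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(kept = report$kept, removed = report$removed,
         corr = report$corr, vif = as.list(report$vif),
         threshold = report$threshold, priority = report$priority),
    file.path(dir, "selection_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
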