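#' Suitability thresholds from training-presence predictions
#'
#' Three standard presence-only thresholds: the Minimum Training Presence
#' (MTP), the lowest prediction at any training presence; the 10th
#' Percentile Training Presence (P10), the value below which 10% of the
#' training presence predictions fall (linear interpolation between order
#' statistics); and the fixed threshold `1 - 1/e ~ 0.632`, the cloglog
#' value of a cell expected to hold one individual.
#'
#' @param pred_at_presences cloglog predictions at the training presences
#'   (>= 10 values for a meaningful P10).
#' @return A `threshold_set`: `mtp`, `p10`, `fixed`.
#' @export
compute_thresholds <- function(pred_at_presences) {
  if (length(pred_at_presences) == 0) stop("need presence predictions")
  if (length(pred_at_presences) < 10)
    warning("fewer than 10 presence predictions: P10 is poorly defined")
  ts <- list(mtp = min(pred_at_presences),
             p10 = unname(stats::quantile(pred_at_presences, 0.10, type = 7)),
             fixed = 1 - exp(-1))
  if (ts$p10 > ts$fixed)
    warning("P10 exceeds the fixed threshold: class 'Moderate' is empty")
  structure(ts, class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("Thresholds: MTP %.4f, P10 %.4f, fixed %.4f (1 - 1/e)\n",
              x$mtp, x$p10, x$fixed))
  invisible(x)
}

#' Classify a suitability raster into suitability classes
#'
#' Four-class scheme: High `(fixed, 1]`, Moderate `(p10, fixed]`, Low
#' `(mtp, p10]`, Negligible `[0, mtp]` — intervals half-open so a cell
#' exactly at a threshold joins the lower class. Binary scheme: High above
#' the fixed threshold, Low otherwise. Class areas are cell counts times
#' the cell area; percentages are relative to the total non-nodata study
#' area.
#'
#' @param suitability a [raster_grid()] of cloglog values in `[0, 1]`.
#' @param thresholds a [compute_thresholds()] result.
#' @param scheme `"four"` or `"binary"`.
#' @param cell_area_km2 area of one cell; default derived from the cell
#'   size assuming metre units.
#' @return A `classified_map`: `class_raster` (integer codes, 1 =
#'   Negligible/Low ... 4 = High), `labels`, `thresholds`, `area_table`
#'   (class, `area_km2`, `pct`), `cell_area_km2`.
#' @export
classify_map <- function(suitability, thresholds,
                         scheme = c("four", "binary"),
                         cell_area_km2 = NULL) {
  scheme <- match.arg(scheme)
  v <- suitability$values
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1)) stop("suitability must lie in [0, 1]")
  th <- thresholds
  if (!(th$mtp <= th$p10)) stop("thresholds out of order (MTP > P10)")
  if (is.null(cell_area_km2)) cell_area_km2 <- (suitability$cellsize / 1000)^2
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  if (scheme == "four") {
    labels <- c("Negligible", "Low", "Moderate", "High")
    cls[ok] <- 1 + (v[ok] > th$mtp) + (v[ok] > th$p10) + (v[ok] > th$fixed)
  } else {
    labels <- c("Low", "High")
    cls[ok] <- 1 + (v[ok] > th$fixed)
  }
  counts <- vapply(seq_along(labels), function(i) sum(cls[ok] == i), numeric(1))
  total <- sum(ok) * cell_area_km2
  area <- data.frame(class = factor(labels, levels = labels),
                     area_km2 = counts * cell_area_km2,
                     pct = 100 * counts * cell_area_km2 / total)
  structure(list(
    class_raster = raster_grid(cls, suitability$xmin, suitability$ymax,
                               suitability$cellsize, suitability$crs),
    labels = labels, thresholds = th, scheme = scheme,
    area_table = area, cell_area_km2 = cell_area_km2),
    class = "classified_map")
}

#' @export
print.classified_map <- function(x, ...) {
  cat(sprintf("Classified suitability map (%s-class):\n", x$scheme))
  df <- x$area_table
  df$area_km2 <- format(round(df$area_km2), big.mark = ",")
  df$pct <- sprintf("%.1f%%", df$pct)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

high_area_km2 <- function(cm) {
  with(cm$area_table, sum(area_km2[class == "High"]))
}

#' Project a fitted model onto a future scenario
#'
#' Predicts cloglog suitability on the scenario's predictor stack (with
#' clamping, since transferred conditions can exceed the training range),
#' classifies it into High/Low at the fixed threshold, and summarizes the
#' change: high-suitability area, percent change relative to the present
#' map, and the altitude distribution of high-suitability cells (to track
#' upward elevational shifts under warming).
#'
#' @param model a [maxent()] model.
#' @param future_stack an [env_stack()] aligned to the model's grid, with
#'   the climate layers replaced by scenario values (static layers reused).
#' @param label scenario label, e.g. `"SSP1-2.6"`.
#' @param period period label, e.g. `"2071-2100"`.
#' @param present the present-day [classify_map()] result (or a numeric
#'   present high-suitability area in km2).
#' @param dem optional elevation [raster_grid()] on the same geometry.
#' @return A `scenario_result`: `suitability`, `binary` (classified map),
#'   `high_km2`, `present_km2`, `pct_change`
#'   (`100 * (future - present)/present`), `altitude` (quantile summary of
#'   high cells), `label`, `period`.
#' @export
project_scenario <- function(model, future_stack, label, period,
                             present, dem = NULL) {
  suit <- predict(model, future_stack, type = "cloglog", clamp = TRUE)
  present_km2 <- if (is.numeric(present)) present else high_area_km2(present)
  th <- compute_thresholds_like(present)
  bin <- classify_map(suit, th, scheme = "binary")
  fut_km2 <- high_area_km2(bin)
  alt <- NULL
  if (!is.null(dem)) {
    if (!same_geometry(dem, suit)) stop("geometry mismatch between DEM and grid")
    hi <- bin$class_raster$values == 2 & !is.na(bin$class_raster$values)
    z <- dem$values[hi]
    z <- z[!is.na(z)]
    alt <- if (length(z)) stats::quantile(z, c(0, 0.25, 0.5, 0.75, 1)) else
      stats::setNames(rep(NA_real_, 5), c("0%", "25%", "50%", "75%", "100%"))
  }
  structure(list(label = label, period = period, suitability = suit,
                 binary = bin, high_km2 = fut_km2, present_km2 = present_km2,
                 pct_change = 100 * (fut_km2 - present_km2) / present_km2,
                 altitude = alt),
            class = "scenario_result")
}

compute_thresholds_like <- function(present) {
  if (is.numeric(present))
    structure(list(mtp = 0, p10 = 0, fixed = 1 - exp(-1)),
              class = "threshold_set")
  else present$thresholds
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %s (%s): high-suitability %.0f km2 (present %.0f), change %+.1f%%\n",
              x$label, x$period, x$high_km2, x$present_km2, x$pct_change))
  if (!is.null(x$altitude)) {
    cat("  altitude of high-suitability cells (min/Q1/median/Q3/max):\n   ")
    cat(sprintf(" %.0f", x$altitude), "\n")
  }
  invisible(x)
}

#' Multivariate environmental similarity surface (MESS)
#'
#' Compares the conditions of a projection area against the training
#' reference sample, one variable at a time, and keeps the minimum
#' similarity. For a query value `v` with `f` = percentage of reference
#' values strictly below `v`: `f = 0` gives `100 (v - min)/(max - min)`;
#' `0 < f <= 50` gives `2 f`; `50 < f < 100` gives `2 (100 - f)`;
#' `f = 100` gives `100 (max - v)/(max - min)`. Negative values flag novel
#' (extrapolated) environments where model output is unreliable.
#'
#' @param reference data frame of continuous predictor values used in
#'   training; constant variables are excluded with a warning.
#' @param query an [env_stack()] (returns a [raster_grid()]) or a data
#'   frame (returns a vector). Only variables present in `reference` are
#'   used.
#' @export
mess <- function(reference, query) {
  reference <- as.data.frame(reference)
  keep <- vapply(reference, function(v) {
    r <- range(v, na.rm = TRUE); r[1] < r[2]
  }, logical(1))
  if (any(!keep))
    warning("constant reference variable(s) excluded: ",
            paste(names(reference)[!keep], collapse = ", "))
  reference <- reference[keep]
  if (ncol(reference) == 0) stop("no usable reference variables")
  if (inherits(query, "env_stack")) {
    g <- query$grid
    cells <- which(!is.na(g$values))
    qv <- stack_extract(query, cells = cells)
    s <- mess(reference, qv)
    out <- matrix(NA_real_, nrow(g$values), ncol(g$values))
    out[cells] <- s
    return(raster_grid(out, g$xmin, g$ymax, g$cellsize, g$crs))
  }
  query <- as.data.frame(query)
  vars <- intersect(names(reference), names(query))
  if (length(vars) == 0) stop("query shares no variables with the reference")
  smin <- rep(Inf, nrow(query))
  for (v in vars) {
    ref <- sort(reference[[v]])
    n <- length(ref)
    q <- query[[v]]
    f <- 100 * findInterval(q, ref, left.open = TRUE) / n
    mn <- ref[1]; mx <- ref[n]
    s <- ifelse(f == 0, 100 * (q - mn) / (mx - mn),
         ifelse(f <= 50, 2 * f,
         ifelse(f < 100, 2 * (100 - f),
                100 * (mx - q) / (mx - mn))))
    smin <- pmin(smin, s)
  }
  smin
}

#' Write the class-area table of a classified map as CSV
#' @param cm a [classify_map()] result.
#' @param path output path.
#' @export
write_area_table <- function(cm, path) {
  utils::write.csv(cm$area_table, path, row.names = FALSE)
  invisible(path)
}
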