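#' Run the full distribution-modelling pipeline
#'
#' Sequences the whole analysis from a single configuration: occurrence
#' gridding (and optional protection summary), collinearity-driven
#' variable selection with VIF audit, background sampling, feature-class /
#' regularization tuning under spatial block cross-validation, final model
#' fit, threshold derivation and four-class suitability mapping with area
#' accounting, scenario projections with range-change and altitude
#' statistics, and MESS extrapolation surfaces. Every intermediate table
#' and raster is written to the run directory together with a
#' machine-readable manifest of parameters and seeds; a rerun with the
#' same configuration and seeds reproduces the tables bit for bit.
#'
#' @param config a list, or the path of a YAML file, with entries:
#'   `out_dir`; `layers` (path to a layer `manifest.csv`, see
#'   [read_stack()]); `occurrences` (CSV path); optional
#'   `protected_areas` (GeoJSON path), `dem` (ASC path); `selection`
#'   (`threshold`, `priority`, `n_sample`, `seed`); `background` (`n`,
#'   `seed`); `tuning` (`classes`, `multipliers`, `k`, `select_family`,
#'   `hinge_knots`, `threshold_knots`); `scenarios` (list of `label`,
#'   `period`, and either `layers` manifest path or named `deltas`);
#'   `seed`.
#' @return (Invisibly) a list with the fitted model, tuning table,
#'   thresholds, present classified map and scenario results; side effect:
#'   artifacts under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  stack <- stage("load layers", read_stack(cfg$layers))
  occ <- stage("load occurrences",
               read_occurrences(cfg$occurrences, crs = stack$grid$crs))
  occg <- stage("grid occurrences", dedup_to_grid(occ, stack$grid))
  write_occurrences(occg, file.path(out, "gridded_occurrences.csv"))

  if (!is.null(cfg$protected_areas)) {
    prot <- stage("protection summary", {
      polys <- read_polygons(cfg$protected_areas)
      protection_summary(occg, polys)
    })
    utils::write.csv(as.data.frame(prot),
                     file.path(out, "protection_summary.csv"),
                     row.names = FALSE)
  }

  sel <- stage("variable selection",
               correlation_select(stack,
                                  threshold = cfg$selection$threshold,
                                  priority = cfg$selection$priority,
                                  n_sample = cfg$selection$n_sample,
                                  seed = cfg$selection$seed))
  write_selection_report(sel, file.path(out, "selection"))
  stack <- stack_subset(stack, sel$kept)

  bg <- stage("background sample",
              sample_background(stack, cfg$background$n,
                                seed = cfg$background$seed))

  tuning <- stage("tuning", tune_maxent(
    stack, occg, bg,
    classes_grid = cfg$tuning$classes,
    mult_grid = cfg$tuning$multipliers,
    k = cfg$tuning$k,
    select_family = cfg$tuning$select_family,
    hinge_knots = cfg$tuning$hinge_knots,
    threshold_knots = cfg$tuning$threshold_knots))
  write_tuning_table(tuning, file.path(out, "tuning.csv"))
  model <- tuning$best_model
  maxent_to_json(model, file.path(out, "model.json"))

  imp <- stage("variable importance",
               variable_importance(model, seed = cfg$seed))
  utils::write.csv(imp, file.path(out, "variable_importance.csv"),
                   row.names = FALSE)
  curves <- stage("response curves", {
    do.call(rbind, lapply(model$features$vars, function(v) {
      rc <- response_curve(model, v)
      cbind(variable = v, rc)
    }))
  })
  utils::write.csv(curves, file.path(out, "response_curves.csv"),
                   row.names = FALSE)

  present <- stage("present map", {
    pred_pres <- predict(model, stack_extract(stack, occg$x, occg$y),
                         type = "cloglog", clamp = FALSE)
    th <- compute_thresholds(pred_pres)
    suit <- predict(model, stack, type = "cloglog", clamp = FALSE)
    write_asc(suit, file.path(out, "present_suitability.asc"))
    cm <- classify_map(suit, th, scheme = "four")
    write_asc(cm$class_raster, file.path(out, "present_classes.asc"))
    write_area_table(cm, file.path(out, "present_area_table.csv"))
    utils::write.csv(data.frame(threshold = c("MTP", "P10", "fixed"),
                                value = c(th$mtp, th$p10, th$fixed)),
                     file.path(out, "thresholds.csv"), row.names = FALSE)
    cm
  })

  dem <- if (!is.null(cfg$dem)) read_asc(cfg$dem) else NULL
  ref_vals <- stack_extract(stack, bg$x, bg$y)
  cont_ref <- ref_vals[names(stack$kind)[stack$kind == "continuous"]]
  scen_results <- list()
  change_rows <- list()
  for (sc in cfg$scenarios) {
    res <- stage(paste0("scenario ", sc$label, " ", sc$period), {
      fstack <- if (!is.null(sc$layers)) {
        fs <- read_stack(sc$layers)
        stack_subset(fs, sel$kept)
      } else shift_future(stack, unlist(sc$deltas))
      r <- project_scenario(model, fstack, sc$label, sc$period,
                            present = present, dem = dem)
      ms <- mess(cont_ref, stack_subset(fstack, names(cont_ref)))
      tag <- gsub("[^A-Za-z0-9]+", "_", paste(sc$label, sc$period))
      write_asc(r$suitability, file.path(out, paste0("suit_", tag, ".asc")))
      write_asc(r$binary$class_raster,
                file.path(out, paste0("binary_", tag, ".asc")))
      write_asc(ms, file.path(out, paste0("mess_", tag, ".asc")))
      r
    })
    scen_results[[length(scen_results) + 1L]] <- res
    change_rows[[length(change_rows) + 1L]] <- data.frame(
      label = res$label, period = res$period,
      high_km2 = res$high_km2, present_km2 = res$present_km2,
      pct_change = res$pct_change,
      alt_median = if (is.null(res$altitude)) NA else res$altitude[["50%"]])
  }
  if (length(change_rows))
    utils::write.csv(do.call(rbind, change_rows),
                     file.path(out, "scenario_changes.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(config = cfg, n_occurrences_raw = nrow(occ),
         n_occurrences_gridded = nrow(occg),
         kept_variables = sel$kept,
         selected = as.list(tuning$selected),
         r_version = as.character(getRversion())),
    file.path(out, "run_manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(list(model = model, tuning = tuning, selection = sel,
                 present = present, scenarios = scen_results,
                 importance = imp))
}

validate_config <- function(config) {
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config error: `out_dir` is required")
  for (key in c("layers", "occurrences")) {
    if (is.null(cfg[[key]])) stop("config error: `", key, "` is required")
    if (!file.exists(cfg[[key]]))
      stop("config error: `", key, "` path does not exist: ", cfg[[key]])
  }
  for (key in c("protected_areas", "dem"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config error: `", key, "` path does not exist: ", cfg[[key]])
  cfg$seed <- as.integer(cfg$seed %||% 1)
  s <- cfg$selection %||% list()
  cfg$selection <- list(threshold = s$threshold %||% 0.7,
                        priority = as.character(s$priority %||% character(0)),
                        n_sample = s$n_sample %||% 10000,
                        seed = as.integer(s$seed %||% cfg$seed))
  b <- cfg$background %||% list()
  cfg$background <- list(n = b$n %||% 20000,
                         seed = as.integer(b$seed %||% cfg$seed))
  t <- cfg$tuning %||% list()
  cfg$tuning <- list(
    classes = as.character(t$classes %||% c("L", "LQ", "LQH", "LQHP", "LQHPT")),
    multipliers = as.numeric(t$multipliers %||% seq(0.5, 5, by = 0.5)),
    k = t$k %||% 4,
    select_family = t$select_family,
    hinge_knots = t$hinge_knots %||% 50,
    threshold_knots = t$threshold_knots %||% 50)
  cfg$scenarios <- cfg$scenarios %||% list()
  for (sc in cfg$scenarios) {
    if (is.null(sc$label) || is.null(sc$period))
      stop("config error: every scenario needs `label` and `period`")
    if (!is.null(sc$layers) && !file.exists(sc$layers))
      stop("config error: scenario layer manifest does not exist: ", sc$layers)
    if (is.null(sc$layers) && is.null(sc$deltas))
      stop("config error: scenario needs `layers` or `deltas`")
  }
  cfg
}

#' Write a small self-contained virtual-species demo dataset
#'
#' Generates a 64 x 64 landscape of eight smooth continuous layers (two
#' highly correlated pairs, so the collinearity filter has work to do)
#' plus a five-class soil layer, a virtual species with unimodal responses
#' to two climate-like layers and soil preferences, 300 presence-only
#' records sampled from the truth, a warming-style future shift, a
#' synthetic DEM, a protected-area polygon, and a ready-to-run pipeline
#' configuration (`config.yaml`).
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param n_presences number of presence records.
#' @return (Invisibly) a list with the truth and paths.
#' @export
make_demo <- function(dir, seed = 1, n_presences = 300) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- raster_grid(matrix(1, 64, 64), xmin = 600000, ymax = 4800000,
                      cellsize = 1000, crs = "EPSG:32632")
  corr <- diag(8)
  corr[1, 2] <- corr[2, 1] <- 0.85
  corr[3, 4] <- corr[4, 3] <- 0.75
  stack <- generate_env_stack(grid, n_continuous = 8, target_corr = corr,
                              n_classes = 5, smoothness = 4, seed = seed)
  truth <- true_suitability(stack, list(
    true_response("env01", "unimodal",
                  list(center = 0.5, width = 0.8, height = 6)),
    true_response("env03", "unimodal",
                  list(center = -0.3, width = 1.0, height = 4)),
    true_response("soil", "categorical",
                  list(weights = c("1" = 0, "2" = 0.6, "3" = 1.2,
                                   "4" = 0.6, "5" = 0)))),
    offset = -6)
  occ <- sample_presences(truth, n_presences, seed = seed + 1)
  fut <- shift_future(stack, c(env01 = 1.2, env03 = 0.9, env05 = 0.5))

  layers_dir <- file.path(dir, "layers")
  write_stack(stack, layers_dir)
  fut_dir <- file.path(dir, "layers_future")
  write_stack(fut, fut_dir)
  write_occurrences(occ, file.path(dir, "occurrences.csv"))
  write_asc(truth$suitability, file.path(dir, "true_suitability.asc"))

  dem <- raster_grid(500 + 300 * stack$layers[["env02"]],
                     grid$xmin, grid$ymax, grid$cellsize, grid$crs)
  write_asc(dem, file.path(dir, "dem.asc"))

  cx <- grid$xmin + c(8, 40) * 1000; cy <- grid$ymax - c(40, 8) * 1000
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(name = "synthetic reserve"),
    geometry = list(type = "Polygon", coordinates = list(list(
      c(cx[1], cy[1]), c(cx[2], cy[1]), c(cx[2], cy[2]),
      c(cx[1], cy[2]), c(cx[1], cy[1])))))))
  jsonlite::write_json(gj, file.path(dir, "protected.geojson"),
                       auto_unbox = TRUE, digits = NA)

  cfg <- list(
    out_dir = file.path(dir, "run"),
    layers = file.path(layers_dir, "manifest.csv"),
    occurrences = file.path(dir, "occurrences.csv"),
    protected_areas = file.path(dir, "protected.geojson"),
    dem = file.path(dir, "dem.asc"),
    seed = seed,
    selection = list(threshold = 0.7, priority = list("env01", "env03")),
    background = list(n = 1000),
    tuning = list(k = 4, hinge_knots = 8, threshold_knots = 8),
    scenarios = list(list(label = "SSP5-8.5", period = "2071-2100",
                          layers = file.path(fut_dir, "manifest.csv"))))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(list(truth = truth, stack = stack, occurrences = occ,
                 config = file.path(dir, "config.yaml")))
}
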