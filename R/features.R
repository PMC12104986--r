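#' MaxEnt feature expansion
#'
#' Builds the classic MaxEnt feature classes from raw predictor values.
#' Continuous variables are first rescaled to `[0, 1]` by their training
#' range; features are then: linear (L) the rescaled value; quadratic (Q)
#' its square; product (P) pairwise products of distinct continuous
#' variables; hinge (H) forward ramps `max(0, (v - t)/(1 - t))` and reverse
#' ramps `max(0, (t - v)/t)` at empirical quantile knots; threshold (T)
#' step functions `1[v > t]` at quantile knots. Categorical variables
#' always expand to one indicator per class observed in training,
#' regardless of `classes`. Constant variables are dropped with a warning.
#'
#' `feature_map()` learns the scaling, knots and categories from training
#' data; `feature_eval()` applies a learned map to new data, optionally
#' clamping continuous values to the training range (used when
#' transferring a model beyond the conditions it was fitted on).
#'
#' @param values data frame of predictor values (training sample).
#' @param kind named character vector: `"continuous"` or `"categorical"`
#'   per column of `values`.
#' @param classes feature classes as a string (`"LQHP"`) or character
#'   vector (`c("L","Q","H","P")`); subset of L, Q, P, H, T.
#' @param hinge_knots,threshold_knots knots per variable (per direction for
#'   hinges), placed at empirical quantiles of the training data.
#' @return `feature_map()`: an object of class `feature_map` holding the
#'   feature definitions (`defs`: data frame with `name`, `class`, `var1`,
#'   `var2`, `knot`, `category`), per-variable training ranges (`scale`)
#'   and observed categories. `feature_eval()`: the numeric feature matrix
#'   (rows = points, columns = features).
#' @export
feature_map <- function(values, kind, classes = "LQ",
                        hinge_knots = 50, threshold_knots = 50) {
  classes <- parse_classes(classes)
  values <- as.data.frame(values)
  vars <- names(values)
  if (is.null(kind) || !all(vars %in% names(kind)))
    stop("`kind` must cover every column of `values`")
  cont <- vars[kind[vars] == "continuous"]
  cats <- vars[kind[vars] == "categorical"]

  scale <- list()
  for (v in cont) {
    rng <- range(values[[v]], na.rm = TRUE)
    if (rng[1] == rng[2]) {
      warning("constant variable dropped: ", v)
      next
    }
    scale[[v]] <- rng
  }
  cont <- names(scale)

  defs <- list()
  add <- function(name, class, var1, var2 = NA, knot = NA, category = NA)
    defs[[length(defs) + 1L]] <<- data.frame(
      name = name, class = class, var1 = var1, var2 = var2,
      knot = knot, category = category, stringsAsFactors = FALSE)

  sc <- function(v) (values[[v]] - scale[[v]][1]) /
    (scale[[v]][2] - scale[[v]][1])

  if ("L" %in% classes) for (v in cont) add(v, "linear", v)
  if ("Q" %in% classes) for (v in cont) add(paste0(v, "^2"), "quadratic", v)
  if ("P" %in% classes && length(cont) >= 2) {
    prs <- utils::combn(cont, 2)
    for (i in seq_len(ncol(prs)))
      add(paste0(prs[1, i], "*", prs[2, i]), "product", prs[1, i], prs[2, i])
  }
  qknots <- function(v, k) {
    kn <- unique(stats::quantile(sc(v), probs = seq_len(k) / (k + 1),
                                 names = FALSE, type = 7))
    kn[kn > 1e-9 & kn < 1 - 1e-9]
  }
  if ("H" %in% classes) for (v in cont) for (t in qknots(v, hinge_knots)) {
    add(sprintf("hinge(%s,%.6g)", v, t), "fhinge", v, knot = t)
    add(sprintf("rhinge(%s,%.6g)", v, t), "rhinge", v, knot = t)
  }
  if ("T" %in% classes) for (v in cont) for (t in qknots(v, threshold_knots))
    add(sprintf("thr(%s,%.6g)", v, t), "threshold", v, knot = t)

  categories <- list()
  for (v in cats) {
    lev <- sort(unique(values[[v]]))
    categories[[v]] <- lev
    for (cl in lev)
      add(sprintf("%s==%g", v, cl), "indicator", v, category = cl)
  }
  defs <- if (length(defs)) do.call(rbind, defs) else
    data.frame(name = character(0), class = character(0), var1 = character(0),
               var2 = character(0), knot = numeric(0), category = numeric(0))
  if (nrow(defs) == 0) stop("no usable features (all variables constant?)")
  structure(list(defs = defs, scale = scale, categories = categories,
                 kind = kind, classes = classes,
                 vars = c(cont, cats)),
            class = "feature_map")
}

parse_classes <- function(classes) {
  cl <- if (length(classes) == 1L && nchar(classes) > 1L)
    strsplit(classes, "")[[1]] else classes
  cl <- toupper(cl)
  bad <- setdiff(cl, c("L", "Q", "P", "H", "T"))
  if (length(bad)) stop("unknown feature class: ", paste(bad, collapse = ","))
  if (length(cl) == 0) stop("`classes` must be non-empty")
  unique(cl)
}

#' @rdname feature_map
#' @param fm a `feature_map`.
#' @param newvalues data frame of predictor values to expand.
#' @param clamp pin continuous values outside the training range to its
#'   boundary before building features.
#' @export
feature_eval <- function(fm, newvalues, clamp = FALSE) {
  newvalues <- as.data.frame(newvalues)
  miss <- setdiff(fm$vars, names(newvalues))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  n <- nrow(newvalues)
  scaled <- list()
  for (v in names(fm$scale)) {
    s <- (newvalues[[v]] - fm$scale[[v]][1]) /
      (fm$scale[[v]][2] - fm$scale[[v]][1])
    if (clamp) s <- pmin(pmax(s, 0), 1)
    scaled[[v]] <- s
  }
  d <- fm$defs
  X <- matrix(0, n, nrow(d), dimnames = list(NULL, d$name))
  for (j in seq_len(nrow(d))) {
    v <- scaled[[d$var1[j]]]
    X[, j] <- switch(d$class[j],
      linear = v,
      quadratic = v^2,
      product = v * scaled[[d$var2[j]]],
      fhinge = pmax(0, (v - d$knot[j]) / (1 - d$knot[j])),
      rhinge = pmax(0, (d$knot[j] - v) / d$knot[j]),
      threshold = as.numeric(v > d$knot[j]),
      indicator = as.numeric(newvalues[[d$var1[j]]] == d$category[j]))
  }
  X
}

# Published MaxEnt default regularization base values, linearly
# interpolated by presence sample size (constant beyond the table ends).
reg_base <- function(class, n_presence) {
  interp <- function(xs, ys)
    stats::approx(xs, ys, xout = n_presence, rule = 2)$y
  switch(class,
    linear = , quadratic = , product =
      interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    indicator = interp(c(0, 10, 17), c(0.65, 0.5, 0.25)),
    threshold = interp(c(0, 100), c(2, 1)),
    fhinge = , rhinge = 0.5,
    stop("unknown feature class: ", class))
}
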