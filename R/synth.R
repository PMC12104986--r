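#' Generate a virtual-species predictor stack
#'
#' Builds spatially smooth, cross-correlated continuous layers plus one
#' spatially coherent categorical layer on a given grid. Continuous layers
#' are produced by mixing independent Gaussian noise fields through the
#' Cholesky factor of `target_corr` and then Gaussian-smoothing each mixed
#' field with the same kernel, so the empirical pairwise correlations over
#' the landscape approximate `target_corr` (smoothing reduces the effective
#' number of independent cells, hence small deviations). The categorical
#' layer is obtained by quantile-slicing an auxiliary smooth field, which
#' yields contiguous patches, as soil classes are in reality.
#'
#' @param grid a [raster_grid()] supplying geometry and nodata mask.
#' @param n_continuous number of continuous layers.
#' @param target_corr target correlation matrix (unit diagonal, positive
#'   semi-definite, dimension `n_continuous`); default identity.
#' @param n_classes number of categories in the categorical layer (>= 1).
#' @param smoothness Gaussian smoothing length-scale in cells.
#' @param seed integer seed; same seed, same stack, bit for bit.
#' @param names_continuous,name_categorical layer names.
#' @return An [env_stack()] with `n_continuous` continuous layers (roughly
#'   zero mean, unit variance) and one categorical layer of integer codes
#'   `1..n_classes`.
#' @export
generate_env_stack <- function(grid, n_continuous, target_corr = NULL,
                               n_classes = 4, smoothness = 3, seed = 1,
                               names_continuous = sprintf("env%02d", seq_len(n_continuous)),
                               name_categorical = "soil") {
  if (n_continuous < 1) stop("need at least one continuous layer")
  if (n_classes < 1) stop("`n_classes` must be >= 1")
  if (is.null(target_corr)) target_corr <- diag(n_continuous)
  target_corr <- as.matrix(target_corr)
  if (nrow(target_corr) != n_continuous || ncol(target_corr) != n_continuous)
    stop("`target_corr` dimension must equal `n_continuous`")
  if (max(abs(target_corr - t(target_corr))) > 1e-8 ||
      max(abs(diag(target_corr) - 1)) > 1e-8)
    stop("`target_corr` must be symmetric with unit diagonal")
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("`target_corr` must be positive semi-definite")

  nr <- nrow(grid$values); nc <- ncol(grid$values)
  R <- chol(target_corr + diag(1e-10, n_continuous))
  with_seed(seed, {
    W <- matrix(stats::rnorm(nr * nc * n_continuous), nrow = nr * nc)
    M <- W %*% R
    layers <- vector("list", n_continuous)
    for (j in seq_len(n_continuous)) {
      f <- smooth_field(matrix(M[, j], nr, nc), smoothness)
      f <- (f - mean(f)) / stats::sd(as.vector(f))
      layers[[j]] <- raster_grid(mask_like(f, grid), grid$xmin, grid$ymax,
                                 grid$cellsize, grid$crs)
    }
    names(layers) <- names_continuous
    aux <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), smoothness)
    qs <- stats::quantile(aux, probs = seq_len(n_classes - 1) / n_classes)
    cat_vals <- matrix(findInterval(aux, qs) + 1, nr, nc)
    layers[[name_categorical]] <-
      raster_grid(mask_like(cat_vals, grid), grid$xmin, grid$ymax,
                  grid$cellsize, grid$crs)
    kind <- stats::setNames(c(rep("continuous", n_continuous), "categorical"),
                            c(names_continuous, name_categorical))
    env_stack(layers, kind = kind)
  })
}

mask_like <- function(v, grid) {
  v[is.na(grid$values)] <- NA_real_
  v
}

# Separable Gaussian smoothing with reflected edges; sigma in cells.
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  r <- min(r, nrow(m) - 1L, ncol(m) - 1L)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  sm_cols <- function(mm) {
    n <- nrow(mm)
    pad <- rbind(mm[r:1, , drop = FALSE], mm, mm[n:(n - r + 1), , drop = FALSE])
    out <- stats::filter(pad, k, sides = 2)
    matrix(out[(r + 1):(r + n), ], nrow = n)
  }
  t(sm_cols(t(sm_cols(m))))
}

#' Define a true species response to one predictor
#'
#' Building block for virtual-species truths: how habitat suitability
#' responds to a single environmental layer.
#'
#' @param variable layer name the response applies to.
#' @param shape `"unimodal"` (Gaussian bump: params `center`, `width`,
#'   optional `height`), `"linear"` (params `slope`, optional `intercept`),
#'   `"quadratic"` (params `a`, `b`), or `"categorical"` (param `weights`, a
#'   vector named by class code; unnamed classes score 0).
#' @param params named list of shape parameters.
#' @return A `true_response` object.
#' @export
true_response <- function(variable, shape = c("unimodal", "linear",
                                              "quadratic", "categorical"),
                          params = list()) {
  shape <- match.arg(shape)
  if (shape == "unimodal") {
    if (is.null(params$center) || is.null(params$width))
      stop("unimodal response needs `center` and `width`")
    if (params$width <= 0) stop("unimodal `width` must be > 0")
    params$height <- params$height %||% 1
  }
  if (shape == "linear" && is.null(params$slope))
    stop("linear response needs `slope`")
  if (shape == "quadratic" && (is.null(params$a) || is.null(params$b)))
    stop("quadratic response needs `a` and `b`")
  if (shape == "categorical") {
    w <- params$weights
    if (is.null(w) || is.null(names(w)) || any(!is.finite(w)))
      stop("categorical response needs finite `weights` named by class code")
  }
  structure(list(variable = variable, shape = shape, params = params),
            class = "true_response")
}

response_term <- function(resp, v) {
  p <- resp$params
  switch(resp$shape,
    unimodal = p$height * exp(-(v - p$center)^2 / (2 * p$width^2)),
    linear = p$slope * v + (p$intercept %||% 0),
    quadratic = p$a * v^2 + p$b * v,
    categorical = {
      w <- p$weights
      out <- rep(0, length(v))
      m <- match(as.character(round(v)), names(w))
      out[!is.na(m)] <- w[m[!is.na(m)]]
      out
    })
}

#' True suitability surface from known responses
#'
#' Composes per-variable responses into a suitability surface in `[0, 1]`.
#' With `combine = "logistic"` the per-response terms are summed on the
#' linear-predictor scale and passed through the logistic function (no
#' responses gives constant 0.5); with `combine = "product"` the terms are
#' clipped to `[0, 1]` and multiplied.
#'
#' @param stack an [env_stack()].
#' @param responses list of [true_response()] objects; every referenced
#'   variable must exist in `stack`.
#' @param combine `"logistic"` or `"product"`.
#' @param offset added to the linear predictor before the logistic (ignored
#'   for `"product"`); shifts overall prevalence.
#' @return A `synthetic_truth` object: `responses`, `suitability` (a
#'   [raster_grid()] in `[0, 1]`) and `combine`.
#' @export
true_suitability <- function(stack, responses = list(),
                             combine = c("logistic", "product"), offset = 0) {
  combine <- match.arg(combine)
  for (r in responses)
    if (!r$variable %in% names(stack$layers))
      stop("response variable not in stack: ", r$variable)
  g <- stack$grid
  n <- length(g$values)
  if (combine == "logistic") {
    eta <- rep(offset, n)
    for (r in responses)
      eta <- eta + response_term(r, as.vector(stack$layers[[r$variable]]))
    suit <- stats::plogis(eta)
  } else {
    suit <- rep(1, n)
    for (r in responses) {
      term <- response_term(r, as.vector(stack$layers[[r$variable]]))
      suit <- suit * pmin(1, pmax(0, term))
    }
  }
  sv <- matrix(suit, nrow(g$values), ncol(g$values))
  sv[is.na(g$values)] <- NA_real_
  structure(list(responses = responses, combine = combine,
                 suitability = raster_grid(sv, g$xmin, g$ymax, g$cellsize, g$crs)),
            class = "synthetic_truth")
}

#' Sample presence-only records from a true suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to
#' suitability times an optional observation-bias surface; each draw becomes
#' one presence record at the cell centroid plus uniform sub-cell jitter,
#' mimicking opportunistically collected occurrence data.
#'
#' @param truth a [true_suitability()] result.
#' @param n number of records to draw.
#' @param bias optional [raster_grid()] of non-negative sampling weights on
#'   the same geometry (default: uniform).
#' @param seed integer seed.
#' @param jitter fraction of the cell size used for sub-cell jitter.
#' @return An [occurrence_set()] with `n` rows, `source = "synthetic"`.
#' @export
sample_presences <- function(truth, n, bias = NULL, seed = 1, jitter = 0.49) {
  if (n < 0) stop("`n` must be >= 0")
  suit <- truth$suitability
  w <- as.vector(suit$values)
  if (!is.null(bias)) {
    if (!same_geometry(bias, suit)) stop("`bias` must share the grid geometry")
    w <- w * as.vector(bias$values)
  }
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("degenerate input: all sampling weights are zero")
  nr <- nrow(suit$values)
  with_seed(seed, {
    cells <- sample.int(length(w), size = n, replace = TRUE, prob = w)
    row <- ((cells - 1L) %% nr) + 1L
    col <- ((cells - 1L) %/% nr) + 1L
    xy <- grid_xy(suit, row, col)
    cs <- suit$cellsize
    if (n > 0) {
      xy[, 1] <- xy[, 1] + stats::runif(n, -jitter, jitter) * cs
      xy[, 2] <- xy[, 2] + stats::runif(n, -jitter, jitter) * cs
    }
    occurrence_set(data.frame(id = seq_len(n),
                              x = xy[, 1], y = xy[, 2],
                              source = rep("synthetic", n)),
                   crs = suit$crs)
  })
}

#' Shift continuous layers to emulate a future climate scenario
#'
#' Adds per-layer offsets to the named continuous layers; categorical and
#' unnamed layers (topography, soil) are returned unchanged, since slow
#' geomorphological and pedological change is assumed negligible on the
#' projection horizon.
#'
#' @param stack an [env_stack()].
#' @param deltas named numeric vector of additive offsets; names must be
#'   continuous layers of `stack`.
#' @return An [env_stack()] with shifted continuous layers.
#' @export
shift_future <- function(stack, deltas) {
  if (length(deltas) == 0) return(stack)
  if (is.null(names(deltas)) || any(names(deltas) == ""))
    stop("`deltas` must be named by layer")
  unknown <- setdiff(names(deltas), names(stack$layers))
  if (length(unknown)) stop("unknown layer in `deltas`: ",
                            paste(unknown, collapse = ", "))
  on_cat <- names(deltas)[stack$kind[names(deltas)] == "categorical"]
  if (length(on_cat)) stop("cannot shift categorical layer: ",
                           paste(on_cat, collapse = ", "))
  out <- stack
  for (nm in names(deltas))
    out$layers[[nm]] <- out$layers[[nm]] + deltas[[nm]]
  out
}
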