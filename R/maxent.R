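#' Sample background points from a study grid
#'
#' Uniform sample of non-nodata cell centroids without replacement,
#' characterizing the available environment (these are not absences).
#'
#' @param stack an [env_stack()] (or a [raster_grid()]).
#' @param n number of points; must not exceed the number of non-nodata
#'   cells.
#' @param seed integer seed.
#' @return Data frame with columns `x`, `y`, `cell`.
#' @export
sample_background <- function(stack, n, seed = 1) {
  grid <- if (inherits(stack, "env_stack")) stack$grid else stack
  cells <- which(!is.na(grid$values))
  if (n > length(cells))
    stop("`n` (", n, ") exceeds the ", length(cells), " non-nodata cells")
  take <- if (n == length(cells)) cells else
    with_seed(seed, sort(sample(cells, n)))
  nr <- nrow(grid$values)
  xy <- grid_xy(grid, ((take - 1L) %% nr) + 1L, ((take - 1L) %/% nr) + 1L)
  data.frame(x = xy[, 1], y = xy[, 2], cell = take)
}

#' Fit a presence-background maximum-entropy model
#'
#' Fits the Gibbs distribution `p(x) = exp(sum_j beta_j f_j(x)) / Z` over
#' the background points by maximizing the L1-penalized presence
#' log-likelihood
#' `mean_presence(eta) - log Z - sum_j lambda_j |beta_j|`,
#' where `Z` sums `exp(eta)` over the background, the features `f_j` are
#' the L/Q/P/H/T expansion of [feature_map()], and
#' `lambda_j = reg_mult * base(class_j, m) * sd_j / sqrt(m)` with `m` the
#' number of presences, `base` the published MaxEnt per-class default
#' tables, and `sd_j` the feature's standard deviation over the presence
#' sample (floored at `sd_floor` to keep the problem bounded).
#' Optimization is by FISTA (accelerated proximal gradient with
#' backtracking and adaptive restart) on the exact convex objective.
#'
#' @param presence data frame of predictor values at presence points (or,
#'   if `stack` is given, a data frame with `x`, `y` coordinates).
#' @param background same, for background points.
#' @param kind named character vector, `"continuous"`/`"categorical"` per
#'   predictor (taken from `stack` when given).
#' @param stack optional [env_stack()]; when supplied, `presence` and
#'   `background` are coordinate tables and values are extracted from it.
#' @param classes feature classes, e.g. `"LQHP"` (see [feature_map()]).
#' @param reg_mult regularization multiplier (> 0); larger values give
#'   sparser, smoother models.
#' @param hinge_knots,threshold_knots knots per variable (see
#'   [feature_map()]).
#' @param sd_floor lower bound on the per-feature sd used in the penalty.
#' @param clamp default clamping behaviour stored on the model, applied by
#'   `predict()` when projecting (values outside the training range pinned
#'   to its boundary).
#' @param tol convergence tolerance on the relative objective change.
#' @param max_iter iteration cap.
#' @return An object of class `maxent`: feature map, coefficients `beta`,
#'   penalties `lambda`, `logZ`, entropy `H` of the fitted distribution
#'   over the background, training log-likelihood, convergence info, and
#'   the training data (used by [variable_importance()] and
#'   [response_curve()]).
#' @examples
#' set.seed(1)
#' bg <- data.frame(a = runif(200))
#' pr <- data.frame(a = rbeta(40, 4, 2))
#' m <- maxent(pr, bg, kind = c(a = "continuous"), classes = "LQ")
#' summary(m)
#' @export
maxent <- function(presence, background, kind = NULL, stack = NULL,
                   classes = "LQ", reg_mult = 1,
                   hinge_knots = 50, threshold_knots = 50,
                   sd_floor = 1e-3, clamp = TRUE,
                   tol = 1e-7, max_iter = 10000) {
  if (!is.null(stack)) {
    kind <- stack$kind
    presence <- stack_extract(stack, presence$x, presence$y)
    background <- stack_extract(stack,
                                x = background$x, y = background$y)
  }
  presence <- stats::na.omit(as.data.frame(presence))
  background <- stats::na.omit(as.data.frame(background))
  m <- nrow(presence); N <- nrow(background)
  if (m < 2) stop("need at least 2 presence points")
  if (N < 1) stop("background must be non-empty")
  if (reg_mult <= 0) stop("`reg_mult` must be > 0")

  # scaling, knots and categories are learned from the combined sample:
  # the background characterizes the available environment
  fm <- feature_map(rbind(presence, background), kind, classes,
                    hinge_knots = hinge_knots,
                    threshold_knots = threshold_knots)
  Xp <- feature_eval(fm, presence)
  Xb <- feature_eval(fm, background)

  sd_p <- pmax(apply(Xp, 2, stats::sd), sd_floor)
  base <- vapply(fm$defs$class, reg_base, numeric(1), n_presence = m)
  lambda <- reg_mult * base * sd_p / sqrt(m)

  fit <- fit_penalized_gibbs(Xp, Xb, lambda, tol = tol, max_iter = max_iter)

  eta_b <- drop(Xb %*% fit$beta)
  logZ <- log_sum_exp(eta_b)
  raw <- exp(eta_b - logZ)
  H <- -sum(raw * log(pmax(raw, 1e-300)))
  lnL <- sum(drop(Xp %*% fit$beta) - logZ)

  structure(list(features = fm, beta = stats::setNames(fit$beta, fm$defs$name),
                 lambda = stats::setNames(lambda, fm$defs$name),
                 reg_mult = reg_mult, classes = paste(fm$classes, collapse = ""),
                 logZ = logZ, H = H, lnL = lnL,
                 n_presence = m, n_background = N, clamp = clamp,
                 converged = fit$converged, n_iter = fit$n_iter,
                 objective = fit$objective,
                 data = list(presence = presence, background = background)),
            class = "maxent")
}

log_sum_exp <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }

# FISTA with backtracking on
#   f(beta) = -mean(Xp beta) + log sum exp(Xb beta) + sum lambda |beta|
fit_penalized_gibbs <- function(Xp, Xb, lambda, tol = 1e-7, max_iter = 10000) {
  J <- ncol(Xp)
  mean_p <- colMeans(Xp)
  smooth <- function(beta) {
    eta <- drop(Xb %*% beta)
    list(f = -sum(mean_p * beta) + log_sum_exp(eta), eta = eta)
  }
  grad <- function(beta, eta) {
    w <- exp(eta - log_sum_exp(eta))
    drop(crossprod(Xb, w)) - mean_p
  }
  objective <- function(beta, fs) fs + sum(lambda * abs(beta))
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

  beta <- numeric(J); yv <- beta; tk <- 1
  sv <- smooth(beta)
  obj <- objective(beta, sv$f)
  step <- 1
  stable <- 0L
  iter <- 0L
  rel <- Inf
  restarts <- 0L
  stagnated <- FALSE
  f_y <- sv$f; eta_y <- sv$eta
  repeat {
    iter <- iter + 1L
    g <- grad(yv, eta_y)
    repeat {
      cand <- soft(yv - step * g, step * lambda)
      sc <- smooth(cand)
      dlt <- cand - yv
      if (sc$f <= f_y + sum(g * dlt) + sum(dlt^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    beta_new <- cand
    obj_new <- objective(beta_new, sc$f)
    if (obj_new > obj + 1e-14 * max(1, abs(obj))) {   # adaptive restart
      restarts <- restarts + 1L
      if (restarts >= 2L || iter >= max_iter) {
        # two restarts in a row: progress is below floating-point noise
        stagnated <- restarts >= 2L
        break
      }
      yv <- beta; tk <- 1
      sy <- smooth(yv); f_y <- sy$f; eta_y <- sy$eta
      next
    }
    restarts <- 0L
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yv <- beta_new + ((tk - 1) / t_new) * (beta_new - beta)
    beta <- beta_new; tk <- t_new
    sy <- smooth(yv); f_y <- sy$f; eta_y <- sy$eta
    rel <- abs(obj - obj_new) / max(1, abs(obj_new))
    obj <- obj_new
    stable <- if (rel < tol) stable + 1L else 0L
    if (stable >= 3L || iter >= max_iter) break
    step <- min(step * 2, 1e6)
  }
  converged <- stable >= 3L || stagnated
  if (!converged)
    warning("maxent fit did not converge in ", max_iter, " iterations ",
            "(last relative change ", signif(rel, 3), ")")
  list(beta = beta, converged = converged, n_iter = iter, objective = obj)
}

#' Predict from a fitted MaxEnt model
#'
#' `type = "raw"` gives the Gibbs density normalized over the training
#' background (sums to 1 there); `type = "cloglog"` gives
#' `1 - exp(-exp(H) * raw)`, scaled so that a cell expected to hold one
#' individual has value `1 - 1/e ~ 0.632`; `type = "link"` the linear
#' predictor.
#'
#' @param object a [maxent()] model.
#' @param newdata data frame of predictor values, or an [env_stack()] (then
#'   a [raster_grid()] of predictions is returned).
#' @param type `"cloglog"`, `"raw"` or `"link"`.
#' @param clamp pin predictors outside the training range to its boundary;
#'   defaults to the model's stored setting.
#' @param ... unused.
#' @export
predict.maxent <- function(object, newdata = NULL,
                           type = c("cloglog", "raw", "link"),
                           clamp = object$clamp, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data$presence
  if (inherits(newdata, "env_stack")) {
    g <- newdata$grid
    cells <- which(!is.na(g$values))
    vals <- stack_extract(newdata, cells = cells)
    p <- predict.maxent(object, vals, type = type, clamp = clamp)
    out <- matrix(NA_real_, nrow(g$values), ncol(g$values))
    out[cells] <- p
    return(raster_grid(out, g$xmin, g$ymax, g$cellsize, g$crs))
  }
  X <- feature_eval(object$features, newdata, clamp = clamp)
  eta <- drop(X %*% object$beta)
  switch(type,
         link = eta,
         raw = exp(eta - object$logZ),
         cloglog = 1 - exp(-exp(object$H) * exp(eta - object$logZ)))
}

#' @export
print.maxent <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("MaxEnt model (%s, reg_mult %g): %d features (%d non-zero)\n",
              x$classes, x$reg_mult, length(x$beta), nz))
  cat(sprintf("  %d presences, %d background points; entropy H = %.4f\n",
              x$n_presence, x$n_background, x$H))
  invisible(x)
}

#' @export
summary.maxent <- function(object, ...) {
  nz <- object$beta[object$beta != 0]
  structure(list(model = object,
                 nonzero = nz[order(-abs(nz))],
                 aicc = aicc_score(object)),
            class = "summary.maxent")
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  cat(sprintf("  lnL = %.3f, AICc = %.3f, converged: %s (%d iterations)\n",
              x$model$lnL, x$aicc, x$model$converged, x$model$n_iter))
  cat("  largest coefficients:\n")
  top <- utils::head(x$nonzero, 10)
  for (n in names(top)) cat(sprintf("    %-24s %+.4f\n", n, top[[n]]))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$beta

#' @export
logLik.maxent <- function(object, ...) {
  structure(object$lnL, df = sum(object$beta != 0),
            nobs = object$n_presence, class = "logLik")
}

#' Simulate presence points from a fitted model
#'
#' Draws background points with probability proportional to the fitted raw
#' distribution — the model's idea of where presences come from.
#'
#' @param object a [maxent()] model.
#' @param nsim number of points per draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return Data frame of sampled rows from the model's background values.
#' @export
simulate.maxent <- function(object, nsim = 1, seed = NULL, ...) {
  raw <- predict.maxent(object, object$data$background, type = "raw",
                        clamp = FALSE)
  idx <- with_seed(seed, sample.int(nrow(object$data$background), nsim,
                                    replace = TRUE, prob = raw))
  object$data$background[idx, , drop = FALSE]
}

#' Serialize a MaxEnt model to JSON (and back)
#'
#' @param model a [maxent()] model.
#' @param path output path. The training data tables are not serialized.
#' @export
maxent_to_json <- function(model, path) {
  fm <- model$features
  jsonlite::write_json(list(
    defs = fm$defs, scale = fm$scale, categories = fm$categories,
    kind = as.list(fm$kind), classes = model$classes,
    beta = as.list(model$beta), lambda = as.list(model$lambda),
    reg_mult = model$reg_mult, logZ = model$logZ, H = model$H,
    lnL = model$lnL, n_presence = model$n_presence,
    n_background = model$n_background, clamp = model$clamp),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname maxent_to_json
#' @export
maxent_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- unlist(j$kind)
  defs <- as.data.frame(j$defs)
  for (col in c("var2", "knot", "category"))
    if (is.null(defs[[col]])) defs[[col]] <- NA
  scale <- lapply(j$scale, as.numeric)
  fm <- structure(list(defs = defs, scale = scale,
                       categories = lapply(j$categories, as.numeric),
                       kind = kind,
                       classes = strsplit(j$classes, "")[[1]],
                       vars = c(names(scale),
                                names(j$categories))),
                  class = "feature_map")
  structure(list(features = fm,
                 beta = unlist(j$beta), lambda = unlist(j$lambda),
                 reg_mult = j$reg_mult, classes = j$classes,
                 logZ = j$logZ, H = j$H, lnL = j$lnL,
                 n_presence = j$n_presence, n_background = j$n_background,
                 clamp = j$clamp, converged = NA, n_iter = NA,
                 objective = NA, data = NULL),
            class = "maxent")
}
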