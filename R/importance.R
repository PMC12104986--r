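#' Variable importance of a fitted MaxEnt model
#'
#' Two complementary measures per predictor. Permutation importance:
#' the variable's values are permuted jointly across the presence and
#' background samples (so every feature built from it is scrambled), the
#' drop in training AUC is measured, averaged over `n_permutations`, and
#' the drops are normalized to sum to 100. Percent contribution: a
#' coefficient-magnitude proxy, `|beta_j| * sd(f_j over background)`
#' summed over the variable's features (product features counted half to
#' each variable) and normalized to 100. The original MaxEnt percent
#' contribution is bookkeeping internal to its sequential optimizer and is
#' not reproducible from a closed formula; this proxy preserves its
#' intent — how much of the fitted linear predictor's variation a variable
#' carries — and is comparable across variables of one model.
#'
#' @param model a [maxent()] model (with stored training data).
#' @param n_permutations permutation rounds (>= 1).
#' @param seed integer seed.
#' @return Data frame: `variable`, `percent_contribution`,
#'   `permutation_importance`, sorted by contribution.
#' @export
variable_importance <- function(model, n_permutations = 5, seed = 1) {
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")
  pres <- model$data$presence
  bg <- model$data$background
  if (is.null(pres)) stop("model carries no training data")
  vars <- model$features$vars
  d <- model$features$defs

  # percent contribution proxy
  Xb <- feature_eval(model$features, bg)
  wgt <- abs(model$beta) * apply(Xb, 2, stats::sd)
  contrib <- stats::setNames(rep(0, length(vars)), vars)
  for (j in seq_len(nrow(d))) {
    if (!is.na(d$var2[j])) {
      contrib[d$var1[j]] <- contrib[d$var1[j]] + wgt[j] / 2
      contrib[d$var2[j]] <- contrib[d$var2[j]] + wgt[j] / 2
    } else contrib[d$var1[j]] <- contrib[d$var1[j]] + wgt[j]
  }
  contrib <- if (sum(contrib) > 0) 100 * contrib / sum(contrib) else contrib

  # permutation importance
  base_auc <- auc_score(predict(model, pres, type = "link", clamp = FALSE),
                        predict(model, bg, type = "link", clamp = FALSE))
  m <- nrow(pres)
  all_vals <- rbind(pres[vars], bg[vars])
  drops <- stats::setNames(rep(0, length(vars)), vars)
  with_seed(seed, {
    for (v in vars) {
      acc <- 0
      for (r in seq_len(n_permutations)) {
        perm <- all_vals
        perm[[v]] <- sample(perm[[v]])
        pp <- predict(model, perm[seq_len(m), , drop = FALSE],
                      type = "link", clamp = FALSE)
        pb <- predict(model, perm[-seq_len(m), , drop = FALSE],
                      type = "link", clamp = FALSE)
        acc <- acc + (base_auc - auc_score(pp, pb))
      }
      drops[v] <- max(acc / n_permutations, 0)
    }
  })
  imp <- if (sum(drops) > 0) 100 * drops / sum(drops) else drops
  out <- data.frame(variable = vars,
                    percent_contribution = unname(contrib[vars]),
                    permutation_importance = unname(imp[vars]))
  out[order(-out$percent_contribution), ]
}

#' Response curve of one predictor
#'
#' Sweeps the predictor over its training range while holding the other
#' continuous predictors at their background mean and categorical ones at
#' their background mode, and returns the cloglog prediction — the model's
#' estimated suitability profile along that environmental gradient.
#'
#' @param model a [maxent()] model (with stored training data).
#' @param variable predictor name.
#' @param n_steps sweep resolution (categorical variables use their
#'   observed classes instead).
#' @param others_at `"mean"` or `"median"` for the fixed values of the
#'   other continuous predictors.
#' @return Data frame with columns `value` and `cloglog`.
#' @export
response_curve <- function(model, variable, n_steps = 100,
                           others_at = c("mean", "median")) {
  others_at <- match.arg(others_at)
  fm <- model$features
  if (!variable %in% fm$vars) stop("unknown variable: ", variable)
  bg <- model$data$background
  if (is.null(bg)) stop("model carries no training data")
  fixed <- lapply(fm$vars, function(v) {
    if (v %in% names(fm$categories)) {
      tb <- table(bg[[v]])
      as.numeric(names(tb)[which.max(tb)])
    } else if (others_at == "mean") mean(bg[[v]]) else stats::median(bg[[v]])
  })
  names(fixed) <- fm$vars
  sweep_vals <- if (variable %in% names(fm$categories))
    fm$categories[[variable]]
  else seq(fm$scale[[variable]][1], fm$scale[[variable]][2],
           length.out = n_steps)
  nd <- as.data.frame(fixed)[rep(1, length(sweep_vals)), , drop = FALSE]
  nd[[variable]] <- sweep_vals
  data.frame(value = sweep_vals,
             cloglog = predict(model, nd, type = "cloglog", clamp = FALSE))
}

#' Plot response curves of a fitted model
#'
#' @param x a [maxent()] model.
#' @param variables which predictors to plot (default all).
#' @param n_steps sweep resolution.
#' @param ... passed to [graphics::plot()].
#' @export
plot.maxent <- function(x, variables = x$features$vars, n_steps = 100, ...) {
  nv <- length(variables)
  mf <- grDevices::n2mfrow(nv)
  op <- graphics::par(mfrow = mf, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in variables) {
    rc <- response_curve(x, v, n_steps = n_steps)
    if (v %in% names(x$features$categories))
      graphics::plot(rc$value, rc$cloglog, type = "h", lwd = 3,
                     xlab = v, ylab = "cloglog suitability",
                     ylim = c(0, 1), ...)
    else
      graphics::plot(rc$value, rc$cloglog, type = "l",
                     xlab = v, ylab = "cloglog suitability",
                     ylim = c(0, 1), ...)
  }
  invisible(x)
}
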