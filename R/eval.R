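#' Spatial block fold assignment
#'
#' Splits presences and background points into spatially contiguous blocks
#' so that validation folds are geographically independent of training
#' folds, limiting the optimism caused by spatial autocorrelation. The
#' default construction uses the quadrants defined by the median longitude
#' and median latitude of the presences (`k = 4`), or the median-longitude
#' halves (`k = 2`); `method = "kmeans"` clusters presence coordinates
#' into `k` blocks instead and assigns background points to the nearest
#' block center.
#'
#' @param presences,background data frames with `x`, `y`.
#' @param k number of blocks (4 or 2 for `"quadrant"`; any >= 2 for
#'   `"kmeans"`).
#' @param method `"quadrant"` or `"kmeans"`.
#' @param seed seed for the kmeans construction.
#' @return A `fold_assignment`: integer block id per presence and per
#'   background point, and `k`.
#' @export
assign_blocks <- function(presences, background, k = 4,
                          method = c("quadrant", "kmeans"), seed = 1) {
  method <- match.arg(method)
  if (k < 2) stop("`k` must be >= 2")
  if (nrow(presences) < k) stop("need at least `k` presences")
  if (method == "quadrant") {
    if (!k %in% c(2L, 4L))
      stop("quadrant blocks support k = 2 or 4; use method = 'kmeans'")
    mx <- stats::median(presences$x)
    my <- stats::median(presences$y)
    blk <- function(df) {
      b <- 1L + as.integer(df$x > mx)
      if (k == 4L) b <- b + 2L * as.integer(df$y > my)
      b
    }
    bp <- blk(presences); bb <- blk(background)
  } else {
    km <- with_seed(seed, stats::kmeans(presences[c("x", "y")], centers = k,
                                        nstart = 5))
    bp <- km$cluster
    d2 <- function(df) {
      dd <- outer(df$x, km$centers[, "x"], `-`)^2 +
            outer(df$y, km$centers[, "y"], `-`)^2
      max.col(-dd)
    }
    bb <- d2(background)
  }
  empty <- setdiff(seq_len(k), unique(bp))
  if (length(empty))
    stop("block(s) ", paste(empty, collapse = ","),
         " hold no presences; use a smaller k")
  structure(list(presence = bp, background = bb, k = k), class = "fold_assignment")
}

#' Area under the ROC curve, rank-based
#'
#' Probability that a randomly chosen presence prediction outranks a
#' randomly chosen background prediction; ties count one half
#' (Mann-Whitney form). Invariant under strictly monotone transforms of
#' the predictions.
#'
#' @param pred_presence,pred_background numeric prediction vectors.
#' @export
auc_score <- function(pred_presence, pred_background) {
  m <- length(pred_presence); n <- length(pred_background)
  if (m == 0 || n == 0) stop("both prediction sets must be non-empty")
  r <- rank(c(pred_presence, pred_background))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Small-sample corrected AIC of a MaxEnt model
#'
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)` with `k` the number of non-zero
#' coefficients and `lnL` the presence log-likelihood under the raw output
#' standardized to sum to 1 over the model's background set. Undefined
#' when `n <= k + 1`; returned as `+Inf` with a warning so the model
#' cannot win selection.
#'
#' @param model a [maxent()] model.
#' @param presence_values optional data frame of predictor values at the
#'   presences (defaults to the model's training presences).
#' @export
aicc_score <- function(model, presence_values = NULL) {
  if (is.null(presence_values)) presence_values <- model$data$presence
  raw <- predict(model, presence_values, type = "raw", clamp = FALSE)
  lnL <- sum(log(pmax(raw, 1e-300)))
  k <- sum(model$beta != 0)
  n <- nrow(presence_values)
  if (n <= k + 1) {
    warning("AICc undefined: n_presence <= k + 1")
    return(Inf)
  }
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Continuous Boyce Index
#'
#' Moving-window calibration statistic for presence-only evaluation:
#' windows of width `window_frac * (max - min)` are centered at
#' `n_windows` evenly spaced midpoints spanning the prediction range; in
#' each window, `P` is the share of presence predictions and `E` the share
#' of reference (background/area) predictions falling inside, and the
#' index is the Spearman rank correlation between `F = P/E` (over windows
#' with `E > 0`) and the window midpoints. 1 means the predicted-to-
#' expected ratio increases monotonically with suitability (a calibrated
#' ranking), 0 random, -1 inverted.
#'
#' @param pred_presence predictions at presence points.
#' @param pred_reference predictions over the reference set (background or
#'   the whole area).
#' @param n_windows number of window midpoints.
#' @param window_frac window width as a fraction of the prediction range.
#' @export
boyce_index <- function(pred_presence, pred_reference,
                        n_windows = 101, window_frac = 0.1) {
  if (length(pred_reference) == 0) stop("reference must be non-empty")
  rng <- range(c(pred_presence, pred_reference))
  if (diff(rng) == 0) stop("undefined CBI: constant predictions")
  w <- window_frac * diff(rng)
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_windows)
  P <- E <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    lo <- mids[i] - w / 2; hi <- mids[i] + w / 2
    P[i] <- mean(pred_presence >= lo & pred_presence <= hi)
    E[i] <- mean(pred_reference >= lo & pred_reference <= hi)
  }
  ok <- E > 0
  if (sum(ok) < 3) stop("undefined CBI: fewer than 3 windows with E > 0")
  F <- P[ok] / E[ok]
  if (stats::sd(F) == 0) stop("undefined CBI: constant P/E ratio")
  stats::cor(F, mids[ok], method = "spearman")
}

#' Tune feature classes and regularization multiplier
#'
#' Grid search over feature-class configurations and regularization
#' multipliers. Every combination is fitted on the full data for AICc and
#' evaluated by spatial block cross-validation (train on k-1 blocks, test
#' on the held-out one) for training/validation AUC, their absolute
#' difference (overfitting gauge) and the Continuous Boyce Index. The
#' table is ranked by AICc (ties broken by fewer non-zero parameters, then
#' lower multiplier). The returned selection minimizes the mean AUC
#' difference and maximizes the mean CBI, optionally restricted to one
#' feature-class family — the final judgement on response-curve
#' plausibility is left to the analyst, for whom per-candidate curves can
#' be exported with [response_curve()].
#'
#' @param stack an [env_stack()].
#' @param presences,background data frames with `x`, `y`.
#' @param classes_grid character vector of feature-class configurations.
#' @param mult_grid numeric vector of regularization multipliers.
#' @param k number of spatial blocks.
#' @param folds optional precomputed [assign_blocks()] result.
#' @param select_family restrict the selection (not the table) to this
#'   feature-class configuration, e.g. `"LQHP"`; `NULL` selects over all.
#' @param ... passed to [maxent()] (knots, tolerance, ...).
#' @return A `maxent_tuning` object: `table` (one row per combination,
#'   ranked by AICc), `selected` (one row), `folds`, and `best_model` (the
#'   selected combination refitted on the full data).
#' @export
tune_maxent <- function(stack, presences, background,
                        classes_grid = c("L", "LQ", "LQH", "LQHP", "LQHPT"),
                        mult_grid = seq(0.5, 5, by = 0.5),
                        k = 4, folds = NULL, select_family = NULL, ...) {
  if (length(classes_grid) == 0 || length(mult_grid) == 0)
    stop("grids must be non-empty")
  if (is.null(folds)) folds <- assign_blocks(presences, background, k = k)
  pv <- stack_extract(stack, presences$x, presences$y)
  bv <- stack_extract(stack, background$x, background$y)
  rows <- list()
  for (cl in classes_grid) for (mu in mult_grid) {
    row <- data.frame(classes = cl, reg_mult = mu, n_params = NA, aicc = NA,
                      auc_train = NA, auc_val = NA,
                      auc_diff = NA, auc_diff_sd = NA,
                      cbi = NA, cbi_sd = NA, failed = FALSE)
    res <- tryCatch({
      full <- maxent(pv, bv, kind = stack$kind, classes = cl,
                     reg_mult = mu, ...)
      at <- av <- ad <- cb <- numeric(folds$k)
      for (b in seq_len(folds$k)) {
        trp <- pv[folds$presence != b, , drop = FALSE]
        trb <- bv[folds$background != b, , drop = FALSE]
        tep <- pv[folds$presence == b, , drop = FALSE]
        teb <- bv[folds$background == b, , drop = FALSE]
        fit <- maxent(trp, trb, kind = stack$kind, classes = cl,
                      reg_mult = mu, ...)
        prt <- predict(fit, trp, type = "cloglog", clamp = FALSE)
        brt <- predict(fit, trb, type = "cloglog", clamp = FALSE)
        prv <- predict(fit, tep, type = "cloglog", clamp = TRUE)
        brv <- predict(fit, teb, type = "cloglog", clamp = TRUE)
        at[b] <- auc_score(prt, brt)
        av[b] <- auc_score(prv, brv)
        ad[b] <- abs(at[b] - av[b])
        cb[b] <- boyce_index(prv, brv)
      }
      row$n_params <- sum(full$beta != 0)
      row$aicc <- aicc_score(full)
      row$auc_train <- mean(at); row$auc_val <- mean(av)
      row$auc_diff <- mean(ad); row$auc_diff_sd <- stats::sd(ad)
      row$cbi <- mean(cb); row$cbi_sd <- stats::sd(cb)
      row
    }, error = function(e) {
      message("candidate ", cl, " x ", mu, " failed: ", conditionMessage(e))
      row$failed <- TRUE
      row
    })
    rows[[length(rows) + 1L]] <- res
  }
  tab <- do.call(rbind, rows)
  ok <- !tab$failed
  ord <- order(tab$aicc, tab$n_params, tab$reg_mult)
  tab <- tab[ord, ]
  tab$rank <- NA_integer_
  tab$rank[!tab$failed] <- seq_len(sum(!tab$failed))

  cand <- tab[!tab$failed, , drop = FALSE]
  if (!is.null(select_family)) {
    fam <- cand[cand$classes == select_family, , drop = FALSE]
    if (nrow(fam) == 0) stop("no successful candidate in family ", select_family)
    cand <- fam
  }
  if (nrow(cand) == 0) stop("all tuning candidates failed")
  sel <- cand[order(cand$auc_diff, -cand$cbi, cand$reg_mult), ][1, ]
  best <- maxent(pv, bv, kind = stack$kind, classes = sel$classes,
                 reg_mult = sel$reg_mult, ...)
  structure(list(table = tab, selected = sel, folds = folds,
                 best_model = best),
            class = "maxent_tuning")
}

#' @export
print.maxent_tuning <- function(x, ...) {
  cat(sprintf("MaxEnt tuning: %d candidates (%d failed)\n",
              nrow(x$table), sum(x$table$failed)))
  cat("Top of the AICc ranking:\n")
  print.data.frame(utils::head(x$table[c("rank", "classes", "reg_mult",
                                         "n_params", "aicc", "auc_diff",
                                         "cbi")], 8),
                   row.names = FALSE, digits = 4)
  cat(sprintf("Selected: %s, reg_mult %g (AUC_diff %.3f +/- %.3f, CBI %.3f +/- %.3f)\n",
              x$selected$classes, x$selected$reg_mult,
              x$selected$auc_diff, x$selected$auc_diff_sd,
              x$selected$cbi, x$selected$cbi_sd))
  invisible(x)
}

#' Write a tuning table as CSV
#' @param tuning a [tune_maxent()] result.
#' @param path output path.
#' @export
write_tuning_table <- function(tuning, path) {
  utils::write.csv(tuning$table, path, row.names = FALSE)
  invisible(path)
}
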