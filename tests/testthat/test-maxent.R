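test_that("background sampling is uniform, exhaustive and deterministic", {
  fx <- tiny_truth(nrow = 20, ncol = 20, seed = 1)
  all_bg <- sample_background(fx$stack, 400, seed = 1)
  expect_equal(nrow(all_bg), 400)
  expect_equal(sort(all_bg$cell), 1:400)  # n = all cells: every cell once
  a <- sample_background(fx$stack, 150, seed = 9)
  b <- sample_background(fx$stack, 150, seed = 9)
  expect_identical(a, b)
  expect_error(sample_background(fx$stack, 401, seed = 1), "exceeds")
  # CLT check: per-layer background means match the landscape means
  # within 3 standard errors (finite-population corrected)
  fx2 <- tiny_truth(nrow = 60, ncol = 60, seed = 2)
  bg <- sample_background(fx2$stack, 1500, seed = 3)
  vals <- stack_extract(fx2$stack, bg$x, bg$y)
  N <- 3600
  for (v in c("env01", "env02")) {
    land <- as.vector(fx2$stack$layers[[v]])
    se <- sd(land) / sqrt(1500) * sqrt((N - 1500) / (N - 1))
    expect_lt(abs(mean(vals[[v]]) - mean(land)), 3 * se)
  }
})

test_that("no-signal presences get shrunk to near-zero coefficients", {
  fx <- tiny_truth(nrow = 40, ncol = 40, seed = 5)
  bg <- sample_background(fx$stack, 1600, seed = 1)
  bv <- stack_extract(fx$stack, bg$x, bg$y)
  # exact no-signal limit: presences distributed as the background itself
  m0 <- maxent(bv, bv, kind = fx$stack$kind, classes = "LQ", reg_mult = 1)
  expect_true(all(abs(m0$beta) <= 0.05))
  # finite presence sample: coefficients stay at the sampling-noise scale
  # (the default L1 penalty bounds noise but does not null it)
  set.seed(11)
  pv <- bv[sample(nrow(bv), 1000, replace = TRUE), ]
  m1 <- maxent(pv, bv, kind = fx$stack$kind, classes = "LQ", reg_mult = 1)
  expect_true(all(abs(m1$beta) <= 1.5))
  expect_lt(abs(auc_score(predict(m1, pv, type = "cloglog"),
                          predict(m1, bv, type = "cloglog")) - 0.5), 0.05)
})

test_that("fit matches the brute-force maximizer on a discrete problem", {
  # 4 background cells, one binary feature, presences only where f = 1
  bv <- data.frame(f = c(0, 0, 1, 1))
  pv <- data.frame(f = c(1, 1, 1, 1, 1, 1))
  m <- maxent(pv, bv, kind = c(f = "continuous"), classes = "L",
              reg_mult = 1e-3, sd_floor = 1, tol = 1e-12)
  # independent oracle: grid search over beta on the same objective
  lam <- unname(m$lambda)
  betas <- seq(0, 20, by = 1e-3)
  obj <- vapply(betas, function(b)
    ref_objective(b, as.matrix(pv), as.matrix(bv), lam), numeric(1))
  b_star <- betas[which.min(obj)]
  raw_star <- exp(b_star * bv$f) / sum(exp(b_star * bv$f))
  raw_fit <- predict(m, bv, type = "raw", clamp = FALSE)
  expect_lt(max(abs(raw_fit - raw_star)), 1e-3)
})

test_that("objective value matches exhaustive search on tiny problems", {
  set.seed(13)
  for (rep in 1:3) {
    Xb <- matrix(runif(12), 6, 2)
    Xp <- Xb[sample(6, 10, replace = TRUE, prob = c(1, 1, 2, 2, 4, 4)), ]
    pv <- as.data.frame(Xp); bv <- as.data.frame(Xb)
    names(pv) <- names(bv) <- c("u", "v")
    m <- maxent(pv, bv, kind = c(u = "continuous", v = "continuous"),
                classes = "L", reg_mult = 1, tol = 1e-12)
    fm <- m$features
    Xp_f <- feature_eval(fm, pv); Xb_f <- feature_eval(fm, bv)
    lam <- unname(m$lambda)
    # coarse grid + Nelder-Mead refinement, independent of the fitter
    grid <- as.matrix(expand.grid(seq(-6, 6, 0.25), seq(-6, 6, 0.25)))
    vals <- apply(grid, 1, ref_objective, Xp = Xp_f, Xb = Xb_f, lambda = lam)
    start <- grid[which.min(vals), ]
    opt <- optim(start, ref_objective, Xp = Xp_f, Xb = Xb_f, lambda = lam,
                 control = list(reltol = 1e-14, maxit = 5000))
    mine <- ref_objective(unname(m$beta), Xp_f, Xb_f, lam)
    expect_lt(mine, opt$value + 1e-6)
  }
})

test_that("heavy regularization collapses to the uniform model", {
  fx <- tiny_truth(nrow = 16, ncol = 16, seed = 6)
  occ <- sample_presences(fx$truth, 50, seed = 2)
  bg <- sample_background(fx$stack, 256, seed = 3)
  m <- maxent(occ, bg, stack = fx$stack, classes = "LQ", reg_mult = 1e6)
  expect_true(all(m$beta == 0))
  raw <- predict(m, stack_extract(fx$stack, bg$x, bg$y), type = "raw")
  expect_equal(unname(raw), rep(1 / 256, 256))
  cll <- predict(m, stack_extract(fx$stack, bg$x, bg$y), type = "cloglog")
  expect_equal(unname(cll), rep(1 - exp(-1), 256))
})

test_that("raw output is a probability distribution over the background", {
  fx <- tiny_truth(nrow = 24, ncol = 24, seed = 7)
  occ <- sample_presences(fx$truth, 120, seed = 4)
  bg <- sample_background(fx$stack, 500, seed = 5)
  for (cl in c("LQ", "LQH")) {
    m <- maxent(occ, bg, stack = fx$stack, classes = cl, reg_mult = 1,
                hinge_knots = 8)
    raw <- predict(m, stack_extract(fx$stack, bg$x, bg$y), type = "raw",
                   clamp = FALSE)
    expect_equal(sum(raw), 1, tolerance = 1e-9)
    cll <- predict(m, stack_extract(fx$stack, bg$x, bg$y), type = "cloglog")
    expect_true(all(cll > 0 & cll < 1))
    # cloglog is strictly increasing in raw
    o <- order(raw)
    expect_true(all(diff(cll[o]) >= 0))
    expect_gt(cor(cll, raw, method = "spearman"), 1 - 1e-12)
  }
})

test_that("total shrinkage is monotone in the regularization multiplier", {
  fx <- tiny_truth(nrow = 24, ncol = 24, seed = 8)
  occ <- sample_presences(fx$truth, 100, seed = 6)
  bg <- sample_background(fx$stack, 500, seed = 7)
  pv <- stack_extract(fx$stack, occ$x, occ$y)
  bv <- stack_extract(fx$stack, bg$x, bg$y)
  norms <- vapply(c(0.5, 1, 2, 4), function(mu) {
    m <- maxent(pv, bv, kind = fx$stack$kind, classes = "LQ", reg_mult = mu)
    sum(abs(m$beta))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("variable importance separates signal from noise", {
  fx <- tiny_truth(nrow = 40, ncol = 40, seed = 9, height = 6)
  occ <- sample_presences(fx$truth, 300, seed = 8)
  bg <- sample_background(fx$stack, 1000, seed = 9)
  m <- maxent(occ, bg, stack = fx$stack, classes = "LQ", reg_mult = 1)
  imp <- variable_importance(m, n_permutations = 3, seed = 1)
  e1 <- imp[imp$variable == "env01", ]
  e2 <- imp[imp$variable == "env02", ]
  expect_gt(e1$permutation_importance, e2$permutation_importance)
  expect_gt(e1$percent_contribution, e2$percent_contribution)
  expect_equal(sum(imp$percent_contribution), 100, tolerance = 1e-8)
  expect_equal(sum(imp$permutation_importance), 100, tolerance = 1e-8)
  expect_error(variable_importance(m, n_permutations = 0), "n_permutations")
  # single-variable model: both measures are 100% by normalization
  m1 <- maxent(data.frame(a = rbeta(50, 4, 2)), data.frame(a = runif(400)),
               kind = c(a = "continuous"), classes = "LQ")
  i1 <- variable_importance(m1, n_permutations = 2, seed = 1)
  expect_equal(i1$percent_contribution, 100)
  expect_equal(i1$permutation_importance, 100)
})

test_that("response curves recover the shape of the fitted model", {
  # linear-only single-variable model with positive coefficient: increasing
  set.seed(20)
  bv <- data.frame(a = runif(500))
  pv <- data.frame(a = rbeta(100, 5, 1.5))
  m <- maxent(pv, bv, kind = c(a = "continuous"), classes = "L")
  expect_gt(unname(m$beta["a"]), 0)
  rc <- response_curve(m, "a", n_steps = 50)
  expect_true(all(diff(rc$cloglog) > 0))
  # L+Q model with negative quadratic: peak at -bL/(2 bQ) on the scaled axis
  pv2 <- data.frame(a = pmin(pmax(rnorm(300, 0.6, 0.12), 0), 1))
  m2 <- maxent(pv2, bv, kind = c(a = "continuous"), classes = "LQ")
  bL <- unname(m2$beta["a"]); bQ <- unname(m2$beta["a^2"])
  expect_lt(bQ, 0)
  peak_scaled <- min(max(-bL / (2 * bQ), 0), 1)
  rng <- m2$features$scale$a
  rc2 <- response_curve(m2, "a", n_steps = 401)
  peak_obs <- (rc2$value[which.max(rc2$cloglog)] - rng[1]) / diff(rng)
  expect_lt(abs(peak_obs - peak_scaled), 0.01)
})

test_that("models survive a JSON round-trip", {
  fx <- tiny_truth(nrow = 16, ncol = 16, seed = 10)
  occ <- sample_presences(fx$truth, 60, seed = 2)
  bg <- sample_background(fx$stack, 200, seed = 3)
  m <- maxent(occ, bg, stack = fx$stack, classes = "LQH", hinge_knots = 5)
  f <- tempfile(fileext = ".json")
  maxent_to_json(m, f)
  m2 <- maxent_from_json(f)
  nd <- stack_extract(fx$stack, bg$x, bg$y)
  expect_equal(predict(m2, nd, type = "cloglog", clamp = FALSE),
               predict(m, nd, type = "cloglog", clamp = FALSE),
               tolerance = 1e-12)
})
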