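test_that("median quadrant blocks partition presences and background", {
  set.seed(30)
  # four tight clusters, one per quadrant
  centers <- data.frame(x = c(10, 90, 10, 90), y = c(10, 10, 90, 90))
  pres <- data.frame(x = rep(centers$x, each = 25) + rnorm(100),
                     y = rep(centers$y, each = 25) + rnorm(100))
  bg <- data.frame(x = runif(400, 0, 100), y = runif(400, 0, 100))
  fa <- assign_blocks(pres, bg, k = 4)
  expect_equal(sort(unique(fa$presence)), 1:4)
  expect_length(fa$presence, 100)
  expect_length(fa$background, 400)
  # each cluster lands in exactly one block
  expect_equal(length(unique(fa$presence[1:25])), 1)
  # median splits balance presence counts per axis to within 1
  tab <- table(fa$presence)
  left <- sum(tab[c("1", "3")]); right <- sum(tab[c("2", "4")])
  expect_lte(abs(left - right), 1)
  # points on a diagonal leave two quadrants empty: error
  lop <- data.frame(x = 1:5, y = 1:5)
  expect_error(assign_blocks(lop, bg, k = 4), "smaller k")
})

test_that("AUC equals pairwise enumeration and ranks ties as half", {
  expect_equal(auc_score(c(0.9, 0.4), c(0.5, 0.1)), 0.75)  # 3 of 4 pairs
  expect_equal(auc_score(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc_score(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  set.seed(31)
  pp <- round(runif(23), 1); pb <- round(runif(17), 1)
  brute <- mean(outer(pp, pb, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(auc_score(pp, pb), brute)
  # invariance under a strictly monotone transform
  expect_equal(auc_score(qlogis(pmin(pmax(pp, .01), .99)),
                         qlogis(pmin(pmax(pb, .01), .99))),
               auc_score(pp, pb))
})

test_that("AICc follows its closed form and blows up when n <= k + 1", {
  # uniform raw over N = 10 cells, n = 5 presences, k = 0
  bv <- data.frame(a = seq(0.05, 0.95, by = 0.1))
  pv <- data.frame(a = bv$a[c(1, 3, 5, 7, 9)])
  m <- maxent(pv, bv, kind = c(a = "continuous"), classes = "L",
              reg_mult = 1e9)
  expect_true(all(m$beta == 0))
  expect_equal(aicc_score(m), -2 * 5 * log(0.1), tolerance = 1e-9)
  # recomputing from (k, lnL, n) reproduces the value exactly
  raw <- predict(m, pv, type = "raw", clamp = FALSE)
  k <- sum(m$beta != 0); n <- nrow(pv); lnL <- sum(log(raw))
  expect_equal(aicc_score(m), 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1))
  # k = n - 1 makes the correction blow up
  set.seed(32)
  bv2 <- data.frame(a = runif(200), b = runif(200), c = runif(200))
  pv2 <- data.frame(a = rbeta(4, 5, 1), b = rbeta(4, 5, 1), c = rbeta(4, 1, 5))
  m2 <- suppressWarnings(  # near-separable toy fit may hit the iteration cap
    maxent(pv2, bv2, kind = c(a = "continuous", b = "continuous",
                              c = "continuous"),
           classes = "L", reg_mult = 0.1))
  if (sum(m2$beta != 0) >= nrow(pv2) - 1)
    expect_warning(expect_equal(aicc_score(m2), Inf), "undefined")
})

test_that("the Boyce index rewards calibration and punishes inversion", {
  fx <- tiny_truth(nrow = 50, ncol = 50, seed = 33, height = 6)
  occ <- sample_presences(fx$truth, 4000, seed = 12, jitter = 0)
  suit <- fx$truth$suitability
  pred_pres <- grid_extract(suit, occ$x, occ$y)
  pred_ref <- as.vector(suit$values)
  expect_gte(boyce_index(pred_pres, pred_ref), 0.95)
  expect_lte(boyce_index(1 - pred_pres, 1 - pred_ref), -0.95)
  # uniform presences carry no calibration signal: the null CBI is
  # centered at zero (single draws are noisy because windows overlap)
  set.seed(34)
  nulls <- replicate(6, boyce_index(sample(pred_ref, 1000, replace = TRUE),
                                    pred_ref))
  expect_lt(abs(mean(nulls)), 0.3)
  expect_error(boyce_index(rep(0.5, 5), rep(0.5, 9)), "constant")
})

test_that("AICc does not reward spurious threshold complexity", {
  # data generated from an LQ-representable truth: the threshold-laden
  # family should not beat the parsimonious one in most replicates
  wins <- 0
  for (s in 1:3) {
    fx <- tiny_truth(nrow = 32, ncol = 32, seed = 60 + s)
    occ <- sample_presences(fx$truth, 150, seed = 70 + s)
    bg <- sample_background(fx$stack, 500, seed = 80 + s)
    pv <- stack_extract(fx$stack, occ$x, occ$y)
    bv <- stack_extract(fx$stack, bg$x, bg$y)
    a_lq <- aicc_score(maxent(pv, bv, kind = fx$stack$kind, classes = "LQ"))
    a_t <- aicc_score(maxent(pv, bv, kind = fx$stack$kind, classes = "LQHPT",
                             hinge_knots = 8, threshold_knots = 8))
    if (a_lq <= a_t) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("tuning tables cover the grid and single candidates win", {
  fx <- tiny_truth(nrow = 32, ncol = 32, seed = 35)
  occ <- sample_presences(fx$truth, 120, seed = 13)
  bg <- sample_background(fx$stack, 400, seed = 14)
  tun <- tune_maxent(fx$stack, occ, bg, classes_grid = c("L", "LQ"),
                     mult_grid = c(1, 2), hinge_knots = 5)
  expect_equal(nrow(tun$table), 4)
  expect_equal(sort(tun$table$rank), 1:4)
  # ranking is by AICc
  expect_equal(tun$table$aicc, sort(tun$table$aicc))
  single <- tune_maxent(fx$stack, occ, bg, classes_grid = "LQ",
                        mult_grid = 2, folds = tun$folds)
  expect_equal(single$selected$classes, "LQ")
  expect_equal(single$selected$reg_mult, 2)
  # family restriction confines the selection, not the table
  fam <- tune_maxent(fx$stack, occ, bg, classes_grid = c("L", "LQ"),
                     mult_grid = c(1, 2), folds = tun$folds,
                     select_family = "L")
  expect_equal(fam$selected$classes, "L")
  expect_equal(nrow(fam$table), 4)
})
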