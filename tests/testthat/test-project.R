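test_that("thresholds follow the stated order-statistic conventions", {
  th <- compute_thresholds(seq(0.1, 1.0, by = 0.1))
  expect_equal(th$fixed, 1 - exp(-1))
  expect_equal(round(th$fixed, 4), 0.6321)
  expect_equal(th$mtp, 0.1)
  expect_equal(th$p10, 0.19)  # linear interpolation between order statistics
  ch <- suppressWarnings(compute_thresholds(rep(0.4, 12)))
  expect_equal(ch$mtp, 0.4)
  expect_equal(ch$p10, 0.4)
  expect_error(compute_thresholds(numeric(0)), "presence")
})

test_that("classification partitions area and respects boundaries", {
  th <- structure(list(mtp = 0.05, p10 = 0.2, fixed = 1 - exp(-1)),
                  class = "threshold_set")
  # uniform map above the fixed threshold is all High
  u <- raster_grid(matrix(0.7, 5, 5), cellsize = 1000)
  cm <- classify_map(u, th)
  expect_equal(cm$area_table$pct[cm$area_table$class == "High"], 100)
  # counting: 7 cells above the fixed threshold on a 10x10 1-km grid
  v <- matrix(0.1, 10, 10); v[1:7] <- 0.9
  cm2 <- classify_map(raster_grid(v, cellsize = 1000), th)
  expect_equal(cm2$area_table$area_km2[cm2$area_table$class == "High"], 7)
  # partition: class areas sum to the non-nodata extent exactly
  v[3, 5] <- NA
  cm3 <- classify_map(raster_grid(v, cellsize = 1000), th)
  expect_equal(sum(cm3$area_table$area_km2), 99)
  # a cell exactly at a threshold joins the lower class
  b <- classify_map(raster_grid(matrix(c(0.05, 0.2, 1 - exp(-1), 0.9), 2, 2),
                                cellsize = 1000), th)
  got <- as.vector(b$class_raster$values)
  expect_equal(sort(got), 1:4)  # Negligible, Low, Moderate, High
  # binary High cells equal four-class High cells
  v2 <- matrix(runif(100), 10, 10)
  r2 <- raster_grid(v2, cellsize = 1000)
  four <- classify_map(r2, th, "four")
  bin <- classify_map(r2, th, "binary")
  expect_equal(bin$class_raster$values == 2, four$class_raster$values == 4)
})

test_that("scenario projection measures range change and altitude shift", {
  fx <- tiny_truth(nrow = 32, ncol = 32, seed = 40, height = 6, offset = -4)
  occ <- sample_presences(fx$truth, 200, seed = 15)
  bg <- sample_background(fx$stack, 600, seed = 16)
  m <- maxent(occ, bg, stack = fx$stack, classes = "LQ", reg_mult = 1)
  pred_pres <- predict(m, stack_extract(fx$stack, occ$x, occ$y),
                       type = "cloglog", clamp = FALSE)
  th <- compute_thresholds(pred_pres)
  present <- classify_map(predict(m, fx$stack, type = "cloglog"), th)
  # identical future stack: zero change
  same <- project_scenario(m, fx$stack, "same", "now", present)
  expect_equal(same$pct_change, 0)
  expect_equal(same$high_km2, high_area_km2(present))
  # uniformly less suitable conditions never gain area (monotonicity):
  # push env01 far from the species' optimum
  worse <- shift_future(fx$stack, c(env01 = 3))
  res <- project_scenario(m, worse, "worse", "2100", present)
  expect_lte(res$high_km2, same$high_km2)
  # the DEM summary tracks high-suitability cells
  dem <- raster_grid(100 + 50 * fx$stack$layers$env02,
                     fx$grid$xmin, fx$grid$ymax, fx$grid$cellsize, fx$grid$crs)
  with_dem <- project_scenario(m, fx$stack, "same", "now", present, dem = dem)
  hi <- with_dem$binary$class_raster$values == 2
  expect_equal(unname(with_dem$altitude[["50%"]]),
               unname(median(dem$values[hi], na.rm = TRUE)))
})

test_that("warming shifts suitable habitat upslope", {
  # a truth whose optimum sits at low values of a temperature-like layer
  # that decreases with elevation: uniform warming pushes the suitable
  # band to higher altitude
  g <- raster_grid(matrix(1, 48, 48), cellsize = 1000, crs = "EPSG:32632")
  st <- generate_env_stack(g, 3, n_classes = 3, smoothness = 4, seed = 41)
  elev <- 1500 * stats::plogis(st$layers$env01)      # synthetic DEM
  temp <- 20 - 0.006 * elev + 0.3 * st$layers$env02  # lapse-rate temperature
  st$layers$temp <- temp
  st$kind <- c(st$kind, temp = "continuous")
  tr <- true_suitability(st, list(
    true_response("temp", "unimodal", list(center = 14, width = 1.5,
                                           height = 6))), offset = -3)
  occ <- sample_presences(tr, 250, seed = 17)
  bg <- sample_background(st, 800, seed = 18)
  m <- maxent(occ, bg, stack = st, classes = "LQ", reg_mult = 1)
  th <- compute_thresholds(predict(m, stack_extract(st, occ$x, occ$y),
                                   type = "cloglog", clamp = FALSE))
  present <- classify_map(predict(m, st, type = "cloglog"), th)
  dem <- raster_grid(elev, g$xmin, g$ymax, g$cellsize, g$crs)
  now <- project_scenario(m, st, "now", "now", present, dem = dem)
  warm <- project_scenario(m, shift_future(st, c(temp = 1.5)),
                           "warm", "2100", present, dem = dem)
  expect_gt(warm$altitude[["50%"]], now$altitude[["50%"]])
})

test_that("MESS matches its per-branch formula and a scalar oracle", {
  ref <- data.frame(a = 1:10)
  # inside the reference range: similarity is non-negative
  expect_true(all(mess(ref, data.frame(a = c(2, 5, 9))) >= 0))
  # below the minimum: f = 0 branch
  expect_equal(mess(ref, data.frame(a = 0)), 100 * (0 - 1) / 9)
  # at the reference median: f = 50 gives 100
  expect_equal(mess(ref, data.frame(a = 5.5)), 100)
  # constant reference variables are excluded with a warning
  expect_warning(
    s <- mess(data.frame(a = 1:10, z = rep(2, 10)), data.frame(a = 5.5, z = 9)),
    "excluded")
  expect_equal(s, 100)

  # scalar re-implementation as an independent oracle on random instances
  mess_scalar <- function(ref_v, q) {
    f <- 100 * sum(ref_v < q) / length(ref_v)
    mn <- min(ref_v); mx <- max(ref_v)
    if (f == 0) 100 * (q - mn) / (mx - mn)
    else if (f <= 50) 2 * f
    else if (f < 100) 2 * (100 - f)
    else 100 * (mx - q) / (mx - mn)
  }
  set.seed(43)
  for (rep in 1:5) {
    refd <- data.frame(a = rnorm(150), b = runif(150), c = rexp(150))
    qd <- data.frame(a = rnorm(60, sd = 2), b = runif(60, -0.5, 1.5),
                     c = rexp(60, 0.5))
    expected <- vapply(seq_len(60), function(i)
      min(vapply(names(refd), function(v)
        mess_scalar(refd[[v]], qd[[v]][i]), numeric(1))), numeric(1))
    expect_equal(mess(refd, qd), expected, tolerance = 1e-12)
  }
})
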