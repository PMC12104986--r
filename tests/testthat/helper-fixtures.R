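# Shared fixture builders. Everything is generated in code at test time.

# A 1 x n grid stack whose layer values are the columns of `df`, so
# point-free operations (correlation, VIF, features) can be driven with
# exact numbers. Cell centroids are x = i - 0.5, y = 0.5.
stack_from_values <- function(df, kind = NULL) {
  df <- as.data.frame(df)
  layers <- lapply(df, function(v)
    sdmaxent::raster_grid(matrix(v, nrow = 1), cellsize = 1))
  if (is.null(kind))
    kind <- stats::setNames(rep("continuous", ncol(df)), names(df))
  sdmaxent::env_stack(layers, kind = kind)
}

all_points <- function(stack) {
  ctr <- sdmaxent::grid_centroids(stack$grid)
  data.frame(x = ctr[, "x"], y = ctr[, "y"])
}

# n x k sample whose empirical correlation matrix is exactly C:
# orthonormalize centered Gaussian noise, then mix through chol(C).
exact_corr_sample <- function(C, n, seed = 1) {
  k <- ncol(C)
  set.seed(seed)
  Z <- scale(matrix(rnorm(n * k), n, k), scale = FALSE)
  W <- qr.Q(qr(Z))
  X <- W %*% chol(C)
  as.data.frame(X)
}

# Small landscape + unimodal truth used across tests.
tiny_truth <- function(nrow = 64, ncol = 64, seed = 7, center = 0.3,
                       height = 5, offset = -3) {
  g <- sdmaxent::raster_grid(matrix(1, nrow, ncol), cellsize = 1000,
                             crs = "EPSG:32632")
  st <- sdmaxent::generate_env_stack(g, 4, n_classes = 3, smoothness = 3,
                                     seed = seed)
  tr <- sdmaxent::true_suitability(st, list(
    sdmaxent::true_response("env01", "unimodal",
                            list(center = center, width = 0.8,
                                 height = height))),
    offset = offset)
  list(grid = g, stack = st, truth = tr)
}

# Reference MaxEnt objective, written independently of the fitting code:
# -mean_presence(eta) + log sum_bg exp(eta) + sum lambda |beta|.
ref_objective <- function(beta, Xp, Xb, lambda) {
  eta_b <- drop(Xb %*% beta)
  m <- max(eta_b)
  -mean(drop(Xp %*% beta)) + m + log(sum(exp(eta_b - m))) +
    sum(lambda * abs(beta))
}
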