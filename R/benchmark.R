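#' Reference virtual-species benchmark landscape
#'
#' Builds the default virtual species used to validate the pipeline:
#' a 160 x 160 lattice of 1-km cells (25,600 cells, so a 20,000-point
#' background sample fits without replacement) with eight smooth
#' continuous layers — two pairs strongly correlated, so collinearity
#' screening has work to do — and a five-class soil layer; a truth with
#' unimodal (Gaussian-bump) responses to two climate-like layers and mild
#' soil preferences, combined on the logistic scale with a negative
#' offset so mean suitability stays moderate (a Gaussian bump is exactly
#' quadratic on the link scale, so an L+Q feature set can represent the
#' truth); and presence-only records sampled proportionally to
#' suitability.
#'
#' @param seed integer seed driving every random step.
#' @param nrow,ncol grid dimensions.
#' @param n_presences presence records sampled from the truth.
#' @param n_background uniform background points.
#' @return List with `stack`, `truth`, `presences`, `background`, and
#'   `responses` (the true response list).
#' @export
make_benchmark <- function(seed = 1, nrow = 160, ncol = 160,
                           n_presences = 500, n_background = 20000) {
  grid <- raster_grid(matrix(1, nrow, ncol), xmin = 600000, ymax = 4800000,
                      cellsize = 1000, crs = "EPSG:32632")
  corr <- diag(8)
  corr[1, 2] <- corr[2, 1] <- 0.85
  corr[5, 6] <- corr[6, 5] <- 0.75
  stack <- generate_env_stack(grid, n_continuous = 8, target_corr = corr,
                              n_classes = 5, smoothness = 4, seed = seed)
  responses <- list(
    true_response("env01", "unimodal",
                  list(center = 0.4, width = 0.8, height = 4)),
    true_response("env03", "unimodal",
                  list(center = -0.2, width = 1.0, height = 3)),
    true_response("soil", "categorical",
                  list(weights = c("1" = 0, "2" = 0.3, "3" = 0.8,
                                   "4" = 0.3, "5" = 0))))
  truth <- true_suitability(stack, responses, offset = -6)
  presences <- sample_presences(truth, n_presences, seed = seed + 1)
  background <- sample_background(stack, n_background, seed = seed + 2)
  list(stack = stack, truth = truth, presences = presences,
       background = background, responses = responses)
}
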