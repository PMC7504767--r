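#' Pipeline configuration
#'
#' Collects the pipeline constants: heatmap dimensions (280 x 300),
#' grid dimensions (56 x 60), gradient anchor potencies (3.72 green,
#' 5.75 yellow, 8.75 red), probability-smoothing epsilon, relative-
#' entropy log base, and the Gaussian-process search settings. Image
#' dimensions must be exact multiples of the grid dimensions so cell
#' blocks tile the image.
#'
#' @param grid_width,grid_height grid dimensions (defaults 56, 60).
#' @param image_width,image_height heatmap dimensions (defaults 280,
#'   300).
#' @param anchors gradient anchor potencies `c(low, mid, high)`.
#' @param epsilon per-bin additive smoothing for probabilities.
#' @param log_base `exp(1)` for nats (default) or `2` for bits.
#' @param mds_restarts number of MDS starting configurations.
#' @param length_scale_bounds,noise_bounds GPR hyperparameter bounds.
#' @param extent_margin fractional bounding-box expansion of the raster
#'   extent.
#' @return A list of class `al_config`.
#' @export
al_config <- function(grid_width = 56L, grid_height = 60L,
                      image_width = 280L, image_height = 300L,
                      anchors = c(low = 3.72, mid = 5.75, high = 8.75),
                      epsilon = 0.5, log_base = exp(1),
                      mds_restarts = 4L,
                      length_scale_bounds = c(1e-2, 1e2),
                      noise_bounds = c(1e-5, 1),
                      extent_margin = 0.05) {
  if (image_width %% grid_width != 0L || image_height %% grid_height != 0L)
    stop_actland("image dimensions (", image_width, " x ", image_height,
                 ") must be divisible by grid dimensions (", grid_width,
                 " x ", grid_height, ")")
  if (length(anchors) != 3L || any(diff(as.numeric(anchors)) <= 0))
    stop_actland("anchors must be three increasing potencies")
  if (epsilon < 0) stop_actland("epsilon must be >= 0")
  structure(list(grid_width = as.integer(grid_width),
                 grid_height = as.integer(grid_height),
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 anchors = stats::setNames(as.numeric(anchors),
                                           c("low", "mid", "high")),
                 epsilon = epsilon, log_base = log_base,
                 mds_restarts = as.integer(mds_restarts),
                 length_scale_bounds = length_scale_bounds,
                 noise_bounds = noise_bounds,
                 extent_margin = extent_margin,
                 alpha_candidates = ALPHA_GRID),
            class = "al_config")
}

#' @export
print.al_config <- function(x, ...) {
  cat("Activity-landscape pipeline configuration\n")
  cat("  image:", x$image_width, "x", x$image_height,
      " grid:", x$grid_width, "x", x$grid_height,
      " (cells of", (x$image_width / x$grid_width) *
        (x$image_height / x$grid_height), "px)\n")
  cat("  gradient anchors (pKi):", paste(x$anchors, collapse = " / "), "\n")
  cat("  epsilon:", x$epsilon, " log base:",
      if (abs(x$log_base - exp(1)) < 1e-12) "e" else x$log_base, "\n")
  invisible(x)
}
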