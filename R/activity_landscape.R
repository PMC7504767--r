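#' Fit a 3D activity landscape model
#'
#' Builds the full activity-landscape (AL) model of a compound dataset:
#' pairwise ECFP4 Tanimoto distances, a 2D chemical-space projection by
#' metric multidimensional scaling, a Gaussian-process potency surface
#' (Matern 3/2 + White kernel with log-marginal-likelihood alpha
#' selection), the red-yellow-green potency heatmap (280 x 300), and the
#' eight-category cell-intensity distribution on the 56 x 60 grid.
#'
#' @param x a [compound_set()], a data frame with columns `id`, `pki`
#'   and optionally `smiles`, or the path to a compound table readable
#'   by [read_compound_table()].
#' @param config an [al_config()] with the pipeline constants.
#' @param seed integer seed for the MDS restarts (the only stochastic
#'   stage); the whole fit is deterministic given `x` and `seed`.
#' @param id dataset identifier carried into the feature vector;
#'   defaults to `"AL"`.
#' @param fingerprints optional list of bit-index fingerprints
#'   overriding those in `x`.
#' @return An object of class `activity_landscape` with components
#'   `compounds`, `distances` (Tanimoto matrix), `projection`
#'   (`mds_projection`), `surface` (`potency_surface`), `raster`
#'   (`potency_raster`), `heatmap` (`heatmap_image`), `intensity`
#'   (`intensity_map`), `cells` (`cell_grid`), `distribution`
#'   (`cell_distribution`), `config`, `seed` and `id`.
#' @examples
#' d <- generate_dataset(n_compounds = 60, n_series = 4, seed = 1)
#' al <- activity_landscape(d$compounds, seed = 1)
#' al
#' summary(al)
#' @export
activity_landscape <- function(x, config = al_config(), seed = 0L,
                               id = "AL", fingerprints = NULL) {
  cs <- if (inherits(x, "compound_set")) {
    x
  } else if (is.data.frame(x)) {
    nm <- tolower(names(x)); names(x) <- nm
    if (!all(c("id", "pki") %in% nm))
      stop_actland("data frame must have columns 'id' and 'pki'")
    compound_set(x$id, x$pki, fingerprints = fingerprints,
                 smiles = if ("smiles" %in% nm) x$smiles else NULL)
  } else if (is.character(x) && length(x) == 1L) {
    read_compound_table(x)
  } else {
    stop_actland("x must be a compound_set, data frame or file path")
  }
  if (!is.null(fingerprints)) cs$fingerprints <- NULL
  if (is.null(cs$fingerprints)) {
    fps <- if (!is.null(fingerprints)) fingerprints else
      compute_fingerprints(cs$smiles)
    cs <- compound_set(cs$ids, cs$potencies, fingerprints = fps,
                       smiles = cs$smiles)
  }
  dm <- tanimoto_distance_matrix(cs)
  proj <- project_mds(dm, seed = seed, n_restarts = config$mds_restarts)
  surf <- fit_surface(proj, cs$potencies,
                      length_scale_bounds = config$length_scale_bounds,
                      noise_bounds = config$noise_bounds)
  raster <- evaluate_surface(surf, width = config$image_width,
                             height = config$image_height,
                             margin = config$extent_margin)
  hm <- render_heatmap(raster, anchors = config$anchors)
  im <- rg_intensity(hm)
  cells <- partition_cells(im, grid_width = config$grid_width,
                           grid_height = config$grid_height)
  fv <- categorize_cells(cells, epsilon = config$epsilon, id = id)
  fv$image <- paste0(config$image_width, "x", config$image_height)
  structure(list(compounds = cs, distances = dm, projection = proj,
                 surface = surf, raster = raster, heatmap = hm,
                 intensity = im, cells = cells, distribution = fv,
                 config = config, seed = seed, id = id),
            class = "activity_landscape")
}

#' @export
feature_vector.activity_landscape <- function(x, ...) x$distribution

#' @export
print.activity_landscape <- function(x, ...) {
  cat("3D activity landscape '", x$id, "'\n", sep = "")
  cat("  compounds:", x$compounds$n,
      " pKi range: [", format(min(x$compounds$potencies), digits = 3), ",",
      format(max(x$compounds$potencies), digits = 3), "]\n")
  cat("  MDS stress ratio:", format(x$projection$stress_ratio, digits = 3),
      " GPR alpha:", format(x$surface$alpha, digits = 3),
      " length scale:", format(x$surface$length_scale, digits = 3), "\n")
  cat("  cell counts (valleys -> peaks):",
      paste(x$distribution$counts, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.activity_landscape <- function(object, ...) {
  res <- residuals(object)
  structure(list(id = object$id, n = object$compounds$n,
                 potency_range = range(object$compounds$potencies),
                 stress = object$projection$stress,
                 stress_ratio = object$projection$stress_ratio,
                 coef = coef(object$surface),
                 lml = object$surface$lml,
                 residual_quartiles = quantile(res),
                 distribution = object$distribution),
            class = "summary.activity_landscape")
}

#' @export
print.summary.activity_landscape <- function(x, ...) {
  cat("3D activity landscape '", x$id, "': ", x$n, " compounds, pKi [",
      format(x$potency_range[1L], digits = 3), ", ",
      format(x$potency_range[2L], digits = 3), "]\n", sep = "")
  cat("MDS: raw stress ", format(x$stress, digits = 4), " (ratio ",
      format(x$stress_ratio, digits = 4), ")\n", sep = "")
  cat("GPR (Matern 3/2 + White):\n")
  print(round(x$coef, 5))
  cat("log marginal likelihood:", format(x$lml, digits = 6), "\n")
  cat("Surface residuals (observed - fitted pKi):\n")
  print(round(x$residual_quartiles, 4))
  cat("Cell intensity distribution:\n")
  print(x$distribution)
  invisible(x)
}

#' @export
coef.activity_landscape <- function(object, ...) coef(object$surface)

#' @rdname predict.potency_surface
#' @export
predict.activity_landscape <- function(object, newdata = NULL,
                                       se.fit = FALSE, ...) {
  if (is.null(newdata)) newdata <- object$projection$coords
  predict(object$surface, newdata, se.fit = se.fit, ...)
}

#' @export
fitted.activity_landscape <- function(object, ...) {
  stats::setNames(predict(object), object$compounds$ids)
}

#' @export
residuals.activity_landscape <- function(object, ...) {
  stats::setNames(object$compounds$potencies - predict(object),
                  object$compounds$ids)
}

#' Plot an activity landscape heatmap
#'
#' Draws the rendered heatmap in projection coordinates; optionally
#' overlays the projected compound positions.
#'
#' @param x an `activity_landscape`.
#' @param points overlay compound positions.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.activity_landscape <- function(x, points = FALSE, ...) {
  ext <- x$raster$extent
  graphics::plot(NA, xlim = ext[1:2], ylim = ext[3:4], xlab = "MDS 1",
                 ylab = "MDS 2", asp = NA,
                 main = paste0("Activity landscape '", x$id, "'"), ...)
  graphics::rasterImage(unclass(x$heatmap) / 255, ext[1L], ext[3L],
                        ext[2L], ext[4L], interpolate = FALSE)
  if (points)
    graphics::points(x$projection$coords, pch = 21, cex = 0.5,
                     bg = "white")
  invisible(x)
}

#' Simulate from the posterior potency surface
#'
#' Draws joint samples of the potency surface at the training
#' coordinates from the Gaussian-process posterior (including the fitted
#' observation noise), one column per replicate.
#'
#' @param object an `activity_landscape`.
#' @param nsim number of posterior draws.
#' @param seed integer seed.
#' @param ... unused.
#' @return A data frame of dimension `n x nsim` of simulated pKi values.
#' @export
simulate.activity_landscape <- function(object, nsim = 1, seed = NULL, ...) {
  surf <- object$surface
  X <- surf$train_coords
  n <- nrow(X)
  K <- matern32_kernel(X, surf$length_scale)
  Ky <- K; diag(Ky) <- diag(Ky) + surf$noise_level + surf$alpha
  ch <- chol(Ky)
  V <- backsolve(ch, forwardsolve(t(ch), K))
  post_cov <- K - crossprod(V, K)
  diag(post_cov) <- diag(post_cov) + surf$noise_level
  e <- eigen((post_cov + t(post_cov)) / 2, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
  mu <- predict(object)
  draws <- with_seed(seed, matrix(rnorm(n * nsim), n, nsim))
  out <- as.data.frame(mu + surf$scale * (L %*% draws))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$compounds$ids
  out
}

#' Compare two or more activity landscapes
#'
#' Convenience wrapper around [compare_all()] accepting fitted
#' landscapes, feature vectors, or a mixture.
#'
#' @param ... `activity_landscape` or `cell_distribution` objects (or a
#'   single list of them).
#' @param base logarithm base for the relative entropy.
#' @return See [compare_all()].
#' @export
al_compare <- function(..., base = exp(1)) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) &&
      !inherits(args[[1L]], c("activity_landscape", "cell_distribution")))
    args <- args[[1L]]
  compare_all(lapply(args, feature_vector), base = base)
}
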