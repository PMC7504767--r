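# Gaussian-process interpolation of the potency surface.
#
# Model: standardized potencies z = (pKi - mean) / sd are given a
# zero-mean GP prior with covariance
#   k(x, x') = Matern_{3/2}(|x - x'| / length_scale) + noise_level * 1[x = x']
# (the "Sum of Matern and White" kernel), and an additional ridge term
# alpha on the diagonal of the training covariance. The noise level and
# length scale are hyperparameters fitted by maximizing the log marginal
# likelihood; alpha is selected from a fixed grid of 10 log-spaced
# candidates spanning [1e-7, 1e-1], again by maximum log marginal
# likelihood.

ALPHA_GRID <- 10^seq(-7, -1, length.out = 10)

# log marginal likelihood given the eigenvalues of the Matern kernel
# matrix and z-coefficients in its eigenbasis; s is the total diagonal
# addition (noise_level + alpha)
lml_from_eigen <- function(lambda, z2, s, n) {
  lam <- pmax(lambda + s, 1e-12)
  -0.5 * sum(z2 / lam) - 0.5 * sum(log(lam)) - n / 2 * log(2 * pi)
}

# best noise level for a fixed length scale (via its eigendecomposition)
# and alpha; returns c(noise, lml)
profile_noise <- function(lambda, z2, alpha, n,
                          noise_bounds = c(1e-5, 1)) {
  f <- function(ln_s) -lml_from_eigen(lambda, z2, exp(ln_s) + alpha, n)
  opt <- optimize(f, log(noise_bounds), tol = 1e-4)
  c(noise = exp(opt$minimum), lml = -opt$objective)
}

#' Fit a Gaussian-process potency surface
#'
#' Fits a zero-mean GP with a Matern (nu = 3/2) plus White-noise kernel
#' to standardized potencies over 2D chemical-space coordinates. For
#' each of 10 log-spaced ridge (`alpha`) candidates in `[1e-7, 1e-1]`
#' the kernel hyperparameters (length scale, noise level) are optimized
#' by maximum log marginal likelihood -- the length scale over a
#' log-spaced grid on `[1e-2, 1e2]` with golden-section refinement, the
#' noise level by exact 1D profile optimization -- and the candidate with
#' the highest marginal likelihood is selected.
#'
#' @param proj an `mds_projection` from [project_mds()], or a bare
#'   `n x 2` coordinate matrix.
#' @param potencies numeric pKi values, one per row of the projection.
#' @param length_scale_bounds,noise_bounds hyperparameter search bounds.
#' @param n_length_scales size of the length-scale search grid.
#' @return An object of class `potency_surface` with elements
#'   `train_coords`, `train_potencies`, `length_scale`, `noise_level`,
#'   `alpha`, `offset` (mean pKi subtracted), `scale` (sd divided out),
#'   `lml` (selected log marginal likelihood), `alpha_candidates` /
#'   `alpha_lml` (the candidate grid and per-candidate maximized log
#'   marginal likelihoods), and `weights` (the representer weights
#'   `(K + (noise + alpha) I)^{-1} z`).
#' @examples
#' x <- cbind(runif(50), runif(50))
#' p <- 6 + sin(3 * x[, 1]) + cos(3 * x[, 2])
#' surf <- fit_surface(x, p)
#' coef(surf)
#' @export
fit_surface <- function(proj, potencies,
                        length_scale_bounds = c(1e-2, 1e2),
                        noise_bounds = c(1e-5, 1),
                        n_length_scales = 24L) {
  coords <- if (inherits(proj, "mds_projection")) proj$coords else as.matrix(proj)
  if (ncol(coords) != 2L) stop_actland("coordinates must be n x 2")
  n <- nrow(coords)
  potencies <- as.numeric(potencies)
  if (length(potencies) != n)
    stop_actland("length of potencies (", length(potencies),
                 ") does not match number of coordinates (", n, ")")
  if (n < 2L) stop_actland("need at least 2 points to fit a surface")
  if (all(dist(coords) < 1e-12))
    stop_actland("degenerate coordinates: all points identical")
  offset <- mean(potencies)
  s <- sd(potencies)
  scale <- if (is.finite(s) && s > 0) s else 1
  z <- (potencies - offset) / scale
  ls_grid <- exp(seq(log(length_scale_bounds[1L]),
                     log(length_scale_bounds[2L]),
                     length.out = n_length_scales))
  # one eigendecomposition per length scale serves every alpha candidate
  eigs <- lapply(ls_grid, function(ls) {
    e <- eigen(matern32_kernel(coords, ls), symmetric = TRUE)
    list(lambda = e$values, z2 = as.vector(crossprod(e$vectors, z))^2)
  })
  n_alpha <- length(ALPHA_GRID)
  best_per_alpha <- matrix(NA_real_, n_alpha, 3,
                           dimnames = list(NULL, c("ls", "noise", "lml")))
  for (a in seq_len(n_alpha)) {
    alpha <- ALPHA_GRID[a]
    res <- vapply(eigs, function(e)
      profile_noise(e$lambda, e$z2, alpha, n, noise_bounds), numeric(2))
    k <- which.max(res["lml", ])
    best_per_alpha[a, ] <- c(ls_grid[k], res["noise", k], res["lml", k])
  }
  sel <- which.max(best_per_alpha[, "lml"])
  alpha <- ALPHA_GRID[sel]
  # golden-section refinement of the length scale for the winning candidate
  k <- match(best_per_alpha[sel, "ls"], ls_grid)
  lo <- ls_grid[max(1L, k - 1L)]; hi <- ls_grid[min(length(ls_grid), k + 1L)]
  refine <- optimize(function(ln_ls) {
    e <- eigen(matern32_kernel(coords, exp(ln_ls)), symmetric = TRUE)
    z2 <- as.vector(crossprod(e$vectors, z))^2
    -profile_noise(e$values, z2, alpha, n, noise_bounds)[["lml"]]
  }, log(c(lo, hi)), tol = 0.02)
  length_scale <- exp(refine$minimum)
  e <- eigen(matern32_kernel(coords, length_scale), symmetric = TRUE)
  z2 <- as.vector(crossprod(e$vectors, z))^2
  pn <- profile_noise(e$values, z2, alpha, n, noise_bounds)
  noise_level <- pn[["noise"]]
  lml <- pn[["lml"]]
  if (lml < best_per_alpha[sel, "lml"]) {  # keep the grid optimum if better
    length_scale <- best_per_alpha[sel, "ls"]
    noise_level <- best_per_alpha[sel, "noise"]
    lml <- best_per_alpha[sel, "lml"]
    e <- eigen(matern32_kernel(coords, length_scale), symmetric = TRUE)
  }
  alpha_lml <- best_per_alpha[, "lml"]
  alpha_lml[sel] <- lml
  lam <- pmax(e$values + noise_level + alpha, 1e-12)
  weights <- e$vectors %*% (crossprod(e$vectors, z) / lam)
  structure(list(train_coords = coords, train_potencies = potencies,
                 length_scale = length_scale, noise_level = noise_level,
                 nu = 1.5, alpha = alpha, offset = offset, scale = scale,
                 lml = lml, alpha_candidates = ALPHA_GRID,
                 alpha_lml = alpha_lml, weights = as.vector(weights)),
            class = "potency_surface")
}

#' @export
print.potency_surface <- function(x, ...) {
  cat("Gaussian-process potency surface (Matern 3/2 + White kernel)\n")
  cat("  n =", nrow(x$train_coords),
      " length scale =", format(x$length_scale, digits = 4),
      " noise level =", format(x$noise_level, digits = 4),
      " alpha =", format(x$alpha, digits = 3), "\n")
  cat("  log marginal likelihood:", format(x$lml, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.potency_surface <- function(object, ...) {
  c(length_scale = unname(object$length_scale),
    noise_level = unname(object$noise_level),
    alpha = unname(object$alpha), offset = unname(object$offset),
    scale = unname(object$scale))
}

#' Predict potency at new chemical-space coordinates
#'
#' Posterior-mean pKi of the fitted surface; optionally the posterior
#' standard deviation.
#'
#' @param object a `potency_surface`.
#' @param newdata `m x 2` matrix or data frame of coordinates.
#' @param se.fit if `TRUE`, also return posterior standard deviations.
#' @param ... unused.
#' @return Numeric vector of pKi predictions, or a list with elements
#'   `fit` and `se.fit`.
#' @export
predict.potency_surface <- function(object, newdata, se.fit = FALSE, ...) {
  A <- as.matrix(newdata)
  if (ncol(A) != 2L) stop_actland("newdata must have two coordinate columns")
  storage.mode(A) <- "double"
  mu <- matern32_cross_mult(A, object$train_coords, object$weights,
                            object$length_scale) * object$scale + object$offset
  if (!se.fit)
    return(as.vector(mu))
  K <- matern32_kernel(object$train_coords, object$length_scale)
  diag(K) <- diag(K) + object$noise_level + object$alpha
  ch <- chol(K)
  kx <- matern32_cross(A, object$train_coords, object$length_scale)
  v <- backsolve(ch, forwardsolve(t(ch), t(kx)))
  var_z <- pmax(1 + object$noise_level - colSums(v^2), 0)
  list(fit = as.vector(mu), se.fit = sqrt(var_z) * object$scale)
}

#' Rasterize a potency surface
#'
#' Evaluates the posterior-mean surface on a regular pixel grid,
#' producing the top-down view from which the heatmap is rendered. Row 1
#' is the top of the image and column 1 the left; pixel centers are
#' evenly spaced over the extent.
#'
#' @param model a `potency_surface`.
#' @param extent `c(xmin, xmax, ymin, ymax)`; defaults to the bounding
#'   box of the training coordinates expanded by `margin` per side.
#' @param width,height raster dimensions in pixels (defaults 280 x 300).
#' @param margin fractional bounding-box expansion used when `extent` is
#'   not given.
#' @return An object of class `potency_raster`: list with `values`
#'   (`height x width` matrix of pKi), `extent`, `width`, `height`.
#' @export
evaluate_surface <- function(model, extent = NULL, width = 280L,
                             height = 300L, margin = 0.05) {
  if (!inherits(model, "potency_surface"))
    stop_actland("model must be a potency_surface")
  if (is.null(extent)) {
    rx <- range(model$train_coords[, 1L]); ry <- range(model$train_coords[, 2L])
    pad <- function(r) {
      w <- diff(r)
      if (w == 0) w <- 1
      r + c(-1, 1) * margin * w
    }
    extent <- c(pad(rx), pad(ry))
  }
  extent <- as.numeric(extent)
  if (length(extent) != 4L || extent[2L] <= extent[1L] || extent[4L] <= extent[3L])
    stop_actland("extent must be c(xmin, xmax, ymin, ymax) with positive area")
  xs <- extent[1L] + (seq_len(width) - 0.5) / width * (extent[2L] - extent[1L])
  ys <- extent[4L] - (seq_len(height) - 0.5) / height * (extent[4L] - extent[3L])
  grid <- cbind(rep(xs, each = height), rep(ys, times = width))
  vals <- matern32_cross_mult(grid, model$train_coords, model$weights,
                              model$length_scale) * model$scale + model$offset
  structure(list(values = matrix(vals, nrow = height, ncol = width),
                 extent = extent, width = width, height = height),
            class = "potency_raster")
}

#' @export
print.potency_raster <- function(x, ...) {
  cat("Potency raster ", x$width, " x ", x$height, " px, pKi range [",
      format(min(x$values), digits = 3), ", ",
      format(max(x$values), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Save / load a potency surface archive
#'
#' Portable JSON archive of the training data, kernel hyperparameters
#' and standardization constants; the representer weights are
#' reconstructed on load, so the round trip is exact up to numerical
#' precision.
#'
#' @param model a `potency_surface`.
#' @param path archive path (JSON).
#' @return `write_surface` returns `path` invisibly; `read_surface`
#'   returns the restored `potency_surface`.
#' @export
write_surface <- function(model, path) {
  obj <- list(format = "actland_surface", version = 1L,
              train_coords = model$train_coords,
              train_potencies = model$train_potencies,
              length_scale = model$length_scale,
              noise_level = model$noise_level, nu = model$nu,
              alpha = model$alpha, offset = model$offset,
              scale = model$scale, lml = model$lml,
              alpha_candidates = model$alpha_candidates,
              alpha_lml = model$alpha_lml)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "actland_surface"))
    stop_actland(path, " is not a potency-surface archive")
  coords <- matrix(as.numeric(obj$train_coords), ncol = 2L)
  z <- (obj$train_potencies - obj$offset) / obj$scale
  K <- matern32_kernel(coords, obj$length_scale)
  diag(K) <- diag(K) + obj$noise_level + obj$alpha
  weights <- as.vector(solve(K, z))
  structure(list(train_coords = coords,
                 train_potencies = as.numeric(obj$train_potencies),
                 length_scale = obj$length_scale,
                 noise_level = obj$noise_level, nu = obj$nu,
                 alpha = obj$alpha, offset = obj$offset, scale = obj$scale,
                 lml = obj$lml, alpha_candidates = obj$alpha_candidates,
                 alpha_lml = obj$alpha_lml, weights = weights),
            class = "potency_surface")
}
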