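#' Project a distance matrix into 2D by metric multidimensional scaling
#'
#' Minimizes the raw metric stress `sum_(i<j) (d_ij - |x_i - x_j|)^2`
#' with the SMACOF majorization algorithm (Guttman transform). The first
#' restart is initialized from classical scaling ([stats::cmdscale()]),
#' the remaining restarts from random configurations; the solution with
#' the lowest stress is kept, so the result is deterministic for a fixed
#' seed.
#'
#' @param dm symmetric distance matrix with zero diagonal (e.g. from
#'   [tanimoto_distance_matrix()]).
#' @param seed integer seed for the random restarts.
#' @param n_restarts number of starting configurations (default 4).
#' @param max_iter maximum majorization iterations per restart.
#' @param tol relative stress-decrease convergence tolerance.
#' @return A list of class `mds_projection`: `coords` (`n x 2`, rows in
#'   input order, dimnames from `dm`), `stress` (raw stress of the kept
#'   solution), `stress_ratio` (stress divided by the total squared
#'   distance, a scale-free badness-of-fit in `[0, 1]`), and
#'   `stress_trace` of the kept restart.
#' @examples
#' pts <- cbind(runif(10), runif(10))
#' proj <- project_mds(as.matrix(dist(pts)), seed = 1)
#' proj$stress_ratio  # near zero: the input was exactly 2D
#' @export
project_mds <- function(dm, seed = 0L, n_restarts = 4L, max_iter = 500L,
                        tol = 1e-6) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop_actland("need at least 2 items to project")
  if (ncol(dm) != n || any(abs(dm - t(dm)) > 1e-8))
    stop_actland("distance matrix must be square and symmetric")
  total_sq <- sum(dm^2) / 2
  scale0 <- max(dm)
  if (scale0 == 0) {  # all-identical items: place at the origin
    coords <- matrix(0, n, 2, dimnames = list(rownames(dm), c("x", "y")))
    return(structure(list(coords = coords, stress = 0, stress_ratio = 0,
                          stress_trace = 0), class = "mds_projection"))
  }
  inits <- with_seed(seed, {
    first <- suppressWarnings(stats::cmdscale(dm, k = min(2L, n - 1L)))
    if (ncol(first) < 2L)
      first <- cbind(first, matrix(0, n, 2L - ncol(first)))
    c(list(first),
      lapply(seq_len(max(0L, n_restarts - 1L)), function(i)
        matrix(runif(2L * n, -scale0, scale0), n, 2L)))
  })
  best <- NULL
  for (x0 in inits) {
    fit <- smacof_once(dm, x0, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- scale(best$coords, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  dimnames(coords) <- list(rownames(dm), c("x", "y"))
  structure(list(coords = coords, stress = best$stress,
                 stress_ratio = if (total_sq > 0) best$stress / total_sq else 0,
                 stress_trace = best$trace),
            class = "mds_projection")
}

# one SMACOF run: repeated Guttman transforms until the relative stress
# decrease falls below tol (compiled inner loop)
smacof_once <- function(dm, x, max_iter, tol) {
  storage.mode(dm) <- "double"
  storage.mode(x) <- "double"
  fit <- smacof_engine(dm, x, as.integer(max_iter), tol)
  list(coords = fit$coords, stress = fit$stress, trace = fit$trace)
}

#' @export
print.mds_projection <- function(x, ...) {
  cat("2D chemical-space projection (metric MDS):",
      nrow(x$coords), "compounds\n")
  cat("  raw stress:", format(x$stress, digits = 4),
      " stress ratio:", format(x$stress_ratio, digits = 4), "\n")
  invisible(x)
}

#' Write projected coordinates to CSV
#'
#' Columns `id`, `x`, `y`.
#'
#' @param proj an `mds_projection` (or bare `n x 2` matrix with rownames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(proj, path) {
  coords <- if (inherits(proj, "mds_projection")) proj$coords else proj
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  df <- data.frame(id = ids, x = coords[, 1L], y = coords[, 2L])
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
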