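# Grid featurization: 56 x 60 cells of 5 x 5 pixels over the 280 x 300
# intensity map, categorized into eight intensity-threshold intervals.

CATEGORY_BREAKS <- c(-1, -0.75, -0.5, -0.25, 0, 0.25, 0.5, 0.75, 1)

#' Partition an intensity map into grid cells
#'
#' Maps the intensity image onto an evenly spaced `grid_width x
#' grid_height` grid (default 56 x 60 over a 280 x 300 image, i.e. 3360
#' cells of 5 x 5 = 25 pixels) and assigns each cell the mean intensity
#' of its pixel block.
#'
#' @param im an `intensity_map` (or numeric matrix in `[-1, 1]`) of
#'   dimensions `image_height x image_width`.
#' @param grid_width,grid_height grid dimensions; image dimensions must
#'   be exact multiples.
#' @return Numeric `grid_height x grid_width` matrix of mean cell
#'   intensities (class `cell_grid`).
#' @export
partition_cells <- function(im, grid_width = 56L, grid_height = 60L) {
  im <- unclass(im)
  if (!is.matrix(im))
    stop_actland("intensity map must be a matrix")
  h <- nrow(im); w <- ncol(im)
  exp_h <- 300L * grid_height / 60L; exp_w <- 280L * grid_width / 56L
  if (h %% grid_height != 0L || w %% grid_width != 0L)
    stop_actland("image is ", w, " x ", h, " but dimensions divisible by ",
                 "the ", grid_width, " x ", grid_height, " grid are ",
                 "expected (280 x 300 for the default grid)")
  bh <- h %/% grid_height; bw <- w %/% grid_width
  sums <- rowsum(im, rep(seq_len(grid_height), each = bh))
  sums <- t(rowsum(t(sums), rep(seq_len(grid_width), each = bw)))
  # round far below the intensity resolution (multiples of 1/6375 for
  # 8-bit RG inputs) so cell means are independent of within-block
  # summation order; without this, a block summing to exactly 0 can land
  # on either side of the 0 category boundary after image flips
  structure(round(sums / (bh * bw), 12), class = "cell_grid")
}

#' Categorize grid cells into the eight threshold intervals
#'
#' Cells are binned by mean intensity into eight half-open,
#' lower-inclusive intervals ordered from the deepest valleys to the
#' highest peaks: `[-1,-0.75)`, `[-0.75,-0.5)`, `[-0.5,-0.25)`,
#' `[-0.25,0)`, `[0,0.25)`, `[0.25,0.5)`, `[0.5,0.75)`, `[0.75,1]`.
#' A mean intensity of exactly 0 falls in the first positive interval.
#'
#' @param grid a `cell_grid` from [partition_cells()] (or numeric matrix
#'   of values in `[-1, 1]`).
#' @param epsilon additive smoothing applied per bin when converting
#'   counts to probabilities, so the Kullback-Leibler divergence stays
#'   finite for empty bins: `prob = (count + epsilon) / (n + 8 epsilon)`.
#' @param id optional dataset identifier stored with the result.
#' @return An object of class `cell_distribution`: list with `id`,
#'   `counts` (8 integers summing to the number of cells),
#'   `probabilities` (smoothed relative frequencies summing to 1),
#'   `epsilon`, `n_cells`, `grid` (e.g. `"56x60"`) and `image` (e.g.
#'   `"280x300"`).
#' @examples
#' g <- matrix(0.8, 60, 56)
#' categorize_cells(g)$counts  # all 3360 cells in category 8
#' @export
categorize_cells <- function(grid, epsilon = 0.5, id = NULL) {
  vals <- as.vector(unclass(grid))
  if (any(!is.finite(vals)) || min(vals) < -1 - 1e-9 || max(vals) > 1 + 1e-9)
    stop_actland("cell intensities must lie in [-1, 1]")
  cat <- findInterval(vals, CATEGORY_BREAKS)
  cat[cat > 8L] <- 8L  # close the top bin at +1
  cat[cat < 1L] <- 1L
  counts <- tabulate(cat, nbins = 8L)
  n <- length(vals)
  probs <- (counts + epsilon) / (n + 8 * epsilon)
  gd <- if (is.matrix(grid)) paste0(ncol(grid), "x", nrow(grid)) else NA_character_
  structure(list(id = id, counts = counts, probabilities = probs,
                 epsilon = epsilon, n_cells = n, grid = gd,
                 image = NA_character_),
            class = "cell_distribution")
}

#' @export
print.cell_distribution <- function(x, ...) {
  cat("Cell intensity distribution",
      if (!is.null(x$id) && !is.na(x$id)) paste0("'", x$id, "'"), "\n")
  labs <- c("[-1,-.75)", "[-.75,-.5)", "[-.5,-.25)", "[-.25,0)",
            "[0,.25)", "[.25,.5)", "[.5,.75)", "[.75,1]")
  tab <- rbind(counts = x$counts,
               prob = round(x$probabilities, 4))
  colnames(tab) <- labs
  print(tab)
  invisible(x)
}

#' Cell-distribution feature vector of an input
#'
#' End-to-end convenience composing the pipeline stages: for a compound
#' set, build the landscape (MDS projection, GP surface, heatmap) and
#' featurize it; for a heatmap image, PNG path or intensity map, start
#' at the corresponding stage. Deterministic for a fixed seed.
#'
#' @param x a `compound_set`, `activity_landscape`, `heatmap_image`,
#'   `intensity_map`, or path to a heatmap PNG.
#' @param ... passed on to downstream stages ([activity_landscape()] for
#'   compound sets; [read_heatmap_png()] for paths; [categorize_cells()]
#'   otherwise, e.g. `epsilon`, `id`).
#' @return A `cell_distribution`.
#' @export
feature_vector <- function(x, ...) UseMethod("feature_vector")

#' @export
feature_vector.cell_distribution <- function(x, ...) x

#' @export
feature_vector.compound_set <- function(x, ...) {
  feature_vector(activity_landscape(x, ...))
}

#' @export
feature_vector.character <- function(x, id = NULL, epsilon = 0.5, ...) {
  img <- read_heatmap_png(x, ...)
  if (is.null(id)) id <- sub("\\.png$", "", basename(x))
  feature_vector(img, id = id, epsilon = epsilon)
}

#' @export
feature_vector.heatmap_image <- function(x, id = NULL, epsilon = 0.5, ...) {
  fv <- categorize_cells(partition_cells(rg_intensity(x), ...),
                         epsilon = epsilon, id = id)
  fv$image <- paste0(dim(x)[2L], "x", dim(x)[1L])
  fv
}

#' @export
feature_vector.intensity_map <- function(x, id = NULL, epsilon = 0.5, ...) {
  fv <- categorize_cells(partition_cells(x, ...), epsilon = epsilon, id = id)
  fv$image <- paste0(ncol(x), "x", nrow(x))
  fv
}

#' Write / read a cell-distribution feature vector
#'
#' JSON with fields `dataset_id`, `counts`, `probabilities`, `epsilon`,
#' `grid` and `image`. `write_features_csv` writes a one-row CSV.
#'
#' @param fv a `cell_distribution`.
#' @param path output path.
#' @return `path` invisibly, or the restored `cell_distribution`.
#' @export
write_features <- function(fv, path) {
  obj <- list(dataset_id = if (is.null(fv$id)) NA else fv$id,
              counts = fv$counts, probabilities = fv$probabilities,
              epsilon = fv$epsilon, grid = fv$grid, image = fv$image)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$counts) || length(obj$counts) != 8L)
    stop_actland(path, " is not a feature-vector file (8 counts expected)")
  structure(list(id = obj$dataset_id, counts = as.integer(obj$counts),
                 probabilities = as.numeric(obj$probabilities),
                 epsilon = obj$epsilon, n_cells = sum(obj$counts),
                 grid = obj$grid, image = obj$image),
            class = "cell_distribution")
}

#' @rdname write_features
#' @export
write_features_csv <- function(fv, path) {
  df <- data.frame(dataset_id = if (is.null(fv$id)) NA else fv$id,
                   category = 1:8, count = fv$counts,
                   probability = fv$probabilities)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
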