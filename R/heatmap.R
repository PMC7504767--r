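# Potency color coding and heatmap rendering.
#
# The color gradient runs green -> yellow -> red over a fixed pKi window
# anchored at 3.72 (pure green), 5.75 (pure yellow) and 8.75 (pure red),
# clamping outside the window; the blue channel is always 0. Potency is
# therefore recoverable from a pixel as the combined RG intensity
# (R - G) / 255 in [-1, 1].

GRADIENT_ANCHORS <- c(low = 3.72, mid = 5.75, high = 8.75)

#' Map pKi values to gradient colors
#'
#' Piecewise-linear RGB gradient: green `(0,255,0)` at or below pKi
#' 3.72, yellow `(255,255,0)` at 5.75, red `(255,0,0)` at or above 8.75;
#' the blue channel is always 0. Channels are rounded half-up to
#' integers.
#'
#' @param pki numeric vector of pKi values (finite).
#' @param anchors gradient anchor potencies `c(low, mid, high)`.
#' @return Integer matrix with `length(pki)` rows and columns `R`, `G`,
#'   `B` in `[0, 255]`.
#' @examples
#' potency_to_rgb(c(3.72, 5.75, 8.75))
#' @export
potency_to_rgb <- function(pki, anchors = GRADIENT_ANCHORS) {
  pki <- as.numeric(pki)
  if (!all(is.finite(pki)))
    stop_actland("pKi values must be finite")
  lo <- anchors[[1L]]; mid <- anchors[[2L]]; hi <- anchors[[3L]]
  r <- numeric(length(pki)); g <- numeric(length(pki))
  below <- pki <= lo
  lower <- !below & pki < mid          # green -> yellow: R ramps up
  upper <- pki >= mid & pki < hi       # yellow -> red:  G ramps down
  above <- pki >= hi
  r[below] <- 0;   g[below] <- 255
  r[lower] <- 255 * (pki[lower] - lo) / (mid - lo); g[lower] <- 255
  r[upper] <- 255; g[upper] <- 255 * (hi - pki[upper]) / (hi - mid)
  r[above] <- 255; g[above] <- 0
  cbind(R = as.integer(round_half_up(r)),
        G = as.integer(round_half_up(g)),
        B = 0L)
}

#' Render a potency raster as an RGB heatmap
#'
#' Applies [potency_to_rgb()] per pixel.
#'
#' @param raster a `potency_raster` from [evaluate_surface()], or a bare
#'   numeric matrix of pKi values.
#' @param anchors gradient anchors, see [potency_to_rgb()].
#' @return An object of class `heatmap_image`: integer array
#'   `height x width x 3` (R, G, B in `[0, 255]`).
#' @export
render_heatmap <- function(raster, anchors = GRADIENT_ANCHORS) {
  vals <- if (inherits(raster, "potency_raster")) raster$values else as.matrix(raster)
  h <- nrow(vals); w <- ncol(vals)
  rgb <- potency_to_rgb(as.vector(vals), anchors)
  img <- array(0L, dim = c(h, w, 3L))
  img[, , 1L] <- rgb[, "R"]; img[, , 2L] <- rgb[, "G"]; img[, , 3L] <- rgb[, "B"]
  structure(img, class = "heatmap_image")
}

assert_heatmap <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop_actland("heatmap image must be a height x width x 3 array")
  if (min(img) < 0 || max(img) > 255)
    stop_actland("heatmap channel values must lie in [0, 255]")
  invisible(img)
}

#' Combined red-green intensity of a heatmap
#'
#' Per pixel, `(R - G) / 255`, the normalized combined RG intensity in
#' `[-1, 1]`: brightest green (lowest potency) maps to -1, yellow to 0,
#' brightest red (highest potency) to +1. The blue channel is ignored.
#' Near-white pixels (all channels >= `white_threshold`), which can
#' occur in externally rendered images as unpainted surface, are treated
#' as yellow-equivalent intensity 0.
#'
#' @param img a `heatmap_image` (or any `h x w x 3` array with channel
#'   values in `[0, 255]`).
#' @param white_threshold minimum channel value for the near-white rule.
#' @return Numeric `h x w` matrix in `[-1, 1]` (class `intensity_map`).
#' @examples
#' img <- array(c(255, 0, 0), dim = c(1, 1, 3))  # pure red
#' rg_intensity(img)  # +1
#' @export
rg_intensity <- function(img, white_threshold = 250) {
  assert_heatmap(img)
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  v <- (r - g) / 255
  v[r >= white_threshold & g >= white_threshold & b >= white_threshold] <- 0
  dim(v) <- dim(img)[1:2]  # keep matrix shape even for 1 x 1 images
  structure(v, class = "intensity_map")
}

#' Write / read a heatmap PNG
#'
#' 8-bit RGB PNG without alpha. `read_heatmap_png` enforces the expected
#' image dimensions unless `resize = TRUE`, in which case the image is
#' downsampled to `width x height` by area averaging.
#'
#' @param img a `heatmap_image`.
#' @param path PNG file path.
#' @param width,height expected dimensions on read (defaults 280 x 300).
#' @param resize allow reading other sizes by area-average resampling.
#' @return `write_heatmap_png` returns `path` invisibly;
#'   `read_heatmap_png` returns a `heatmap_image`.
#' @export
write_heatmap_png <- function(img, path) {
  assert_heatmap(img)
  arr <- unclass(img) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname write_heatmap_png
#' @export
read_heatmap_png <- function(path, width = 280L, height = 300L,
                             resize = FALSE) {
  if (!file.exists(path))
    stop_actland("PNG file not found: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L)
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (dim(arr)[3L] == 4L)
    arr <- arr[, , 1:3, drop = FALSE]
  img <- array(as.integer(round_half_up(arr * 255)), dim = dim(arr))
  if (dim(img)[1L] != height || dim(img)[2L] != width) {
    if (!resize)
      stop_actland("heatmap PNG is ", dim(img)[2L], " x ", dim(img)[1L],
                   " but 280 x 300 (width x height) is expected; pass ",
                   "resize = TRUE to downsample")
    img <- resize_area_average(img, width, height)
  }
  structure(img, class = "heatmap_image")
}

# area-average resampling to exact target dimensions (used only for
# ingesting externally rendered heatmaps of other sizes)
resize_area_average <- function(img, width, height) {
  h0 <- dim(img)[1L]; w0 <- dim(img)[2L]
  row_bins <- pmin(floor(((seq_len(h0) - 0.5) / h0) * height) + 1L, height)
  col_bins <- pmin(floor(((seq_len(w0) - 0.5) / w0) * width) + 1L, width)
  out <- array(0L, dim = c(height, width, 3L))
  for (ch in 1:3) {
    m <- rowsum(img[, , ch], row_bins)
    m <- t(rowsum(t(m), col_bins))
    cnt <- tcrossprod(as.vector(table(row_bins)), as.vector(table(col_bins)))
    out[, , ch] <- as.integer(round_half_up(m / cnt))
  }
  structure(out, class = "heatmap_image")
}
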