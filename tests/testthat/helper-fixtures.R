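# Shared fixtures built in code: small synthetic datasets and simple
# hand-made images keep the unit tests fast.

tiny_dataset <- function(seed = 1L, n = 60L, series = 4L, ...) {
  generate_dataset(n_compounds = n, n_series = series, seed = seed, ...)
}

# deterministic fingerprints without the chemistry backend
fp_fixture <- function(n, seed = 1L, nbits = 256L, nbits_on = 30L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) sort(sample(0:(nbits - 1L), nbits_on)))
}

# uniform single-color heatmap image
solid_image <- function(r, g, b, width = 280L, height = 300L) {
  img <- array(0L, dim = c(height, width, 3L))
  img[, , 1L] <- r; img[, , 2L] <- g; img[, , 3L] <- b
  structure(img, class = "heatmap_image")
}
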