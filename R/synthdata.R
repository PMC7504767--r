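# Synthetic compound datasets with controlled SAR continuity /
# discontinuity, emulating the scale of typical ChEMBL activity classes
# (several hundred compounds forming analog series, pKi roughly 4-10).

#' Generate a synthetic compound dataset
#'
#' Emulates a compound dataset with tunable structure-activity
#' relationship (SAR) topology. Analog series are modeled as Gaussian
#' clusters in a latent unit-square chemical space; each series draws
#' its base potency from a smooth random potency field over that square
#' (SAR continuity), and in a `ruggedness` fraction of the series one
#' random member is flipped to the opposite potency extreme, creating an
#' activity cliff (SAR discontinuity). Binary fingerprints are
#' synthesized so that Tanimoto distances increase with latent 2D
#' distance: each series contributes a disjoint block of core bits, each
#' compound a set of random-hyperplane locality bits (shared between
#' nearby compounds) plus a few private noise bits.
#'
#' @param n_compounds number of compounds (default 700).
#' @param n_series number of analog series (default 20).
#' @param ruggedness fraction of series containing an activity cliff,
#'   in `[0, 1]` (default 0).
#' @param potency_range `c(min, max)` pKi window (default `c(4, 10)`).
#' @param noise_sd standard deviation of Gaussian potency noise in pKi
#'   units (default 0.2, a typical inter-assay reproducibility).
#' @param cluster_sd standard deviation of the analog-series clusters in
#'   the latent unit square.
#' @param cliff_fraction fraction of a cliff-containing series flipped
#'   to the opposite extreme (default 0.2): the cliff is a matched
#'   analog subgroup -- a nucleus compound and its nearest series
#'   neighbors -- as substituent-driven potency flips affect analog
#'   subseries rather than single isolated molecules.
#' @param seed integer seed; the dataset is fully reproducible. For a
#'   fixed seed, datasets generated with different `ruggedness` are
#'   topology variants of the same landscape: identical series layout,
#'   base potencies, noise and fingerprints, with nested cliff sets.
#' @return List with elements `compounds` (a [compound_set()]), `latent`
#'   (`n x 2` latent coordinates), `series` (integer series labels) and
#'   `cliff` (logical activity-cliff flags).
#' @examples
#' d <- generate_dataset(n_compounds = 60, n_series = 4, seed = 1)
#' d$compounds
#' @export
generate_dataset <- function(n_compounds = 700L, n_series = 20L,
                             ruggedness = 0, potency_range = c(4, 10),
                             noise_sd = 0.2, cluster_sd = 0.04,
                             cliff_fraction = 0.2, seed = 1L) {
  if (!is_count(n_compounds) || !is_count(n_series) ||
      n_series < 1L || n_compounds < n_series)
    stop_actland("need n_compounds >= n_series >= 1")
  if (ruggedness < 0 || ruggedness > 1)
    stop_actland("ruggedness must lie in [0, 1]")
  if (potency_range[1L] >= potency_range[2L])
    stop_actland("potency_range must satisfy min < max")
  if (noise_sd < 0) stop_actland("noise_sd must be >= 0")
  n <- as.integer(n_compounds); ns <- as.integer(n_series)
  with_seed(seed, {
    centers <- cbind(runif(ns, 0.08, 0.92), runif(ns, 0.08, 0.92))
    series <- sort(c(seq_len(ns),
                     sample.int(ns, n - ns, replace = TRUE)))
    coords <- centers[series, , drop = FALSE] +
      matrix(rnorm(2L * n, sd = cluster_sd), n, 2L)
    # smooth random potency field over the unit square: a few
    # low-frequency sinusoids with random orientation and phase
    nw <- 4L
    u <- matrix(rnorm(2L * nw), nw, 2L)
    u <- u / sqrt(rowSums(u^2)) * runif(nw, 0.5, 1.5)  # cycles per unit
    ph <- runif(nw, 0, 2 * pi)
    amp <- rnorm(nw)
    field <- function(xy)
      as.vector(sin(2 * pi * (xy %*% t(u)) + rep(ph, each = nrow(xy))) %*% amp)
    fc <- field(centers)
    rng <- range(fc)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    base <- potency_range[1L] +
      (fc - rng[1L]) / diff(rng) * diff(potency_range)
    potency <- base[series]
    # RNG use is independent of `ruggedness`: a cliff priority order and
    # one cliff nucleus per series are always drawn, and only the first
    # round(ruggedness * n_series) series are actually modified. Datasets
    # generated with the same seed but different ruggedness are therefore
    # topology variants of one another -- identical series layout,
    # potencies, noise and fingerprints, with nested activity-cliff sets.
    cliff_order <- sample.int(ns, ns)
    cliff_nucleus <- vapply(seq_len(ns), function(s) {
      members <- which(series == s)
      members[sample.int(length(members), 1L)]
    }, integer(1))
    noise <- rnorm(n, sd = noise_sd)
    fps <- synth_fingerprints(coords, series, ns)
    # a cliff is a matched analog subgroup flipped to the opposite
    # potency extreme: the nucleus member plus its nearest series
    # neighbors in the latent space (cliff_fraction of the series)
    cliff <- logical(n)
    n_cliff <- round(ruggedness * ns)
    for (s in cliff_order[seq_len(n_cliff)]) {
      members <- which(series == s)
      k <- max(1L, round(cliff_fraction * length(members)))
      nuc <- cliff_nucleus[s]
      d2 <- (coords[members, 1L] - coords[nuc, 1L])^2 +
        (coords[members, 2L] - coords[nuc, 2L])^2
      pick <- members[order(d2)[seq_len(k)]]
      potency[pick] <- if (base[s] >= mean(potency_range))
        potency_range[1L] else potency_range[2L]
      cliff[pick] <- TRUE
    }
    potency <- potency + noise
    ids <- sprintf("CPD%04d", seq_len(n))
    list(compounds = compound_set(ids, potency, fingerprints = fps),
         latent = coords, series = series, cliff = cliff)
  })
}

# Fingerprint synthesis: 2048-bit layout
#   [0, 1024)    series core bits, disjoint blocks of 48 per series
#   [1024, 1536) locality-sensitive bits: bit j on iff the compound lies
#                on the positive side of random hyperplane j, so the
#                Hamming (and Tanimoto) distance between two compounds
#                grows with their latent 2D separation
#   [1536, 2048) private noise bits, 8 per compound
synth_fingerprints <- function(coords, series, ns) {
  n <- nrow(coords)
  core_per_series <- max(4L, min(48L, 1024L %/% ns))
  core_pool <- sample(0:1023, ns * core_per_series)
  cores <- split(core_pool, rep(seq_len(ns), each = core_per_series))
  n_lsh <- 512L
  w <- matrix(rnorm(2L * n_lsh), n_lsh, 2L)
  p0 <- cbind(runif(n_lsh), runif(n_lsh))
  side <- (coords %*% t(w)) - rep(rowSums(w * p0), each = n)  # n x n_lsh
  lsh_on <- side > 0
  lapply(seq_len(n), function(i) {
    bits <- c(cores[[series[i]]],
              1023L + which(lsh_on[i, ]),
              sample(1536:2047, 8L))
    sort(unique(as.integer(bits)))
  })
}

#' Generate a synthetic heatmap fixture
#'
#' Deterministic (per seed) 280 x 300 heatmap images with known
#' topology, for exercising the featurization and similarity stages
#' without running the full pipeline:
#' `"constant"` -- uniformly red (high potency everywhere);
#' `"smooth"` -- one broad low-frequency potency gradient with random
#' orientation and phase;
#' `"rugged"` -- many narrow high-potency peaks on a low-potency (green)
#' background;
#' `"split"` -- left half red, right half green, aligned to the cell
#' grid.
#'
#' @param pattern one of `"constant"`, `"smooth"`, `"rugged"`,
#'   `"split"`.
#' @param seed integer seed for the randomized patterns.
#' @param width,height image dimensions (defaults 280 x 300).
#' @return A `heatmap_image` (see [render_heatmap()]).
#' @export
generate_heatmap_fixture <- function(pattern = c("constant", "smooth",
                                                 "rugged", "split"),
                                     seed = 1L, width = 280L,
                                     height = 300L) {
  pattern <- match.arg(pattern)
  x <- (seq_len(width) - 0.5) / width
  y <- (seq_len(height) - 0.5) / height
  gx <- matrix(x, height, width, byrow = TRUE)
  gy <- matrix(y, height, width)
  anchors <- GRADIENT_ANCHORS
  pki <- with_seed(seed, switch(pattern,
    constant = matrix(anchors[["high"]], height, width),
    smooth = {
      th <- runif(1, 0, 2 * pi); ph <- runif(1, 0, 2 * pi)
      v <- sin(2 * pi * 0.8 * (cos(th) * gx + sin(th) * gy) + ph)
      anchors[["mid"]] + v * (anchors[["high"]] - anchors[["low"]]) / 2
    },
    rugged = {
      k <- 40L
      cx <- runif(k); cy <- runif(k)
      base <- matrix(anchors[["low"]] + 0.2, height, width)
      for (i in seq_len(k)) {
        d2 <- (gx - cx[i])^2 + (gy - cy[i])^2
        base <- pmax(base, anchors[["high"]] + 0.5 -
                       (anchors[["high"]] - anchors[["low"]]) *
                       (d2 / 0.0004))
      }
      base
    },
    split = {
      m <- matrix(anchors[["low"]], height, width)
      m[, seq_len(width %/% 2L)] <- anchors[["high"]]
      m
    }))
  render_heatmap(pki, anchors = anchors)
}
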