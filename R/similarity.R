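# Pairwise landscape (dis)similarity from cell-distribution feature
# vectors: symmetric relative entropy on smoothed probabilities and
# cosine distance on raw count vectors.

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `KLD(p || q) = sum_i p_i log(p_i / q_i)`. Natural logarithm by
#' default; pass `base = 2` for bits.
#'
#' @param p,q strictly positive probability vectors of equal length,
#'   each summing to 1 (use the epsilon-smoothed probabilities of
#'   [categorize_cells()] so empty bins cannot occur).
#' @param base logarithm base.
#' @return Nonnegative divergence (nats by default).
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))
#' @export
kl_divergence <- function(p, q, base = exp(1)) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q))
    stop_actland("distributions have different lengths (", length(p),
                 " vs ", length(q), ")")
  if (any(p <= 0) || any(q <= 0))
    stop_actland("distributions must be strictly positive; use the ",
                 "epsilon-smoothed probabilities")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop_actland("distributions must each sum to 1")
  sum(p * log(p / q)) / log(base)
}

#' Symmetric relative entropy
#'
#' The average of the two directed Kullback-Leibler divergences,
#' `RE(p, q) = (KLD(p || q) + KLD(q || p)) / 2`; symmetric and
#' nonnegative, zero iff `p == q`.
#'
#' @inheritParams kl_divergence
#' @return Nonnegative symmetric relative entropy.
#' @export
relative_entropy <- function(p, q, base = exp(1)) {
  (kl_divergence(p, q, base) + kl_divergence(q, p, base)) / 2
}

#' Cosine distance between two feature vectors
#'
#' `CD(x, y) = 1 - (x . y) / (|x| |y|)`; lies in `[0, 1]` for
#' nonnegative vectors and is invariant to positive rescaling, so raw
#' cell counts can be compared directly.
#'
#' @param x,y numeric vectors of equal length with positive Euclidean
#'   norm.
#' @return Cosine distance.
#' @examples
#' cosine_distance(c(1, 0), c(1, 1))  # 1 - 1/sqrt(2)
#' @export
cosine_distance <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop_actland("vectors have different lengths")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop_actland("cosine distance undefined for a zero vector")
  1 - sum(x * y) / (nx * ny)
}

#' Pairwise comparison of cell-distribution feature vectors
#'
#' For every unordered pair of feature vectors, computes the symmetric
#' relative entropy (on smoothed probabilities) and the cosine distance
#' (on raw count vectors). Results are sorted by `(id_a, id_b)` so the
#' output is invariant to input order.
#'
#' @param features list of `cell_distribution` objects (see
#'   [feature_vector()]); each must carry a unique `id`, or names of the
#'   list are used.
#' @param base logarithm base for the relative entropy.
#' @return A `data.frame` with columns `id_a`, `id_b`, `re`, `cd`, one
#'   row per unordered pair, with attributes `epsilon` and `log_base`.
#' @export
compare_all <- function(features, base = exp(1)) {
  if (length(features) < 2L)
    stop_actland("need at least 2 feature vectors to compare")
  features <- lapply(seq_along(features), function(i) {
    fv <- features[[i]]
    if (!inherits(fv, "cell_distribution"))
      stop_actland("element ", i, " is not a cell_distribution")
    if (is.null(fv$id) || is.na(fv$id))
      fv$id <- if (!is.null(names(features)) && nzchar(names(features)[i]))
        names(features)[i] else paste0("AL", i)
    fv
  })
  ids <- vapply(features, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_actland("duplicate feature ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(ids)
  features <- features[ord]; ids <- ids[ord]
  k <- length(features)
  pairs <- utils::combn(k, 2L)
  res <- apply(pairs, 2L, function(ij) {
    a <- features[[ij[1L]]]; b <- features[[ij[2L]]]
    c(re = relative_entropy(a$probabilities, b$probabilities, base),
      cd = cosine_distance(a$counts, b$counts))
  })
  out <- data.frame(id_a = ids[pairs[1L, ]], id_b = ids[pairs[2L, ]],
                    re = res["re", ], cd = res["cd", ],
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "epsilon") <- features[[1L]]$epsilon
  attr(out, "log_base") <- base
  out
}
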