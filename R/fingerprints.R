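#' Compute ECFP4 fingerprints from SMILES
#'
#' Folded 2048-bit extended-connectivity fingerprints with bond diameter
#' 4 (Morgan radius 2), returned as sets of on-bit indices. The
#' computation is delegated to the RDKit chemistry backend through a
#' bundled helper script; if no Python interpreter with RDKit is
#' available, supply precomputed fingerprints to [compound_set()]
#' instead.
#'
#' @param smiles_list character vector of SMILES strings.
#' @param nbits fingerprint length after folding (default 2048).
#' @param python path to the Python interpreter; defaults to the first
#'   `python` / `python3` on the PATH.
#' @return List of sorted integer vectors of on-bit indices (0-based).
#' @examples
#' \dontrun{
#' fps <- compute_fingerprints(c("CCO", "c1ccccc1"))
#' }
#' @export
compute_fingerprints <- function(smiles_list, nbits = 2048L, python = NULL) {
  smiles_list <- as.character(smiles_list)
  if (length(smiles_list) == 0L)
    stop_actland("no SMILES provided")
  if (is.null(python)) {
    python <- Sys.which("python")
    if (!nzchar(python)) python <- Sys.which("python3")
  }
  if (!nzchar(python))
    stop_actland("no Python interpreter found; supply precomputed ",
                 "fingerprints instead")
  helper <- system.file("python", "ecfp4.py", package = "actland")
  if (!nzchar(helper))
    stop_actland("bundled fingerprint helper script not found")
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)))
  writeLines(smiles_list, fin)
  status <- system2(python, c(helper, fin, fout, as.integer(nbits)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout))
    stop_actland("fingerprint computation failed (is RDKit installed ",
                 "for ", python, "?)")
  out <- readLines(fout, warn = FALSE)
  if (length(out) != length(smiles_list))
    stop_actland("fingerprint helper returned ", length(out),
                 " records for ", length(smiles_list), " SMILES")
  bad <- which(out == "ERROR")
  if (length(bad))
    stop_actland("unparseable SMILES '", smiles_list[bad[1L]],
                 "' at line ", bad[1L])
  lapply(out, function(line) {
    if (line == "EMPTY")
      return(integer(0))
    sort(as.integer(strsplit(line, " ", fixed = TRUE)[[1L]]))
  })
}

#' Tanimoto distance between two binary fingerprints
#'
#' `1 - |a n b| / |a u b|` over sets of on-bit indices.
#'
#' @param fp_a,fp_b integer vectors of on-bit indices (treated as sets).
#' @return Distance in `[0, 1]`.
#' @examples
#' tanimoto_distance(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
tanimoto_distance <- function(fp_a, fp_b) {
  fp_a <- unique(as.integer(fp_a)); fp_b <- unique(as.integer(fp_b))
  if (length(fp_a) == 0L && length(fp_b) == 0L)
    stop_actland("Tanimoto coefficient undefined for two empty fingerprints")
  inter <- length(intersect(fp_a, fp_b))
  1 - inter / (length(fp_a) + length(fp_b) - inter)
}

#' Pairwise Tanimoto distance matrix of a compound set
#'
#' @param cs a [compound_set()] (fingerprints are computed from SMILES
#'   if absent), or a plain list of bit-index vectors.
#' @return Symmetric `n x n` matrix with zero diagonal, entries in
#'   `[0, 1]`, dimnames set to compound ids when available.
#' @export
tanimoto_distance_matrix <- function(cs) {
  if (inherits(cs, "compound_set")) {
    cs <- ensure_fingerprints(cs)
    fps <- cs$fingerprints
    ids <- cs$ids
  } else {
    fps <- cs
    ids <- names(cs)
  }
  n <- length(fps)
  if (n < 2L) stop_actland("need at least 2 fingerprints")
  if (any(lengths(fps) == 0L)) stop_actland("fingerprints must be non-empty")
  # sparse binary inner products via an indicator matrix
  allbits <- sort(unique(unlist(fps)))
  m <- matrix(0, n, length(allbits))
  idx <- match(unlist(fps), allbits)
  row <- rep.int(seq_len(n), lengths(fps))
  m[cbind(row, idx)] <- 1
  inter <- tcrossprod(m)
  sizes <- lengths(fps)
  un <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  d[d < 0] <- 0
  dimnames(d) <- list(ids, ids)
  d
}
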