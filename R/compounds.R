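#' Construct a compound set
#'
#' Bundles compound identifiers, optional SMILES, binary fingerprints
#' (as sets of on-bit indices) and pKi potencies into a validated
#' container, the raw input to activity-landscape construction.
#'
#' @param ids character vector of unique compound identifiers.
#' @param potencies numeric vector of pKi values (log units), finite.
#' @param fingerprints list of integer vectors of nonnegative bit
#'   indices, one non-empty set per compound. May be `NULL` if `smiles`
#'   is given; fingerprints are then computed on demand by
#'   [compute_fingerprints()].
#' @param smiles optional character vector of SMILES strings.
#' @return An object of class `compound_set`: a list with elements
#'   `ids`, `smiles`, `fingerprints`, `potencies` and `n`.
#' @examples
#' cs <- compound_set(c("a", "b"), c(5.2, 7.9),
#'                    fingerprints = list(c(1L, 5L), c(1L, 9L)))
#' cs$n
#' @export
compound_set <- function(ids, potencies, fingerprints = NULL, smiles = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 2L)
    stop_actland("a compound set needs at least 2 compounds, got ", n)
  if (anyDuplicated(ids))
    stop_actland("compound ids must be unique; duplicated: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  potencies <- as.numeric(potencies)
  if (length(potencies) != n)
    stop_actland("length of potencies (", length(potencies),
                 ") does not match number of ids (", n, ")")
  if (!all(is.finite(potencies)))
    stop_actland("potencies must be finite pKi values; offending ids: ",
                 paste(ids[!is.finite(potencies)], collapse = ", "))
  if (!is.null(smiles)) {
    smiles <- as.character(smiles)
    if (length(smiles) != n)
      stop_actland("length of smiles does not match number of ids")
  }
  if (!is.null(fingerprints)) {
    if (!is.list(fingerprints) || length(fingerprints) != n)
      stop_actland("fingerprints must be a list with one entry per compound")
    fingerprints <- lapply(seq_len(n), function(i) {
      fp <- fingerprints[[i]]
      fp <- sort(unique(as.integer(fp)))
      if (length(fp) == 0L)
        stop_actland("fingerprint for compound '", ids[i], "' is empty")
      if (any(fp < 0L))
        stop_actland("fingerprint for compound '", ids[i],
                     "' has negative bit indices")
      fp
    })
  }
  if (is.null(fingerprints) && is.null(smiles))
    stop_actland("either fingerprints or smiles must be provided")
  structure(list(ids = ids, smiles = smiles, fingerprints = fingerprints,
                 potencies = potencies, n = n),
            class = "compound_set")
}

#' @export
print.compound_set <- function(x, ...) {
  cat("Compound set: ", x$n, " compounds\n", sep = "")
  cat("  pKi range: [", format(min(x$potencies), digits = 3), ", ",
      format(max(x$potencies), digits = 3), "]\n", sep = "")
  cat("  fingerprints: ",
      if (is.null(x$fingerprints)) "not computed" else "present",
      "; SMILES: ", if (is.null(x$smiles)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

# ensure fingerprints exist, computing them from SMILES if needed
ensure_fingerprints <- function(cs) {
  if (is.null(cs$fingerprints)) {
    cs$fingerprints <- compute_fingerprints(cs$smiles)
  }
  cs
}

detect_delimiter <- function(header_line) {
  counts <- vapply(c("," = ",", "\t" = "\t", ";" = ";"), function(d)
    lengths(regmatches(header_line, gregexpr(d, header_line, fixed = TRUE))),
    integer(1))
  if (all(counts == 0L))
    return(",")
  names(counts)[which.max(counts)]
}

#' Read a compound table
#'
#' Reads a delimited text file with (case-insensitive) header columns
#' `id`, `pki` and optionally `smiles`. The delimiter (comma, tab or
#' semicolon) is auto-detected from the header unless given.
#'
#' @param path path to the CSV/TSV file.
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @param fingerprints optional path to a fingerprint file in the format
#'   of [read_fingerprint_file()]; entries are matched to compounds by id.
#' @return A [compound_set()].
#' @export
read_compound_table <- function(path, sep = NULL, fingerprints = NULL) {
  if (!file.exists(path))
    stop_actland("compound table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop_actland("compound table ", path, " has no data rows")
  if (is.null(sep)) sep <- detect_delimiter(lines[1L])
  nf <- count.fields(textConnection(lines), sep = sep, quote = "\"")
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop_actland("malformed row ", bad, " in ", path, ": expected ",
                 nf[1L], " fields, found ", nf[bad])
  }
  df <- read.table(text = lines, sep = sep, header = TRUE,
                   stringsAsFactors = FALSE, quote = "\"",
                   colClasses = "character")
  names(df) <- tolower(names(df))
  for (col in c("id", "pki")) {
    if (!col %in% names(df))
      stop_actland("compound table ", path, " is missing column '", col, "'")
  }
  pki <- suppressWarnings(as.numeric(df$pki))
  if (anyNA(pki)) {
    bad <- which(is.na(pki))[1L] + 1L  # +1: header line
    stop_actland("malformed row ", bad - 1L, " in ", path,
                 ": pki value '", df$pki[bad - 1L], "' is not numeric")
  }
  fps <- NULL
  if (!is.null(fingerprints)) {
    fpmap <- read_fingerprint_file(fingerprints)
    missing <- setdiff(df$id, names(fpmap))
    if (length(missing))
      stop_actland("no fingerprint for compound id(s): ",
                   paste(utils::head(missing, 5L), collapse = ", "))
    fps <- fpmap[df$id]
  }
  compound_set(df$id, pki, fingerprints = fps,
               smiles = if ("smiles" %in% names(df)) df$smiles else NULL)
}

#' Read a fingerprint file
#'
#' One compound per line: `id<TAB>comma-separated bit indices`.
#'
#' @param path file path.
#' @return Named list of sorted integer bit-index vectors.
#' @export
read_fingerprint_file <- function(path) {
  if (!file.exists(path))
    stop_actland("fingerprint file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop_actland("malformed line ", bad[1L], " in ", path,
                 ": expected 'id<TAB>bits'")
  ids <- vapply(parts, `[[`, "", 1L)
  fps <- lapply(seq_along(parts), function(i) {
    bits <- suppressWarnings(as.integer(strsplit(parts[[i]][2L], ",")[[1L]]))
    if (length(bits) == 0L || anyNA(bits))
      stop_actland("malformed bit indices on line ", i, " of ", path)
    sort(unique(bits))
  })
  names(fps) <- ids
  fps
}

#' Write a fingerprint file
#'
#' @param fingerprints named list of integer bit-index vectors, or a
#'   [compound_set()] with fingerprints.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_file <- function(fingerprints, path) {
  if (inherits(fingerprints, "compound_set")) {
    cs <- ensure_fingerprints(fingerprints)
    fingerprints <- stats::setNames(cs$fingerprints, cs$ids)
  }
  lines <- vapply(names(fingerprints), function(id)
    paste0(id, "\t", paste(fingerprints[[id]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a compound table
#'
#' @param cs a [compound_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(cs, path) {
  df <- data.frame(id = cs$ids, pki = cs$potencies,
                   stringsAsFactors = FALSE)
  if (!is.null(cs$smiles)) df$smiles <- cs$smiles
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
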