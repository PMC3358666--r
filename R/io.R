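#' Read RNA sequences from a FASTA file
#'
#' Uses Biostrings when available, with a minimal plain-text fallback.
#' Sequences are normalized (uppercase, `T` to `U`) and validated.
#'
#' @param path FASTA file path.
#' @return List of [rna_sequence] objects (at least one; empty files are an
#'   error).
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no FASTA records in ", path)
    ids <- names(set)
    res <- as.character(set)
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L) stop("no FASTA records in ", path)
    ids <- sub("^>\\s*", "", lines[hdr])
    ends <- c(hdr[-1L] - 1L, length(lines))
    res <- vapply(seq_along(hdr), function(r) {
      paste(lines[seq(hdr[r] + 1L, ends[r])], collapse = "")
    }, character(1))
  }
  ids <- sub("\\s.*$", "", ids)
  mapply(rna_sequence, res, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read base-pair probabilities from a triplet file
#'
#' Plain-text exchange format for externally computed probabilities (e.g.
#' a McCaskill run of a full thermodynamic folding program): whitespace
#' separated lines `i j p` with 1-based `i < j`; `#` starts a comment;
#' unlisted pairs have probability 0.  Unpaired probabilities `q(i)` are
#' derived by normalization.
#'
#' @param path File path.
#' @param n Sequence length.
#' @return A `base_pair_probs` object.
#' @export
read_bpp_file <- function(path, n) {
  lines <- readLines(path)
  ii <- integer(0); jj <- integer(0); pp <- numeric(0)
  seen <- character(0)
  for (ln in seq_along(lines)) {
    txt <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(txt))) next
    parts <- strsplit(trimws(txt), "\\s+")[[1L]]
    if (length(parts) != 3L)
      stop(sprintf("line %d: expected 'i j p', got '%s'", ln, lines[ln]))
    i <- suppressWarnings(as.integer(parts[1L]))
    j <- suppressWarnings(as.integer(parts[2L]))
    p <- suppressWarnings(as.numeric(parts[3L]))
    if (is.na(i) || is.na(j) || is.na(p))
      stop(sprintf("line %d: non-numeric field", ln))
    if (i >= j) stop(sprintf("line %d: need i < j", ln))
    if (j > n) stop(sprintf("line %d: index %d exceeds n = %d", ln, j, n))
    if (p < 0 || p > 1)
      stop(sprintf("line %d: probability %g outside [0, 1]", ln, p))
    key <- paste(i, j)
    if (key %in% seen) stop(sprintf("line %d: duplicate pair (%d,%d)", ln, i, j))
    seen <- c(seen, key)
    ii <- c(ii, i); jj <- c(jj, j); pp <- c(pp, p)
  }
  make_bpp(n, ii, jj, pp)
}

#' Read a list of structures from a dot-bracket file
#'
#' One dot-bracket string per non-empty line (the first whitespace token;
#' trailing fields such as energies are ignored).  Lines whose first token
#' is not a length-`n` dot-bracket string are skipped with a warning, so
#' headers from folding-program output are tolerated.
#'
#' @param path File path.
#' @param n Expected sequence length.
#' @return List of [secondary_structure] objects in file order (possibly
#'   empty).
#' @export
read_structures_file <- function(path, n) {
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    if (!nzchar(trimws(lines[ln]))) next
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]][1L]
    if (!grepl("^[.()]+$", tok) || nchar(tok) != n) {
      warning(sprintf("line %d skipped (not a length-%d dot-bracket)", ln, n))
      next
    }
    S <- tryCatch(parse_dot_bracket(tok),
                  error = function(e)
                    stop(sprintf("line %d: %s", ln, conditionMessage(e))))
    out <- c(out, list(S))
  }
  out
}
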