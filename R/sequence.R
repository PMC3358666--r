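#' RNA sequence object
#'
#' Validates and normalizes a nucleotide string: residues are uppercased,
#' `T` is silently converted to `U`, and anything outside `A`, `C`, `G`, `U`
#' is rejected (no IUPAC ambiguity codes).  Positions are 1-based.
#'
#' @param residues Character scalar, the nucleotide string (length >= 1).
#' @param id Optional identifier label.
#' @return An object of class `rna_sequence`: a list with elements `id`,
#'   `residues` (normalized string) and `n` (length).
#' @examples
#' rna_sequence("gattaca")   # normalized to GAUUACA
#' @export
rna_sequence <- function(residues, id = "seq") {
  if (inherits(residues, "rna_sequence")) return(residues)
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- chartr("acgut", "ACGUT", residues)
  res <- gsub("T", "U", res, fixed = TRUE)
  if (nchar(res) < 1L) stop("empty sequence")
  bad <- regmatches(res, regexpr("[^ACGU]", res))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' in sequence '%s'", bad, id))
  }
  structure(list(id = as.character(id), residues = res, n = nchar(res)),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("rna_sequence '%s' (%d nt)\n%s\n", x$id, x$n, x$residues))
  invisible(x)
}

#' @export
length.rna_sequence <- function(x) x$n

# residues as a character vector, one element per position
seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1L]]

# the six canonical pair types (Watson-Crick + GU wobble)
CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

# n x n logical matrix: can positions i and j form a canonical pair?
canonical_pair_matrix <- function(seq) {
  ch <- seq_chars(seq)
  outer(ch, ch, function(a, b) paste0(a, b) %in% CANONICAL_PAIRS)
}

#' Seeded random RNA sequence
#'
#' Fixture generator: draws residues independently with the given expected
#' GC content (split evenly between G and C, and between A and U).
#'
#' @param n Length (>= 1).
#' @param gc_fraction Expected fraction of G+C residues, in \[0, 1\].
#' @param seed Integer seed; the same seed always yields the same sequence.
#'   `NULL` uses the current RNG state.
#' @param id Identifier for the resulting sequence.
#' @return An [rna_sequence].
#' @export
random_sequence <- function(n, gc_fraction = 0.5, seed = NULL, id = NULL) {
  stopifnot(n >= 1, gc_fraction >= 0, gc_fraction <= 1)
  draw <- function() {
    prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
              G = gc_fraction / 2, U = (1 - gc_fraction) / 2)
    paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (is.null(id)) id <- sprintf("random_n%d", n)
  rna_sequence(res, id = id)
}
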