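#' RNA secondary structure object
#'
#' A secondary structure on a length-`n` sequence is a set of base pairs
#' `(i, j)`, `1 <= i < j <= n`, that is nested (no pseudoknots) and pairs
#' each position at most once (no base triples).  The constructor enforces
#' those sequence-free requirements; the hairpin threshold (`j - i > theta`)
#' and canonical pairing against a concrete sequence are checked by
#' [validate_structure()], so that arbitrary parsed structures can be built
#' first and audited afterwards.
#'
#' @param pairs Two-column integer matrix (or empty) of base pairs; rows may
#'   be in any order and in any endpoint order.
#' @param n Sequence length the structure refers to.
#' @return An object of class `secondary_structure`: list with `n` and
#'   `pairs` (matrix sorted by opening position).
#' @examples
#' secondary_structure(rbind(c(1, 5)), n = 5)
#' @export
secondary_structure <- function(pairs, n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) > 0L) {
    pairs <- t(apply(pairs, 1L, sort))
    if (any(pairs[, 1L] < 1L) || any(pairs[, 2L] > n))
      stop("pair index out of range 1..n")
    if (any(pairs[, 1L] == pairs[, 2L]))
      stop("a position cannot pair with itself")
    pos <- c(pairs[, 1L], pairs[, 2L])
    if (anyDuplicated(pos))
      stop("base triple: a position occurs in more than one pair")
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    if (nrow(pairs) > 1L) {
      for (a in seq_len(nrow(pairs) - 1L)) {
        i <- pairs[a, 1L]; j <- pairs[a, 2L]
        k <- pairs[(a + 1L):nrow(pairs), 1L]
        l <- pairs[(a + 1L):nrow(pairs), 2L]
        if (any(i < k & k < j & j < l))
          stop("pseudoknot: crossing base pairs")
      }
    }
  }
  structure(list(n = n, pairs = pairs), class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary_structure (n = %d, %d pairs)\n%s\n",
              x$n, nrow(x$pairs), write_dot_bracket(x)))
  invisible(x)
}

# partner vector: partner[i] = j if (i,j) or (j,i) in S, else 0
partner_vector <- function(S) {
  p <- integer(S$n)
  if (nrow(S$pairs) > 0L) {
    p[S$pairs[, 1L]] <- S$pairs[, 2L]
    p[S$pairs[, 2L]] <- S$pairs[, 1L]
  }
  p
}

pair_keys <- function(S) {
  if (nrow(S$pairs) == 0L) character(0)
  else paste(S$pairs[, 1L], S$pairs[, 2L])
}

#' Parse a dot-bracket string
#'
#' Vienna dialect: `.` unpaired, matched `(`/`)` base pairs.  No extended
#' bracket alphabets, hence no pseudoknots can be expressed.
#'
#' @param text Dot-bracket string.
#' @return A [secondary_structure] with `n = nchar(text)`.
#' @examples
#' parse_dot_bracket("(((...)))")
#' @export
parse_dot_bracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- which(!(ch %in% c(".", "(", ")")))
  if (length(bad) > 0L)
    stop(sprintf("invalid character '%s' at position %d", ch[bad[1L]], bad[1L]))
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (pos in seq_along(ch)) {
    if (ch[pos] == "(") {
      stack <- c(stack, pos)
    } else if (ch[pos] == ")") {
      if (length(stack) == 0L)
        stop(sprintf("unbalanced ')' at position %d", pos))
      pairs <- rbind(pairs, c(stack[length(stack)], pos))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L)
    stop(sprintf("unbalanced '(' at position %d", stack[length(stack)]))
  secondary_structure(pairs, n = length(ch))
}

#' Serialize a structure to dot-bracket notation
#'
#' @param S A [secondary_structure].
#' @return Dot-bracket string of length `S$n`; round-trips with
#'   [parse_dot_bracket()].
#' @export
write_dot_bracket <- function(S) {
  stopifnot(inherits(S, "secondary_structure"))
  ch <- rep(".", S$n)
  if (nrow(S$pairs) > 0L) {
    ch[S$pairs[, 1L]] <- "("
    ch[S$pairs[, 2L]] <- ")"
  }
  paste(ch, collapse = "")
}

#' Validate a structure against the four structural requirements
#'
#' Checks, clause by clause: canonical pairing (only when a sequence is
#' supplied), the hairpin threshold `j - i > theta`, absence of pseudoknots,
#' and absence of base triples.  Violations are reported, not thrown, so a
#' structure can be audited.
#'
#' @param S A [secondary_structure].
#' @param seq Optional [rna_sequence] of matching length; enables the
#'   canonical-pair check (AU, UA, GC, CG, GU, UG).
#' @param theta Minimum unpaired bases in a hairpin loop (default 3).
#' @return List with `valid` (logical) and `violations` (character vector,
#'   empty iff valid).
#' @export
validate_structure <- function(S, seq = NULL, theta = 3L) {
  stopifnot(inherits(S, "secondary_structure"))
  v <- character(0)
  P <- S$pairs
  if (!is.null(seq)) {
    seq <- rna_sequence(seq)
    if (seq$n != S$n)
      stop("sequence length does not match structure length")
    if (nrow(P) > 0L) {
      ch <- seq_chars(seq)
      pt <- paste0(ch[P[, 1L]], ch[P[, 2L]])
      bad <- which(!(pt %in% CANONICAL_PAIRS))
      for (b in bad)
        v <- c(v, sprintf("non-canonical pair (%d,%d): %s",
                          P[b, 1L], P[b, 2L], pt[b]))
    }
  }
  if (nrow(P) > 0L) {
    bad <- which(P[, 2L] - P[, 1L] <= theta)
    for (b in bad)
      v <- c(v, sprintf("threshold violation (%d,%d): j-i = %d <= theta = %d",
                        P[b, 1L], P[b, 2L], P[b, 2L] - P[b, 1L], theta))
    # pseudoknots / triples are excluded at construction, but re-check in
    # case callers build the list by hand
    pos <- c(P[, 1L], P[, 2L])
    if (anyDuplicated(pos)) v <- c(v, "base triple")
    if (nrow(P) > 1L) {
      for (a in seq_len(nrow(P) - 1L)) {
        i <- P[a, 1L]; j <- P[a, 2L]
        k <- P[(a + 1L):nrow(P), 1L]; l <- P[(a + 1L):nrow(P), 2L]
        if (any(i < k & k < j & j < l)) v <- c(v, "pseudoknot")
      }
    }
  }
  list(valid = length(v) == 0L, violations = v)
}

#' Base-pair distance between two structures
#'
#' The cardinality of the symmetric difference of the two pair sets: the
#' minimum number of base pairs that must be added or removed to transform
#' one structure into the other.
#'
#' @param S,T [secondary_structure] objects on the same sequence length.
#' @return Non-negative integer distance.
#' @examples
#' S <- parse_dot_bracket(".......((((((((....))))))))")
#' T <- parse_dot_bracket("((((((((....)))))))).......")
#' base_pair_distance(S, T)  # 16
#' @export
base_pair_distance <- function(S, T) {
  stopifnot(inherits(S, "secondary_structure"),
            inherits(T, "secondary_structure"))
  if (S$n != T$n) stop("structures refer to different sequence lengths")
  a <- pair_keys(S)
  b <- pair_keys(T)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Restrict a structure to a subinterval
#'
#' Keeps exactly the pairs with both endpoints inside `[i, j]`; pairs with
#' one endpoint inside are dropped.  Positions keep their original indices.
#'
#' @param S A [secondary_structure].
#' @param i,j Interval bounds, `1 <= i <= j <= S$n`.
#' @return A [secondary_structure] with the same `n` whose pairs all lie in
#'   `[i, j]`.
#' @export
restrict_structure <- function(S, i, j) {
  stopifnot(inherits(S, "secondary_structure"))
  if (i < 1L || j > S$n || i > j) stop("interval out of range")
  P <- S$pairs
  keep <- P[, 1L] >= i & P[, 2L] <= j
  secondary_structure(P[keep, , drop = FALSE], n = S$n)
}
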