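#' Exhaustively enumerate all secondary structures of a sequence
#'
#' Brute-force oracle used as the package-wide ground truth.  Follows the
#' inductive construction over subintervals: a structure on `[i, j]` either
#' leaves `j` unpaired, or pairs `j` with some canonical partner
#' `r <= j - theta - 1`, splitting the interval into independent halves.
#' Every structure satisfying the structural requirements appears exactly
#' once.
#'
#' @param seq An [rna_sequence] (or string).
#' @param theta Hairpin threshold (default 3).
#' @param limit Hard cap on sequence length (default 20); enumeration is
#'   exponential and meant for desk-scale oracles only.
#' @return List of [secondary_structure] objects.
#' @examples
#' length(enumerate_structures("GGAAACC"))  # 6
#' @export
enumerate_structures <- function(seq, theta = 3L, limit = 20L) {
  seq <- rna_sequence(seq)
  if (seq$n > limit)
    stop(sprintf("sequence length %d exceeds enumeration limit %d",
                 seq$n, limit))
  can <- canonical_pair_matrix(seq)
  memo <- new.env(parent = emptyenv())
  # returns list of pair matrices (possibly 0-row) on interval [i, j]
  rec <- function(i, j) {
    if (j - i <= theta) return(list(matrix(integer(0), ncol = 2L)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i, j - 1L)                       # j unpaired
    for (r in i:(j - theta - 1L)) {
      if (!can[r, j]) next
      left <- if (r - 1L >= i) rec(i, r - 1L)
              else list(matrix(integer(0), ncol = 2L))
      inner <- rec(r + 1L, j - 1L)
      for (L in left) for (I in inner)
        out <- c(out, list(rbind(L, I, c(r, j))))
    }
    memo[[key]] <- out
    out
  }
  lapply(rec(1L, seq$n), secondary_structure, n = seq$n)
}

#' Count secondary structures by recursion (no enumeration)
#'
#' Independent counter implementing the same inductive construction as
#' [enumerate_structures()] but summing instead of listing; used to verify
#' the enumeration oracle.
#'
#' @inheritParams enumerate_structures
#' @return Total number of secondary structures (double).
#' @export
count_structures <- function(seq, theta = 3L) {
  seq <- rna_sequence(seq)
  n <- seq$n
  can <- canonical_pair_matrix(seq)
  # C[i, j] = number of structures on [i, j]; empty/short intervals -> 1
  C <- matrix(1, n, n)
  getC <- function(i, j) if (j - i <= theta || i > j) 1 else C[i, j]
  if (n > theta + 1L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        tot <- getC(i, j - 1L)
        for (r in i:(j - theta - 1L)) {
          if (can[r, j])
            tot <- tot + getC(i, r - 1L) * getC(r + 1L, j - 1L)
        }
        C[i, j] <- tot
      }
    }
  }
  getC(1L, n)
}

#' Count structures in each base-pair-distance class
#'
#' Computes `N^(k)`, the number of structures at base-pair distance exactly
#' `k` from a reference structure `S0`, for all feasible `k`.  For
#' `n <= limit` the counts come from the enumeration oracle; for longer
#' sequences a counting variant of the distance-resolved dynamic program is
#' used (the maximization replaced by a sum of unit weights).  The two
#' routes agree wherever both run.
#'
#' @param seq An [rna_sequence] (or string).
#' @param S0 Reference [secondary_structure] (default: empty structure).
#' @param theta Hairpin threshold.
#' @param limit Enumeration cap; above it the DP route is used.
#' @return Object of class `distance_profile_counts`: list with `k`
#'   (0..k_max), `counts` (`N^(k)`), and `total` (`N`).
#' @export
count_by_distance <- function(seq, S0 = NULL, theta = 3L, limit = 14L) {
  seq <- rna_sequence(seq)
  if (is.null(S0)) S0 <- secondary_structure(NULL, n = seq$n)
  if (S0$n != seq$n) stop("S0 length does not match sequence")
  if (seq$n <= limit) {
    all_S <- enumerate_structures(seq, theta = theta, limit = limit)
    d <- vapply(all_S, base_pair_distance, integer(1), T = S0)
    kmax <- max(d)
    counts <- vapply(0:kmax, function(k) sum(d == k), numeric(1))
  } else {
    counts <- count_by_distance_dp(seq, S0, theta = theta)
    kmax <- length(counts) - 1L
  }
  structure(list(k = 0:kmax, counts = counts, total = sum(counts)),
            class = "distance_profile_counts")
}

#' @export
print.distance_profile_counts <- function(x, ...) {
  cat(sprintf("distance_profile_counts: N = %g over k = 0..%d\n",
              x$total, max(x$k)))
  print(stats::setNames(x$counts, x$k))
  invisible(x)
}
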