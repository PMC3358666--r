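#' Parse a hard-constraint string
#'
#' Same length as the sequence: `.` leaves a position free, `x` forces it
#' unpaired, and matched `(` / `)` force a specific base pair.  Forced
#' pairs must be mutual (guaranteed by the bracket matching), non-crossing,
#' satisfy the hairpin threshold, and be canonical for the bound sequence.
#'
#' @param text Constraint string, or `NULL` for no constraints.
#' @param seq Optional [rna_sequence] to check canonical pairing and length.
#' @param theta Hairpin threshold.
#' @return Integer vector of per-position status (class `rna_constraints`):
#'   0 free, -1 forced unpaired, `t > 0` forced to pair with position `t`.
#' @export
parse_constraints <- function(text, seq = NULL, theta = 3L) {
  if (is.null(text)) return(NULL)
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- which(!(ch %in% c(".", "x", "(", ")")))
  if (length(bad) > 0L)
    stop(sprintf("invalid constraint character '%s' at position %d",
                 ch[bad[1L]], bad[1L]))
  paired <- parse_dot_bracket(gsub("x", ".", text))
  status <- partner_vector(paired)
  status[ch == "x"] <- -1L
  if (nrow(paired$pairs) > 0L) {
    v <- validate_structure(paired, seq = seq, theta = theta)
    if (!v$valid)
      stop("inconsistent constraints: ", paste(v$violations, collapse = "; "))
  }
  if (!is.null(seq)) {
    seq <- rna_sequence(seq)
    if (length(status) != seq$n)
      stop("constraint string length does not match sequence")
  }
  structure(status, class = "rna_constraints")
}

# normalize constraints input to a bare status vector
constraint_status <- function(constraints, seq, theta) {
  if (is.null(constraints)) return(integer(seq$n))
  if (is.character(constraints))
    constraints <- parse_constraints(constraints, seq = seq, theta = theta)
  if (length(constraints) != seq$n)
    stop("constraint vector length does not match sequence")
  as.integer(constraints)
}

#' Expected accuracy score of a structure
#'
#' `sigma(S) = sum_{(i,j) in S} 2 alpha p(i,j) + sum_{i unpaired} beta q(i)`,
#' where `p` and `q` are ensemble base-pair and unpaired probabilities.
#'
#' @param S A [secondary_structure].
#' @param bpp A `base_pair_probs` object of matching length.
#' @param alpha,beta Positive pair / unpaired weights (default 1).
#' @return The score (real).
#' @export
mea_score <- function(S, bpp, alpha = 1, beta = 1) {
  stopifnot(inherits(S, "secondary_structure"))
  if (S$n != bpp$n) stop("length mismatch between structure and bpp")
  pm <- dense_bpp(bpp)
  paired <- if (nrow(S$pairs) > 0L) sum(2 * alpha * pm[S$pairs]) else 0
  unp <- setdiff(seq_len(S$n), c(S$pairs))
  paired + sum(beta * bpp$q[unp])
}

#' Fill the distance-resolved MEA tables
#'
#' For every subinterval `[i, j]` and every `0 <= k <= K`, computes the
#' maximum expected accuracy score `M(i, j, k)` over all structures on
#' `[i, j]` (respecting any hard constraints) at base-pair distance exactly
#' `k` from the restriction of `S0` to `[i, j]`, together with traceback
#' triples `(r, k0, k1)`.  Infeasible cells carry `-Inf`.  Time is
#' `O(n^3 K^2)`, space `O(n^2 K)`.
#'
#' @param seq An [rna_sequence] (or string).
#' @param S0 Reference [secondary_structure] (default: empty structure).
#' @param bpp A `base_pair_probs` for the sequence (e.g. from
#'   [base_pair_probabilities()] or [read_bpp_file()]).
#' @param alpha,beta Positive pair / unpaired weights (default 1).
#' @param theta Hairpin threshold (default 3).
#' @param K Largest distance to consider; default covers the full feasible
#'   range (`|S0|` plus the maximum pair count).
#' @param constraints Optional constraint string or [parse_constraints()]
#'   result.
#' @return Object of class `mea_tables` (the engine state), with elements
#'   `V` (the `M(i, j, k)` array, third index `k + 1`), traceback arrays,
#'   and `feasible` (logical over `k = 0..K`).
#' @export
fill_mea_tables <- function(seq, S0 = NULL, bpp, alpha = 1, beta = 1,
                            theta = 3L, K = NULL, constraints = NULL) {
  stopifnot(alpha > 0, beta > 0)
  dp <- neighbor_dp(seq, S0, bpp = bpp, alpha = alpha, beta = beta,
                    theta = theta, K = K, mode = "max",
                    constraints = constraints)
  class(dp) <- "mea_tables"
  dp
}

#' @export
print.mea_tables <- function(x, ...) {
  cat(sprintf("mea_tables: n = %d, K = %d, feasible k: %s\n", x$n, x$K,
              paste(which(x$feasible) - 1L, collapse = " ")))
  invisible(x)
}

#' Trace back the MEA k-neighbor from filled tables
#'
#' Deterministic under the tie-breaking rule used when filling (prefer
#' leaving `j` unpaired, then pairing partners `r` in increasing order,
#' then the smallest left distance `k0`).
#'
#' @param tables An `mea_tables` object from [fill_mea_tables()].
#' @param k Feasible base-pair distance.
#' @return The [secondary_structure] `MEA(k)`: at distance exactly `k`
#'   from `S0`, with score `M(1, n, k)`.
#' @export
mea_traceback <- function(tables, k) {
  stopifnot(inherits(tables, "mea_tables"))
  k <- as.integer(k)
  if (k < 0L || k > tables$K || !tables$feasible[k + 1L])
    stop(sprintf("k = %d is infeasible", k))
  choose <- function(i, j, kk) {
    r <- tables$tb_r[i, j, kk + 1L]
    if (is.na(r)) stop("traceback reached an infeasible cell")
    if (r == -1L) return(list(case = "leaf"))
    if (r == 0L)
      return(list(case = "unpaired", k0 = tables$tb_k0[i, j, kk + 1L]))
    list(case = "pair", r = r,
         k0 = tables$tb_k0[i, j, kk + 1L],
         k1 = tables$tb_k1[i, j, kk + 1L])
  }
  dp_traceback(tables, k, choose)
}

#' Profile of MEA k-neighbors over all distances
#'
#' Convenience wrapper: fills the tables and traces back every feasible
#' `MEA(k)`.
#'
#' @inheritParams fill_mea_tables
#' @return Data frame with one row per `k = 0..K`: `k`, `feasible`,
#'   `mea_score` (`M(1, n, k)`, `NA` if infeasible) and `structure`
#'   (dot-bracket, `NA` if infeasible).  The filled tables are attached as
#'   attribute `"tables"`.
#' @examples
#' seq <- rna_sequence("GGAAACC")
#' bpp <- base_pair_probabilities(seq, energy_model(RT = 1))
#' mea_profile(seq, bpp = bpp)
#' @export
mea_profile <- function(seq, S0 = NULL, bpp, alpha = 1, beta = 1,
                        theta = 3L, K = NULL, constraints = NULL) {
  tab <- fill_mea_tables(seq, S0, bpp = bpp, alpha = alpha, beta = beta,
                         theta = theta, K = K, constraints = constraints)
  ks <- 0:tab$K
  strs <- rep(NA_character_, length(ks))
  for (k in ks[tab$feasible]) {
    strs[k + 1L] <- write_dot_bracket(mea_traceback(tab, k))
  }
  sc <- tab$V[1L, tab$n, ]
  sc[!tab$feasible] <- NA_real_
  out <- data.frame(k = ks, feasible = tab$feasible,
                    mea_score = sc, structure = strs,
                    stringsAsFactors = FALSE)
  attr(out, "tables") <- tab
  out
}
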