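#' Simple additive pair energy model
#'
#' A self-contained stand-in for a full nearest-neighbor thermodynamic
#' model: the free energy of a structure is the sum of one energy term per
#' base pair, by pair type, with no stacking or loop contributions.  With
#' additive pair energies the partition-function recursions mirror the
#' inductive construction of all structures, every quantity is exactly
#' enumerable at small `n`, and externally computed probability files can
#' stand in when a realistic model is wanted.
#'
#' @param pair_energy Named energies (kcal/mol) for the six canonical pair
#'   types.  Defaults: GC/CG -3, AU/UA -2, GU/UG -1.
#' @param theta Hairpin threshold (default 3).
#' @param RT Thermal energy in kcal/mol; default 0.6 (gas constant
#'   0.00198 kcal/mol/K times 310 K, rounded).
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(pair_energy = c(AU = -2, UA = -2, GC = -3, CG = -3,
                                         GU = -1, UG = -1),
                         theta = 3L, RT = 0.6) {
  stopifnot(RT > 0, theta >= 0)
  if (!setequal(names(pair_energy), CANONICAL_PAIRS))
    stop("pair_energy must name exactly the six canonical pair types")
  structure(list(pair_energy = pair_energy[CANONICAL_PAIRS],
                 theta = as.integer(theta), RT = RT),
            class = "energy_model")
}

#' Free energy of a structure under an additive pair model
#'
#' @param S A [secondary_structure].
#' @param seq Matching [rna_sequence] (or string).
#' @param model An [energy_model].
#' @return Energy in kcal/mol (0 for the empty structure).
#' @export
structure_energy <- function(S, seq, model = energy_model()) {
  seq <- rna_sequence(seq)
  if (S$n != seq$n) stop("length mismatch")
  if (nrow(S$pairs) == 0L) return(0)
  ch <- seq_chars(seq)
  pt <- paste0(ch[S$pairs[, 1L]], ch[S$pairs[, 2L]])
  if (any(!(pt %in% CANONICAL_PAIRS)))
    stop("structure contains a non-canonical pair for this sequence")
  sum(model$pair_energy[pt])
}

# n x n matrix of Boltzmann pair weights exp(-E(i,j)/RT); 0 if non-canonical
pair_weight_matrix <- function(seq, model) {
  ch <- seq_chars(seq)
  n <- seq$n
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pt <- paste0(ch[i], ch[j])
    if (pt %in% CANONICAL_PAIRS)
      w[i, j] <- exp(-model$pair_energy[[pt]] / model$RT)
  }
  w
}

# inside recursions:
#   Z(i, j)  = Z(i, j-1) + sum_r Z(i, r-1) * Zb(r, j)
#   Zb(i, j) = w(i, j) * Z(i+1, j-1)
# with Z = 1 on empty/short intervals.  Z[i, j] is only stored for
# j - i > theta; use inside_Z() to read with boundary convention.
inside_tables <- function(seq, model) {
  seq <- rna_sequence(seq)
  n <- seq$n
  theta <- model$theta
  w <- pair_weight_matrix(seq, model)
  Z <- matrix(1, n, n)
  Zb <- matrix(0, n, n)
  gZ <- function(i, j) if (i > j || j - i <= theta) 1 else Z[i, j]
  if (n > theta + 1L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        tot <- gZ(i, j - 1L)
        for (r in i:(j - theta - 1L)) {
          if (w[r, j] > 0) {
            Zb[r, j] <- w[r, j] * gZ(r + 1L, j - 1L)
            tot <- tot + gZ(i, r - 1L) * Zb[r, j]
          }
        }
        Z[i, j] <- tot
      }
    }
  }
  list(seq = seq, model = model, n = n, theta = theta, w = w, Z = Z, Zb = Zb)
}

inside_Z <- function(tab, i, j) {
  if (i > j || j - i <= tab$theta) 1 else tab$Z[i, j]
}

#' Partition function over all secondary structures
#'
#' `Z = sum_S exp(-E(S)/RT)` over every structure satisfying the structural
#' requirements, computed by the inside recursion; the tables are retained
#' for reuse by [base_pair_probabilities()] and [sample_structures()].
#'
#' @inheritParams structure_energy
#' @return List with `Z` (total weight) and `tables` (inside tables).
#' @examples
#' partition_function("GGAAACC", energy_model(RT = 1))$Z
#' @export
partition_function <- function(seq, model = energy_model()) {
  tab <- inside_tables(seq, model)
  list(Z = inside_Z(tab, 1L, tab$n), tables = tab)
}

# construct a base_pair_probs object from sparse triplets
make_bpp <- function(n, i = integer(0), j = integer(0), p = numeric(0),
                     tol = 1e-9) {
  stopifnot(length(i) == length(j), length(j) == length(p))
  q <- rep(1, n)
  for (t in seq_along(i)) {
    q[i[t]] <- q[i[t]] - p[t]
    q[j[t]] <- q[j[t]] - p[t]
  }
  if (any(q < -tol))
    stop("pair probabilities at some position sum to more than 1")
  q <- pmin(pmax(q, 0), 1)
  structure(list(n = as.integer(n), i = as.integer(i), j = as.integer(j),
                 p = as.numeric(p), q = q),
            class = "base_pair_probs")
}

#' @export
print.base_pair_probs <- function(x, ...) {
  cat(sprintf("base_pair_probs: n = %d, %d nonzero pairs\n",
              x$n, length(x$p)))
  invisible(x)
}

# dense n x n matrix of p(i, j) (symmetric fill)
dense_bpp <- function(bpp) {
  m <- matrix(0, bpp$n, bpp$n)
  if (length(bpp$p) > 0L) {
    m[cbind(bpp$i, bpp$j)] <- bpp$p
    m[cbind(bpp$j, bpp$i)] <- bpp$p
  }
  m
}

#' Boltzmann base-pair and unpaired probabilities
#'
#' `p(i, j)` is the total Boltzmann weight of structures containing the
#' pair `(i, j)`, divided by the partition function, computed by the
#' inside--outside method; `q(i) = 1 - sum_{j} p(i, j)` is the probability
#' that position `i` is unpaired.
#'
#' @inheritParams structure_energy
#' @return A `base_pair_probs` object (sparse `i`, `j`, `p` plus `q`).
#' @export
base_pair_probabilities <- function(seq, model = energy_model()) {
  tab <- inside_tables(seq, model)
  n <- tab$n; theta <- tab$theta
  Ztot <- inside_Z(tab, 1L, n)
  ZOut <- matrix(0, n, n)
  ZbOut <- matrix(0, n, n)
  ZOut[1L, n] <- 1
  if (n > theta + 1L) {
    for (d in (n - 1L):(theta + 1L)) {
      # phase A: expand Z-cells of this span
      for (i in seq_len(n - d)) {
        j <- i + d
        zo <- ZOut[i, j]
        if (zo == 0) next
        if (j - 1L >= i) ZOut[i, j - 1L] <- ZOut[i, j - 1L] + zo
        for (r in i:(j - theta - 1L)) {
          if (tab$w[r, j] > 0) {
            ZbOut[r, j] <- ZbOut[r, j] + zo * inside_Z(tab, i, r - 1L)
            if (r - 1L >= i)
              ZOut[i, r - 1L] <- ZOut[i, r - 1L] + zo * tab$Zb[r, j]
          }
        }
      }
      # phase B: expand pair-cells of this span into their interiors
      for (i in seq_len(n - d)) {
        j <- i + d
        if (tab$w[i, j] > 0 && ZbOut[i, j] > 0 && j - 1L >= i + 1L)
          ZOut[i + 1L, j - 1L] <- ZOut[i + 1L, j - 1L] +
            ZbOut[i, j] * tab$w[i, j]
      }
    }
  }
  P <- tab$Zb * ZbOut / Ztot
  idx <- which(P > 0, arr.ind = TRUE)
  make_bpp(n, i = idx[, 1L], j = idx[, 2L], p = P[idx])
}

#' Sample structures from the Boltzmann ensemble
#'
#' Stochastic traceback through the inside tables: each draw is an
#' independent sample with `P(S) = exp(-E(S)/RT) / Z`.
#'
#' @inheritParams structure_energy
#' @param N Number of structures to draw.
#' @param seed Integer seed for reproducibility (`NULL`: current RNG state).
#' @return List of `N` [secondary_structure] objects.
#' @export
sample_structures <- function(seq, model = energy_model(), N = 1L,
                              seed = NULL) {
  stopifnot(N >= 1L)
  tab <- inside_tables(seq, model)
  draw_all <- function() replicate(N, sample_one(tab), simplify = FALSE)
  if (is.null(seed)) draw_all() else withr::with_seed(seed, draw_all())
}

sample_one <- function(tab) {
  pairs <- matrix(integer(0), ncol = 2L)
  theta <- tab$theta
  rec <- function(i, j) {
    if (i > j || j - i <= theta) return(invisible(NULL))
    u <- stats::runif(1L) * inside_Z(tab, i, j)
    acc <- inside_Z(tab, i, j - 1L)
    if (u <= acc) {
      rec(i, j - 1L)
      return(invisible(NULL))
    }
    for (r in i:(j - theta - 1L)) {
      if (tab$w[r, j] > 0) {
        acc <- acc + inside_Z(tab, i, r - 1L) * tab$Zb[r, j]
        if (u <= acc) {
          pairs <<- rbind(pairs, c(r, j))
          if (r - 1L >= i) rec(i, r - 1L)
          rec(r + 1L, j - 1L)
          return(invisible(NULL))
        }
      }
    }
    # numerical slack: fall back to the last pairing case
    stop("stochastic traceback failed (numerical inconsistency)")
  }
  rec(1L, tab$n)
  secondary_structure(pairs, n = tab$n)
}
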