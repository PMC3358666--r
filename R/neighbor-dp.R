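# Distance-resolved dynamic programming engine.
#
# For every subinterval [i, j] and every base-pair distance k, the engine
# considers all secondary structures T on [i, j] whose distance to the
# restriction S0[i, j] of the reference structure is exactly k, and either
# maximizes the expected-accuracy score sigma(T) (mode "max") or accumulates
# log sum exp(sigma(T)/RT) (mode "logsum"; with sigma = 0 this counts
# structures).  The decomposition is the classical unambiguous one: position
# j is unpaired, or pairs with some r in [i, j - theta - 1], splitting the
# interval at r.  Distance bookkeeping relative to S0[i, j]:
#
#   * j unpaired: any reference pair (x, j) inside [i, j] is lost -> offset
#     b0 = 1 if j is paired within S0[i, j].
#   * pair (r, j) added: if (r, j) is a reference pair the offset b1 = 0;
#     otherwise b1 = 1 (for the added pair) plus one for each reference pair
#     inside [r, j] touching r or j (those can no longer occur).
#   * split at r: reference pairs with one endpoint in [i, r-1] and the
#     other in [r, j] cross the split and can occur on neither side ->
#     offset c(r) = number of such pairs.
#
# These offsets follow from the symmetric difference decomposing over the
# three disjoint groups of reference pairs (left of split, right of split,
# crossing); correctness is pinned down by the enumeration-oracle tests.

# logaddexp for vectors, -Inf-safe
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

# default upper bound for K: |S0| plus the maximum possible number of pairs
default_K <- function(n, S0, theta) {
  nrow(S0$pairs) + max(0L, floor((n - theta) / 2))
}

neighbor_dp <- function(seq, S0, bpp = NULL, alpha = 1, beta = 1,
                        theta = 3L, K = NULL, RT = 1, mode = c("max", "logsum"),
                        constraints = NULL, zero_scores = FALSE) {
  mode <- match.arg(mode)
  seq <- rna_sequence(seq)
  n <- seq$n
  if (is.null(S0)) S0 <- secondary_structure(NULL, n = n)
  if (S0$n != n) stop("S0 length does not match sequence")
  val <- validate_structure(S0, seq = seq, theta = theta)
  if (!val$valid)
    stop("S0 is not a valid structure of the sequence: ",
         paste(val$violations, collapse = "; "))
  if (is.null(bpp) && !zero_scores)
    stop("base-pair probabilities are required")
  if (is.null(K)) K <- default_K(n, S0, theta)
  K <- as.integer(K)
  if (K < 0L || K > 2L * n) stop("K must lie in [0, 2n]")

  cs <- constraint_status(constraints, seq = seq, theta = theta)
  forced <- which(cs > 0L)
  forced_pairs <- if (length(forced)) {
    fp <- cbind(forced, cs[forced])
    fp[fp[, 1L] < fp[, 2L], , drop = FALSE]
  } else matrix(integer(0), ncol = 2L)

  if (zero_scores) {
    pair_sc <- matrix(0, n, n)
    unp_sc <- numeric(n)
  } else {
    if (bpp$n != n) stop("bpp length does not match sequence")
    scale <- if (mode == "logsum") RT else 1
    pair_sc <- 2 * alpha * dense_bpp(bpp) / scale
    unp_sc <- beta * bpp$q / scale
  }
  can <- canonical_pair_matrix(seq)
  s0p <- partner_vector(S0)
  s0pairs <- S0$pairs

  NEG <- -Inf
  V <- array(NEG, dim = c(n, n, K + 1L))
  max_mode <- mode == "max"
  if (max_mode) {
    tb_r <- array(NA_integer_, dim = c(n, n, K + 1L))
    tb_k0 <- array(NA_integer_, dim = c(n, n, K + 1L))
    tb_k1 <- array(NA_integer_, dim = c(n, n, K + 1L))
  }
  # value vector (k = 0..K) of the empty interval
  empty_vec <- c(0, rep(NEG, K))
  get_vec <- function(i, j) {           # i > j means empty interval
    if (i > j) empty_vec else V[i, j, ]
  }

  for (d in 0:(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      if (d <= theta) {
        # only the empty structure fits; infeasible if a forced pair
        # endpoint lies inside (its partner cannot)
        if (!any(cs[i:j] > 0L)) {
          V[i, j, 1L] <- sum(unp_sc[i:j])
          if (max_mode) tb_r[i, j, 1L] <- -1L
        }
        next
      }
      acc <- rep(NEG, K + 1L)
      if (max_mode) {
        arg_r <- rep(NA_integer_, K + 1L)
        arg_k0 <- rep(NA_integer_, K + 1L)
        arg_k1 <- rep(NA_integer_, K + 1L)
      }
      # ---- case: j unpaired ------------------------------------------
      if (cs[j] <= 0L) {
        b0 <- as.integer(s0p[j] >= i && s0p[j] < j)
        prev <- get_vec(i, j - 1L)
        cand <- rep(NEG, K + 1L)
        if (b0 == 0L) cand <- prev + unp_sc[j]
        else if (K >= 1L) cand[2L:(K + 1L)] <- prev[1L:K] + unp_sc[j]
        if (max_mode) {
          better <- cand > acc
          if (any(better)) {
            acc[better] <- cand[better]
            arg_r[better] <- 0L
            arg_k0[better] <- which(better) - 1L - b0   # child k on [i, j-1]
            arg_k1[better] <- 0L
          }
        } else {
          acc <- logaddexp(acc, cand)
        }
      }
      # ---- cases: pair (r, j), r in [i, j - theta - 1] ----------------
      for (r in i:(j - theta - 1L)) {
        if (!can[r, j]) next
        if (!(cs[r] == 0L || cs[r] == j)) next
        if (!(cs[j] == 0L || cs[j] == r)) next
        if (nrow(forced_pairs) > 0L && r > i) {
          # a forced pair may not straddle the split [i, r-1] | [r, j]
          x <- forced_pairs[, 1L]; y <- forced_pairs[, 2L]
          if (any(x >= i & x < r & y >= r & y <= j)) next
        }
        # distance offset for adding pair (r, j) on [r, j]
        if (s0p[r] == j) {
          b1 <- 0L
        } else {
          b1 <- 1L + as.integer(s0p[r] > r && s0p[r] <= j) +
                     as.integer(s0p[j] >= r && s0p[j] < j)
        }
        # reference pairs crossing the split at r
        cr <- 0L
        if (r > i && nrow(s0pairs) > 0L) {
          x <- s0pairs[, 1L]; y <- s0pairs[, 2L]
          cr <- sum(x >= i & x < r & y >= r & y <= j)
        }
        left <- get_vec(i, r - 1L)
        inner <- get_vec(r + 1L, j - 1L)
        # right[k1+1] = best over structures on [r, j] containing (r, j)
        # at distance k1 from S0[r, j]
        right <- rep(NEG, K + 1L)
        if (b1 <= K)
          right[(b1 + 1L):(K + 1L)] <-
            inner[1L:(K + 1L - b1)] + pair_sc[r, j]
        for (k in cr:K) {
          kk <- k - cr
          k0s <- 0L:kk
          vals <- left[k0s + 1L] + right[kk - k0s + 1L]
          if (max_mode) {
            bi <- which.max(vals)        # ties -> smallest k0
            if (vals[bi] > acc[k + 1L]) {
              acc[k + 1L] <- vals[bi]
              arg_r[k + 1L] <- r
              arg_k0[k + 1L] <- k0s[bi]              # child k on [i, r-1]
              arg_k1[k + 1L] <- kk - k0s[bi] - b1    # child k on [r+1, j-1]
            }
          } else {
            acc[k + 1L] <- logaddexp(acc[k + 1L], logsumexp(vals))
          }
        }
      }
      V[i, j, ] <- acc
      if (max_mode) {
        tb_r[i, j, ] <- arg_r
        tb_k0[i, j, ] <- arg_k0
        tb_k1[i, j, ] <- arg_k1
      }
    }
  }

  out <- list(mode = mode, n = n, K = K, theta = as.integer(theta),
              alpha = alpha, beta = beta, RT = RT,
              seq = seq, S0 = S0, bpp = bpp, constraints = cs,
              pair_sc = pair_sc, unp_sc = unp_sc,
              s0p = s0p, s0pairs = s0pairs, can = can,
              V = V, feasible = is.finite(V[1L, n, ]))
  if (max_mode) {
    out$tb_r <- tb_r; out$tb_k0 <- tb_k0; out$tb_k1 <- tb_k1
  }
  out
}

# shared recursive traceback skeleton.  choose_case(i, j, k) must return a
# list(case = "leaf" | "unpaired" | "pair", r, k0, k1) consistent with the
# DP decomposition; used both for deterministic MEA traceback (argmax
# triples) and stochastic sampling (case drawn proportionally to weight).
dp_traceback <- function(dp, k, choose_case) {
  pairs <- matrix(integer(0), ncol = 2L)
  rec <- function(i, j, k) {
    if (i > j) {
      stopifnot(k == 0L)
      return(invisible(NULL))
    }
    if (j - i <= dp$theta) {
      stopifnot(k == 0L)
      return(invisible(NULL))
    }
    ch <- choose_case(i, j, k)
    if (ch$case == "unpaired") {
      rec(i, j - 1L, ch$k0)
    } else {
      pairs <<- rbind(pairs, c(ch$r, j))
      if (ch$r > i) rec(i, ch$r - 1L, ch$k0)
      rec(ch$r + 1L, j - 1L, ch$k1)
    }
    invisible(NULL)
  }
  rec(1L, dp$n, as.integer(k))
  secondary_structure(pairs, n = dp$n)
}

# offsets used during traceback (must mirror neighbor_dp)
dp_offsets <- function(dp, i, j, r) {
  if (dp$s0p[r] == j) {
    b1 <- 0L
  } else {
    b1 <- 1L + as.integer(dp$s0p[r] > r && dp$s0p[r] <= j) +
               as.integer(dp$s0p[j] >= r && dp$s0p[j] < j)
  }
  cr <- 0L
  if (r > i && nrow(dp$s0pairs) > 0L) {
    x <- dp$s0pairs[, 1L]; y <- dp$s0pairs[, 2L]
    cr <- sum(x >= i & x < r & y >= r & y <= j)
  }
  list(b1 = b1, cr = cr)
}

# counting variant: unit weights, log-space sums, rounded back to integers
count_by_distance_dp <- function(seq, S0, theta = 3L, K = NULL) {
  dp <- neighbor_dp(seq, S0, theta = theta, K = K, mode = "logsum",
                    zero_scores = TRUE)
  counts <- round(exp(dp$V[1L, dp$n, ]))
  kmax <- max(which(dp$feasible)) - 1L
  counts[seq_len(kmax + 1L)]
}
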