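#' Fill the pseudo-Boltzmann partition tables
#'
#' Runs the same distance-resolved decomposition as [fill_mea_tables()]
#' with maximization replaced by summation of pseudo-Boltzmann factors:
#' `Ztilde_{i,j}(k) = sum exp(sigma(T)/RT)` over structures `T` on
#' `[i, j]` at distance `k` from the restricted reference.  Because the
#' decomposition is unambiguous every structure is counted exactly once.
#' All sums are carried in log space, so large `sigma/RT` cannot overflow.
#'
#' The parameter `RT` here is purely formal -- the exponent weights an
#' accuracy score, not an energy; `RT = n` (sequence length) normalizes
#' the maximal MEA score to about 1.
#'
#' @inheritParams fill_mea_tables
#' @param RT Formal temperature parameter (> 0), default 0.6.
#' @return Object of class `pseudo_tables` with elements `log_Zk`
#'   (`log Ztilde_k`, `k = 0..K`), `Zk`, `Z` (their sum), `p_tilde`
#'   (normalized probabilities) and the engine state for sampling.
#' @export
fill_pseudo_tables <- function(seq, S0 = NULL, bpp, alpha = 1, beta = 1,
                               theta = 3L, K = NULL, RT = 0.6,
                               constraints = NULL) {
  stopifnot(alpha > 0, beta > 0, RT > 0)
  dp <- neighbor_dp(seq, S0, bpp = bpp, alpha = alpha, beta = beta,
                    theta = theta, K = K, RT = RT, mode = "logsum",
                    constraints = constraints)
  log_Zk <- dp$V[1L, dp$n, ]
  lZ <- logsumexp(log_Zk)
  dp$log_Zk <- log_Zk
  dp$Zk <- exp(log_Zk)
  dp$Z <- exp(lZ)
  dp$p_tilde <- exp(log_Zk - lZ)
  class(dp) <- "pseudo_tables"
  dp
}

#' @export
print.pseudo_tables <- function(x, ...) {
  cat(sprintf("pseudo_tables: n = %d, K = %d, RT = %g\n", x$n, x$K, x$RT))
  print(data.frame(k = 0:x$K, Z_tilde = x$Zk, p_tilde = x$p_tilde))
  invisible(x)
}

#' Pseudo-Boltzmann distance-class probabilities
#'
#' `p_tilde_k = Ztilde_k / sum_k Ztilde_k`.
#'
#' @param pp A `pseudo_tables` object from [fill_pseudo_tables()].
#' @return Numeric vector over `k = 0..K` summing to 1.
#' @export
pseudo_probabilities <- function(pp) {
  stopifnot(inherits(pp, "pseudo_tables"))
  pp$p_tilde
}

#' Sample structures from the MEA ensemble
#'
#' Stochastic traceback through the pseudo-partition tables.  Without
#' conditioning, draws with `P(T) = exp(sigma(T)/RT) / Ztilde` (the
#' distance class `k` is drawn first, proportionally to `Ztilde_k`, then a
#' structure within the class); with `condition_k = k`, draws within the
#' `k`-neighbor class with `P(T) = exp(sigma(T)/RT) / Ztilde_k`.
#'
#' @param tables A `pseudo_tables` object.
#' @param N Number of draws.
#' @param seed Integer seed (`NULL`: current RNG state).
#' @param condition_k Restrict draws to this distance class, or `NULL`.
#' @return List of `N` [secondary_structure] objects.
#' @export
sample_mea_ensemble <- function(tables, N = 1L, seed = NULL,
                                condition_k = NULL) {
  stopifnot(inherits(tables, "pseudo_tables"), N >= 1L)
  if (!is.null(condition_k)) {
    condition_k <- as.integer(condition_k)
    if (condition_k < 0L || condition_k > tables$K ||
        !tables$feasible[condition_k + 1L])
      stop(sprintf("condition_k = %d is infeasible", condition_k))
  }
  draw_all <- function() {
    replicate(N, {
      k <- if (is.null(condition_k)) {
        sample.int(tables$K + 1L, 1L, prob = tables$p_tilde) - 1L
      } else condition_k
      pseudo_sample_one(tables, k)
    }, simplify = FALSE)
  }
  if (is.null(seed)) draw_all() else withr::with_seed(seed, draw_all())
}

# one stochastic traceback conditioned on top-level distance k
pseudo_sample_one <- function(dp, k) {
  choose <- function(i, j, kk) {
    cell <- dp$V[i, j, kk + 1L]
    if (!is.finite(cell)) stop("sampling reached an infeasible cell")
    if (j - i <= dp$theta) return(list(case = "leaf"))
    logw <- numeric(0)
    cases <- list()
    emptyv <- c(0, rep(-Inf, dp$K))
    getv <- function(a, b) if (a > b) emptyv else dp$V[a, b, ]
    if (dp$constraints[j] <= 0L) {
      b0 <- as.integer(dp$s0p[j] >= i && dp$s0p[j] < j)
      k0 <- kk - b0
      if (k0 >= 0L) {
        w <- getv(i, j - 1L)[k0 + 1L] + dp$unp_sc[j]
        if (is.finite(w)) {
          logw <- c(logw, w)
          cases <- c(cases, list(list(case = "unpaired", k0 = k0)))
        }
      }
    }
    for (r in i:(j - dp$theta - 1L)) {
      if (!dp$can[r, j]) next
      if (!(dp$constraints[r] == 0L || dp$constraints[r] == j)) next
      if (!(dp$constraints[j] == 0L || dp$constraints[j] == r)) next
      off <- dp_offsets(dp, i, j, r)
      forced <- which(dp$constraints > 0L)
      if (length(forced) && r > i) {
        x <- forced[forced < dp$constraints[forced]]
        y <- dp$constraints[x]
        if (any(x >= i & x < r & y >= r & y <= j &
                !(x == r & y == j))) next
      }
      left <- getv(i, r - 1L)
      inner <- getv(r + 1L, j - 1L)
      kk2 <- kk - off$cr
      if (kk2 < 0L) next
      for (k0 in 0L:kk2) {
        k1 <- kk2 - k0 - off$b1
        if (k1 < 0L || k1 > dp$K || k0 > dp$K) next
        w <- left[k0 + 1L] + inner[k1 + 1L] + dp$pair_sc[r, j]
        if (is.finite(w)) {
          logw <- c(logw, w)
          cases <- c(cases,
                     list(list(case = "pair", r = r, k0 = k0, k1 = k1)))
        }
      }
    }
    pr <- exp(logw - logsumexp(logw))
    cases[[sample.int(length(cases), 1L, prob = pr)]]
  }
  dp_traceback(dp, k, choose)
}

#' Uniform distribution over distance classes
#'
#' `P_u(k) = N^(k) / N`, where `N^(k)` counts the `k`-neighbors of the
#' reference structure and `N` the total number of structures; the
#' distance profile of a structure ensemble in which every structure is
#' equally likely.
#'
#' @param counts A `distance_profile_counts` object from
#'   [count_by_distance()].
#' @return Numeric vector `P_u(k)` over `k = 0..k_max`, summing to 1.
#' @export
uniform_distance_distribution <- function(counts) {
  stopifnot(inherits(counts, "distance_profile_counts"))
  counts$counts / counts$total
}
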