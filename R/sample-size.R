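#' Minimal sample size for uniform accuracy over distance bins
#'
#' Closed-form bound: sampling at least `N(eps, p, K)` structures from the
#' Boltzmann ensemble guarantees that the relative frequency `f_k` of each
#' of the `K` distance bins is within `eps` of the true probability `p_k`,
#' simultaneously for all `0 <= k < K`, with total failure probability at
#' most `p`.  With `z = |Phi^-1(p/(2K))|` the bound is
#' `N = z^2 / (4 eps^2)` (worst-case bin variance 1/4).
#'
#' By default `z` is rounded to two decimal places before squaring and the
#' result floored; `exact = TRUE` skips the rounding and returns
#' `ceiling(z^2 / (4 eps^2))` instead.
#'
#' @param epsilon Accuracy margin, in (0, 1).
#' @param confidence_p Total failure probability across all bins, in (0, 1)
#'   (the guarantee holds with confidence `1 - confidence_p`).
#' @param K Number of distance bins (>= 1).
#' @param exact Use the unrounded critical value (default `FALSE`).
#' @return Object of class `sample_size_spec`: list with `epsilon`,
#'   `confidence_p`, `K`, `z` and `N`.
#' @examples
#' required_sample_size(0.01, 0.05, 100)$N   # 30276
#' @export
required_sample_size <- function(epsilon, confidence_p, K, exact = FALSE) {
  if (!(epsilon > 0 && epsilon < 1)) stop("epsilon must be in (0, 1)")
  if (!(confidence_p > 0 && confidence_p < 1))
    stop("confidence_p must be in (0, 1)")
  if (K < 1) stop("K must be >= 1")
  z <- abs(stats::qnorm(confidence_p / (2 * K)))
  if (exact) {
    N <- ceiling(z^2 / (4 * epsilon^2))
  } else {
    z <- round(z, 2L)
    N <- floor(z^2 / (4 * epsilon^2))
  }
  structure(list(epsilon = epsilon, confidence_p = confidence_p,
                 K = as.integer(K), z = z, N = N),
            class = "sample_size_spec")
}

#' @export
print.sample_size_spec <- function(x, ...) {
  cat(sprintf(
    "sample_size_spec: eps = %g, p = %g, K = %d -> z = %.2f, N = %d\n",
    x$epsilon, x$confidence_p, x$K, x$z, x$N))
  invisible(x)
}

#' Distance histogram of a structure sample
#'
#' Counts, for each base-pair distance `k` to the reference structure, the
#' number `N_k` of sampled structures at that distance, and the relative
#' frequencies `f_k = N_k / N`.
#'
#' @param samples Non-empty list of [secondary_structure] objects sharing
#'   the reference's length.
#' @param S0 Reference [secondary_structure].
#' @param K Optional number of bins: the histogram is zero-filled up to
#'   `k = K - 1` (always at least up to the largest observed distance).
#' @return Object of class `sample_summary`: list with `N`, `k`, `counts`
#'   and `freq`.
#' @export
distance_histogram <- function(samples, S0, K = NULL) {
  stopifnot(length(samples) >= 1L)
  d <- vapply(samples, base_pair_distance, integer(1), T = S0)
  kmax <- max(d)
  if (!is.null(K)) kmax <- max(kmax, K - 1L)
  counts <- vapply(0:kmax, function(k) sum(d == k), numeric(1))
  structure(list(N = length(samples), k = 0:kmax, counts = counts,
                 freq = counts / length(samples)),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("sample_summary: N = %d samples\n", x$N))
  print(data.frame(k = x$k, count = x$counts, frequency = x$freq))
  invisible(x)
}

#' Approximate the distance-class probabilities p_k by sampling
#'
#' Draws (or loads) at least `N(eps, p, K)` Boltzmann-ensemble structures
#' and returns their distance histogram relative to `S0`: the frequencies
#' `f_k` estimate the true `p_k = Z_k / Z` with `P(|p_k - f_k| < eps)
#' >= 1 - p` simultaneously for all `k < K`.  A warning is emitted for
#' estimated bins where `N * f_k < 30`, where the normal approximation
#' behind the bound is shaky.
#'
#' @param seq An [rna_sequence] (or string).
#' @param S0 Reference [secondary_structure] (default: empty).
#' @param epsilon,confidence_p,K Passed to [required_sample_size()].
#' @param model [energy_model] used when sampling internally.
#' @param structures Optional list of pre-sampled [secondary_structure]
#'   objects (e.g. from [read_structures_file()]); must contain at least
#'   the required `N`.
#' @param seed Integer seed for internal sampling.
#' @return A `sample_summary` (see [distance_histogram()]) with the
#'   [required_sample_size()] spec attached as element `spec`.
#' @export
approximate_bor_profile <- function(seq, S0 = NULL, epsilon, confidence_p, K,
                                    model = energy_model(),
                                    structures = NULL, seed = NULL) {
  seq <- rna_sequence(seq)
  if (is.null(S0)) S0 <- secondary_structure(NULL, n = seq$n)
  spec <- required_sample_size(epsilon, confidence_p, K)
  if (is.null(structures)) {
    samples <- sample_structures(seq, model = model, N = spec$N, seed = seed)
  } else {
    if (length(structures) < spec$N)
      stop(sprintf("need at least N = %d pre-sampled structures, got %d",
                   spec$N, length(structures)))
    samples <- structures
  }
  h <- distance_histogram(samples, S0, K = K)
  small <- h$counts > 0 & h$N * h$freq < 30
  if (any(small))
    warning(sprintf(
      "bins with N*f_k < 30 (normal approximation unreliable): k = %s",
      paste(h$k[small], collapse = " ")))
  h$spec <- spec
  h
}
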