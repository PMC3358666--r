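# Shared brute-force oracles: everything here works by exhaustive
# enumeration on small sequences and is independent of the DP code paths
# it is used to check.

# exact Boltzmann probability of each enumerated structure
oracle_boltzmann <- function(seq, model, all_S = NULL) {
  if (is.null(all_S)) all_S <- enumerate_structures(seq, theta = model$theta)
  w <- vapply(all_S, function(S)
    exp(-structure_energy(S, seq, model) / model$RT), numeric(1))
  list(structures = all_S, weights = w, Z = sum(w), prob = w / sum(w))
}

# exact p(i, j) by enumeration
oracle_bpp_matrix <- function(seq, model) {
  ob <- oracle_boltzmann(seq, model)
  n <- rna_sequence(seq)$n
  P <- matrix(0, n, n)
  for (t in seq_along(ob$structures)) {
    S <- ob$structures[[t]]
    if (nrow(S$pairs) > 0L)
      P[S$pairs] <- P[S$pairs] + ob$prob[t]
  }
  P + t(P) - diag(diag(P))
}

# exact distance-class probabilities p_k = Z_k / Z
oracle_pk <- function(seq, S0, model) {
  ob <- oracle_boltzmann(seq, model)
  d <- vapply(ob$structures, base_pair_distance, integer(1), T = S0)
  vapply(0:max(d), function(k) sum(ob$weights[d == k]) / ob$Z, numeric(1))
}

# per-k brute-force MEA optimum (score; -Inf if no k-neighbor)
oracle_mea_by_k <- function(seq, S0, bpp, alpha = 1, beta = 1, K) {
  all_S <- enumerate_structures(seq)
  d <- vapply(all_S, base_pair_distance, integer(1), T = S0)
  sig <- vapply(all_S, mea_score, numeric(1), bpp = bpp,
                alpha = alpha, beta = beta)
  vapply(0:K, function(k) if (any(d == k)) max(sig[d == k]) else -Inf,
         numeric(1))
}

# chi-square goodness-of-fit p-value for observed counts vs probabilities
gof_pvalue <- function(obs_counts, prob) {
  keep <- prob > 0
  exp_counts <- sum(obs_counts) * prob[keep]
  stat <- sum((obs_counts[keep] - exp_counts)^2 / exp_counts)
  stats::pchisq(stat, df = sum(keep) - 1L, lower.tail = FALSE)
}

# structures keyed by dot-bracket, for tabulating samples
db_keys <- function(structures) {
  vapply(structures, write_dot_bracket, character(1))
}

toy_seq <- function() rna_sequence("GGAAACC")
toy_model <- function() {
  energy_model(pair_energy = c(AU = -1, UA = -1, GC = -1, CG = -1,
                               GU = -1, UG = -1), RT = 1)
}
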