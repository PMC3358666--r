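test_that("pseudo-partition values equal enumeration sums per k", {
  seq <- toy_seq()
  bpp <- base_pair_probabilities(seq, toy_model())
  S0 <- secondary_structure(NULL, 7)
  pt <- fill_pseudo_tables(seq, S0, bpp = bpp, RT = 1)
  expect_equal(pt$Zk[1], exp(mea_score(S0, bpp)), tolerance = 1e-12)
  all_S <- enumerate_structures(seq)
  d <- vapply(all_S, base_pair_distance, integer(1), T = S0)
  sig <- vapply(all_S, mea_score, numeric(1), bpp = bpp)
  for (k in 0:pt$K)
    expect_equal(pt$Zk[k + 1], sum(exp(sig[d == k])), tolerance = 1e-9)
  expect_equal(pt$Z, sum(exp(sig)), tolerance = 1e-9)
  # probabilities normalize and match enumeration ratios
  p <- pseudo_probabilities(pt)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(p, vapply(0:pt$K, function(k) sum(exp(sig[d == k])),
                         numeric(1)) / sum(exp(sig)), tolerance = 1e-9)
})

test_that("pseudo DP matches enumeration across random sequences and RT", {
  set.seed(99)
  for (t in 1:10) {
    seq <- random_sequence(sample(6:12, 1), gc_fraction = 0.6,
                           seed = 2000 + t)
    bpp <- base_pair_probabilities(seq)
    all_S <- enumerate_structures(seq)
    S0 <- all_S[[sample(length(all_S), 1)]]
    d <- vapply(all_S, base_pair_distance, integer(1), T = S0)
    sig <- vapply(all_S, mea_score, numeric(1), bpp = bpp)
    RT <- sample(c(0.6, 1, seq$n), 1)
    pt <- fill_pseudo_tables(seq, S0, bpp = bpp, RT = RT)
    for (k in 0:pt$K) {
      want <- sum(exp(sig[d == k] / RT))
      expect_equal(pt$Zk[k + 1], want, tolerance = 1e-9)
    }
  }
})

test_that("log-space sums survive scores far beyond overflow", {
  seq <- toy_seq()
  bpp <- base_pair_probabilities(seq, toy_model())
  pt <- fill_pseudo_tables(seq, NULL, bpp = bpp, RT = 1e-4)
  expect_true(all(is.finite(pt$log_Zk[pt$feasible])))
  expect_equal(sum(pt$p_tilde), 1, tolerance = 1e-9)
  # max-sum consistency: RT * log Ztilde_k >= M(1, n, k), tight as RT -> 0
  tab <- fill_mea_tables(seq, NULL, bpp = bpp)
  M <- tab$V[1, 7, ]
  bound <- 1e-4 * pt$log_Zk
  expect_true(all(bound[tab$feasible] >= M[tab$feasible] - 1e-9))
  gap <- bound[tab$feasible] - M[tab$feasible]
  expect_true(all(gap < 1e-2 * pmax(abs(M[tab$feasible]), 1)))
})

test_that("MEA-ensemble sampling is seeded, conditioned and calibrated", {
  seq <- toy_seq()
  bpp <- base_pair_probabilities(seq, toy_model())
  all_S <- enumerate_structures(seq)
  S0 <- parse_dot_bracket("((...))")
  pt <- fill_pseudo_tables(seq, S0, bpp = bpp, RT = 1)
  expect_equal(db_keys(sample_mea_ensemble(pt, N = 10, seed = 4,
                                           condition_k = 0)),
               rep("((...))", 10))
  expect_equal(db_keys(sample_mea_ensemble(pt, N = 30, seed = 8)),
               db_keys(sample_mea_ensemble(pt, N = 30, seed = 8)))
  expect_error(sample_mea_ensemble(pt, N = 1, condition_k = 50),
               "infeasible")
  # unconditioned draws follow exp(sigma/RT)/Z within 3 standard errors
  sig <- vapply(all_S, mea_score, numeric(1), bpp = bpp)
  pr <- exp(sig) / sum(exp(sig))
  N <- 20000
  samp <- sample_mea_ensemble(pt, N = N, seed = 21)
  emp <- table(factor(db_keys(samp), levels = db_keys(all_S)))
  for (s in seq_along(pr)) {
    se <- sqrt(pr[s] * (1 - pr[s]) / N)
    expect_lt(abs(emp[[s]] / N - pr[s]), 3 * se + 1e-12)
  }
  # distance marginals of the sample converge to p_tilde
  h <- distance_histogram(samp, S0, K = pt$K + 1L)
  expect_lt(max(abs(h$freq[1:(pt$K + 1)] - pt$p_tilde)), 0.02)
})

test_that("conditioned sampling matches within-class probabilities", {
  seq <- toy_seq()
  bpp <- base_pair_probabilities(seq, toy_model())
  S0 <- secondary_structure(NULL, 7)
  pt <- fill_pseudo_tables(seq, S0, bpp = bpp, RT = 1)
  all_S <- enumerate_structures(seq)
  d <- vapply(all_S, base_pair_distance, integer(1), T = S0)
  sig <- vapply(all_S, mea_score, numeric(1), bpp = bpp)
  k <- 1L
  idx <- which(d == k)
  pr <- exp(sig[idx]) / sum(exp(sig[idx]))
  N <- 8000
  samp <- sample_mea_ensemble(pt, N = N, seed = 31, condition_k = k)
  expect_true(all(vapply(samp, base_pair_distance, integer(1), T = S0) == k))
  emp <- table(factor(db_keys(samp), levels = db_keys(all_S)[idx]))
  for (s in seq_along(pr)) {
    se <- sqrt(pr[s] * (1 - pr[s]) / N)
    expect_lt(abs(emp[[s]] / N - pr[s]), 3.5 * se + 1e-12)
  }
})

test_that("uniform distance distribution is N^(k)/N", {
  counts <- count_by_distance(toy_seq())
  expect_equal(uniform_distance_distribution(counts), c(1, 4, 1) / 6)
  expect_equal(sum(uniform_distance_distribution(counts)), 1)
  single <- count_by_distance(rna_sequence("AAAA"))
  expect_equal(uniform_distance_distribution(single), 1)
})
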