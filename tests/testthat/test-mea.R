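test_that("MEA score matches its closed form", {
  seq <- toy_seq()
  bpp <- base_pair_probabilities(seq, toy_model())
  pm <- rnaneighbors:::dense_bpp(bpp)
  empty <- secondary_structure(NULL, 7)
  expect_equal(mea_score(empty, bpp), sum(bpp$q))
  one <- parse_dot_bracket("(.....)")
  expect_equal(mea_score(one, bpp), 2 * pm[1, 7] + sum(bpp$q[2:6]))
  # alpha/beta scale the two terms independently
  expect_equal(mea_score(one, bpp, alpha = 2, beta = 0.5),
               4 * pm[1, 7] + 0.5 * sum(bpp$q[2:6]))
  expect_error(mea_score(one, base_pair_probabilities(rna_sequence("AAAA"))),
               "length mismatch")
})

test_that("M(i,j,k) base facts: k = 0 recovers S0, huge k infeasible", {
  seq <- toy_seq()
  bpp <- base_pair_probabilities(seq, toy_model())
  S0 <- parse_dot_bracket("((...))")
  tab <- fill_mea_tables(seq, S0, bpp = bpp, K = 2 * 7)
  expect_equal(tab$V[1, 7, 1], mea_score(S0, bpp))
  expect_equal(write_dot_bracket(mea_traceback(tab, 0)), "((...))")
  expect_false(tab$feasible[nrow(S0$pairs) + 7 + 1])
  expect_error(mea_traceback(tab, 13), "infeasible")
})

test_that("DP equals brute-force per-k optimum on seeded random sequences", {
  set.seed(303)
  for (t in 1:12) {
    seq <- random_sequence(sample(5:12, 1),
                           gc_fraction = runif(1, 0.3, 0.8),
                           seed = 1000 + t)
    bpp <- base_pair_probabilities(seq)
    all_S <- enumerate_structures(seq)
    S0 <- all_S[[sample(length(all_S), 1)]]
    tab <- fill_mea_tables(seq, S0, bpp = bpp)
    want <- oracle_mea_by_k(seq, S0, bpp, K = tab$K)
    expect_equal(is.finite(want), tab$feasible)
    expect_equal(tab$V[1, seq$n, ][tab$feasible], want[is.finite(want)],
                 tolerance = 1e-9)
    for (k in which(tab$feasible) - 1L) {
      Tk <- mea_traceback(tab, k)
      expect_equal(base_pair_distance(Tk, S0), k)
      expect_equal(mea_score(Tk, bpp), tab$V[1, seq$n, k + 1],
                   tolerance = 1e-9)
    }
    # feasible distances equal the set realized by enumeration
    d <- vapply(all_S, base_pair_distance, integer(1), T = S0)
    expect_setequal(which(tab$feasible) - 1L, sort(unique(d)))
  }
})

test_that("maximum over k equals the unconstrained MEA optimum", {
  for (t in 1:6) {
    seq <- random_sequence(10, gc_fraction = 0.6, seed = 1100 + t)
    bpp <- base_pair_probabilities(seq)
    all_S <- enumerate_structures(seq)
    best <- max(vapply(all_S, mea_score, numeric(1), bpp = bpp))
    S0 <- all_S[[(t %% length(all_S)) + 1L]]
    tab <- fill_mea_tables(seq, S0, bpp = bpp)
    expect_equal(max(tab$V[1, 10, ][tab$feasible]), best, tolerance = 1e-9)
  }
})

test_that("adding a constant to q shifts scores through unpaired counts", {
  seq <- random_sequence(9, gc_fraction = 0.7, seed = 77)
  bpp <- base_pair_probabilities(seq)
  shift <- 0.25
  bpp2 <- bpp
  bpp2$q <- bpp$q + shift
  S0 <- secondary_structure(NULL, 9)
  t1 <- fill_mea_tables(seq, S0, bpp = bpp)
  t2 <- fill_mea_tables(seq, S0, bpp = bpp2)
  for (k in which(t1$feasible) - 1L) {
    Tk <- mea_traceback(t2, k)
    unpaired <- 9 - 2 * nrow(Tk$pairs)
    expect_equal(t2$V[1, 9, k + 1] - shift * unpaired,
                 mea_score(Tk, bpp), tolerance = 1e-9)
  }
})

test_that("hard constraints prune exactly the disallowed structures", {
  seq <- random_sequence(10, gc_fraction = 0.8, seed = 55)
  bpp <- base_pair_probabilities(seq)
  all_S <- enumerate_structures(seq)
  S0 <- secondary_structure(NULL, 10)
  d <- vapply(all_S, base_pair_distance, integer(1), T = S0)
  sig <- vapply(all_S, mea_score, numeric(1), bpp = bpp)
  # force position 3 unpaired
  cstr <- "..x......."
  keep <- vapply(all_S, function(S) !(3 %in% c(S$pairs)), logical(1))
  tab <- fill_mea_tables(seq, S0, bpp = bpp, constraints = cstr)
  for (k in 0:tab$K) {
    sel <- keep & d == k
    bf <- if (any(sel)) max(sig[sel]) else -Inf
    expect_equal(is.finite(bf), tab$feasible[k + 1])
    if (is.finite(bf)) {
      expect_equal(tab$V[1, 10, k + 1], bf, tolerance = 1e-9)
      expect_false(3 %in% c(mea_traceback(tab, k)$pairs))
    }
  }
  expect_error(parse_constraints("..x...)...", seq = seq), "unbalanced")
  expect_error(parse_constraints("(.x......)", seq = rna_sequence("AAAAAAAAAA")),
               "inconsistent")
})

test_that("profile wrapper reports scores, structures and feasibility", {
  seq <- rna_sequence("AAAA")
  bpp <- base_pair_probabilities(seq)
  prof <- mea_profile(seq, bpp = bpp)
  expect_equal(prof$feasible, TRUE)
  expect_equal(prof$structure, "....")
  seq <- toy_seq()
  bpp <- base_pair_probabilities(seq, toy_model())
  prof <- mea_profile(seq, bpp = bpp)
  expect_equal(prof$k, 0:max(prof$k))
  expect_true(all(is.na(prof$structure[!prof$feasible])))
  for (r in which(prof$feasible)) {
    S <- parse_dot_bracket(prof$structure[r])
    expect_equal(mea_score(S, bpp), prof$mea_score[r], tolerance = 1e-12)
  }
})
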