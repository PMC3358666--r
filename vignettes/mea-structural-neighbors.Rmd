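---
title: "Distance-resolved maximum expected accuracy folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-resolved maximum expected accuracy folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaneighbors)
```

## The problem

Conformational switches — RNAs with two or more metastable secondary
structures, such as riboswitch expression platforms — cannot be recognized
from a single predicted structure.  A useful signal is the *distance
profile* of the thermal ensemble around a reference structure $S_0$: for
each base-pair distance $k$, how much probability mass sits on the
$k$-neighbors of $S_0$ (structures whose pair set differs from $S_0$'s in
exactly $k$ pairs), and what the best-scoring $k$-neighbor looks like.  Two
well-separated peaks in that profile suggest a bistable molecule.

`rnaneighbors` provides two complementary routes to this profile:

1. **Sampling with a rigorous accuracy bound.**  Distance-class
   probabilities $p_k = Z_k / Z$ are estimated by relative frequencies
   $f_k$ over $N$ structures drawn from the Boltzmann ensemble, with a
   closed-form minimal $N$ that guarantees
   $P(|p_k - f_k| < \varepsilon) \ge 1 - p$ *simultaneously for all*
   $k < K$.
2. **Exact dynamic programming over MEA scores.**  For every $k$ at once,
   the structure $MEA(k)$ maximizing the expected accuracy score
   $\sigma(S) = \sum_{(i,j) \in S} 2\alpha\, p_{ij} + \sum_{i\ \mathrm{unpaired}} \beta\, q_i$
   over all $k$-neighbors of $S_0$, plus a pseudo-Boltzmann partition
   function $\tilde Z_k = \sum_{d_{BP}(S, S_0) = k} e^{\sigma(S)/RT}$ over
   the same classes, with stochastic sampling from that ensemble.

## The structure model

A secondary structure is a set of pairs $(i, j)$, $1 \le i < j \le n$,
that are canonical against the sequence (AU, UA, GC, CG, GU, UG), satisfy
the hairpin threshold $j - i > \theta$ (default $\theta = 3$: at least
three unpaired bases in every hairpin loop), and contain no pseudoknots
and no base triples.  These requirements admit the classical unambiguous
decomposition — the last position of an interval is either unpaired or
paired to some $r$ — on which every recursion in the package is built.
The same decomposition drives the exhaustive enumeration oracle
(`enumerate_structures()`), which is the ground truth for all the DP code:
every distance-resolved table the package fills is tested cell-by-cell
against brute-force maxima/sums over enumerated structures at small $n$.

Base-pair distance is the cardinality of the symmetric difference of two
pair sets.  It is a metric bounded by $|S| + |T| \le 2n$.

## The sample-size bound

Treating each distance class $k < K$ as a bin with true probability
$p_k$, the frequency $f_k$ over $N$ draws is binomial with worst-case
standard deviation $\tfrac{1}{2\sqrt N}$.  Splitting the total failure
probability $p$ evenly over the $K$ bins and applying the normal
approximation gives the critical value $z = |\Phi^{-1}(p / 2K)|$ and

$$N(\varepsilon, p, K) = \frac{z^2}{4 \varepsilon^2}.$$

`required_sample_size()` rounds $z$ to two decimals before squaring and
floors the result — the convention under which the reference table values
(30276; 74256; 82082; 3027600) are reproduced digit for digit; pass
`exact = TRUE` for the unrounded ceiling instead.  The bound is
conservative (it assumes bin variance $1/4$); when an estimated bin has
$N f_k < 30$ the normal approximation itself is shaky and the package
warns.  The argument applies to *any* binning, but only the distance
histogram API is provided here.

## The distance-resolved DP

`fill_mea_tables()` computes $M(i, j, k)$: the best $\sigma$-score of any
structure on $[i, j]$ at distance exactly $k$ from the *restriction*
$S_0[i, j]$ (reference pairs with both ends inside the window).  The three
cases mirror the inductive construction, with distance offsets:

* $j$ unpaired: a reference pair ending at $j$ inside the window can no
  longer occur, offset $b_0 \in \{0, 1\}$;
* pair $(r, j)$ added: offset $0$ if $(r, j)$ is a reference pair,
  otherwise $1$ plus one for each reference pair touching $r$ or $j$
  inside $[r, j]$;
* split at $r$: reference pairs straddling the split can occur on neither
  side, offset $c(r)$, and the remaining distance is divided over the two
  halves ($k_0 + k_1$).

These offsets follow from the symmetric difference decomposing over
disjoint groups of reference pairs.  Because the prose description of the
original recursion is approximate, the package treats the *semantics* —
$M(1, n, k)$ equals the brute-force optimum over enumerated $k$-neighbors,
for every $k$, including which $k$ are feasible — as the binding contract,
and the test suite enforces it over all $4^6$ hexamers and dozens of
seeded random sequences up to length 14, with $S_0$ drawn from the
enumerated structure sets.  Cost is $O(n^3 K^2)$ time and $O(n^2 K)$
space; the implementation stores the full tables and makes no attempt at
the boustrophedon traceback acceleration.

Ties are broken deterministically: leave $j$ unpaired first, then prefer
the smallest pairing partner $r$, then the smallest left distance $k_0$.
Infeasible cells carry $-\infty$ and never contaminate a maximum.

Hard constraints (`.` free, `x` forced unpaired, matched brackets a forced
pair) are implemented by pruning cases: a forced-unpaired position cannot
become a pair endpoint, a forced-pair endpoint admits only its partner,
and splits separating a forced pair are disallowed.  Constrained tables
are tested against filtered enumeration.

## The pseudo-Boltzmann ensemble

Replacing the maximum by a sum of factors $e^{\sigma(T)/RT}$ in the same
unambiguous recursion yields $\tilde Z_{i,j}(k)$, each structure counted
exactly once; `fill_pseudo_tables()` carries all sums in log space, so
small $RT$ (large exponents) cannot overflow.  The temperature here is
purely formal — $\sigma$ is an accuracy, not an energy.  Defaults: $RT =
0.6$ (the thermal value $0.00198 \times 310$, for continuity with the
Boltzmann machinery); $RT = n$ rescales the maximal MEA score to about 1.
As $RT \to 0^+$, $RT \log \tilde Z_k \to M(1, n, k)$, which the tests
check numerically.  Whether the pseudo-Boltzmann distribution at $RT = n$
coincides with the uniform distribution $P_u(k) = N^{(k)}/N$ is reported
(both series are computable, see `uniform_distance_distribution()`), not
asserted: $\sigma$ is not constant across structures, so exact equality
has no reason to hold in general.

`sample_mea_ensemble()` draws structures with probability
$e^{\sigma(T)/RT} / \tilde Z$ by stochastic traceback (distance class
first, proportional to $\tilde Z_k$, then a structure within the class);
`condition_k` restricts draws to one class.  Each draw re-derives the
case weights from the stored tables.

## The internal energy model

The Turner nearest-neighbor model is deliberately out of scope.  The
built-in `energy_model()` is additive over pairs — GC/CG $-3$, AU/UA
$-2$, GU/UG $-1$ kcal/mol, $RT = 0.6$ — which makes every ensemble
quantity exactly enumerable and keeps the McCaskill-style inside–outside
recursions in lockstep with the structure decomposition.  This is a
*stated world*, not an approximation claim: partition function, pair
probabilities $p(i,j)$, unpaired probabilities
$q(i) = 1 - \sum_j p(i, j)$, and Ding–Lawrence-style sampling are all
computed under it and verified against enumeration to $10^{-10}$.
Realistic probabilities from an external thermodynamic folding program
can be supplied as a plain-text triplet file (`read_bpp_file()`), and
pre-sampled structure lists as dot-bracket files
(`read_structures_file()`); results under the internal model should not
be expected to match published Turner-model free energies or MEA scores.

## What the generators emulate — and what a green test shows

`random_sequence()` draws i.i.d. residues at a chosen GC content; test
sequences are short (≤ 14 nt) so that exhaustive enumeration stays exact.
Real RNAs have correlated composition, and real ensembles have stacking
energetics the additive model lacks — a green oracle-equivalence test
establishes that the DP computes exactly what it claims *under the stated
model*, for any probability input, not that predictions match experiment.
The stochastic tests (sampler calibration by chi-square at
$N = 50{,}000$, the $\varepsilon$-accuracy contract over 20 seeded
trials with an 18/20 pass requirement) have small, quantified false-alarm
rates under their fixed seeds.

## Numerical choices

* Scores use plain doubles; DP-vs-oracle comparisons at $10^{-9}$,
  inside–outside at $10^{-10}$.
* $\tilde Z$ in log space via a two-term `logaddexp`/`logsumexp`,
  $-\infty$-safe.
* Counting by distance for $n$ beyond the enumeration cap reuses the
  log-space sum engine with unit weights and rounds back to integers
  (exact far beyond any practical count).
* The enumeration oracle refuses $n > 20$ by default (configurable).
* `K` defaults to $|S_0| + \lfloor (n - \theta)/2 \rfloor$, an upper bound
  on any realizable distance; any $K \le 2n$ is accepted and unreachable
  classes are reported infeasible rather than arbitrated away.

## Worked example

```{r example}
seq <- rna_sequence("GGAAACC")
model <- energy_model(RT = 1)
bpp <- base_pair_probabilities(seq, model)
S0 <- parse_dot_bracket("((...))")
mea_profile(seq, S0, bpp = bpp)
pt <- fill_pseudo_tables(seq, S0, bpp = bpp, RT = 1)
round(pseudo_probabilities(pt), 4)
uniform_distance_distribution(count_by_distance(seq, S0))
```

## Limitations

* No pseudoknots, base triples, extended bracket alphabets, or circular
  RNAs; riboswitch aptamers often contain pseudoknots, which this
  structure class cannot express.
* The internal energy model is intentionally minimal; quantitative
  ensemble claims require externally supplied probabilities.
* Pure-R tables: comfortable to ~100 nt with moderate `K`; the
  $O(n^3 K^2)$ fill dominates.
* The sample-size bound assumes independent draws and the normal
  approximation; bins with very small $p_k$ need many samples to be seen
  at all.
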