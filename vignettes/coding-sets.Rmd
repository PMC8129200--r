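---
title: "Constructing robust DNA storage coding sets with CLGBO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing robust DNA storage coding sets with CLGBO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clgbo)
```

## The problem

DNA data storage addresses files with short synthetic oligonucleotides:
primers and address blocks that must be amplified and sequenced reliably.
Errors concentrate in predictable sequence features, which motivates four
constraints on a library of length-`n` codewords:

* **Hamming distance** `H(v, u) >= d` for every pair, limiting non-specific
  hybridisation between any two addresses;
* **GC content** near 50% (an allowed set of G+C counts, `n/2` for even
  `n`), balancing duplex stability;
* **No-runlength (NL)**: no two adjacent identical bases, since homopolymer
  runs are misread as shorter or longer runs;
* **Non-adjacent subsequence (NS)**: no immediately tandem-repeated K-mer
  for K = 2, 3 (`ACAC`, `TGATGA`, ...), since adjacent repeats promote
  polymerase slippage and sequencing misalignment.

A coding set is a collection of words that individually satisfy the
intra-word constraints and pairwise satisfy the distance constraint. The
largest constructed set size is a *lower bound* `A(n, d, w)` on what the
constraints admit; larger sets at fixed `n` raise the coding rate
`R = log4(M) / n`, so better constructions directly buy storage addressing
capacity.

Finding maximum sets is a maximum-clique problem (vertices = feasible
words, edges = pairs at distance `>= d`) and is NP-hard; this package
attacks it from two sides: an exact branch-and-bound oracle for small
instances, and a stochastic constructor driven by the CLGBO metaheuristic
for the rest.

## The optimizer

CLGBO is a gradient-based optimizer (GBO) — a population metaheuristic
whose *gradient search rule* (GSR) moves each agent using finite-difference
style steps blending the agent, the incumbent best, and random peers, and
whose *local escape operator* (LEO) is entered with probability `pr = 0.5`
to jump out of local basins — augmented with two mutation operators applied
after each agent's GBO update:

* **Cauchy mutation** `x_new = x + x * C`, with `C = tan(pi (u - 1/2))` a
  standard Cauchy deviate: heavy tails give rare long jumps (exploration);
* **Levy mutation** `x_new = x + x * L(beta)`, with `L` drawn by the
  Mantegna algorithm `phi * mu / |nu|^(1/beta)` at `beta = 1.5`: a mix of
  frequent short and rare long steps (local exploration).

Both are multiplicative, so the origin is a fixed point, and a candidate
replaces its parent only when strictly better (greedy selection); the
best-so-far fitness is therefore non-increasing, which every run records
as a convergence curve.

### Numerical design choices

Three places where the published description is open were resolved as
follows, and each alternative remains available through `clgbo_control()`:

* **Draw granularity.** The update formula indexes the mutation draw by
  individual, and we found the distinction matters: one scalar draw per
  agent rescales the whole position vector, so a converged agent can decay
  geometrically toward an origin optimum until the objective underflows to
  an exact floating-point 0 — the behaviour the benchmark tables report.
  Per-coordinate draws (`per_coordinate = TRUE`) are almost always rejected
  near convergence because some coordinate receives a huge deviate. The
  continuous-optimization default is therefore the scalar draw.
* **Mutation anchor.** Mutants are generated around the best individual
  (each still competes greedily with its own parent), concentrating search
  effort near the incumbent optimum; anchoring on each agent's own
  position (`mutation_anchor = "agent"`) converges measurably slower on
  the unimodal suite.
* **Box repair.** Out-of-box candidates are clamped to the bounds — one
  deterministic line, no resampling.

GBO internals follow the published defaults: control parameter annealed
over `beta_range = c(0.2, 1.2)`, LEO probability 0.5, random peers drawn
uniformly with replacement. A single seeded RNG stream drives the whole
run, so every result is bit-reproducible from its seed.

```{r optimizer}
fit <- clgbo("sphere", lower = rep(-100, 30), upper = rep(100, 30),
             control = clgbo_control(), seed = 1)
fit
```

At the study settings (population 50, 500 iterations) the multiplicative
mutations drive the 30-dimensional sphere to an exact 0 — not merely a
small number — via gradual underflow; the same mechanism floors Ackley at
its machine-precision origin value.

## Benchmark harness

`benchmark_suite()` lists the fourteen classical test functions used to
exercise the optimizer: six unimodal (sphere, Schwefel 2.22, Schwefel 1.2,
Rosenbrock, Schwefel 2.21, Step) and eight multimodal (Rastrigin,
Griewank, Kowalik, Ackley, two penalized functions, Schaffer, sum of
increasing powers), at dimension 30 except the inherently fixed-dimension
Kowalik (4) and Schaffer (2). The suite follows the conventional
identities; where a published table pins a function through a numerical
signature (the `8.88E-16` Ackley floor, the exactly-attainable Step and
Rastrigin zeros) those identities are fixed, and each function's
definition is visible through `benchmark_function()`. `run_experiment()`
repeats seeded runs (default 30) and reports best/average/sample-sd;
`rank_sum_compare()` wraps the two-sided Wilcoxon rank-sum test, returning
`NA` when the pooled sample is constant and the statistic undefined.

## Building coding sets

The continuous optimizer hunts codewords through a fixed decoding: a
position in `[0, 4]^n` maps per-coordinate (floor, clamped) to bases
`A, C, G, T`, so the map is constant on unit cells and surjective onto all
`4^n` words. The objective (`candidate_fitness()`) penalizes a candidate
by its GC deviation, its homopolymer and tandem-repeat counts, its
distance shortfall `max(0, d - H)` against every current member, and a
duplicate flag; it is 0 exactly when the decoded word extends the set.

`build_codeset()` appends one word per successful search and restarts
against the enlarged set. Because the decoded landscape is piecewise
constant, the builder's default control switches the mutations to
per-coordinate draws — coordinate jumps move between neighbouring cells
far more effectively than whole-position rescaling, which only explores
along a ray.

**Plateau escapes.** Pure greedy accumulation stops at a
maximal-by-inclusion set, and such sets can be far from maximum: at
`n = 4, d = 3` random greedy growth tops out at 7–9 words over many seeds
while the certified optimum is 12. The builder therefore treats
`stall_limit` consecutive failed restarts as a plateau: it snapshots the
best set seen, removes `plateau_drop = 2` random members, and regrows — a
ruin-and-recreate walk across maximal sets — stopping after `plateaus`
(default 20) escapes and returning the largest snapshot. `plateaus = 1`
recovers the plain stop-at-first-stall policy. With the defaults the
builder recovers the certified 12 at `n = 4, d = 3` in about a second and
reaches 66+ words at `n = 9, d = 5` under all four constraints in about a
minute.

```{r builder}
p <- constraint_profile(4, 3)
set <- build_codeset(p, control = clgbo_control(pop_size = 20, max_iter = 100,
                                                per_coordinate = TRUE),
                     stall_limit = 5, plateaus = 80, seed = 53)
summary(set)
```

## The exact oracle

`enumerate_feasible()` generates every feasible word (growing prefixes
with homopolymer pruning, so the NL case touches `4 * 3^(n-1)` prefixes
rather than `4^n`; guarded at `n <= 12`), and `exact_max_codeset()` runs a
bitset branch-and-bound with a greedy-coloring upper bound over the
compatibility graph. Completed searches certify the maximum — e.g. 12 at
`n = 4, d = 3` and 8 at `n = 6, d = 5` — and always dominate the
stochastic builder, which the test suite asserts wherever both run. Dense
instances (small `d` at larger `n`) are genuinely exponential; the search
then stops at `node_budget` explored nodes and returns its best clique
flagged `optimal = FALSE` rather than pretending to certify.

For odd `n` the GC window question is real: "50% GC" is not an integer
count, and this package's default window `{floor(n/2), ceiling(n/2)}`
admits more words than a single-count convention, so odd-`n` sizes here
can exceed single-`w` published tables. The window is configurable
(`gc_counts`) for users who want one count.

## Melting-temperature analysis

The point of the NS constraint is robustness, and one measurable proxy is
thermal uniformity: all members of an address library should melt at
similar temperatures so a single PCR condition serves the whole pool.
`melting_temperature()` implements the two-state nearest-neighbor model

`Tm = 1000 dH / (dS + 0.368 (n-1) ln[Na+] + R ln(C_T / x)) - 273.15`

with the unified oligonucleotide parameter table (packaged as a TSV and
swappable), terminal initiation penalties, symmetry factor `x = 4`
(1 for self-complementary words, which also receive the symmetry entropy),
`R = 1.987` cal/mol/K, and defaults of 10 nM total strand and 1 M
monovalent salt — conditions at which the entropic salt correction
vanishes. Tm is invariant under reverse complement (the duplex is the same
molecule) and strictly monotone in `ln C_T`, both asserted in the tests.
`tm_variance()` reports the population variance of a set's Tm values, and
`ns_effect()` builds paired sets with and without the NS constraint under
identical seeds and budgets to compare their variances; the bundled
`tm_reference_table()` carries the published 15-cell comparison in which
14 cells (93%) show the constraint reducing the variance.

## What the synthetic fixtures do and do not show

Tests draw random words uniformly (seeded) and plant specific violations
with `generate_fixtures()`; they exercise every constraint predicate
against independent scanning oracles, the metric axioms of the Hamming
distance, the degenerate `K = 1` equivalence of NS and NL, the A/T–G/C
relabeling symmetry, and distributional checks of the mutation operators
(Kolmogorov–Smirnov against the closed-form Cauchy CDF, the Mantegna
scale constant, tail-mass comparisons). Passing them shows the
combinatorics and the sampler are right; it does not show that real
synthesis or sequencing error rates fall — the thermodynamic model is a
two-state approximation, and no secondary-structure, reverse-complement
cross-talk, or kinetic effects are modelled (deliberately out of scope).

## Problem sizes used in the checks

The packaged checks certify the exact cells `(n=4, d=3)` and `(n=6, d=5)`
(56 and 424 feasible words), build `n = 9, d = 5` sets with all four
constraints at population 50, 500 iterations per restart, stall limit 20
and up to 5 master seeds, and run the benchmark protocol at its published
settings (30 repeats, population 50, 500 iterations, dimension 30). These
sizes were chosen as the smallest instances that pin each published
quantity.

## Known limitations

* Heuristic lower bounds are stochastic: a single seed lands a few words
  below the best published `n = 9, d = 5` size roughly half the time;
  several seeds close the gap.
* Dense clique instances (`d = 3` beyond `n = 4`) exceed any practical
  exact budget; only sparse cells are certified.
* The absolute Tm values depend on the parameter table convention; only
  table-consistent comparisons (such as the NS-vs-no-NS variance drop)
  transfer across conventions.
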