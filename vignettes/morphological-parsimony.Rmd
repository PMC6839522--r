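---
title: "Maximum-parsimony analysis of morphological matrices with maxpars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-parsimony analysis of morphological matrices with maxpars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxpars)
```

## The model and its assumptions

maxpars analyses discrete morphological character matrices under equal-weights,
unordered (Fitch) parsimony, the optimality criterion of classical cladistics.
The data are a taxa-by-characters grid of state sets: a single observed state
(digits 0–9), a polymorphic set such as `{01}`, missing (`?`), or inapplicable
(`-`). The method makes no rate or time assumptions; a tree is scored by the
minimum number of character-state changes it requires, and the preferred trees
are those of minimum total length.

Three modelling conventions matter and are fixed package-wide:

* **Polymorphism is uncertainty.** A polymorphic cell enters the downpass as
  its state set; no within-terminal step is charged. This is the default of
  the major parsimony programs and the only reading consistent with matrices
  scored that way.
* **Missing and inapplicable are computationally identical.** The distinction
  is kept in the data model (so files round-trip exactly) but `?` and `-` both
  mean "any state". Internally an empty cell is replaced by the set of states
  observed in that character — equivalent for tree length, and it keeps
  reconstruction sets from ballooning.
* **The alphabet is 0–9.** Bigger alphabets are rejected with an error; state
  sets are bit masks, so per-character work is branch-free and order-independent.

## Tree length and homoplasy indices

Lengths come from the Hartigan form of the Fitch recursion (compiled via
Rcpp): at each node, keep the states shared by the most child sets and add
`children − max-count` steps. On binary trees this is the textbook
intersection/union rule; on multifurcations it remains exact, so consensus
trees can be scored directly. The result is invariant to the arbitrary
rooting used for computation (this is a tested property).

Per character, the floor `m` is the fewest steps conceivable on any tree and
the ceiling `g` the steps on a completely unresolved bush. With polymorphism,
`m` is computed as (size of the smallest state set that intersects every
scored cell) − 1 — an exact search over the ≤ 10-state alphabet. The more
familiar "distinct observed states − 1" is equivalent on polymorphism-free
data but can exceed the attainable minimum when a state occurs only in
polymorphic cells, which would break the invariant `m ≤ s`; the hitting-set
form is the one consistent with uncertainty semantics. For `g`, polymorphic
cells are resolved in favour of the most frequent state (the standard
convention, stated so the retention index is reproducible). The ensemble
indices are `CI = ΣM/ΣS` and `RI = (ΣG−ΣS)/(ΣG−ΣM)`; both are reported with
all characters included (the convention of the usual program output), and an
informative-only variant is available via `include_uninformative = FALSE`,
since published reports rarely say which convention they used.

## Reconstructions, synapomorphies and branch collapsing

`ancestral_state_sets()` returns, per node and character, the set of states
occurring in at least one most-parsimonious reconstruction (MPR), computed
from directional state sets so the answer does not depend on the
computational rooting. Two resolution rules are provided:
ACCTRAN (Farris backtracking from the downpass sets — changes pulled toward
the root) and DELTRAN (an exact per-state cost table, keeping the parent's
state on every branch where that is still globally optimal — changes pushed
away from the root). Both are verified to be most-parsimonious on random
fixtures. A change is listed as *unambiguous* when the MPR sets of the two
branch ends are disjoint (every reconstruction changes there) and ACCTRAN
and DELTRAN agree on its endpoints; the test suite checks listed changes
against brute-force enumeration of all minimal reconstructions.

The same MPR sets drive branch collapsing: a branch whose two ends share a
state in every character has minimum length zero and carries no grouping
information. Pools of equally optimal trees are deduplicated by these
*collapsed* topologies (the "rule 1" convention), and — importantly —
consensus and rogue analysis intersect the collapsed split sets, not the
splits of the arbitrary binary representatives. Collapsing is configurable
(`collapse = FALSE` gives raw binary-topology identity) because the count of
"equally optimal trees" a study reports depends directly on this setting.

## Heuristic search

The search protocol mirrors standard practice for matrices of this size:

* `random_addition_tree()` — Wagner stepwise addition in random order, ties
  broken by the RNG (seeded, so reproducible).
* `swap_search()` — hill climbing through NNI, SPR or TBR neighborhoods,
  keeping up to `keep` equally best trees, until every retained tree has
  been swapped without improvement. TBR is implemented as bisection of every
  edge plus all reconnection pairs; correctness is defined against full
  rescoring of each neighbor (lengths are computed by the same compiled
  scorer used everywhere, so "incremental vs full" discrepancies cannot
  arise by construction).
* `replicated_search()` — many independent addition+swap rounds
  (study defaults: 1,000 rounds, TBR, 10 trees kept, 10,000-tree buffer).
* `driven_search()` — rounds repeat until the best length has been hit a
  target number of times (default 50), with a safety cap of 20 × target
  rounds.
* `expand_pool_tbr()` — the "second round of TBR on the trees in memory":
  swaps every pool member, adding new equal-length collapsed topologies to
  closure, with its own buffer since this stage can legitimately outgrow the
  search buffer.
* `exhaustive_search()` — all `(2n−5)!!` topologies for ≤ 9 taxa; the exact
  oracle used throughout the tests.

An optional parsimony ratchet (periodic upweighting of a random quarter of
the characters, off by default) adds search effort on rugged landscapes
without changing any contract.

## Supports and rogue taxa

Bremer support is computed by reverse-constrained search: for each clade,
the best length among trees lacking its bipartition, minus the optimal
length. Up to 9 taxa this is exact (enumeration); above that, constrained
searches reject any tree containing the clade (both routes are
cross-checked on small instances). The bootstrap resamples characters with
replacement to the original count, reruns a reduced-effort search per
pseudoreplicate (default 10 additions, TBR, keep 10 — configurable), and
reports TNT-style *absolute frequencies*: the percentage of pseudoreplicate
strict consensuses containing the clade. The pseudoreplicate count defaults
to 1,000, a community standard, because protocols rarely state it;
percentages at that size carry a Monte-Carlo band of roughly ±3 points.
`taxon_deletion_experiment()` reruns the bootstrap after deleting named
taxa, the usual probe for support suppressed by poorly preserved material.

Rogue detection is greedy: prune the single taxon (then pairs) whose removal
most increases the number of internal edges of the strict consensus,
stopping when no removal helps or the budget (default 2) is spent. The full
exponential subset search is deliberately out of scope. For each pruned
taxon the distinct attachment positions across the pool are reported — the
"a / b" alternative-position annotations of reduced consensus figures.

## The synthetic-data generator

`simulate_matrix()` exists so that every stage can be validated without any
third-party data. Its defaults emulate the structure of a large
fossil-crocodylian matrix: 114 taxa by 202 characters, 3 states per
character, per-taxon missing fractions drawn from 0.1–0.7 (so the most
incomplete rows are scorable for roughly a third of characters, like a
fragmentary fossil), 1% polymorphic cells, and Poisson-distributed change
counts per character placed on branches proportionally to length
(`expected_changes = 8`). The change-count model was chosen over a
continuous-time rate matrix because it gives direct control of homoplasy,
which is what the tests need. The homoplasy dial was calibrated once:
λ = 8 puts the ensemble CI of a good tree near 0.31 and RI near 0.76 on
study-sized simulations, the regime of real matrices of this size; it was
fixed before the acceptance tests were written and not revisited.
`change_model = "one"` gives every character exactly one change — a
homoplasy-free dataset on which the generating tree provably attains
`s = m` for every character (asserted in the tests), the anchor for the
CI = RI = 1 calibration.

Missing data are imposed per taxon: a fraction is drawn uniformly from the
configured range and `floor(fraction × n_char)` cells are blanked. The
floor convention is what makes a 0.42 fraction on 202 characters leave 118
scored cells — the completeness of the type fossil the generator emulates.

What the simulations do *not* emulate: correlated characters and
morphological integration, ascertainment ("variable characters only")
bias, among-character rate structure beyond the Poisson spread, and any
generative model of polymorphism (it is injected post hoc as an adjacent
state). Passing the recovery and calibration tests therefore shows the
pipeline is correct and well-calibrated on clean generative data, not that
real matrices of this difficulty will resolve equally well.

## Validation harness and problem sizes

`recovery_experiment()` runs simulate → search → strict consensus and
scores Robinson-Foulds distance to the generating tree, counting resolved
bipartitions only (a consensus polytopy shows up as missing splits). Under
the homoplasy-free model at 12 taxa × 100 characters, each of the 9
internal edges is missed by all characters with probability
(20/21)^100 ≈ 0.8%, so full recovery is expected in about 93% of runs; the
acceptance band (≥ 18 of 20 runs) follows from that arithmetic. Under
Poisson(1) changes, exact ties among MPTs are common enough that the strict
consensus legitimately loses edges in a third or more of runs — that regime
is exercised by looser module tests, and is worth remembering when reading
published consensus trees.

The test and acceptance problem sizes — 200 brute-force Fitch fixtures at
≤ 6 taxa, 100 driven-vs-exhaustive searches at 7–8 taxa, 20 Bremer
enumerations at 6 taxa, 200 bootstrap pseudoreplicates on calibration
matrices, 20 recovery runs at 12 × 100, and best-of-five Wagner trees with
NNI polish for the study-scale synthetic summary — were chosen so the whole
suite completes in minutes on one CPU while every heuristic is still checked
against an exact oracle at a size where the oracle is feasible. Full TBR on
a 114-taxon matrix is supported but is an hours-scale computation, as it is
in any scripting-language reimplementation; the ratchet option is the
recommended accelerant there.

## Numerical and degenerate-input choices

* Stepwise-addition and swap ties are broken by the seeded RNG; identical
  seed and configuration give byte-identical outputs (tested end to end).
* A character with no observations (or all-missing after deletion) gets
  `m = g = 0`, contributes 0 steps, and is flagged uninformative.
* `RI` is undefined when `ΣG = ΣM` (e.g. a matrix of autapomorphies); it is
  returned as `NA` with a warning rather than a silent 0/0.
* `CI` is defined as 1 when `ΣS = 0` (no variation at all).
* Trees with fewer than 3 taxa are rejected by the search; exhaustive
  enumeration refuses > 9 taxa ((2n−5)!! growth).
* Buffers (`max_trees`, expansion cap, driven-search round cap) warn and
  return partial results rather than failing.

## Known limitations

Sankoff (step-matrix) parsimony, implied weighting, and likelihood/Bayesian
inference are out of scope, as are TNT's sectorial/fusing "new technology"
searches. Ordered characters exist only as a metadata flag; analysis treats
everything unordered, matching the study configuration this package
reproduces. The rogue search is greedy and can in principle miss a jointly
rogue pair whose single deletions gain nothing — the pair stage mitigates
but does not eliminate this. Bremer values from the constrained heuristic
route are upper-bound estimates above 9 taxa, as in all heuristic decay
analyses.
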