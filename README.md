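# maxpars

Maximum-parsimony cladistics for discrete morphological character matrices,
in R. The package implements, end to end, the analysis pipeline used to
build phylogenies of fossil-rich groups (its test bed is the scale of a
modern crocodylian matrix: ~114 taxa scored for ~202 unordered characters
with heavy, uneven missing data): reading and writing NEXUS and TNT
(`xread`) matrices, Fitch parsimony scoring, replicated and hit-driven
heuristic tree searches with TBR branch swapping, strict and reduced
(rogue-pruned) consensus trees, Bremer decay and absolute-frequency
bootstrap supports, ancestral-state and synapomorphy mapping, and a seeded
simulator of morphological matrices so that every stage can be validated
against known truth.

## The method

For an unordered character `c` with leaf state sets given by the matrix
(polymorphic cells contribute their whole set; `?` and `-` are free), the
number of steps `s_c` on a tree is the minimum number of state changes over
all assignments of states to internal nodes. It is computed by the
Fitch/Hartigan set recursion (in C++ via Rcpp): at each node, keep the
states occurring in the largest number of child sets, adding
`(children − max count)` steps; on binary trees this is the familiar
intersection/union rule. Tree length is `S = Σ_c w_c s_c` with all
weights 1 here. Each character also has a floor `m_c` (fewest steps on any
tree) and ceiling `g_c` (steps on a completely unresolved bush), giving the
ensemble homoplasy indices

    CI = ΣM / ΣS        RI = (ΣG − ΣS) / (ΣG − ΣM)

A most parsimonious tree (MPT) is found heuristically: random-addition
Wagner trees, TBR hill climbing keeping up to `k` equally best trees,
replicated searches, hit-driven stopping ("repeat until the best length has
been found 50 times"), and a second TBR round that closes the pool of
equally optimal trees. Equally optimal topologies are identified after
collapsing branches whose minimum length over all reconstructions is zero.
Clade support is quantified by the Bremer decay index (extra steps of the
best tree lacking the clade, by reverse-constrained search) and by the
absolute-frequency bootstrap (percentage of character-resampled
pseudoreplicate analyses whose strict consensus contains the clade),
including taxon-deletion experiments. An exhaustive-search oracle
(all `(2n−5)!!` topologies, up to 9 taxa) backs every heuristic with an
exact reference.

## Worked example

Simulate a small fossil-style matrix with known truth, run the full
protocol, and read the report:

```r
library(maxpars)
set.seed(7)
sim <- simulate_matrix(simulation_config(n_taxa = 10, n_char = 40,
  expected_changes = 2, missing_range = c(0, 0.3),
  polymorphism_prob = 0.02, rng_seed = 7))
cfg <- protocol_config(
  search = search_config(n_replications = 10, trees_saved_per_rep = 5,
                         target_hits = 10),
  bootstrap_reps = 200,
  bootstrap_config = search_config(n_replications = 3,
                                   trees_saved_per_rep = 3, target_hits = 3),
  bremer_config = search_config(n_replications = 5, trees_saved_per_rep = 3,
                                target_hits = 5),
  seed = 7)
bundle <- run_protocol(sim$matrix, cfg)
report(bundle)
```

which prints (abridged):

```
- matrix: 10 taxa x 40 characters
- best tree length: 56 steps
- equally parsimonious trees retained: 5
- ensemble CI: 0.821, RI: 0.667
- pruned rogue taxa: none

## Clade supports

| clade | Bremer | bootstrap % |
|---|---|---|
| t10+t3 | 2 | 83.0 |
| t10+t3+t5+t6+t9 | 1 | 33.5 |
| t5+t6+t9 | 2 | 76.5 |
| t6+t9 | 1 | 44.5 |
```

The best length is 56 steps over 40 characters, with five equally
parsimonious (collapsed) topologies; CI 0.821 says roughly one character in
five changes more than once on the tree. The strongly supported cherries
(`t10+t3`, `t5+t6+t9`) decay at 2 extra steps and appear in 77–83% of
bootstrap pseudoreplicates, while the weakly supported deeper clade would
vanish with a single extra step. With this much simulated noise and
missing data the strict consensus resolves only part of the generating
tree (`rf_distance(bundle$consensus, sim$tree)` is 7 here) — exactly the
behaviour the rogue-pruning and support machinery exists to diagnose.
Everything in the report is recomputable from the result bundle
(`bundle$pool`, `bundle$supports`, `bundle$synapomorphies`, ...), and
`run_protocol(..., out_dir = "out/")` writes the trees (Newick), support
and character-fit tables (TSV) and a JSON run manifest.

A thin command-line wrapper for shell use ships in
`inst/scripts/mp.R` (`mp.R summary|run|simulate ...`).

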