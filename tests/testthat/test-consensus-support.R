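test_that("strict consensus retains exactly the shared bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  # identical trees -> the tree itself
  cons_same <- strict_consensus(list(t1, t1, t1))
  expect_equal(rf_distance(cons_same, t1), 0L)
  # two trees sharing only {A,B}
  t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
  cons <- strict_consensus(list(t1, t2))
  ut <- maxpars:::as_utree(cons)
  taxa <- sort(ut$tip_label)
  keys <- maxpars:::utree_splits(ut, taxa)
  expect_length(keys, 1L)
  side <- taxa[maxpars:::split_key_tips(keys)]
  smaller <- if (length(side) <= length(taxa) / 2) side else
    setdiff(taxa, side)
  expect_equal(sort(smaller), c("A", "B"))
  # all 15 topologies on 5 taxa -> star
  m <- rand_matrix(5, 1)
  all5 <- all_topologies_phylo(m)
  star <- strict_consensus(all5)
  expect_equal(ape::Nnode(star), 1L)
})

test_that("strict consensus is idempotent, order-invariant and matches ape", {
  skip_if_not_installed("ape")
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(6:8, 1)
    trees <- lapply(1:4, function(i)
      maxpars:::as_phylo(maxpars:::random_topology(paste0("t", 1:n))))
    cons <- strict_consensus(trees)
    expect_equal(rf_distance(strict_consensus(rev(trees)), cons), 0L)
    expect_equal(rf_distance(strict_consensus(list(cons)), cons), 0L)
    ac <- ape::consensus(lapply(trees, ape::unroot), p = 1)
    expect_equal(rf_distance(cons, ac), 0L)
  }
})

test_that("majority-rule consensus keeps splits above the threshold", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
  t3 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  mc <- majority_consensus(list(t1, t2, t3))
  ut <- maxpars:::as_utree(mc)
  keys <- maxpars:::utree_splits(ut, sort(ut$tip_label))
  expect_length(keys, 2L)  # {A,B} in 3/3 and {D,E} in 2/3
  strict <- strict_consensus(list(t1, t2, t3))
  sut <- maxpars:::as_utree(strict)
  expect_length(maxpars:::utree_splits(sut, sort(sut$tip_label)), 1L)
})

test_that("rf_distance agrees with phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (rep in 1:10) {
    a <- maxpars:::as_phylo(maxpars:::random_topology(paste0("t", 1:8)))
    b <- maxpars:::as_phylo(maxpars:::random_topology(paste0("t", 1:8)))
    expect_equal(rf_distance(a, b), as.integer(phangorn::RF.dist(a, b)))
  }
})

# a pool in which one taxon wanders over the pendant edges of k taxa spread
# across a fixed backbone (its instability destroys the consensus backbone
# until it is pruned)
wandering_pool <- function(hosts = c("A", "C", "E")) {
  backbone <- ape::read.tree(text = "((A,B),(C,D),(E,(F,G)));")
  ub <- maxpars:::as_utree(backbone)
  lapply(hosts, function(h) {
    tip <- match(h, ub$tip_label)
    e <- which(ub$edge[, 1] == tip | ub$edge[, 2] == tip)[1]
    maxpars:::as_phylo(maxpars:::utree_insert_tip(ub, e, "Rogue"))
  })
}

test_that("rogue pruning finds a grafted taxon and its attachment positions", {
  trees <- wandering_pool(c("A", "C", "E"))
  rr <- rogue_prune(trees, max_prune = 2)
  expect_equal(rr$pruned$taxon, "Rogue")
  expect_equal(rr$pruned$n_positions, 3L)
  expect_length(rr$pruned$positions[[1]], 3L)
  # the reduced consensus is the fully resolved backbone
  expect_equal(ape::Ntip(rr$reduced_consensus), 7L)
  expect_equal(ape::Nnode(rr$reduced_consensus), 5L)
  # a pool of identical trees prunes nothing
  same <- wandering_pool("A")
  rr0 <- rogue_prune(list(same[[1]], same[[1]]))
  expect_equal(nrow(rr0$pruned), 0L)
})

test_that("pruning never decreases consensus resolution", {
  set.seed(14)
  for (rep in 1:5) {
    trees <- lapply(1:3, function(i)
      maxpars:::as_phylo(maxpars:::random_topology(paste0("t", 1:8))))
    inp <- maxpars:::as_utree_list(trees)
    before <- length(Reduce(intersect, inp$sets))
    rr <- rogue_prune(trees, max_prune = 2)
    after <- ape::Nnode(rr$reduced_consensus) - 1L  # internal edges
    expect_gte(after, before)
  }
})

test_that("Bremer values match enumeration over all 105 six-taxon topologies", {
  set.seed(15)
  m <- rand_matrix(6, 12, k = 3, missing_p = 0.1)
  ex <- exhaustive_search(m)
  tab <- bremer_support(m, ex)
  # independent oracle: scan all topologies, tracking the best length with
  # and without each consensus clade
  topo <- all_topologies_phylo(m)
  lens <- vapply(topo, brute_tree_length, numeric(1), matrix = m)
  for (i in seq_len(nrow(tab))) {
    tips <- strsplit(tab$tips[i], ",")[[1]]
    key <- maxpars:::canonical_split(match(tips, m$taxa), 6L)
    lacking <- vapply(topo, function(tr) {
      ut <- maxpars:::utree_standardize(maxpars:::as_utree(tr, m$taxa),
                                        m$taxa)
      !key %in% maxpars:::utree_splits(ut, m$taxa)
    }, logical(1))
    expect_equal(tab$bremer[i], min(lens[lacking]) - ex$best_length)
  }
  # a clade absent from the strict consensus has Bremer 0
  absent <- setdiff(
    unique(unlist(lapply(topo[which(lens == min(lens))], function(tr) {
      ut <- maxpars:::utree_standardize(maxpars:::as_utree(tr, m$taxa), m$taxa)
      maxpars:::utree_splits(ut, m$taxa)
    }))),
    maxpars:::common_split_keys(ex))
  if (length(absent)) {
    cl <- list(m$taxa[maxpars:::split_key_tips(absent[1])])
    expect_equal(bremer_support(m, ex, cl)$bremer, 0)
  }
})

test_that("every strict-consensus clade of the optimal pool has Bremer >= 1", {
  set.seed(16)
  m <- rand_matrix(7, 14, k = 3)
  ex <- exhaustive_search(m)
  tab <- bremer_support(m, ex)
  if (nrow(tab)) expect_true(all(tab$bremer >= 1))
})

test_that("bootstrap calibration: clean signal high, zero signal low", {
  set.seed(17)
  cfg <- search_config(n_replications = 2, trees_saved_per_rep = 2,
                       target_hits = 2)
  clean <- clade_signal_matrix(8, 1:4, n_clean = 12)
  bs <- bootstrap_support(clean, list(paste0("t", 1:4)),
                          n_pseudoreplicates = 40, replicate_config = cfg)
  expect_gte(bs$bootstrap_pct, 95)
  none <- autapomorphy_matrix(8, 16)
  bs0 <- bootstrap_support(none, list(paste0("t", 1:4)),
                           n_pseudoreplicates = 20, replicate_config = cfg)
  expect_lte(bs0$bootstrap_pct, 5)
})

test_that("bootstrap is reproducible under a seed and honors taxon deletion", {
  set.seed(18)
  m <- rand_matrix(7, 15, k = 2, missing_p = 0.1)
  cfg <- search_config(n_replications = 2, trees_saved_per_rep = 2,
                       target_hits = 2)
  b1 <- bootstrap_support(m, list(c("t1", "t2")), 10, cfg, rng_seed = 7)
  b2 <- bootstrap_support(m, list(c("t1", "t2")), 10, cfg, rng_seed = 7)
  expect_identical(b1$bootstrap_pct, b2$bootstrap_pct)
  # empty deletion set is the identity experiment
  d0 <- taxon_deletion_experiment(m, character(0), list(c("t1", "t2")),
                                  n_pseudoreplicates = 10,
                                  replicate_config = cfg, rng_seed = 7)
  expect_identical(d0$bootstrap_pct, b1$bootstrap_pct)
  # dropping a taxon re-keys the clades to the reduced matrix
  d1 <- taxon_deletion_experiment(m, "t7", list(c("t1", "t2")),
                                  n_pseudoreplicates = 5,
                                  replicate_config = cfg, rng_seed = 7)
  expect_equal(attr(d1, "dropped_taxa"), "t7")
  expect_error(taxon_deletion_experiment(m, "t1", list(c("t1", "t2")),
                                         n_pseudoreplicates = 5,
                                         replicate_config = cfg),
               "fewer than 2")
})
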