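test_that("topology enumeration has the (2n-5)!! counts", {
  expect_length(maxpars:::enumerate_topologies(4), 3L)
  expect_length(maxpars:::enumerate_topologies(5), 15L)
  expect_length(maxpars:::enumerate_topologies(6), 105L)
  # all distinct
  m <- rand_matrix(5, 1)
  keys <- vapply(maxpars:::enumerate_topologies(5), function(ed)
    maxpars:::utree_key(maxpars:::utree(ed, 5L, m$taxa), m$taxa),
    character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("NNI neighborhoods have size 2(n-3) and TBR includes them", {
  set.seed(1)
  for (n in c(5, 7)) {
    ut <- maxpars:::random_topology(paste0("t", 1:n))
    nni <- maxpars:::utree_neighborhood(ut, "nni")
    expect_length(nni, 2L * (n - 3L))
    taxa <- sort(ut$tip_label)
    nni_keys <- vapply(nni, maxpars:::utree_key, character(1),
                       ref_taxa = taxa)
    tbr_keys <- vapply(maxpars:::utree_neighborhood(ut, "tbr"),
                       maxpars:::utree_key, character(1), ref_taxa = taxa)
    spr_keys <- vapply(maxpars:::utree_neighborhood(ut, "spr"),
                       maxpars:::utree_key, character(1), ref_taxa = taxa)
    expect_true(all(nni_keys %in% tbr_keys))
    expect_true(all(spr_keys %in% tbr_keys))
    # every neighbor is a valid binary topology on the same tips
    for (nb in sample(nni, 3)) {
      expect_equal(nrow(nb$edge), 2L * n - 3L)
      expect_equal(sort(unique(as.integer(nb$edge))), seq_len(2L * n - 2L))
    }
  }
})

test_that("random addition returns the unique 3-taxon topology and finds known optima", {
  m3 <- rand_matrix(3, 4)
  tr3 <- random_addition_tree(m3)
  expect_equal(ape::Ntip(tr3), 3L)
  # homoplasy-free 6-taxon data: the addition tree attains the true length
  set.seed(3)
  sim <- simulate_characters(simulate_tree(6), n_char = 30,
                             change_model = "one", k_states = 2)
  truth <- fitch_length(sim$tree, sim$matrix)$total
  at <- random_addition_tree(sim$matrix)
  expect_equal(fitch_length(at, sim$matrix)$total, truth)
})

test_that("swap search keeps the optimum as a fixed point and never stores worse trees", {
  set.seed(4)
  m <- rand_matrix(7, 12, k = 3)
  ex <- exhaustive_search(m)
  best_tree <- pool_trees(ex)[[1]]
  pool <- swap_search(best_tree, m, keep = 10)
  expect_equal(pool$best_length, ex$best_length)
  rescored <- vapply(pool$trees, function(ut)
    fitch_length(maxpars:::as_phylo(ut), m)$total, numeric(1))
  expect_true(all(rescored == pool$best_length))
})

test_that("replicated and driven searches hit the exhaustive optimum on small matrices", {
  set.seed(5)
  for (rep in 1:5) {
    m <- rand_matrix(6, 10, k = 3, missing_p = 0.1)
    ex <- exhaustive_search(m)
    pool <- replicated_search(m, search_config(n_replications = 5,
                                               trees_saved_per_rep = 5,
                                               target_hits = 5))
    expect_equal(pool$best_length, ex$best_length)
    expect_length(pool$diagnostics$rep_best, 5L)
    # monotonicity: the merged pool is at the minimum of replicate bests
    expect_equal(pool$best_length, min(pool$diagnostics$rep_best))
  }
  m <- rand_matrix(7, 10, k = 3)
  ex <- exhaustive_search(m)
  dv <- driven_search(m, search_config(trees_saved_per_rep = 5,
                                       target_hits = 3))
  expect_equal(dv$best_length, ex$best_length)
  expect_gte(dv$diagnostics$hits, 3L)
})

test_that("driven search with target_hits = 1 is a single completed round", {
  set.seed(6)
  m <- rand_matrix(6, 8, k = 2)
  dv <- driven_search(m, search_config(trees_saved_per_rep = 3,
                                       target_hits = 1))
  expect_equal(dv$diagnostics$hits, 1L)
  expect_length(dv$diagnostics$rep_best, 1L)
})

test_that("identical seeds give identical pools", {
  m <- rand_matrix(7, 10, k = 3)
  cfg <- search_config(n_replications = 3, trees_saved_per_rep = 5,
                       target_hits = 3, rng_seed = 99L)
  p1 <- replicated_search(m, cfg)
  p2 <- replicated_search(m, cfg)
  expect_identical(p1$best_length, p2$best_length)
  expect_identical(sort(p1$keys), sort(p2$keys))
})

test_that("pool expansion reaches closure and recovers all tied optima", {
  set.seed(7)
  for (rep in 1:5) {
    m <- rand_matrix(7, 8, k = 2, missing_p = 0.2)
    ex <- exhaustive_search(m)          # the complete set of optima
    one <- new_pool <- swap_search(pool_trees(ex)[[1]], m, keep = 1)
    expanded <- expand_pool_tbr(one, m)
    expect_setequal(expanded$keys, ex$keys)
    # idempotence: a TBR-closed pool does not grow
    again <- expand_pool_tbr(expanded, m)
    expect_setequal(again$keys, expanded$keys)
  }
})

test_that("exhaustive search scores every topology and flags big inputs", {
  m <- rand_matrix(4, 5, k = 2)
  ex <- exhaustive_search(m)
  expect_equal(ex$diagnostics$n_topologies, 3L)
  # 3 taxa: single topology with length = sum of per-character minima
  m3 <- rand_matrix(3, 6, k = 3)
  ex3 <- exhaustive_search(m3)
  expect_equal(ex3$best_length, sum(character_bounds(m3)$m))
  big <- rand_matrix(10, 4)
  expect_error(exhaustive_search(big), "9 taxa")
})

test_that("the ratchet option keeps contracts while adding effort", {
  set.seed(8)
  m <- rand_matrix(8, 15, k = 3, missing_p = 0.2)
  ex <- exhaustive_search(m)
  pr <- replicated_search(m, search_config(n_replications = 2,
                                           trees_saved_per_rep = 5,
                                           target_hits = 5, ratchet = TRUE,
                                           ratchet_iterations = 2))
  expect_equal(pr$best_length, ex$best_length)
  rescored <- vapply(pr$trees, function(ut)
    fitch_length(maxpars:::as_phylo(ut), m)$total, numeric(1))
  expect_true(all(rescored == pr$best_length))
})
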