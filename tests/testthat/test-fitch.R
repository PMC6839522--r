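test_that("textbook four-taxon lengths are recovered", {
  m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  expect_equal(fitch_length(ape::read.tree(text = "((A,B),(C,D));"), m)$total, 1)
  expect_equal(fitch_length(ape::read.tree(text = "((A,C),(B,D));"), m)$total, 2)
  const <- char_matrix(rbind(A = "1", B = "1", C = "1", D = "1"))
  expect_equal(fitch_length(ape::read.tree(text = "((A,B),(C,D));"), const)$total, 0)
})

test_that("fitch_length matches brute-force enumeration on random fixtures", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(4:6, 1)
    m <- rand_matrix(n, sample(3:8, 1), k = sample(2:4, 1),
                     missing_p = 0.15, poly_p = 0.1)
    tr <- maxpars:::as_phylo(maxpars:::random_topology(m$taxa))
    expect_equal(fitch_length(tr, m)$total, brute_tree_length(tr, m),
                 info = paste("rep", rep))
  }
})

test_that("length is invariant to rooting and to all-missing taxa", {
  set.seed(11)
  m <- rand_matrix(6, 10, k = 3, missing_p = 0.2)
  tr <- maxpars:::as_phylo(maxpars:::random_topology(m$taxa))
  base <- fitch_length(tr, m)$steps
  for (og in m$taxa[1:4]) {
    rooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(fitch_length(rooted, m)$steps, base)
  }
  # append a taxon scored for nothing: no per-character step may change
  m2 <- char_matrix(rbind(m$states, 0L), taxa = c(m$taxa, "ghost"))
  tr2 <- ape::read.tree(text = sub(";", ",ghost);",
                                   sub("^\\(", "((", ape::write.tree(tr))))
  expect_equal(fitch_length(tr2, m2)$steps, base)
})

test_that("fitch_length agrees with phangorn on polymorphism-free data", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  m <- rand_matrix(8, 20, k = 3, missing_p = 0.2)
  f <- tempfile(fileext = ".nex")
  write_nexus(m, f)
  dat <- phangorn::phyDat(do.call(rbind, ape::read.nexus.data(f)),
                          type = "USER", levels = as.character(0:2),
                          ambiguity = "?")
  for (rep in 1:5) {
    tr <- maxpars:::as_phylo(maxpars:::random_topology(m$taxa))
    tr$tip.label <- gsub(" ", "_", tr$tip.label)
    expect_equal(fitch_length(tr, m)$total,
                 as.numeric(phangorn::parsimony(tr, dat, method = "fitch")))
  }
})

test_that("character bounds follow the m/g conventions", {
  # observed state counts {0:3, 1:2, 2:1} over 6 scored taxa -> m=2, g=3
  m <- char_matrix(matrix(c("0", "0", "0", "1", "1", "2"), ncol = 1),
                   taxa = paste0("t", 1:6))
  b <- character_bounds(m)
  expect_equal(b$m, 2L)
  expect_equal(b$g, 3L)
  # invariant character
  b2 <- character_bounds(char_matrix(matrix("1", 4, 1),
                                     taxa = paste0("t", 1:4)))
  expect_equal(c(b2$m, b2$g), c(0L, 0L))
  # two scored taxa, states 0 and 1: m = g = 1, uninformative
  m3 <- char_matrix(matrix(c("0", "1", "?", "?"), ncol = 1),
                    taxa = paste0("t", 1:4))
  b3 <- character_bounds(m3)
  expect_equal(c(b3$m, b3$g), c(1L, 1L))
  expect_false(b3$informative)
  # a state present only in a polymorphic cell is not forced to appear
  m4 <- char_matrix(matrix(c("0", "0", "0", "{01}"), ncol = 1),
                    taxa = paste0("t", 1:4))
  expect_equal(character_bounds(m4)$m, 0L)
})

test_that("m <= s <= g on random fixtures with missing and polymorphism", {
  set.seed(41)
  for (rep in 1:30) {
    m <- rand_matrix(sample(4:8, 1), sample(4:12, 1), k = sample(2:4, 1),
                     missing_p = 0.25, poly_p = 0.1)
    tr <- maxpars:::as_phylo(maxpars:::random_topology(m$taxa))
    s <- fitch_length(tr, m)$steps
    b <- character_bounds(m)
    expect_true(all(b$m <= s), info = paste("rep", rep))
    expect_true(all(s <= b$g), info = paste("rep", rep))
  }
})

test_that("ensemble CI/RI match exhaustive hand computation on 5 taxa", {
  set.seed(51)
  m <- rand_matrix(5, 8, k = 3, missing_p = 0.1)
  trees <- all_topologies_phylo(m)
  expect_length(trees, 15L)
  lens <- vapply(trees, function(tr) brute_tree_length(tr, m), numeric(1))
  best <- trees[[which.min(lens)]]
  ens <- ensemble_fit(best, m)
  b <- character_bounds(m)
  s_or <- vapply(seq_len(ncol(m$states)), function(j)
    brute_char_length(maxpars:::utree_standardize(
      maxpars:::as_utree(best, m$taxa), m$taxa)$edge, 5L,
      oracle_leaf_sets(m, j), 3L), numeric(1))
  expect_equal(ens$ci, sum(b$m) / sum(s_or))
  expect_equal(ens$ri, (sum(b$g) - sum(s_or)) / (sum(b$g) - sum(b$m)))
})

test_that("ensemble indices agree with phangorn's CI and RI", {
  skip_if_not_installed("phangorn")
  set.seed(61)
  m <- rand_matrix(7, 15, k = 3)
  f <- tempfile(fileext = ".nex")
  write_nexus(m, f)
  dat <- phangorn::phyDat(do.call(rbind, ape::read.nexus.data(f)),
                          type = "USER", levels = as.character(0:2),
                          ambiguity = "?")
  tr <- maxpars:::as_phylo(maxpars:::random_topology(m$taxa))
  ens <- ensemble_fit(tr, m)
  expect_equal(ens$ci, phangorn::CI(tr, dat), tolerance = 1e-9)
  expect_equal(ens$ri, phangorn::RI(tr, dat), tolerance = 1e-9)
})

test_that("homoplasy-free data give CI = RI = 1 on the generating tree", {
  set.seed(71)
  sim <- simulate_characters(simulate_tree(10), n_char = 40,
                             change_model = "one", k_states = 2)
  ens <- ensemble_fit(sim$tree, sim$matrix)
  expect_identical(ens$ci, 1)
  expect_identical(ens$ri, 1)
})

test_that("ancestral MPR sets match enumeration of minimal reconstructions", {
  # invariant character: every node set is that state
  m0 <- char_matrix(matrix("2", 4, 1), taxa = c("A", "B", "C", "D"))
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  a0 <- ancestral_state_sets(tr, m0)
  expect_true(all(a0$states == "2"))
  # classic 0,0,1,1: internal nodes {0} and {1}
  m1 <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  a1 <- ancestral_state_sets(tr, m1)
  internal <- a1[is.na(a1$taxon), ]
  expect_setequal(internal$states, c("0", "1"))
  # random fixtures against the brute-force MPR oracle
  set.seed(81)
  for (rep in 1:10) {
    m <- rand_matrix(5, 3, k = 3, missing_p = 0.1, poly_p = 0.1)
    tr <- maxpars:::as_phylo(maxpars:::random_topology(m$taxa))
    anc <- ancestral_state_sets(tr, m)
    for (j in seq_len(3)) {
      oracle <- brute_mpr_sets(tr, m, j, k = 3L)
      got <- anc[anc$character == j & is.na(anc$taxon), ]
      for (key in names(oracle)) {
        row <- got[got$clade == key, ]
        if (nrow(row) == 0L) next  # computational root is one of the nodes
        expect_equal(sort(as.integer(strsplit(row$states, "")[[1]])),
                     oracle[[key]],
                     info = paste("rep", rep, "char", j, "node", key))
      }
    }
  }
})

test_that("synapomorphy mapping separates unambiguous from ACCTRAN-only changes", {
  # one clean change on the internal branch
  m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  syn <- map_synapomorphies(tr, m)
  expect_equal(nrow(syn), 1L)
  expect_true(syn$unambiguous)
  expect_equal(sort(c(syn$from, syn$to)), c(0L, 1L))
  # ambiguous single change: 0,0,1 on a triplet-like quartet
  m2 <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "?"))
  acc <- map_synapomorphies(tr, m2, mode = "acctran")
  un <- map_synapomorphies(tr, m2, mode = "unambiguous")
  expect_gte(nrow(acc), 1L)
  expect_equal(nrow(un), 0L)
  # oracle: a change listed as unambiguous on an internal branch must be
  # present in every minimal reconstruction (enumerated by brute force)
  set.seed(91)
  checked <- 0L
  for (rep in 1:15) {
    m3 <- rand_matrix(6, 6, k = 3, missing_p = 0.2)
    tr3 <- maxpars:::as_phylo(maxpars:::random_topology(m3$taxa))
    fit <- fitch_length(tr3, m3)
    un3 <- map_synapomorphies(fit, m3, mode = "unambiguous")
    un3 <- un3[un3$node > 6L, ]
    if (!nrow(un3)) next
    for (i in seq_len(nrow(un3))) {
      v <- un3$node[i]; j <- un3$character[i]
      sets <- brute_mpr_sets(tr3, m3, j, k = 3L)
      below <- maxpars:::node_tipsets(fit$tree)
      key_v <- paste(sort(fit$tree$tip_label[below[[v]]]), collapse = ",")
      u <- fit$parent[v]
      key_u <- paste(sort(fit$tree$tip_label[below[[u]]]), collapse = ",")
      if (is.null(sets[[key_v]]) || is.null(sets[[key_u]])) next
      expect_length(intersect(sets[[key_v]], sets[[key_u]]), 0L)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("ACCTRAN and DELTRAN resolutions are most-parsimonious", {
  set.seed(93)
  for (rep in 1:20) {
    m <- rand_matrix(sample(5:7, 1), 8, k = 3, missing_p = 0.2, poly_p = 0.05)
    tr <- maxpars:::as_phylo(maxpars:::random_topology(m$taxa))
    fit <- fitch_length(tr, m)
    ori <- maxpars:::utree_orient(fit$tree)
    resolutions <- list(
      acctran = maxpars:::resolve_assignment(fit$down, ori$parent, ori$order),
      deltran = maxpars:::resolve_deltran(fit, ori))
    for (s in resolutions) {
      changes <- 0L
      for (v in seq_len(nrow(s))) {
        if (ori$parent[v] == 0L) next
        changes <- changes + sum(s[v, ] != s[ori$parent[v], ])
      }
      expect_equal(changes, sum(fit$steps), info = paste("rep", rep))
    }
  }
})

test_that("tidy and glance expose per-character and ensemble fit", {
  set.seed(95)
  m <- rand_matrix(6, 12, k = 3)
  tr <- maxpars:::as_phylo(maxpars:::random_topology(m$taxa))
  fit <- fitch_length(tr, m)
  td <- tidy(fit)
  expect_equal(nrow(td), 12L)
  expect_true(all(td$ci >= 0 & td$ci <= 1, na.rm = TRUE))
  gl <- glance(fit)
  expect_equal(gl$total_steps, fit$total)
})
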