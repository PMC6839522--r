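#' Simulation configuration
#'
#' Settings for the synthetic morphological-matrix generator. The defaults
#' emulate the structure of a large fossil-crocodylian matrix: 114 taxa by
#' 202 unordered characters with mostly 2-4 states, substantial homoplasy
#' (ensemble CI on good trees near 0.3), occasional polymorphic cells, and
#' heavy, heterogeneous per-taxon missing data (fossils scorable for only a
#' fraction of characters).
#'
#' @param n_taxa number of taxa (>= 4).
#' @param n_char number of characters (>= 1).
#' @param k_states states per character; a single value or a vector sampled
#'   from per character (2-4 is typical for morphology).
#' @param expected_changes mean number of state changes per character placed
#'   on the tree (Poisson); this is the homoplasy dial. The default 8 was
#'   fixed by a one-off calibration so that study-sized matrices give
#'   best-tree ensemble CI near 0.3 and RI near 0.76, the regime of large
#'   real morphological matrices.
#' @param change_model `"poisson"` draws Poisson(expected_changes) changes;
#'   `"one"` gives every character exactly one change (homoplasy-free by
#'   construction when `k_states = 2`).
#' @param missing_range per-taxon missing fraction is drawn uniformly from
#'   this `c(lo, hi)` range.
#' @param polymorphism_prob probability that a scored cell gains one extra
#'   adjacent state (polymorphic coding).
#' @param tree_shape `"uniform"` (uniform over unrooted topologies, unit
#'   branch lengths) or `"birth"` (pure-birth relaxed clock via ape).
#' @param rng_seed optional integer seed.
#' @return A list of class `mp_sim_config`.
#' @export
simulation_config <- function(n_taxa = 114L, n_char = 202L, k_states = 3L,
                              expected_changes = 8, change_model = c("poisson", "one"),
                              missing_range = c(0.1, 0.7),
                              polymorphism_prob = 0.01,
                              tree_shape = c("uniform", "birth"),
                              rng_seed = NULL) {
  change_model <- match.arg(change_model)
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_taxa >= 4L, n_char >= 1L, all(k_states >= 2L & k_states <= 10L),
            length(missing_range) == 2L, all(missing_range >= 0),
            all(missing_range <= 1), missing_range[1] <= missing_range[2],
            polymorphism_prob >= 0, polymorphism_prob <= 1,
            expected_changes >= 0)
  structure(list(n_taxa = as.integer(n_taxa), n_char = as.integer(n_char),
                 k_states = as.integer(k_states),
                 expected_changes = expected_changes,
                 change_model = change_model,
                 missing_range = missing_range,
                 polymorphism_prob = polymorphism_prob,
                 tree_shape = tree_shape, rng_seed = rng_seed),
            class = "mp_sim_config")
}

#' Simulate an unrooted tree
#'
#' `"uniform"` draws uniformly over unrooted binary topologies (random
#' stepwise insertion; every topology corresponds to exactly one sequence of
#' insertion edges) with unit branch lengths; `"birth"` uses a pure-birth
#' process ([ape::rphylo]) and keeps its branch lengths.
#'
#' @param n_taxa number of taxa (>= 4).
#' @param shape `"uniform"` or `"birth"`.
#' @param labels optional taxon labels (default `t1..tn`).
#' @return An unrooted [ape::phylo] with branch lengths.
#' @export
simulate_tree <- function(n_taxa, shape = c("uniform", "birth"),
                          labels = NULL) {
  shape <- match.arg(shape)
  stopifnot(n_taxa >= 4L)
  labels <- labels %||% paste0("t", seq_len(n_taxa))
  if (shape == "uniform") {
    phy <- as_phylo(random_topology(labels))
    phy$edge.length <- rep(1, nrow(phy$edge))
  } else {
    phy <- ape::rphylo(n_taxa, birth = 1, death = 0)
    phy$tip.label <- sample(labels)
    phy <- ape::unroot(phy)
  }
  phy
}

#' Simulate morphological characters on a tree
#'
#' Each character evolves by a number of state changes (Poisson with mean
#' `expected_changes`, or exactly one under `change_model = "one"`) placed on
#' branches with probability proportional to branch length; each change
#' moves to a state drawn uniformly from the other `k - 1` states (symmetric
#' unordered model). True per-character change counts are recorded so
#' homoplasy is known exactly. Polymorphism, if requested, is injected
#' afterwards by adding one adjacent-index state to random scored cells.
#'
#' @param tree an [ape::phylo] with branch lengths (see [simulate_tree()]).
#' @param n_char,k_states,expected_changes,change_model,polymorphism_prob
#'   see [simulation_config()].
#' @return An object of class `mp_sim_dataset`: list with `tree` (the true
#'   tree), `matrix` (a [char_matrix()]), `true_changes` (integer vector) and
#'   `config` (the effective settings).
#' @examples
#' set.seed(7)
#' sim <- simulate_characters(simulate_tree(8), n_char = 30,
#'                            expected_changes = 1)
#' sim$matrix
#' @export
simulate_characters <- function(tree, n_char = 202L, k_states = 3L,
                                expected_changes = 7,
                                change_model = c("poisson", "one"),
                                polymorphism_prob = 0) {
  change_model <- match.arg(change_model)
  phy <- ape::unroot(tree)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  n <- length(phy$tip.label)
  edge <- phy$edge
  elen <- phy$edge.length
  # orient from ape's root; edge rows already parent->child
  n_edge <- nrow(edge)
  states <- matrix(0L, n, n_char)
  true_changes <- integer(n_char)
  N <- max(edge)
  # edges in parent-before-child order (BFS from the basal node)
  root_node <- setdiff(edge[, 1], edge[, 2])[1]
  preorder <- integer(0)
  frontier <- root_node
  remaining <- seq_len(n_edge)
  while (length(frontier) && length(remaining)) {
    sel <- remaining[edge[remaining, 1] %in% frontier]
    preorder <- c(preorder, sel)
    frontier <- edge[sel, 2]
    remaining <- setdiff(remaining, sel)
  }
  ks <- if (length(k_states) == 1L) rep(k_states, n_char) else
    sample(k_states, n_char, replace = TRUE)
  for (j in seq_len(n_char)) {
    k <- ks[j]
    nch <- switch(change_model,
                  poisson = stats::rpois(1, expected_changes),
                  one = 1L)
    true_changes[j] <- nch
    ch_per_edge <- if (nch > 0)
      tabulate(sample.int(n_edge, nch, replace = TRUE, prob = elen), n_edge)
    else integer(n_edge)
    node_state <- integer(N)
    root <- edge[preorder[1], 1]
    node_state[root] <- if (change_model == "one") 0L else
      sample.int(k, 1L) - 1L
    for (e in preorder) {
      s <- node_state[edge[e, 1]]
      m <- ch_per_edge[e]
      if (m > 0) {
        for (i in seq_len(m)) {
          s <- if (change_model == "one") 1L else
            (s + sample.int(k - 1L, 1L)) %% k
        }
      }
      node_state[edge[e, 2]] <- s
    }
    states[, j] <- node_state[seq_len(n)]
  }
  masks <- matrix(bitwShiftL(1L, states), n, n_char)
  if (polymorphism_prob > 0) {
    for (j in seq_len(n_char)) {
      k <- ks[j]
      hit <- which(stats::runif(n) < polymorphism_prob)
      for (i in hit) {
        extra <- (states[i, j] + 1L) %% k
        masks[i, j] <- bitwOr(masks[i, j], bitwShiftL(1L, extra))
      }
    }
  }
  cm <- char_matrix(masks, taxa = phy$tip.label,
                    characters = tibble::tibble(
                      index = seq_len(n_char),
                      n_states_declared = ks))
  structure(list(tree = phy, matrix = cm, true_changes = true_changes,
                 config = list(n_char = n_char, k_states = k_states,
                               expected_changes = expected_changes,
                               change_model = change_model,
                               polymorphism_prob = polymorphism_prob)),
            class = "mp_sim_dataset")
}

#' @export
print.mp_sim_dataset <- function(x, ...) {
  cat("Simulated dataset:", n_taxa(x$matrix), "taxa x", n_char(x$matrix),
      "characters;", sum(x$true_changes), "true changes\n")
  invisible(x)
}

#' Impose fossil-style missing data
#'
#' Each taxon draws a missing fraction uniformly from `missing_range`; then
#' `floor(fraction * n_char)` of its cells, chosen at random, are set to
#' missing (`?`). Non-missing cells are never altered.
#'
#' @param dataset an `mp_sim_dataset` from [simulate_characters()].
#' @param missing_range `c(lo, hi)` fractions in `[0, 1]`.
#' @return The dataset with an updated matrix.
#' @export
apply_missingness <- function(dataset, missing_range) {
  stopifnot(inherits(dataset, "mp_sim_dataset"),
            length(missing_range) == 2L, all(missing_range >= 0),
            all(missing_range <= 1), missing_range[1] <= missing_range[2])
  cm <- dataset$matrix
  n <- n_taxa(cm); nc <- n_char(cm)
  st <- cm$states
  frac <- stats::runif(n, missing_range[1], missing_range[2])
  for (i in seq_len(n)) {
    k <- floor(frac[i] * nc)
    if (k > 0) st[i, sample.int(nc, k)] <- 0L
  }
  dataset$matrix <- char_matrix(st, taxa = cm$taxa,
                                characters = cm$characters)
  dataset$config$missing_range <- missing_range
  dataset
}

#' Simulate a full dataset from a configuration
#'
#' Convenience wrapper: tree, characters, polymorphism and missingness in
#' one call, deterministically reproducible from `config$rng_seed`.
#'
#' @param config a [simulation_config()].
#' @return An `mp_sim_dataset`.
#' @export
simulate_matrix <- function(config = simulation_config()) {
  stopifnot(inherits(config, "mp_sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  tree <- simulate_tree(config$n_taxa, config$tree_shape)
  sim <- simulate_characters(tree, n_char = config$n_char,
                             k_states = config$k_states,
                             expected_changes = config$expected_changes,
                             change_model = config$change_model,
                             polymorphism_prob = config$polymorphism_prob)
  if (config$missing_range[2] > 0)
    sim <- apply_missingness(sim, config$missing_range)
  sim$config$rng_seed <- config$rng_seed
  sim$config$tree_shape <- config$tree_shape
  sim
}

#' Tree-recovery experiment
#'
#' Validation harness: repeatedly simulate a dataset, run the search
#' pipeline, and compare the strict consensus of the recovered trees with
#' the generating tree by Robinson-Foulds distance (counted over resolved
#' bipartitions; consensus polytomies show up as missing splits).
#'
#' @param n_runs number of simulate-search-compare runs.
#' @param sim_config a [simulation_config()].
#' @param search_cfg an [search_config()] for the per-run search.
#' @return A tibble with one row per run: `run`, `rf` (Robinson-Foulds
#'   distance between strict consensus and true tree), `best_length`,
#'   `true_length` (Fitch length of the generating tree) and `length_gap`.
#' @export
recovery_experiment <- function(n_runs = 20L,
                                sim_config = simulation_config(
                                  n_taxa = 12, n_char = 100,
                                  change_model = "one", k_states = 2,
                                  missing_range = c(0, 0),
                                  polymorphism_prob = 0),
                                search_cfg = search_config(
                                  n_replications = 5, trees_saved_per_rep = 5,
                                  target_hits = 50)) {
  purrr::map_dfr(seq_len(n_runs), function(r) {
    sim <- simulate_matrix(sim_config)
    if (n_char(sim$matrix) == 0L)
      return(tibble::tibble(run = r, rf = NA_real_,
                            best_length = NA_real_, true_length = NA_real_,
                            length_gap = NA_real_))
    pool <- replicated_search(sim$matrix, search_cfg)
    cons <- strict_consensus(pool)
    rf <- rf_distance(cons, sim$tree)
    true_len <- fitch_length(sim$tree, sim$matrix)$total
    tibble::tibble(run = r, rf = rf, best_length = pool$best_length,
                   true_length = true_len,
                   length_gap = true_len - pool$best_length)
  })
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference distance between the bipartition sets of two trees
#' on the same leaves; polytomies simply contribute fewer bipartitions.
#'
#' @param tree1,tree2 [ape::phylo] trees with identical tip labels.
#' @return A non-negative integer.
#' @export
rf_distance <- function(tree1, tree2) {
  u1 <- as_utree(tree1); u2 <- as_utree(tree2)
  if (!setequal(u1$tip_label, u2$tip_label))
    stop("trees do not share a leaf set")
  taxa <- sort(u1$tip_label)
  s1 <- utree_splits(u1, taxa); s2 <- utree_splits(u2, taxa)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
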