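#' Search configuration
#'
#' Bundles the knobs of the heuristic parsimony search. The defaults are the
#' protocol of the analysis this package reproduces: 1,000 random-addition
#' replications, TBR branch swapping with 10 trees saved per replication, a
#' tree buffer of 10,000, and hit-driven stopping after the best length has
#' been found 50 times.
#'
#' @param n_replications number of independent random-addition + swap rounds.
#' @param trees_saved_per_rep equally best trees kept per round.
#' @param max_trees cap on stored trees (counting continues past it).
#' @param swap branch-swapping neighborhood: `"tbr"`, `"spr"` or `"nni"`.
#' @param target_hits independent hits on the best length required by
#'   [driven_search()].
#' @param rng_seed optional integer seed applied on entry to the searches.
#' @param ratchet logical; use parsimony-ratchet perturbation rounds inside
#'   each replication (extra search effort, same contracts).
#' @param ratchet_iterations perturbation cycles per replication when
#'   `ratchet = TRUE`.
#' @param collapse collapse branches of minimum length zero before comparing
#'   topologies in the pool (the convention that controls how many distinct
#'   equally parsimonious trees are reported).
#' @return A list of class `mp_search_config`.
#' @export
search_config <- function(n_replications = 1000L, trees_saved_per_rep = 10L,
                          max_trees = 10000L, swap = c("tbr", "spr", "nni"),
                          target_hits = 50L, rng_seed = NULL,
                          ratchet = FALSE, ratchet_iterations = 5L,
                          collapse = TRUE) {
  swap <- match.arg(swap)
  stopifnot(n_replications >= 1L, trees_saved_per_rep >= 1L,
            max_trees >= trees_saved_per_rep, target_hits >= 1L)
  structure(list(n_replications = as.integer(n_replications),
                 trees_saved_per_rep = as.integer(trees_saved_per_rep),
                 max_trees = as.integer(max_trees), swap = swap,
                 target_hits = as.integer(target_hits), rng_seed = rng_seed,
                 ratchet = isTRUE(ratchet),
                 ratchet_iterations = as.integer(ratchet_iterations),
                 collapse = isTRUE(collapse)),
            class = "mp_search_config")
}

matrix_prep <- function(matrix) {
  list(tip_state = prep_tip_states(matrix, matrix$taxa),
       weights = as.numeric(matrix$characters$weight),
       taxa = matrix$taxa)
}

score_utrees <- function(uts, prep, tip_labels = NULL) {
  if (!length(uts)) return(numeric(0))
  if (is.null(tip_labels)) {
    ts <- prep$tip_state
  } else {
    ts <- prep$tip_state[match(tip_labels, prep$taxa), , drop = FALSE]
  }
  ntip <- if (is.null(tip_labels)) length(prep$taxa) else length(tip_labels)
  fitch_batch_cpp(lapply(uts, function(u) u$edge), ntip, ts, prep$weights)
}

# remap a tree built in addition order so tip ids follow matrix taxon order
utree_standardize <- function(ut, taxa) {
  perm <- match(ut$tip_label, taxa)
  n <- ut$n_tip
  map <- c(perm, seq.int(n + 1L, max(ut$edge)))
  utree(matrix(map[ut$edge], ncol = 2), n, taxa)
}

pool_key <- function(ut, matrix, collapse) {
  if (!collapse) return(utree_key(ut, matrix$taxa))
  fit <- fitch_length(as_utree(ut), matrix)
  utree_key(ut, matrix$taxa, drop_splits = zero_length_splits(fit))
}

new_tree_pool <- function(best_length, trees, keys, matrix, collapse,
                          diagnostics = list()) {
  structure(list(best_length = best_length, trees = trees, keys = keys,
                 taxa = matrix$taxa, collapse = collapse,
                 diagnostics = diagnostics),
            class = "mp_tree_pool")
}

#' @export
print.mp_tree_pool <- function(x, ...) {
  cat("Tree pool:", length(x$trees), "tree(s) at length", x$best_length, "\n")
  if (!is.null(x$diagnostics$rep_best))
    cat("replicate best lengths:",
        paste(utils::head(x$diagnostics$rep_best, 10), collapse = " "),
        if (length(x$diagnostics$rep_best) > 10) "..." else "", "\n")
  invisible(x)
}

#' @rdname replicated_search
#' @param x an `mp_tree_pool`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.mp_tree_pool <- function(x, ...) {
  tibble::tibble(best_length = x$best_length, n_trees = length(x$trees),
                 hits = x$diagnostics$hits %||% NA_integer_,
                 n_rounds = length(x$diagnostics$rep_best %||% integer(0)))
}

#' Extract trees from a pool
#'
#' @param pool an `mp_tree_pool`.
#' @return An [ape::multiPhylo] list of the stored trees.
#' @export
pool_trees <- function(pool) {
  out <- lapply(pool$trees, as_phylo)
  class(out) <- "multiPhylo"
  out
}

# --- stepwise addition -----------------------------------------------------

#' Random-addition starting tree
#'
#' Builds a Wagner tree: taxa are inserted in random order, each at the
#' insertion point that minimises total parsimony length at that moment,
#' with ties broken at random. The standard seeded starting point for
#' replicated heuristic searches.
#'
#' @param matrix a [char_matrix()] with at least 3 taxa.
#' @param order optional integer permutation of taxa to use instead of a
#'   random one.
#' @return An [ape::phylo] unrooted binary tree.
#' @export
random_addition_tree <- function(matrix, order = NULL) {
  as_phylo(random_addition_utree(matrix, matrix_prep(matrix), order))
}

random_addition_utree <- function(matrix, prep, order = NULL) {
  n <- n_taxa(matrix)
  if (n < 3L) stop("need at least 3 taxa")
  ord <- order %||% sample.int(n)
  ut <- triplet_utree(matrix$taxa[ord[1:3]])
  for (k in seq_len(n - 3L) + 3L) {
    label <- matrix$taxa[ord[k]]
    cands <- lapply(seq_len(nrow(ut$edge)), function(e)
      utree_insert_tip(ut, e, label))
    sc <- score_utrees(cands, prep, tip_labels = cands[[1]]$tip_label)
    best <- which(sc == min(sc))
    pick <- if (length(best) == 1L) best else sample(best, 1L)
    ut <- cands[[pick]]
  }
  utree_standardize(ut, matrix$taxa)
}

# --- hill climbing ---------------------------------------------------------

#' Branch-swapping search from a starting tree
#'
#' Hill-climbs through the chosen swap neighborhood (TBR by default),
#' keeping up to `keep` equally best trees, until every retained tree has
#' been swapped without improvement. Tree identity uses collapsed topologies
#' when `collapse = TRUE` (branches of minimum length zero are ignored).
#'
#' @param start starting tree ([ape::phylo]).
#' @param matrix a [char_matrix()].
#' @param swap neighborhood: `"tbr"`, `"spr"` or `"nni"`.
#' @param keep maximum number of equally best trees retained.
#' @param collapse see [search_config()].
#' @return An `mp_tree_pool`.
#' @export
swap_search <- function(start, matrix, swap = "tbr", keep = 10L,
                        collapse = TRUE) {
  ut <- as_utree(start, taxa = matrix$taxa)
  ut <- utree_standardize(ut, matrix$taxa)
  prep <- matrix_prep(matrix)
  swap_search_impl(ut, matrix, prep, swap, keep, collapse)
}

swap_search_impl <- function(ut, matrix, prep, swap, keep, collapse,
                             reject = NULL) {
  best <- score_utrees(list(ut), prep)
  pool <- list(ut)
  keys <- pool_key(ut, matrix, collapse)
  swapped <- c(FALSE)
  n_scored <- 1L
  repeat {
    todo <- which(!swapped)
    if (!length(todo)) break
    i <- todo[1]
    swapped[i] <- TRUE
    nb <- utree_neighborhood(pool[[i]], swap)
    if (!is.null(reject)) nb <- Filter(Negate(reject), nb)
    if (!length(nb)) next
    sc <- score_utrees(nb, prep)
    n_scored <- n_scored + length(nb)
    mn <- min(sc)
    if (mn < best) {
      best <- mn
      sel <- nb[sc == mn]
      pool <- list(); keys <- character(0); swapped <- logical(0)
      for (tr in sel) {
        if (length(pool) >= keep) break
        k <- pool_key(tr, matrix, collapse)
        if (!k %in% keys) {
          pool <- c(pool, list(tr)); keys <- c(keys, k)
          swapped <- c(swapped, FALSE)
        }
      }
    } else if (length(pool) < keep) {
      for (j in which(sc == best)) {
        if (length(pool) >= keep) break
        k <- pool_key(nb[[j]], matrix, collapse)
        if (!k %in% keys) {
          pool <- c(pool, list(nb[[j]])); keys <- c(keys, k)
          swapped <- c(swapped, FALSE)
        }
      }
    }
  }
  new_tree_pool(best, pool, keys, matrix, collapse,
                diagnostics = list(n_scored = n_scored))
}

# one addition + swap round, optionally with ratchet perturbation cycles
search_round <- function(matrix, prep, config) {
  ut <- random_addition_utree(matrix, prep)
  pool <- swap_search_impl(ut, matrix, prep, config$swap,
                           config$trees_saved_per_rep, config$collapse)
  if (config$ratchet) {
    for (i in seq_len(config$ratchet_iterations)) {
      pert <- prep
      nudge <- sample.int(length(prep$weights),
                          max(1L, length(prep$weights) %/% 4L))
      pert$weights[nudge] <- pert$weights[nudge] * 2
      p1 <- swap_search_impl(pool$trees[[1]], matrix, pert, config$swap,
                             1L, FALSE)
      p2 <- swap_search_impl(p1$trees[[1]], matrix, prep, config$swap,
                             config$trees_saved_per_rep, config$collapse)
      if (p2$best_length < pool$best_length) pool <- p2
      else if (p2$best_length == pool$best_length)
        pool <- merge_pools(pool, p2, matrix, config)
    }
  }
  pool
}

merge_pools <- function(a, b, matrix, config) {
  stopifnot(a$best_length == b$best_length)
  keys <- a$keys; trees <- a$trees
  overflow <- FALSE
  for (j in seq_along(b$trees)) {
    if (b$keys[j] %in% keys) next
    if (length(trees) >= config$max_trees) { overflow <- TRUE; next }
    trees <- c(trees, list(b$trees[[j]]))
    keys <- c(keys, b$keys[j])
  }
  if (overflow)
    warning("tree buffer full (max_trees = ", config$max_trees,
            "); further equally parsimonious trees not stored")
  new_tree_pool(a$best_length, trees, keys, matrix, a$collapse,
                diagnostics = a$diagnostics)
}

#' Replicated heuristic search
#'
#' Runs `n_replications` independent random-addition + branch-swapping
#' rounds and merges the equally best trees found, subject to the
#' `max_trees` buffer. Per-replicate best lengths are kept as diagnostics.
#'
#' @param matrix a [char_matrix()].
#' @param config an [search_config()].
#' @return An `mp_tree_pool`; `glance()` summarises it.
#' @examples
#' set.seed(1)
#' sim <- simulate_characters(simulate_tree(8), n_char = 20)
#' pool <- replicated_search(sim$matrix, search_config(n_replications = 3,
#'   trees_saved_per_rep = 5, target_hits = 2))
#' glance(pool)
#' @export
replicated_search <- function(matrix, config = search_config()) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  prep <- matrix_prep(matrix)
  pool <- NULL
  rep_best <- numeric(config$n_replications)
  for (r in seq_len(config$n_replications)) {
    rp <- search_round(matrix, prep, config)
    rep_best[r] <- rp$best_length
    if (is.null(pool) || rp$best_length < pool$best_length) pool <- rp
    else if (rp$best_length == pool$best_length)
      pool <- merge_pools(pool, rp, matrix, config)
  }
  pool$diagnostics$rep_best <- rep_best
  pool
}

#' Hit-driven heuristic search
#'
#' Repeats independent search rounds until the current best length has been
#' hit `target_hits` times (the hit count restarts whenever a better length
#' is found), mirroring a driven "new technology"-style stopping rule. A
#' safety cap of `20 * target_hits` rounds guards against non-convergence.
#'
#' @inheritParams replicated_search
#' @return An `mp_tree_pool` with `diagnostics$hits` and per-round best
#'   lengths.
#' @export
driven_search <- function(matrix, config = search_config()) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  prep <- matrix_prep(matrix)
  pool <- NULL
  hits <- 0L
  rep_best <- numeric(0)
  cap <- 20L * config$target_hits
  round <- 0L
  while (hits < config$target_hits && round < cap) {
    round <- round + 1L
    rp <- search_round(matrix, prep, config)
    rep_best <- c(rep_best, rp$best_length)
    if (is.null(pool) || rp$best_length < pool$best_length) {
      pool <- rp; hits <- 1L
    } else if (rp$best_length == pool$best_length) {
      hits <- hits + 1L
      pool <- merge_pools(pool, rp, matrix, config)
    }
  }
  if (round >= cap && hits < config$target_hits)
    warning("driven search stopped at the safety cap of ", cap, " rounds")
  pool$diagnostics$hits <- hits
  pool$diagnostics$rep_best <- rep_best
  pool
}

#' Expand a pool of optimal trees to TBR closure
#'
#' Branch-swaps every retained tree and keeps adding newly found
#' equal-length (collapsed) topologies until no tree in the pool yields a
#' new one, or `max_trees` is reached. This is the "second round of
#' swapping on the trees in memory" step that turns the trees sampled by
#' replicated searches into the full set of most parsimonious trees.
#'
#' @param pool an `mp_tree_pool` at a fixed best length.
#' @param matrix the matrix the pool was found on.
#' @param max_trees storage cap (the expansion can exceed the search-stage
#'   buffer, so it takes its own).
#' @param swap neighborhood to use (default TBR).
#' @return An `mp_tree_pool` that is a superset of `pool`.
#' @export
expand_pool_tbr <- function(pool, matrix, max_trees = 100000L,
                            swap = "tbr") {
  prep <- matrix_prep(matrix)
  best <- pool$best_length
  trees <- pool$trees; keys <- pool$keys
  swapped <- rep(FALSE, length(trees))
  overflow <- FALSE
  improved <- FALSE
  while (any(!swapped)) {
    i <- which(!swapped)[1]
    swapped[i] <- TRUE
    nb <- utree_neighborhood(trees[[i]], swap)
    sc <- score_utrees(nb, prep)
    if (any(sc < best) && !improved) {
      improved <- TRUE
      warning("pool expansion found a shorter tree (length ", min(sc),
              " < ", best, "); the input pool was not optimal. ",
              "Only trees at the input length are collected.")
    }
    for (j in which(sc == best)) {
      k <- pool_key(nb[[j]], matrix, pool$collapse)
      if (k %in% keys) next
      if (length(trees) >= max_trees) { overflow <- TRUE; next }
      trees <- c(trees, list(nb[[j]]))
      keys <- c(keys, k)
      swapped <- c(swapped, FALSE)
    }
    if (overflow) break
  }
  if (overflow)
    warning("pool expansion stopped at max_trees = ", max_trees)
  diag <- pool$diagnostics
  diag$expanded <- TRUE
  diag$expansion_complete <- !overflow
  new_tree_pool(best, trees, keys, matrix, pool$collapse, diag)
}

#' Exhaustive parsimony search
#'
#' Enumerates every unrooted binary topology (at most 9 taxa,
#' (2n-5)!! trees) and returns all optimal trees. The exact oracle against
#' which the heuristic searches are validated.
#'
#' @inheritParams replicated_search
#' @param collapse collapse zero-minimum-length branches when deduplicating
#'   the optimal trees.
#' @return An `mp_tree_pool` with `diagnostics$n_topologies`.
#' @export
exhaustive_search <- function(matrix, collapse = TRUE) {
  n <- n_taxa(matrix)
  if (n < 3L) stop("need at least 3 taxa")
  if (n > 9L) stop("exhaustive search is limited to 9 taxa (",
                   "(2n-5)!! topologies grow too fast)")
  prep <- matrix_prep(matrix)
  topo <- enumerate_topologies(n)
  sc <- fitch_batch_cpp(topo, n, prep$tip_state, prep$weights)
  best <- min(sc)
  sel <- which(sc == best)
  trees <- list(); keys <- character(0)
  for (i in sel) {
    ut <- utree(topo[[i]], n, matrix$taxa)
    k <- pool_key(ut, matrix, collapse)
    if (!k %in% keys) { trees <- c(trees, list(ut)); keys <- c(keys, k) }
  }
  new_tree_pool(best, trees, keys, matrix, collapse,
                diagnostics = list(n_topologies = length(topo),
                                   all_lengths = sc))
}
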