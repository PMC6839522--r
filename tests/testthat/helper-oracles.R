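# Independent oracles and fixture builders used across the suite.
# The brute-force Fitch oracle enumerates complete internal-node state
# assignments and never calls the package's scoring path.

# random single-state matrix with optional missing / polymorphic cells,
# built directly from sample() so fixtures are independent of the
# package's simulator
rand_matrix <- function(n_taxa, n_char, k = 2L, missing_p = 0,
                        poly_p = 0) {
  states <- matrix(sample.int(k, n_taxa * n_char, replace = TRUE) - 1L,
                   n_taxa, n_char)
  masks <- matrix(bitwShiftL(1L, states), n_taxa, n_char)
  if (poly_p > 0 && k >= 2L) {
    hit <- which(matrix(runif(n_taxa * n_char) < poly_p, n_taxa, n_char))
    for (i in hit) {
      extra <- (states[i] + 1L) %% k
      masks[i] <- bitwOr(masks[i], bitwShiftL(1L, extra))
    }
  }
  if (missing_p > 0) {
    masks[matrix(runif(n_taxa * n_char) < missing_p, n_taxa, n_char)] <- 0L
  }
  char_matrix(masks, taxa = paste0("t", seq_len(n_taxa)))
}

# all (internal-node state) assignments for one character; leaves pick their
# cheapest allowed state given the adjacent internal state. Exact minimum
# for unordered characters.
brute_char_length <- function(edge, n_tip, leaf_sets, k) {
  internals <- sort(unique(as.integer(edge[edge > n_tip])))
  m <- length(internals)
  if (m == 0L) {
    # two leaves joined by one edge
    a <- leaf_sets[[1]]; b <- leaf_sets[[2]]
    if (length(a) == 0L || length(b) == 0L) return(0L)
    return(as.integer(length(intersect(a, b)) == 0L))
  }
  grid <- as.matrix(expand.grid(rep(list(0:(k - 1L)), m)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- integer(max(edge))
    assign[internals] <- grid[g, ]
    cost <- 0L
    for (e in seq_len(nrow(edge))) {
      a <- edge[e, 1]; b <- edge[e, 2]
      if (a <= n_tip || b <= n_tip) {
        leaf <- min(a, b); int <- max(a, b)
        s <- leaf_sets[[leaf]]
        cost <- cost + (if (length(s) == 0L) 0L else
          min(as.integer(s != assign[int])))
      } else {
        cost <- cost + (assign[a] != assign[b])
      }
    }
    if (cost < best) best <- cost
  }
  best
}

# per-character observed leaf sets for the oracle (missing = free choice,
# encoded as empty set costing 0 whatever the neighbor state)
oracle_leaf_sets <- function(matrix, j) {
  lapply(seq_len(nrow(matrix$states)), function(i)
    maxpars:::mask_states(matrix$states[i, j]))
}

brute_tree_length <- function(tree, matrix, k = 4L) {
  ut <- maxpars:::as_utree(tree, taxa = matrix$taxa)
  ut <- maxpars:::utree_standardize(ut, matrix$taxa)
  sum(vapply(seq_len(ncol(matrix$states)), function(j)
    brute_char_length(ut$edge, ut$n_tip, oracle_leaf_sets(matrix, j), k),
    numeric(1)))
}

# states taken by each internal node across all minimum assignments of one
# character; returned as a list keyed by the node's sorted tip set
brute_mpr_sets <- function(tree, matrix, j, k = 4L) {
  ut <- maxpars:::as_utree(tree, taxa = matrix$taxa)
  ut <- maxpars:::utree_standardize(ut, matrix$taxa)
  edge <- ut$edge; n_tip <- ut$n_tip
  leaf_sets <- oracle_leaf_sets(matrix, j)
  internals <- sort(unique(as.integer(edge[edge > n_tip])))
  m <- length(internals)
  grid <- as.matrix(expand.grid(rep(list(0:(k - 1L)), m)))
  costs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    assign <- integer(max(edge))
    assign[internals] <- grid[g, ]
    cost <- 0L
    for (e in seq_len(nrow(edge))) {
      a <- edge[e, 1]; b <- edge[e, 2]
      if (a <= n_tip || b <= n_tip) {
        leaf <- min(a, b); int <- max(a, b)
        s <- leaf_sets[[leaf]]
        cost <- cost + (if (length(s) == 0L) 0L else
          as.integer(!(assign[int] %in% s)))
      } else {
        cost <- cost + (assign[a] != assign[b])
      }
    }
    costs[g] <- cost
  }
  sel <- which(costs == min(costs))
  below <- maxpars:::node_tipsets(ut)
  out <- list()
  for (i in seq_along(internals)) {
    key <- paste(sort(ut$tip_label[below[[internals[i]]]]), collapse = ",")
    out[[key]] <- sort(unique(grid[sel, i]))
  }
  out
}

# all unrooted binary topologies on the matrix taxa, as phylo, via the
# package's enumerator (validated separately against (2n-5)!!)
all_topologies_phylo <- function(matrix) {
  n <- length(matrix$taxa)
  lapply(maxpars:::enumerate_topologies(n), function(ed)
    maxpars:::as_phylo(maxpars:::utree(ed, n, matrix$taxa)))
}

# matrix in which `clean` characters all support one clade and nothing else
clade_signal_matrix <- function(n_taxa, clade_idx, n_clean) {
  states <- matrix("0", n_taxa, n_clean)
  states[clade_idx, ] <- "1"
  rownames(states) <- paste0("t", seq_len(n_taxa))
  char_matrix(states)
}

# zero-signal matrix: every character is an autapomorphy of one taxon
autapomorphy_matrix <- function(n_taxa, n_char) {
  states <- matrix("0", n_taxa, n_char)
  for (j in seq_len(n_char)) states[((j - 1L) %% n_taxa) + 1L, j] <- "1"
  rownames(states) <- paste0("t", seq_len(n_taxa))
  char_matrix(states)
}
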