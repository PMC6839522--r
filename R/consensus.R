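# split set of each tree in a pool, from the stored (collapsed) topology
# keys: branches of minimum length zero carry no grouping information, so
# they must not contribute splits to consensus or rogue analysis
pool_split_sets <- function(pool) {
  lapply(pool$keys, function(k)
    if (!nzchar(k)) character(0) else strsplit(k, "|", fixed = TRUE)[[1]])
}

# input normalisation: a pool, a multiPhylo, or a list of phylo trees;
# `sets` holds the per-tree split keys used for consensus work
as_utree_list <- function(trees) {
  if (inherits(trees, "mp_tree_pool"))
    return(list(uts = trees$trees, taxa = trees$taxa,
                sets = pool_split_sets(trees)))
  if (inherits(trees, "phylo")) trees <- list(trees)
  uts <- lapply(trees, as_utree)
  taxa <- sort(uts[[1]]$tip_label)
  for (u in uts) {
    if (!setequal(u$tip_label, taxa))
      stop("trees do not share an identical leaf set")
  }
  list(uts = uts, taxa = taxa,
       sets = lapply(uts, utree_splits, ref_taxa = taxa))
}

#' Strict consensus tree
#'
#' The tree whose internal branches are exactly the bipartitions present in
#' every input tree; it is in general multifurcating. Input trees must share
#' one leaf set.
#'
#' @param trees an `mp_tree_pool`, an [ape::multiPhylo], or a list of
#'   [ape::phylo] trees.
#' @return An [ape::phylo] consensus tree.
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
#' t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
#' ape::write.tree(strict_consensus(list(t1, t2)))
#' @export
strict_consensus <- function(trees) {
  inp <- as_utree_list(trees)
  keys <- Reduce(intersect, inp$sets)
  as_phylo(utree_from_splits(keys, inp$taxa))
}

common_split_keys <- function(trees) {
  inp <- as_utree_list(trees)
  Reduce(intersect, inp$sets)
}

#' Majority-rule consensus (utility)
#'
#' Bipartitions present in more than `p` of the input trees. Provided as a
#' utility; the headline consensus of the pipeline is [strict_consensus()].
#'
#' @inheritParams strict_consensus
#' @param p minimum fraction of trees a split must occur in (> 0.5 keeps the
#'   result a tree).
#' @return An [ape::phylo].
#' @export
majority_consensus <- function(trees, p = 0.5) {
  stopifnot(p >= 0.5)
  inp <- as_utree_list(trees)
  tab <- table(unlist(inp$sets))
  keys <- names(tab)[tab / length(inp$sets) > p]
  as_phylo(utree_from_splits(keys, inp$taxa))
}

# restrict canonical split keys to the taxa with reference indices in
# `remaining` (sorted); re-canonicalise against the smallest remaining index
restrict_split_keys <- function(keys, remaining, n_total) {
  out <- character(0)
  r0 <- remaining[1]
  m <- length(remaining)
  for (k in keys) {
    side <- intersect(split_key_tips(k), remaining)
    if (r0 %in% side) side <- setdiff(remaining, side)
    if (length(side) < 2L || length(side) > m - 2L) next
    out <- c(out, paste(side, collapse = ","))
  }
  unique(out)
}

#' Detect and prune rogue taxa
#'
#' Searches greedily for taxa whose unstable position across the tree pool
#' collapses the strict consensus: single taxa first, then pairs, pruning
#' only while the strict consensus of the pruned trees gains internal
#' branches. For every pruned taxon the distinct attachment positions it
#' takes across the pool (edges of the reduced consensus leaf set) are
#' reported.
#'
#' @inheritParams strict_consensus
#' @param max_prune maximum number of taxa to remove.
#' @return A list of class `mp_rogue_report`: `pruned` (tibble with columns
#'   `taxon`, `resolution_gain`, `n_positions`, `positions` list-column),
#'   `reduced_consensus` (an [ape::phylo] on the remaining taxa) and
#'   `kept_taxa`.
#' @export
rogue_prune <- function(trees, max_prune = 2L) {
  inp <- as_utree_list(trees)
  taxa <- inp$taxa
  n <- length(taxa)
  sets <- inp$sets
  remaining <- seq_len(n)
  res_now <- length(Reduce(intersect, sets))
  pruned <- integer(0)
  gains <- integer(0)

  res_after <- function(drop_idx) {
    rem <- setdiff(remaining, drop_idx)
    length(Reduce(intersect,
                  lapply(sets, restrict_split_keys, remaining = rem,
                         n_total = n)))
  }

  while (length(pruned) < max_prune && length(remaining) > 4L) {
    cand <- setdiff(remaining, pruned)
    gain1 <- vapply(cand, function(d) res_after(c(pruned, d)) - res_now,
                    numeric(1))
    if (max(gain1) > 0) {
      d <- cand[which.max(gain1)]
      pruned <- c(pruned, d)
      gains <- c(gains, max(gain1))
      remaining <- setdiff(remaining, d)
      res_now <- res_now + max(gain1)
      next
    }
    if (max_prune - length(pruned) >= 2L && length(cand) >= 2L) {
      prs <- utils::combn(cand, 2L, simplify = FALSE)
      gain2 <- vapply(prs, function(d) res_after(c(pruned, d)) - res_now,
                      numeric(1))
      if (max(gain2) > 0) {
        d <- prs[[which.max(gain2)]]
        pruned <- c(pruned, d)
        gains <- c(gains, max(gain2), NA_integer_)
        remaining <- setdiff(remaining, d)
        res_now <- res_now + max(gain2)
        next
      }
    }
    break
  }

  kept <- taxa[remaining]
  positions <- lapply(taxa[pruned], function(tx)
    sort(unique(vapply(inp$uts, function(u)
      attachment_position(u, tx, keep = kept), character(1)))))
  red_keys <- Reduce(intersect,
                     lapply(sets, restrict_split_keys, remaining = remaining,
                            n_total = n))
  # re-express restricted keys over the reduced taxon vector
  remap <- match(seq_len(n), remaining)
  red_keys2 <- vapply(red_keys, function(k)
    paste(remap[split_key_tips(k)], collapse = ","), character(1))
  structure(
    list(pruned = tibble::tibble(
           taxon = taxa[pruned],
           resolution_gain = gains[seq_along(pruned)],
           n_positions = lengths(positions),
           positions = positions),
         reduced_consensus = as_phylo(utree_from_splits(unname(red_keys2),
                                                        kept)),
         kept_taxa = kept),
    class = "mp_rogue_report")
}

#' @export
print.mp_rogue_report <- function(x, ...) {
  if (!nrow(x$pruned)) cat("No rogue taxa detected.\n")
  else {
    cat("Pruned", nrow(x$pruned), "rogue taxon/taxa:\n")
    print(x$pruned[c("taxon", "resolution_gain", "n_positions")])
  }
  invisible(x)
}

#' @rdname rogue_prune
#' @param x an `mp_rogue_report`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.mp_rogue_report <- function(x, ...) x$pruned

# Drop tips (by label) from a binary/multifurcating utree, suppressing
# degree-2 nodes; tips re-packed to 1..m in `keep` order.
utree_drop_tips <- function(ut, keep) {
  drop <- setdiff(ut$tip_label, keep)
  if (!length(drop)) return(ut)
  adj <- lapply(utree_adjacency(ut), identity)
  alive <- rep(TRUE, length(adj))
  for (lab in drop) {
    t <- match(lab, ut$tip_label)
    nb <- adj[[t]]
    alive[t] <- FALSE
    for (v in nb) adj[[v]] <- setdiff(adj[[v]], t)
    # suppress any resulting degree-2 internal nodes
    repeat {
      deg2 <- which(alive & vapply(adj, length, integer(1)) == 2L)
      deg2 <- deg2[deg2 > ut$n_tip]
      if (!length(deg2)) break
      v <- deg2[1]
      ab <- adj[[v]]
      alive[v] <- FALSE
      adj[[v]] <- integer(0)
      adj[[ab[1]]] <- union(setdiff(adj[[ab[1]]], v), ab[2])
      adj[[ab[2]]] <- union(setdiff(adj[[ab[2]]], v), ab[1])
    }
  }
  old_tips <- which(alive[seq_len(ut$n_tip)])
  labels <- ut$tip_label[old_tips]
  ord <- match(intersect(keep, labels), labels)
  old_tips <- old_tips[ord]; labels <- labels[ord]
  old_int <- which(alive)[which(alive) > ut$n_tip]
  map <- integer(length(adj))
  map[old_tips] <- seq_along(old_tips)
  map[old_int] <- length(old_tips) + seq_along(old_int)
  edges <- list()
  for (v in which(alive)) {
    for (w in adj[[v]]) if (w > v) {
      edges[[length(edges) + 1L]] <- c(map[v], map[w])
    }
  }
  utree(do.call(rbind, edges), length(old_tips), labels)
}

# Canonical key of the edge (of the tree restricted to `keep`) on which
# taxon `tx` attaches in tree `ut`.
attachment_position <- function(ut, tx, keep) {
  sub <- utree_drop_tips(ut, c(keep, tx))
  t <- match(tx, sub$tip_label)
  adj <- utree_adjacency(sub)
  v <- adj[[t]]
  stopifnot(length(v) == 1L)
  nb <- setdiff(adj[[v]], t)
  if (length(nb) != 2L) {
    # attachment at a multifurcation: identify by the partition around v
    sides <- lapply(nb, function(a) side_labels(sub, a, v))
    key <- paste(sort(vapply(sides, paste, character(1), collapse = ",")),
                 collapse = " | ")
    return(key)
  }
  a_side <- side_labels(sub, nb[1], v)
  b_side <- side_labels(sub, nb[2], v)
  sides <- list(a_side, b_side)
  pick <- order(lengths(sides), vapply(sides, paste, character(1),
                                       collapse = ","))[1]
  paste(sides[[pick]], collapse = ",")
}

# sorted tip labels on the `a` side of edge (a, v)
side_labels <- function(ut, a, v) {
  adj <- utree_adjacency(ut)
  comp <- component_nodes(adj, a, v)
  sort(ut$tip_label[which(comp[seq_len(ut$n_tip)])])
}
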