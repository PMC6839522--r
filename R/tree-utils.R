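# Internal unrooted-tree representation used by the search machinery.
#
# A "utree" is a list(edge, n_tip, tip_label): `edge` an undirected 2-column
# integer matrix over node ids 1..N, tips 1..n_tip (in tip_label order),
# internal nodes n_tip+1..N. This matches ape's id convention so conversion
# to/from `phylo` is direct. All exported functions speak `phylo`; utrees
# never escape the package.

utree <- function(edge, n_tip, tip_label) {
  storage.mode(edge) <- "integer"
  list(edge = edge, n_tip = as.integer(n_tip), tip_label = tip_label)
}

as_utree <- function(tree, taxa = NULL) {
  if (inherits(tree, "phylo")) {
    tree <- ape::unroot(tree)
    ut <- utree(tree$edge, length(tree$tip.label),
                normalize_taxon(tree$tip.label))
  } else if (is.list(tree) && !is.null(tree$n_tip)) {
    ut <- tree
  } else stop("expected a phylo or internal tree object")
  if (!is.null(taxa)) {
    if (!setequal(ut$tip_label, taxa))
      stop("tree tips do not match matrix taxa (",
           paste(utils::head(c(setdiff(taxa, ut$tip_label),
                               setdiff(ut$tip_label, taxa)), 3),
                 collapse = ", "), ")")
  }
  ut
}

as_phylo <- function(ut) {
  if (inherits(ut, "phylo")) return(ut)
  txt <- utree_newick(ut)
  phy <- ape::read.tree(text = txt)
  phy$tip.label <- gsub("_", " ", phy$tip.label, fixed = TRUE)
  phy
}

utree_newick <- function(ut) {
  n <- ut$n_tip
  labels <- gsub(" ", "_", ut$tip_label, fixed = TRUE)
  if (n == 1L) return(paste0(labels, ";"))
  if (n == 2L) return(paste0("(", labels[1], ",", labels[2], ");"))
  adj <- utree_adjacency(ut)
  root <- n + 1L
  sub <- function(v, from) {
    if (v <= n) return(labels[v])
    kids <- setdiff(adj[[v]], from)
    paste0("(", paste(vapply(kids, sub, character(1), from = v),
                      collapse = ","), ")")
  }
  kids <- adj[[root]]
  paste0("(", paste(vapply(kids, sub, character(1), from = root),
                    collapse = ","), ");")
}

utree_adjacency <- function(ut) {
  N <- max(ut$edge)
  adj <- vector("list", N)
  for (i in seq_len(nrow(ut$edge))) {
    a <- ut$edge[i, 1]; b <- ut$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# orientation from internal root n_tip+1: returns parent vector and a
# children-before-parents node order
utree_orient <- function(ut, root = ut$n_tip + 1L) {
  N <- max(ut$edge)
  adj <- utree_adjacency(ut)
  parent <- integer(N)
  order <- integer(0)
  stack <- root
  parent[root] <- 0L
  seen <- logical(N)
  seen[root] <- TRUE
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE
      parent[w] <- v
      stack <- c(stack, w)
    }
  }
  list(parent = parent, order = rev(pre), adj = adj)
}

# --- splits ----------------------------------------------------------------

# Non-trivial splits of a utree as canonical keys over a reference taxon
# order. Each split is the set of reference indices on the side NOT
# containing reference taxon 1, sorted, pasted with ",".
utree_splits <- function(ut, ref_taxa) {
  map <- match(ut$tip_label, ref_taxa)
  if (anyNA(map)) stop("tree tips not in reference taxa")
  n <- ut$n_tip
  N <- max(ut$edge)
  if (N <= n + 1L) return(character(0))
  ori <- utree_orient(ut)
  below <- vector("list", N)
  for (v in ori$order) {
    if (v <= n) below[[v]] <- map[v]
    else {
      kids <- which(ori$parent == v)
      below[[v]] <- sort(unlist(below[kids]))
    }
  }
  root <- n + 1L
  keys <- character(0)
  for (v in seq_len(N)) {
    if (v <= n || v == root) next
    keys <- c(keys, canonical_split(below[[v]], length(ref_taxa)))
  }
  unique(keys)
}

canonical_split <- function(side, n_total) {
  side <- sort(side)
  if (1L %in% side) side <- setdiff(seq_len(n_total), side)
  if (length(side) < 2L || length(side) > n_total - 2L) return(NA_character_)
  paste(side, collapse = ",")
}

split_key_tips <- function(key) as.integer(strsplit(key, ",")[[1]])

# Build a (possibly multifurcating) utree from a set of compatible canonical
# split keys over ref_taxa. Rooted mentally at taxon 1's attachment node.
utree_from_splits <- function(keys, ref_taxa) {
  n <- length(ref_taxa)
  keys <- keys[!is.na(keys)]
  clusters <- lapply(keys, split_key_tips)
  ord <- order(vapply(clusters, length, integer(1)), decreasing = TRUE)
  clusters <- clusters[ord]
  n_int <- length(clusters) + 1L
  root <- n + 1L
  cl_id <- if (length(clusters)) n + 1L + seq_along(clusters) else integer(0)
  parent <- integer(n + n_int)
  # parent of each cluster: smallest cluster strictly containing it
  for (i in seq_along(clusters)) {
    parent[cl_id[i]] <- root
    if (i > 1) {
      for (j in rev(seq_len(i - 1L))) {
        if (all(clusters[[i]] %in% clusters[[j]])) {
          parent[cl_id[i]] <- cl_id[j]
          break
        }
      }
    }
  }
  for (t in seq_len(n)) {
    parent[t] <- root
    if (t == 1L) next
    best <- 0L; best_size <- Inf
    for (i in seq_along(clusters)) {
      if (t %in% clusters[[i]] && length(clusters[[i]]) < best_size) {
        best <- cl_id[i]; best_size <- length(clusters[[i]])
      }
    }
    if (best > 0L) parent[t] <- best
  }
  edge <- cbind(parent[-root], seq_len(n + n_int)[-root])
  utree(edge, n, ref_taxa)
}

# --- enumeration and random topologies -------------------------------------

.topology_cache <- new.env(parent = emptyenv())

# All unrooted binary topologies on tips 1..n (edge matrices), n <= 9.
enumerate_topologies <- function(n) {
  stopifnot(n >= 3L, n <= 9L)
  key <- as.character(n)
  if (!is.null(.topology_cache[[key]])) return(.topology_cache[[key]])
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2,
                 byrow = TRUE)
  trees <- list(base)
  k <- 3L
  while (k < n) {
    k <- k + 1L
    new_internal <- n + k - 2L
    out <- vector("list", length(trees) * (2L * k - 5L))
    idx <- 0L
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        idx <- idx + 1L
        out[[idx]] <- insert_tip_global(tr, e, k, new_internal)
      }
    }
    trees <- out
  }
  .topology_cache[[key]] <- trees
  trees
}

# insert tip `tip` on edge e of an edge matrix that already uses final ids
insert_tip_global <- function(edge, e, tip, new_internal) {
  u <- edge[e, 1]; v <- edge[e, 2]
  edge[e, ] <- c(u, new_internal)
  rbind(edge, c(new_internal, v), c(new_internal, tip))
}

# Insert a new tip into a self-contained utree with k tips (ids re-packed so
# tips stay 1..k+1 and internals follow).
utree_insert_tip <- function(ut, edge_idx, new_label) {
  k <- ut$n_tip
  remap <- function(x) ifelse(x > k, x + 1L, x)
  edge <- cbind(remap(ut$edge[, 1]), remap(ut$edge[, 2]))
  new_tip <- k + 1L
  new_internal <- 2L * k
  u <- edge[edge_idx, 1]; v <- edge[edge_idx, 2]
  edge[edge_idx, ] <- c(u, new_internal)
  edge <- rbind(edge, c(new_internal, v), c(new_internal, new_tip))
  utree(edge, k + 1L, c(ut$tip_label, new_label))
}

triplet_utree <- function(labels) {
  utree(matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2, byrow = TRUE), 3L,
        labels)
}

# Uniform random unrooted binary topology via random stepwise insertion
# (uniform over topologies because each topology corresponds to exactly one
# insertion-edge sequence for a fixed addition order).
random_topology <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  ut <- triplet_utree(labels[1:3])
  for (k in seq_len(n - 3L) + 3L) {
    e <- sample.int(nrow(ut$edge), 1L)
    ut <- utree_insert_tip(ut, e, labels[k])
  }
  ut
}

# --- branch-swap neighborhoods ---------------------------------------------

# node membership of the component containing `keep` after removing edge
# (keep, avoid)
component_nodes <- function(adj, keep, avoid) {
  comp <- logical(length(adj))
  comp[keep] <- TRUE
  stack <- keep
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[x]]) if (w != avoid && !comp[w]) {
      comp[w] <- TRUE; stack <- c(stack, w)
    }
  }
  comp
}

# component edges after removing edge (drop_u, drop_v), with the degree-2
# endpoint drop_u suppressed. list(edges) or list(single = tip id).
bisect_component <- function(adj, edge, drop_u, drop_v, n_tip) {
  if (drop_u <= n_tip) return(list(single = drop_u))
  nb <- setdiff(adj[[drop_u]], drop_v)   # the two remaining neighbors
  comp <- component_nodes(adj, drop_u, drop_v)
  keep <- comp[edge[, 1]] & comp[edge[, 2]]
  ed <- edge[keep, , drop = FALSE]
  at_u <- (ed[, 1] == drop_u) | (ed[, 2] == drop_u)
  ed <- rbind(ed[!at_u, , drop = FALSE], nb)
  list(edges = ed)
}

# component edges with the cut endpoint kept (for SPR pruned subtrees)
raw_component <- function(adj, edge, keep, avoid) {
  comp <- component_nodes(adj, keep, avoid)
  keep_e <- comp[edge[, 1]] & comp[edge[, 2]]
  edge[keep_e, , drop = FALSE]
}

# subdivide row i of `edges` (a-b) with node w: a-w, w-b
subdivide_edge <- function(edges, i, w) {
  b <- edges[i, 2]
  edges[i, 2] <- w
  rbind(edges, c(w, b))
}

# All TBR reconnections for the bisection at edge (u,v). New connector nodes
# reuse ids u and v.
tbr_reconnect <- function(compA, compB, u, v) {
  out <- list()
  nA <- if (is.null(compA$single)) nrow(compA$edges) else 1L
  nB <- if (is.null(compB$single)) nrow(compB$edges) else 1L
  for (ia in seq_len(nA)) {
    if (is.null(compA$single)) {
      edA <- subdivide_edge(compA$edges, ia, u); pa <- u
    } else { edA <- NULL; pa <- compA$single }
    for (ib in seq_len(nB)) {
      if (is.null(compB$single)) {
        edB <- subdivide_edge(compB$edges, ib, v); pb <- v
      } else { edB <- NULL; pb <- compB$single }
      out[[length(out) + 1L]] <- rbind(edA, edB, c(pa, pb))
    }
  }
  out
}

# SPR regrafts for cutting edge (u,v) and pruning the v-side subtree intact:
# u is suppressed in the remaining tree, v keeps its open slot and is tied
# to a new node u subdividing each remaining edge (or directly to a lone
# remaining tip).
spr_regraft <- function(adj, edge, u, v, n_tip) {
  rem <- bisect_component(adj, edge, u, v, n_tip)
  pruned <- raw_component(adj, edge, v, u)
  out <- list()
  if (!is.null(rem$single)) return(out)  # single attachment = original tree
  for (i in seq_len(nrow(rem$edges))) {
    edR <- subdivide_edge(rem$edges, i, u)
    out[[length(out) + 1L]] <- rbind(edR, pruned, c(u, v))
  }
  out
}

# renumber internal node ids to n_tip+1..N contiguously (suppression can
# leave gaps, and downstream code roots trees at node n_tip+1)
repack_edges <- function(edge, n_tip) {
  ids <- sort(unique(as.integer(edge)))
  internals <- ids[ids > n_tip]
  if (length(internals) && identical(internals,
        seq.int(n_tip + 1L, n_tip + length(internals)))) return(edge)
  map <- integer(max(ids))
  map[ids[ids <= n_tip]] <- ids[ids <= n_tip]
  map[internals] <- n_tip + seq_along(internals)
  matrix(map[edge], ncol = 2)
}

# Neighborhood of an unrooted binary utree under a swap move.
# swap: "nni", "spr" or "tbr". Returns a list of utrees.
utree_neighborhood <- function(ut, swap = c("tbr", "spr", "nni")) {
  swap <- match.arg(swap)
  if (swap == "nni") return(nni_neighbors(ut))
  adj <- utree_adjacency(ut)
  out <- list()
  n <- ut$n_tip
  for (e in seq_len(nrow(ut$edge))) {
    u <- ut$edge[e, 1]; v <- ut$edge[e, 2]
    if (swap == "tbr") {
      compU <- bisect_component(adj, ut$edge, u, v, n)
      compV <- bisect_component(adj, ut$edge, v, u, n)
      news <- tbr_reconnect(compU, compV, u, v)
    } else {
      news <- c(spr_regraft(adj, ut$edge, u, v, n),
                spr_regraft(adj, ut$edge, v, u, n))
    }
    for (ed in news)
      out[[length(out) + 1L]] <- utree(repack_edges(ed, n), n, ut$tip_label)
  }
  out
}

nni_neighbors <- function(ut) {
  n <- ut$n_tip
  adj <- utree_adjacency(ut)
  out <- list()
  for (e in seq_len(nrow(ut$edge))) {
    u <- ut$edge[e, 1]; v <- ut$edge[e, 2]
    if (u <= n || v <= n) next
    nb_u <- setdiff(adj[[u]], v)
    nb_v <- setdiff(adj[[v]], u)
    for (j in 1:2) {
      ed <- ut$edge
      a <- nb_u[2]; b <- nb_v[j]
      ed <- swap_endpoint(ed, a, u, v)
      ed <- swap_endpoint(ed, b, v, u)
      out[[length(out) + 1L]] <- utree(ed, n, ut$tip_label)
    }
  }
  out
}

swap_endpoint <- function(edge, leafside, from, to) {
  i <- which((edge[, 1] == leafside & edge[, 2] == from) |
             (edge[, 2] == leafside & edge[, 1] == from))[1]
  edge[i, ] <- c(to, leafside)
  edge
}

utree_key <- function(ut, ref_taxa, drop_splits = character(0)) {
  keys <- setdiff(utree_splits(ut, ref_taxa), drop_splits)
  paste(sort(keys), collapse = "|")
}
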