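# lowest set bit -> state, as a lookup over masks 0..1023
.LOWBIT <- vapply(0:1023, function(m) {
  if (m == 0L) return(NA_integer_)
  which(bitwAnd(bitwShiftR(m, 0:9), 1L) == 1L)[1L] - 1L
}, integer(1))

# Leaf state sets ready for the downpass: rows in `tip_labels` order;
# missing/inapplicable cells become the set of states observed in that
# character (equivalent for tree length, and it keeps reconstruction sets
# tight); characters with no observation at all become state 0 everywhere.
prep_tip_states <- function(matrix, tip_labels) {
  idx <- match(normalize_taxon(tip_labels), matrix$taxa)
  if (anyNA(idx))
    stop("tree tips not in matrix: ",
         paste(utils::head(tip_labels[is.na(idx)], 3), collapse = ", "))
  st <- matrix$states[idx, , drop = FALSE]
  obs <- vapply(seq_len(ncol(st)), function(j) mask_union(st[, j]),
                integer(1))
  obs[obs == 0L] <- 1L
  for (j in seq_len(ncol(st))) {
    empty <- st[, j] == 0L
    if (any(empty)) st[empty, j] <- obs[j]
  }
  st
}

run_fitch <- function(ut, matrix) {
  if (n_char(matrix) == 0L) stop("matrix has no characters")
  tip_state <- prep_tip_states(matrix, ut$tip_label)
  ana <- fitch_analyze_cpp(ut$edge, ut$n_tip, tip_state)
  ana$tip_state <- tip_state
  ana
}

#' Fitch parsimony length of a tree
#'
#' Scores an unrooted tree against a morphological matrix under equal-weights
#' Fitch (unordered-state) parsimony, via the Hartigan set recursion, which
#' also handles multifurcating trees exactly. Polymorphic cells enter the
#' downpass as their observed state set (uncertainty semantics, no
#' within-terminal step); missing and inapplicable cells are free to take any
#' state observed for that character. The result does not depend on how the
#' unrooted tree is (arbitrarily) rooted for computation.
#'
#' @param tree an [ape::phylo] tree whose tips are exactly the matrix taxa.
#' @param matrix a [char_matrix()].
#' @return An object of class `mp_fitch` with elements `total` (weighted tree
#'   length in steps), `steps` (integer per-character steps) and the node
#'   state sets needed by [ancestral_state_sets()] and
#'   [map_synapomorphies()]. `tidy()` gives a per-character table, `glance()`
#'   a one-row summary including ensemble CI and RI.
#' @examples
#' m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_length(tr, m)$total
#' @export
fitch_length <- function(tree, matrix) {
  stopifnot(inherits(matrix, "char_matrix"))
  ut <- as_utree(tree, taxa = matrix$taxa)
  ana <- run_fitch(ut, matrix)
  structure(
    list(total = sum(matrix$characters$weight * ana$steps),
         steps = as.integer(ana$steps),
         down = ana$down, up = ana$up, final = ana$final,
         parent = ana$parent, tree = ut, matrix = matrix),
    class = "mp_fitch")
}

#' @export
print.mp_fitch <- function(x, ...) {
  cat("Fitch parsimony fit: length", x$total, "steps over",
      length(x$steps), "characters\n")
  invisible(x)
}

#' @rdname fitch_length
#' @param x an `mp_fitch` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.mp_fitch <- function(x, ...) {
  b <- character_bounds(x$matrix)
  s <- x$steps
  dplyr::mutate(
    b,
    steps = s,
    ci = dplyr::if_else(s == 0L, 1, m / pmax(s, 1L)),
    ri = dplyr::if_else(g == m, NA_real_, (g - s) / (g - m)))
}

#' @rdname fitch_length
#' @exportS3Method generics::glance
glance.mp_fitch <- function(x, ...) {
  ens <- ensemble_fit(x$tree, x$matrix)
  tibble::tibble(total_steps = x$total, n_char = length(x$steps),
                 ci = ens$ci, ri = ens$ri)
}

#' Per-character parsimony bounds
#'
#' For each character, the minimum conceivable number of steps on any tree
#' (`m`) and the maximum conceivable number (`g`, the steps on a completely
#' unresolved bush). With polymorphic cells, `m` resolves uncertainty so as
#' to use the fewest distinct states (smallest state set intersecting every
#' scored cell, minus one) and `g` resolves it in favour of the most frequent
#' single state, the convention that makes the retention index reproducible.
#' Characters with fewer than two distinct observed states get `m = g = 0`.
#'
#' @param matrix a [char_matrix()].
#' @return A tibble with columns `character`, `m`, `g` and `informative`
#'   (`g > m`; such characters can discriminate among trees).
#' @export
character_bounds <- function(matrix) {
  stopifnot(inherits(matrix, "char_matrix"))
  nc <- n_char(matrix)
  m <- integer(nc); g <- integer(nc)
  for (j in seq_len(nc)) {
    col <- matrix$states[, j]
    col <- col[col != 0L]
    union_mask <- mask_union(col)
    if (length(col) == 0L || mask_size(union_mask) < 2L) next
    m[j] <- min_hitting_states(unique(col)) - 1L
    g[j] <- length(col) - max_modal_count(col)
  }
  tibble::tibble(character = seq_len(nc), m = m, g = g,
                 informative = g > m)
}

# smallest number of states such that every cell's set contains one of them
min_hitting_states <- function(masks) {
  states <- mask_states(mask_union(masks))
  for (size in seq_along(states)) {
    for (pick in utils::combn(states, size, simplify = FALSE)) {
      t_mask <- states_mask(pick)
      if (all(bitwAnd(masks, t_mask) > 0L)) return(size)
    }
  }
  length(states)
}

# largest achievable count of a single state when each cell commits to one
# of its states
max_modal_count <- function(masks) {
  single <- mask_size(masks) == 1L
  cnt <- integer(MAX_STATES)
  for (s in masks[single]) cnt[.LOWBIT[s + 1L] + 1L] <- cnt[.LOWBIT[s + 1L] + 1L] + 1L
  poly <- masks[!single]
  best <- 0L
  for (k in seq_len(MAX_STATES)) {
    extra <- if (length(poly)) sum(bitwAnd(poly, bitwShiftL(1L, k - 1L)) > 0L) else 0L
    best <- max(best, cnt[k] + extra)
  }
  best
}

#' Ensemble consistency and retention indices
#'
#' The homoplasy statistics conventionally printed with a parsimony result:
#' ensemble CI = sum(m)/sum(s) and ensemble RI = (sum(g) - sum(s)) /
#' (sum(g) - sum(m)), with per-character bounds from [character_bounds()] and
#' observed steps `s` from [fitch_length()]. By default all characters are
#' included, the convention of the usual parsimony software reports; set
#' `include_uninformative = FALSE` for the informative-only variant.
#'
#' @inheritParams fitch_length
#' @param include_uninformative include parsimony-uninformative characters in
#'   the sums (default `TRUE`).
#' @return A one-row tibble: `ci`, `ri`, `total_steps`, `min_steps`,
#'   `max_steps`, `n_char`. `ri` is `NA` (with a warning) when
#'   sum(g) = sum(m), where it is undefined.
#' @examples
#' m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' ensemble_fit(ape::read.tree(text = "((A,B),(C,D));"), m)
#' @export
ensemble_fit <- function(tree, matrix, include_uninformative = TRUE) {
  ut <- as_utree(tree, taxa = matrix$taxa)
  ana <- run_fitch(ut, matrix)
  b <- character_bounds(matrix)
  keep <- if (include_uninformative) rep(TRUE, nrow(b)) else b$informative
  S <- sum(ana$steps[keep]); M <- sum(b$m[keep]); G <- sum(b$g[keep])
  ci <- if (S == 0) 1 else M / S
  if (G == M) {
    warning("retention index undefined: sum(g) equals sum(m)")
    ri <- NA_real_
  } else ri <- (G - S) / (G - M)
  tibble::tibble(ci = ci, ri = ri, total_steps = sum(ana$steps * matrix$characters$weight),
                 min_steps = M, max_steps = G, n_char = sum(keep))
}

#' Ancestral state sets under most-parsimonious reconstruction
#'
#' For every node and character, the set of states that node takes in at
#' least one most-parsimonious reconstruction (the MPR set), from the Fitch
#' final pass generalised to arbitrary rootings via directional state sets.
#'
#' @inheritParams fitch_length
#' @return A tibble with one row per (node, character): `node` (tip ids
#'   first, then internal ids of the computational rooting), `taxon` (label
#'   for tips, `NA` for internal nodes), `clade` (comma-separated tip labels
#'   below the node), `character` (1-based) and `states` (e.g. `"0"` or
#'   `"02"`).
#' @export
ancestral_state_sets <- function(tree, matrix) {
  fit <- if (inherits(tree, "mp_fitch")) tree else fitch_length(tree, matrix)
  ut <- fit$tree
  fin <- fit$final
  N <- nrow(fin)
  below <- node_tipsets(ut)
  states_chr <- apply(fin, c(1, 2), function(m)
    paste0(mask_states(m), collapse = ""))
  tibble::tibble(
    node = rep(seq_len(N), times = ncol(fin)),
    taxon = rep(c(ut$tip_label, rep(NA, N - ut$n_tip)), times = ncol(fin)),
    clade = rep(vapply(below, function(s)
      paste(sort(ut$tip_label[s]), collapse = ","), character(1)),
      times = ncol(fin)),
    character = rep(seq_len(ncol(fin)), each = N),
    states = as.vector(states_chr))
}

node_tipsets <- function(ut) {
  ori <- utree_orient(ut)
  N <- max(ut$edge)
  below <- vector("list", N)
  for (v in ori$order) {
    below[[v]] <- if (v <= ut$n_tip) v else
      sort(unlist(below[which(ori$parent == v)]))
  }
  below
}

# Exact subtree cost per (node, state, character): cost_v(a) is the minimum
# number of changes in the subtree below v when v is fixed to state a
# (min_b over children of cost_child(b) + [a != b] telescopes to
# min(cost_child(a), min_child + 1)).
character_cost_dp <- function(fit, ori) {
  N <- nrow(fit$down); nc <- ncol(fit$down); n <- fit$tree$n_tip
  cost <- vector("list", N)
  for (v in ori$order) {
    if (v <= n) {
      set <- fit$down[v, ]
      cv <- matrix(0L, MAX_STATES, nc)
      for (a in seq_len(MAX_STATES))
        cv[a, ] <- as.integer(bitwAnd(set, bitwShiftL(1L, a - 1L)) == 0L)
      cost[[v]] <- cv
      next
    }
    kids <- which(ori$parent == v)
    acc <- matrix(0L, MAX_STATES, nc)
    for (w in kids) {
      cw <- cost[[w]]
      minw <- do.call(pmin, asplit(cw, 1))
      for (a in seq_len(MAX_STATES))
        acc[a, ] <- acc[a, ] + pmin(cw[a, ], minw + 1L)
    }
    cost[[v]] <- acc
  }
  cost
}

# DELTRAN: top-down, keeping the parent's state on every branch where doing
# so is still globally optimal (changes delayed as far from the root as
# possible), from the exact cost tables.
resolve_deltran <- function(fit, ori) {
  cost <- character_cost_dp(fit, ori)
  N <- nrow(fit$down); nc <- ncol(fit$down)
  s <- matrix(NA_integer_, N, nc)
  for (v in rev(ori$order)) {   # parents first
    cv <- cost[[v]]
    amin <- max.col(-t(cv), ties.method = "first") - 1L
    if (ori$parent[v] == 0L) {
      s[v, ] <- amin
      next
    }
    a <- s[ori$parent[v], ]
    ca <- cv[cbind(a + 1L, seq_len(nc))]
    minv <- cv[cbind(amin + 1L, seq_len(nc))]
    if (v <= fit$tree$n_tip) {
      # a tip's own state must come from its observed set (its DP cost
      # already charges the change to the terminal branch)
      s[v, ] <- ifelse(ca == minv, a, amin)
    } else {
      s[v, ] <- ifelse(ca <= minv + 1L, a, amin)
    }
  }
  s
}

# single-state-per-node resolution from downpass sets (Farris backtracking:
# keep the parent's state when the downpass set allows it, otherwise take
# from the downpass set) -- the classical ACCTRAN resolution
resolve_assignment <- function(sets, parent, order) {
  N <- nrow(sets)
  s <- matrix(NA_integer_, N, ncol(sets))
  for (v in rev(order)) {       # preorder: parents first
    if (parent[v] == 0L) {
      s[v, ] <- .LOWBIT[sets[v, ] + 1L]
    } else {
      su <- s[parent[v], ]
      keep <- bitwAnd(bitwShiftL(1L, su), sets[v, ]) > 0L
      s[v, ] <- ifelse(keep, su, .LOWBIT[sets[v, ] + 1L])
    }
  }
  s
}

#' Map character-state changes onto branches
#'
#' Lists the state changes implied by most-parsimonious reconstructions on
#' each branch: the synapomorphy diagnosis of a tree. ACCTRAN pulls
#' ambiguous changes toward the root (favouring reversal), DELTRAN delays
#' them (favouring parallelism); `"unambiguous"` (the default) lists only
#' changes that are forced on the branch in every reconstruction (the
#' directional state sets on its two sides are disjoint) with identical
#' endpoints under both resolutions.
#'
#' @inheritParams fitch_length
#' @param mode `"unambiguous"`, `"acctran"` or `"deltran"`.
#' @return A tibble with one row per (branch, character) change: `node` (the
#'   child node of the branch), `clade` (comma-separated tip labels below the
#'   branch), `character` (1-based index), `from`, `to` (state integers) and
#'   `unambiguous` (logical).
#' @examples
#' m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' map_synapomorphies(tr, m)
#' @export
map_synapomorphies <- function(tree, matrix,
                               mode = c("unambiguous", "acctran", "deltran")) {
  mode <- match.arg(mode)
  fit <- if (inherits(tree, "mp_fitch")) tree else fitch_length(tree, matrix)
  ut <- fit$tree
  if (max(ut$edge) - ut$n_tip != ut$n_tip - 2L)
    stop("synapomorphy mapping requires a binary (fully resolved) tree")
  ori <- utree_orient(ut)
  acc <- resolve_assignment(fit$down, ori$parent, ori$order)
  del <- resolve_deltran(fit, ori)
  below <- node_tipsets(ut)
  nc <- ncol(fit$down)
  rows <- list()
  for (v in seq_len(nrow(fit$down))) {
    u <- ori$parent[v]
    if (u == 0L) next
    # a change is forced on the branch iff the MPR sets of its endpoints
    # share no state (then every reconstruction changes here)
    forced <- bitwAnd(fit$final[v, ], fit$final[u, ]) == 0L
    ch_acc <- acc[u, ] != acc[v, ]
    ch_del <- del[u, ] != del[v, ]
    unamb <- forced & ch_acc & ch_del &
      acc[u, ] == del[u, ] & acc[v, ] == del[v, ]
    use <- switch(mode, unambiguous = unamb, acctran = ch_acc,
                  deltran = ch_del)
    if (!any(use)) next
    src <- switch(mode, deltran = del, acc)
    idx <- which(use)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      node = v,
      clade = paste(sort(ut$tip_label[below[[v]]]), collapse = ","),
      character = idx,
      from = src[u, idx], to = src[v, idx],
      unambiguous = unamb[idx])
  }
  if (!length(rows))
    return(tibble::tibble(node = integer(), clade = character(),
                          character = integer(), from = integer(),
                          to = integer(), unambiguous = logical()))
  dplyr::arrange(dplyr::bind_rows(rows), character, clade)
}

# splits of branches whose minimum length over all MPRs is zero (the
# "collapse rule 1" convention for identifying topologies in tree pools)
zero_length_splits <- function(fit) {
  ut <- fit$tree
  ori <- utree_orient(ut)
  below <- node_tipsets(ut)
  n <- ut$n_tip
  keys <- character(0)
  for (v in seq_len(nrow(fit$down))) {
    if (v <= n || ori$parent[v] == 0L) next
    # min branch length is 0 iff the endpoint MPR sets intersect for every
    # character (some reconstruction is changeless on the branch)
    if (all(bitwAnd(fit$final[v, ], fit$final[ori$parent[v], ]) > 0L)) {
      key <- canonical_split(match(ut$tip_label[below[[v]]],
                                   fit$matrix$taxa), n)
      keys <- c(keys, key)
    }
  }
  keys[!is.na(keys)]
}
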