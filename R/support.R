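clade_key <- function(tips, taxa) {
  idx <- match(normalize_taxon(tips), taxa)
  if (anyNA(idx)) stop("clade uses unknown taxa: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  canonical_split(idx, length(taxa))
}

clade_list <- function(clades, taxa) {
  if (is.null(clades)) return(NULL)
  if (is.character(clades)) clades <- list(clades)
  if (is.null(names(clades)) || any(names(clades) == ""))
    names(clades) <- vapply(clades, function(x)
      paste(sort(normalize_taxon(x)), collapse = "+"), character(1))
  clades
}

tree_has_split <- function(ut, key, taxa) key %in% utree_splits(ut, taxa)

#' Bremer decay indices
#'
#' The Bremer (decay) support of a clade is the extra length of the best
#' tree that lacks it: (minimum length over trees without the clade's
#' bipartition) minus the optimal length. Computed by reverse-constrained
#' search -- exactly, by enumeration over all topologies, for up to 9 taxa,
#' and by constrained heuristic search (random additions plus branch
#' swapping that never accepts a tree containing the clade) above that.
#'
#' @param matrix a [char_matrix()].
#' @param pool an `mp_tree_pool` at the optimal length (from
#'   [replicated_search()], [driven_search()] or [exhaustive_search()]).
#' @param clades clades to score: a list of character vectors of taxon
#'   labels (optionally named). Defaults to every internal branch of the
#'   strict consensus of `pool`.
#' @param config an [search_config()] controlling the effort of each
#'   constrained heuristic search (ignored under method `"enumerate"`).
#' @param method `"auto"` enumerates exactly for up to 9 taxa and falls back
#'   to constrained search above; `"enumerate"` and `"constrained"` force a
#'   route (useful for cross-checking the two).
#' @return A support table tibble: `clade`, `tips`, `bremer`,
#'   `bootstrap_pct` (`NA` here; see [bootstrap_support()]).
#' @export
bremer_support <- function(matrix, pool, clades = NULL,
                           config = search_config(n_replications = 10,
                                                  trees_saved_per_rep = 5,
                                                  target_hits = 50),
                           method = c("auto", "enumerate", "constrained")) {
  method <- match.arg(method)
  taxa <- matrix$taxa
  clades <- clade_list(clades, taxa)
  if (is.null(clades)) {
    keys <- common_split_keys(pool)
    clades <- lapply(keys, function(k) taxa[split_key_tips(k)])
    names(clades) <- vapply(clades, function(x)
      paste(sort(x), collapse = "+"), character(1))
  }
  keys <- vapply(clades, clade_key, character(1), taxa = taxa)
  L <- pool$best_length
  bremer <- vapply(seq_along(keys), function(i) {
    best_lacking <- best_length_lacking(matrix, keys[i], pool, config,
                                        method)
    as.numeric(best_lacking - L)
  }, numeric(1))
  new_support_table(tibble::tibble(clade = names(clades),
                 tips = vapply(clades, function(x)
                   paste(sort(normalize_taxon(x)), collapse = ","),
                   character(1)),
                 bremer = bremer, bootstrap_pct = NA_real_))
}

new_support_table <- function(x) {
  class(x) <- unique(c("mp_support_table", class(x)))
  x
}

best_length_lacking <- function(matrix, key, pool, config,
                                method = "auto") {
  n <- n_taxa(matrix)
  prep <- matrix_prep(matrix)
  if (method == "enumerate" && n > 9L)
    stop("enumeration route limited to 9 taxa")
  if (method != "constrained" && n <= 9L) {
    topo <- enumerate_topologies(n)
    sc <- fitch_batch_cpp(topo, n, prep$tip_state, prep$weights)
    ord <- order(sc)
    for (i in ord) {
      ut <- utree(topo[[i]], n, matrix$taxa)
      present <- tree_has_split(ut, key, matrix$taxa)
      if (present && pool$collapse) {
        # a clade held only by a zero-minimum-length branch does not count
        fit <- fitch_length(as_utree(ut), matrix)
        present <- !key %in% zero_length_splits(fit)
      }
      if (!present) return(sc[i])
    }
    return(Inf)
  }
  reject <- function(ut) tree_has_split(ut, key, matrix$taxa)
  best <- Inf
  for (r in seq_len(config$n_replications)) {
    ut <- random_addition_utree(matrix, prep)
    if (reject(ut)) ut <- break_clade(ut, key, matrix$taxa, prep)
    if (is.null(ut) || reject(ut)) next
    p <- swap_search_impl(ut, matrix, prep, config$swap, 1L, FALSE,
                          reject = reject)
    best <- min(best, p$best_length)
  }
  best
}

# force a clade out of a tree: take the best NNI neighbor across the clade's
# branch that lacks the split
break_clade <- function(ut, key, taxa, prep) {
  nb <- nni_neighbors(ut)
  ok <- Filter(function(u) !tree_has_split(u, key, taxa), nb)
  if (!length(ok)) return(NULL)
  sc <- score_utrees(ok, prep)
  ok[[which.min(sc)]]
}

#' Absolute-frequency bootstrap supports
#'
#' Nonparametric bootstrap over characters: each pseudoreplicate resamples
#' the characters with replacement (to the original count), reruns a
#' reduced-effort heuristic search, and a clade's support is the percentage
#' of pseudoreplicates whose strict consensus contains it (TNT-style
#' "absolute frequencies", not group-present-minus-contradicted).
#'
#' @inheritParams bremer_support
#' @param n_pseudoreplicates number of bootstrap pseudoreplicates.
#' @param focal_clades clades to report (list of taxon-label vectors,
#'   optionally named); required, since tracking every split of every
#'   replicate is rarely wanted.
#' @param replicate_config an [search_config()] for the per-replicate
#'   search effort (default: 10 random additions, TBR, keep 10).
#' @param rng_seed optional seed for the resampling and searches.
#' @return A support table tibble: `clade`, `tips`, `bremer` (`NA` here),
#'   `bootstrap_pct` in 0-100.
#' @export
bootstrap_support <- function(matrix, focal_clades,
                              n_pseudoreplicates = 1000L,
                              replicate_config = search_config(
                                n_replications = 10, trees_saved_per_rep = 10,
                                target_hits = 50),
                              rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  stopifnot(n_pseudoreplicates >= 1L)
  taxa <- matrix$taxa
  clades <- clade_list(focal_clades, taxa)
  keys <- vapply(clades, clade_key, character(1), taxa = taxa)
  hitcount <- integer(length(keys))
  nc <- n_char(matrix)
  for (b in seq_len(n_pseudoreplicates)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    bm <- resample_characters(matrix, idx)
    pool <- replicated_search(bm, replicate_config)
    common <- common_split_keys(pool)
    hitcount <- hitcount + as.integer(keys %in% common)
  }
  new_support_table(tibble::tibble(
    clade = names(clades),
    tips = vapply(clades, function(x)
      paste(sort(normalize_taxon(x)), collapse = ","), character(1)),
    bremer = NA_real_,
    bootstrap_pct = 100 * hitcount / n_pseudoreplicates))
}

resample_characters <- function(matrix, idx) {
  char_matrix(matrix$states[, idx, drop = FALSE], taxa = matrix$taxa,
              inapplicable = matrix$inapplicable[, idx, drop = FALSE],
              characters = dplyr::mutate(matrix$characters[idx, ],
                                         index = dplyr::row_number()))
}

#' Taxon-deletion bootstrap experiment
#'
#' Removes the given taxa from the matrix and reruns [bootstrap_support()]
#' with identical settings -- the standard probe for whether poorly
#' preserved taxa are dragging a clade's support down.
#'
#' @inheritParams bootstrap_support
#' @param drop_taxa taxon labels to remove before the bootstrap (dropping a
#'   focal-clade member removes it from that clade).
#' @param ... passed on to [bootstrap_support()].
#' @return The support table tibble, with attribute `dropped_taxa`.
#' @export
taxon_deletion_experiment <- function(matrix, drop_taxa, focal_clades, ...) {
  drop_taxa <- normalize_taxon(drop_taxa)
  reduced <- if (length(drop_taxa)) drop_taxa_impl(matrix, drop_taxa) else matrix
  clades <- clade_list(focal_clades, matrix$taxa)
  clades <- lapply(clades, function(x) setdiff(normalize_taxon(x), drop_taxa))
  if (any(lengths(clades) < 2L))
    stop("a focal clade has fewer than 2 members after deletion")
  out <- bootstrap_support(reduced, clades, ...)
  attr(out, "dropped_taxa") <- drop_taxa
  out
}
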