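#' Protocol configuration
#'
#' Full settings for [run_protocol()], defaulting to the study protocol:
#' 1,000 random-addition replications with TBR and 10 trees saved each, a
#' 10,000-tree buffer, hit-driven continuation to 50 hits if the replicated
#' stage has not converged, a second TBR round on the retained trees, up to
#' two rogue taxa pruned, and Bremer plus absolute-frequency bootstrap
#' supports (1,000 pseudoreplicates; the replicate count is a package
#' default, chosen as the community standard, since protocols rarely print
#' it).
#'
#' @param search an [search_config()] for the main search.
#' @param driven_fallback continue with a hit-driven search when the
#'   replicated stage hit its best length fewer than `search$target_hits`
#'   times.
#' @param expand_max_trees buffer for the second swapping round (it may
#'   exceed the search buffer).
#' @param max_prune maximum rogue taxa to prune.
#' @param bootstrap_reps bootstrap pseudoreplicates (0 skips the bootstrap).
#' @param bootstrap_config per-pseudoreplicate search effort.
#' @param bremer_config effort for each reverse-constrained Bremer search.
#' @param focal_clades clades (list of taxon-label vectors) to report
#'   supports for; defaults to every clade of the strict consensus.
#' @param seed integer seed for the whole run.
#' @return A list of class `mp_protocol_config`.
#' @export
protocol_config <- function(search = search_config(),
                            driven_fallback = TRUE,
                            expand_max_trees = 100000L,
                            max_prune = 2L,
                            bootstrap_reps = 1000L,
                            bootstrap_config = search_config(
                              n_replications = 10, trees_saved_per_rep = 10,
                              target_hits = 50),
                            bremer_config = search_config(
                              n_replications = 10, trees_saved_per_rep = 5,
                              target_hits = 50),
                            focal_clades = NULL,
                            seed = 1L) {
  structure(list(search = search, driven_fallback = isTRUE(driven_fallback),
                 expand_max_trees = as.integer(expand_max_trees),
                 max_prune = as.integer(max_prune),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 bootstrap_config = bootstrap_config,
                 bremer_config = bremer_config,
                 focal_clades = focal_clades, seed = as.integer(seed)),
            class = "mp_protocol_config")
}

read_matrix_auto <- function(path) {
  head <- paste(readLines(path, n = 20, warn = FALSE), collapse = "\n")
  if (grepl("#NEXUS", head, ignore.case = TRUE)) read_nexus(path)
  else if (grepl("xread", head, ignore.case = TRUE)) read_tnt(path)
  else stop("cannot identify matrix format (expected NEXUS or TNT xread): ",
            path)
}

#' Run the full parsimony protocol
#'
#' One-command orchestration of the whole analysis: replicated heuristic
#' search (with hit-driven continuation if it has not converged), a second
#' round of branch swapping on the retained trees, strict consensus, rogue
#' pruning, Bremer and bootstrap supports, ensemble fit statistics and
#' synapomorphy mapping. All stages are seeded and the run manifest makes
#' the outputs reproducible.
#'
#' @param matrix a [char_matrix()], or a path to a NEXUS / TNT file.
#' @param config an [protocol_config()].
#' @param out_dir optional directory; when given, writes `mpts.tre`,
#'   `consensus.tre`, `reduced_consensus.tre`, `supports.tsv`,
#'   `charfit.tsv`, `synapomorphies.tsv` and `manifest.json`.
#' @return An object of class `mp_run_bundle`: list with `matrix`, `pool`,
#'   `consensus`, `rogue`, `supports`, `charfit`, `ensemble`,
#'   `synapomorphies`, `manifest`.
#' @examples
#' set.seed(42)
#' sim <- simulate_characters(simulate_tree(7), n_char = 25,
#'                            expected_changes = 2)
#' cfg <- protocol_config(search = search_config(n_replications = 3,
#'     trees_saved_per_rep = 5, target_hits = 3), bootstrap_reps = 20,
#'   bootstrap_config = search_config(n_replications = 2,
#'     trees_saved_per_rep = 2, target_hits = 2), seed = 1)
#' bundle <- run_protocol(sim$matrix, cfg)
#' report(bundle)
#' @export
run_protocol <- function(matrix, config = protocol_config(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  stage <- "read_matrix"
  timings <- list()
  bundle <- list()
  tick <- function() {
    t1 <- Sys.time()
    timings[[stage]] <<- as.numeric(difftime(t1, t0, units = "secs"))
    t0 <<- t1
  }
  run_stage <- function(name, expr) {
    stage <<- name
    out <- tryCatch(expr, error = function(e)
      stop("protocol stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    tick()
    out
  }

  src <- if (is.character(matrix)) matrix else "<in-memory matrix>"
  cm <- run_stage("read_matrix",
                  if (is.character(matrix)) read_matrix_auto(matrix)
                  else matrix)
  stopifnot(inherits(cm, "char_matrix"))
  set.seed(config$seed)

  pool <- run_stage("replicated_search",
                    replicated_search(cm, config$search))
  hits <- sum(pool$diagnostics$rep_best == pool$best_length)
  if (config$driven_fallback && hits < config$search$target_hits) {
    pool2 <- run_stage("driven_search", driven_search(cm, config$search))
    if (pool2$best_length < pool$best_length) pool <- pool2
    else if (pool2$best_length == pool$best_length) {
      pool <- merge_pools(pool, pool2, cm, config$search)
      pool$diagnostics$hits <- pool2$diagnostics$hits
    }
  }
  pool <- run_stage("expand_pool",
                    expand_pool_tbr(pool, cm, config$expand_max_trees))
  cons <- run_stage("strict_consensus", strict_consensus(pool))
  rogue <- run_stage("rogue_prune", rogue_prune(pool, config$max_prune))

  clades <- config$focal_clades
  if (is.null(clades)) {
    keys <- common_split_keys(pool)
    clades <- lapply(keys, function(k) cm$taxa[split_key_tips(k)])
  }
  supports <- NULL
  if (length(clades)) {
    brem <- run_stage("bremer",
                      bremer_support(cm, pool, clades,
                                     config$bremer_config))
    supports <- brem
    if (config$bootstrap_reps > 0) {
      boot <- run_stage("bootstrap",
                        bootstrap_support(cm, clades,
                                          config$bootstrap_reps,
                                          config$bootstrap_config))
      supports$bootstrap_pct <- boot$bootstrap_pct[
        match(supports$tips, boot$tips)]
    }
  } else {
    supports <- tibble::tibble(clade = character(), tips = character(),
                               bremer = numeric(), bootstrap_pct = numeric())
  }
  class(supports) <- c("mp_support_table", class(supports))

  fit <- run_stage("ensemble_fit", fitch_length(pool_trees(pool)[[1]], cm))
  ens <- glance(fit)
  charfit <- tidy(fit)
  syn <- run_stage("synapomorphies",
                   map_synapomorphies(fit, cm, mode = "unambiguous"))

  manifest <- list(
    input = src,
    matrix_digest = rlang::hash(list(cm$taxa, cm$states)),
    n_taxa = n_taxa(cm), n_char = n_char(cm),
    seed = config$seed,
    search = unclass(config$search),
    bootstrap_reps = config$bootstrap_reps,
    best_length = pool$best_length,
    n_mpts = length(pool$trees),
    pruned_taxa = rogue$pruned$taxon,
    ci = ens$ci, ri = ens$ri,
    timings_sec = timings)

  bundle <- structure(
    list(matrix = cm, pool = pool, consensus = cons, rogue = rogue,
         supports = supports, charfit = charfit, ensemble = ens,
         synapomorphies = syn, manifest = manifest),
    class = "mp_run_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  ape::write.tree(pool_trees(bundle$pool), p("mpts.tre"))
  ape::write.tree(bundle$consensus, p("consensus.tre"))
  ape::write.tree(bundle$rogue$reduced_consensus, p("reduced_consensus.tre"))
  wtsv <- function(x, f) utils::write.table(
    x, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(as.data.frame(bundle$supports), "supports.tsv")
  wtsv(as.data.frame(bundle$charfit), "charfit.tsv")
  wtsv(as.data.frame(bundle$synapomorphies), "synapomorphies.tsv")
  manifest <- bundle$manifest
  manifest$outputs <- c("mpts.tre", "consensus.tre", "reduced_consensus.tre",
                        "supports.tsv", "charfit.tsv", "synapomorphies.tsv")
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Summarize a protocol run
#'
#' Renders the result bundle as a human-readable markdown summary: tree
#' statistics, clade supports, pruned rogues and their alternative
#' positions.
#'
#' @param bundle an `mp_run_bundle` from [run_protocol()].
#' @return A character vector of markdown lines (also printed invisibly
#'   when auto-printed).
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "mp_run_bundle"))
  m <- bundle$manifest
  fmt <- function(x) ifelse(is.na(x), "n/a", format(x))
  lines <- c(
    "# Maximum parsimony analysis",
    "",
    sprintf("- matrix: %d taxa x %d characters", m$n_taxa, m$n_char),
    sprintf("- best tree length: %s steps", fmt(m$best_length)),
    sprintf("- equally parsimonious trees retained: %d", m$n_mpts),
    sprintf("- ensemble CI: %s, RI: %s", fmt(round(m$ci, 3)),
            fmt(round(m$ri, 3))),
    sprintf("- pruned rogue taxa: %s",
            if (length(m$pruned_taxa)) paste(m$pruned_taxa, collapse = ", ")
            else "none"),
    "", "## Clade supports", "")
  if (nrow(bundle$supports)) {
    lines <- c(lines, "| clade | Bremer | bootstrap % |", "|---|---|---|",
               sprintf("| %s | %s | %s |", bundle$supports$clade,
                       fmt(bundle$supports$bremer),
                       fmt(round(bundle$supports$bootstrap_pct, 1))))
  } else lines <- c(lines, "(no clades to report: n/a)")
  if (nrow(bundle$rogue$pruned)) {
    lines <- c(lines, "", "## Alternative positions of pruned taxa", "")
    for (i in seq_len(nrow(bundle$rogue$pruned))) {
      lines <- c(lines, sprintf("- %s: %d position(s)",
                                bundle$rogue$pruned$taxon[i],
                                bundle$rogue$pruned$n_positions[i]))
    }
  }
  if (nrow(bundle$synapomorphies)) {
    un <- bundle$synapomorphies[bundle$synapomorphies$unambiguous, ]
    lines <- c(lines, "", "## Unambiguous synapomorphies", "",
               sprintf("- clade {%s}: character %d, %d -> %d", un$clade,
                       un$character, un$from, un$to))
  }
  structure(lines, class = "mp_report")
}

#' @export
print.mp_report <- function(x, ...) {
  cat(paste(x, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.mp_run_bundle <- function(x, ...) {
  m <- x$manifest
  cat("Parsimony run:", m$n_taxa, "taxa x", m$n_char, "characters; length",
      m$best_length, "with", m$n_mpts, "MPT(s)\n")
  cat(sprintf("CI %.3f / RI %.3f; pruned: %s\n", m$ci, m$ri,
              if (length(m$pruned_taxa)) paste(m$pruned_taxa, collapse = ", ")
              else "none"))
  invisible(x)
}
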