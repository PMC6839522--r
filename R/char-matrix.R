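#' Morphological character matrices
#'
#' A `char_matrix` holds a rectangular taxa-by-characters grid of discrete
#' state sets, the container used throughout the package. Each cell is one of:
#' a single observed state (digits 0-9), a polymorphic set of states, missing
#' (`?`) or inapplicable (`-`). Missing and inapplicable cells are
#' distinguished for round-trip fidelity of matrix files but are treated
#' identically by every downstream computation, which is the default
#' behaviour of parsimony software for morphology.
#'
#' @param states integer matrix (taxa x characters) of state-set bitmasks
#'   (bit k set = state k present; 0 = empty set), or a character matrix of
#'   cell tokens such as `"0"`, `"?"`, `"-"`, `"{01}"`.
#' @param taxa character vector of taxon labels (unique after whitespace and
#'   underscore normalisation).
#' @param inapplicable optional logical matrix marking which empty cells were
#'   coded `-` rather than `?`; defaults to all-`FALSE`.
#' @param characters optional tibble of per-character metadata with columns
#'   `index` (1-based display index), `label`, `ordered`, `weight`,
#'   `provenance`, `n_states_declared`. Missing columns are filled with the
#'   study configuration used here: unordered, weight 1.
#'
#' @return An object of class `char_matrix`.
#' @examples
#' m <- char_matrix(rbind(A = c("0", "1"), B = c("0", "?"), C = c("{01}", "1")))
#' matrix_summary(m)
#' @export
char_matrix <- function(states, taxa = rownames(states), inapplicable = NULL,
                        characters = NULL) {
  force(taxa)  # evaluate the rownames default before `states` is rewritten
  if (is.character(states)) {
    tok <- states
    parsed <- parse_cell_tokens(tok)
    states <- parsed$mask
    if (is.null(inapplicable)) inapplicable <- parsed$inapp
  }
  if (!is.matrix(states)) stop("`states` must be a matrix")
  storage.mode(states) <- "integer"
  n_taxa <- nrow(states)
  n_char <- ncol(states)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n_taxa))
  taxa <- normalize_taxon(taxa)
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels after normalization: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (length(taxa) != n_taxa) stop("length(taxa) != nrow(states)")
  if (any(states < 0L | states > FULL_MASK))
    stop("state bitmasks must lie in [0, 1023] (alphabet 0-9)")
  if (is.null(inapplicable)) {
    inapplicable <- matrix(FALSE, n_taxa, n_char)
  } else {
    inapplicable <- inapplicable & (states == 0L)
  }
  characters <- complete_character_meta(characters, n_char)
  if (any(characters$weight <= 0)) stop("character weights must be positive")
  structure(
    list(taxa = taxa, states = unname(states),
         inapplicable = unname(inapplicable), characters = characters),
    class = "char_matrix")
}

parse_cell_tokens <- function(tok) {
  mask <- matrix(0L, nrow(tok), ncol(tok))
  inapp <- matrix(FALSE, nrow(tok), ncol(tok))
  for (i in seq_len(nrow(tok))) {
    for (j in seq_len(ncol(tok))) {
      t1 <- tok[i, j]
      if (t1 == "?") next
      if (t1 == "-") { inapp[i, j] <- TRUE; next }
      digits <- as.integer(strsplit(gsub("[^0-9]", "", t1), "")[[1]])
      if (length(digits) == 0L) stop("unparseable cell token: ", t1)
      mask[i, j] <- states_mask(digits)
    }
  }
  list(mask = mask, inapp = inapp)
}

complete_character_meta <- function(characters, n_char) {
  base <- tibble::tibble(
    index = seq_len(n_char),
    label = paste0("char", seq_len(n_char)),
    ordered = FALSE,
    weight = 1,
    provenance = NA_character_,
    n_states_declared = NA_integer_)
  if (is.null(characters)) return(base)
  characters <- tibble::as_tibble(characters)
  if (!nrow(characters) %in% n_char)
    stop("character metadata has ", nrow(characters), " rows for ",
         n_char, " characters")
  for (col in names(base)) {
    if (!col %in% names(characters)) characters[[col]] <- base[[col]]
  }
  characters[names(base)]
}

normalize_taxon <- function(x) {
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' @export
dim.char_matrix <- function(x) c(length(x$taxa), ncol(x$states))

n_taxa <- function(x) length(x$taxa)
n_char <- function(x) ncol(x$states)

#' @export
print.char_matrix <- function(x, ...) {
  s <- matrix_summary(x)
  cat("Morphological character matrix: ", s$n_taxa, " taxa x ", s$n_char,
      " characters\n", sep = "")
  cat(sprintf("missing/inapplicable cells: %.1f%%\n", 100 * s$missing_fraction))
  cat("taxa: ", paste(utils::head(x$taxa, 4), collapse = ", "),
      if (length(x$taxa) > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Subset a character matrix by taxa
#'
#' Removes the given taxa (rows) from the matrix, keeping all characters.
#' Used by taxon-deletion bootstrap experiments and rogue-taxon analyses.
#'
#' @param x a [char_matrix()].
#' @param drop character vector of taxon labels to remove.
#' @return A `char_matrix` without the dropped taxa.
#' @export
drop_taxa <- function(x, drop) drop_taxa_impl(x, drop)

drop_taxa_impl <- function(x, drop) {
  drop <- normalize_taxon(drop)
  missing_taxa <- setdiff(drop, x$taxa)
  if (length(missing_taxa))
    stop("unknown taxa: ", paste(missing_taxa, collapse = ", "))
  keep <- !(x$taxa %in% drop)
  if (sum(keep) < 4L) stop("cannot drop below 4 taxa")
  char_matrix(x$states[keep, , drop = FALSE], taxa = x$taxa[keep],
              inapplicable = x$inapplicable[keep, , drop = FALSE],
              characters = x$characters)
}

#' Summarize a character matrix
#'
#' Computes the bookkeeping a cladistic analysis reports about its matrix:
#' dimensions, the overall missing-data fraction, per-taxon scored-cell
#' counts (cells that are observed or polymorphic; missing and inapplicable
#' cells are excluded) and per-character observed-state counts.
#'
#' @param matrix a [char_matrix()].
#' @return An object of class `mp_matrix_summary`: a list with `n_taxa`,
#'   `n_char`, `missing_fraction`, and two tibbles `taxa` (taxon, scored,
#'   missing, inapplicable, polymorphic) and `characters` (character index,
#'   number of scored taxa, number of distinct observed states).
#' @examples
#' m <- char_matrix(rbind(A = c("0", "1", "?"), B = c("0", "-", "?"),
#'                        C = c("1", "1", "0"), D = c("0", "1", "0")))
#' matrix_summary(m)$taxa
#' @export
matrix_summary <- function(matrix) {
  stopifnot(inherits(matrix, "char_matrix"))
  scoredm <- matrix$states != 0L
  poly <- .POPCOUNT[matrix$states + 1L] > 1L
  dim(poly) <- dim(matrix$states)
  taxa_tbl <- tibble::tibble(
    taxon = matrix$taxa,
    scored = rowSums(scoredm),
    missing = rowSums(matrix$states == 0L & !matrix$inapplicable),
    inapplicable = rowSums(matrix$inapplicable),
    polymorphic = rowSums(poly))
  obs_states <- vapply(seq_len(n_char(matrix)), function(j)
    mask_size(mask_union(matrix$states[, j])), integer(1))
  char_tbl <- tibble::tibble(
    character = seq_len(n_char(matrix)),
    n_scored = colSums(scoredm),
    n_states_observed = obs_states)
  structure(
    list(n_taxa = n_taxa(matrix), n_char = n_char(matrix),
         missing_fraction = mean(!scoredm),
         taxa = taxa_tbl, characters = char_tbl),
    class = "mp_matrix_summary")
}

#' @export
print.mp_matrix_summary <- function(x, ...) {
  cat(x$n_taxa, "taxa x", x$n_char, "characters;",
      sprintf("%.1f%% empty cells\n", 100 * x$missing_fraction))
  print(x$taxa, n = 10)
  invisible(x)
}

#' @rdname matrix_summary
#' @param x an `mp_matrix_summary` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.mp_matrix_summary <- function(x, ...) x$taxa
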