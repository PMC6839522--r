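#' Read a morphological matrix from a NEXUS file
#'
#' Parses the `DATA` or `CHARACTERS` block of a NEXUS file into a
#' [char_matrix()]. The cell conventions used by published morphological
#' matrices are supported: single digit states 0-9, polymorphic cells written
#' `{01}` or `(01)`, `?` for missing and `-` (the GAP symbol) for
#' inapplicable. Interleaved matrices are handled by appending repeated
#' taxon rows; square-bracket comments are stripped.
#'
#' @param path path to a NEXUS text file.
#' @return A [char_matrix()].
#' @seealso [write_nexus()], [read_tnt()]
#' @export
read_nexus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- strip_bracket_comments(lines)
  up <- toupper(lines)
  begin <- grep("^\\s*BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)
  if (!length(begin))
    parse_error(path, 0, "no DATA or CHARACTERS block found")
  i <- begin[1]
  block_end <- grep("^\\s*END\\s*;", up)
  block_end <- block_end[block_end > i][1]
  if (is.na(block_end)) block_end <- length(lines)
  block <- i:block_end

  dim_line <- grep("DIMENSIONS", up[block], value = FALSE)
  if (!length(dim_line))
    parse_error(path, i, "DIMENSIONS statement missing")
  dl <- lines[block][dim_line[1]]
  ntax <- extract_num(dl, "NTAX")
  nchar_ <- extract_num(dl, "NCHAR")
  if (is.na(nchar_))
    parse_error(path, block[dim_line[1]], "NCHAR missing in DIMENSIONS")

  fmt_line <- grep("FORMAT", up[block])
  missing_sym <- "?"; gap_sym <- "-"
  if (length(fmt_line)) {
    fl <- lines[block][fmt_line[1]]
    missing_sym <- extract_sym(fl, "MISSING") %||% "?"
    gap_sym <- extract_sym(fl, "GAP") %||% "-"
    sym <- regmatches(fl, regexpr('SYMBOLS\\s*=\\s*"[^"]*"', toupper(fl)))
    if (length(sym)) {
      symbols <- gsub('[^0-9A-Za-z]', "", sub(".*=", "", sym))
      bad <- setdiff(strsplit(symbols, "")[[1]], as.character(0:9))
      if (length(bad))
        parse_error(path, block[fmt_line[1]],
                    paste0("unsupported state symbols (alphabet is 0-9): ",
                           paste(bad, collapse = "")))
    }
  }

  mat_line <- grep("^\\s*MATRIX\\b", up[block])
  if (!length(mat_line)) parse_error(path, i, "MATRIX statement missing")
  start <- block[mat_line[1]] + 1L
  rows <- read_matrix_rows(lines, start, path,
                           nchar = nchar_, dialect = "nexus",
                           missing_sym = missing_sym, gap_sym = gap_sym)
  finish_matrix(rows, ntax, nchar_, path)
}

#' Read a morphological matrix from a TNT xread file
#'
#' Parses the `xread` command of a TNT file: a `'...'` quoted title is
#' allowed, the dimensions line is `nchar ntax` (TNT order), and polymorphic
#' cells are written `[01]` (NEXUS-style `{01}`/`(01)` are tolerated too).
#' Semantics are identical to [read_nexus()].
#'
#' @inheritParams read_nexus
#' @return A [char_matrix()].
#' @export
read_tnt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  xi <- grep("^\\s*xread\\b", lines, ignore.case = TRUE)
  if (!length(xi)) parse_error(path, 0, "no xread command found")
  i <- xi[1] + 1L
  # optional quoted title, possibly spanning lines
  txt <- paste(lines[i:length(lines)], collapse = "\n")
  txt <- sub("^\\s*'[^']*'", "", txt)
  toks <- regmatches(txt, regexpr("^\\s*([0-9]+)\\s+([0-9]+)", txt))
  if (!length(toks)) parse_error(path, i, "xread dimensions (nchar ntax) missing")
  dims <- as.integer(strsplit(trimws(toks), "\\s+")[[1]])
  nchar_ <- dims[1]; ntax <- dims[2]
  body <- strsplit(sub("^\\s*[0-9]+\\s+[0-9]+", "", txt), "\n")[[1]]
  rows <- read_matrix_rows(body, 1L, path, nchar = nchar_, dialect = "tnt",
                           missing_sym = "?", gap_sym = "-")
  finish_matrix(rows, ntax, nchar_, path)
}

#' Write a character matrix to NEXUS
#'
#' Emits a standard `DATA` block (`SYMBOLS="0123456789"`, `MISSING=?`,
#' `GAP=-`) that [read_nexus()] re-parses cell-identically, including
#' polymorphic (`{..}`), missing and inapplicable cells. Taxon labels have
#' internal spaces converted to underscores.
#'
#' @param matrix a [char_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(matrix, path) {
  stopifnot(inherits(matrix, "char_matrix"))
  rows <- format_rows(matrix, dialect = "nexus")
  out <- c("#NEXUS", "", "BEGIN DATA;",
           sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(matrix),
                   n_char(matrix)),
           "FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
           "MATRIX", rows, ";", "END;")
  writeLines(out, path)
  invisible(path)
}

#' Write a character matrix to TNT xread format
#'
#' @inheritParams write_nexus
#' @return `path`, invisibly.
#' @export
write_tnt <- function(matrix, path) {
  stopifnot(inherits(matrix, "char_matrix"))
  rows <- format_rows(matrix, dialect = "tnt")
  out <- c("xread", sprintf("%d %d", n_char(matrix), n_taxa(matrix)),
           rows, ";", "proc /;")
  writeLines(out, path)
  invisible(path)
}

format_rows <- function(matrix, dialect) {
  labels <- gsub(" ", "_", matrix$taxa, fixed = TRUE)
  pad <- max(nchar(labels)) + 2L
  vapply(seq_len(n_taxa(matrix)), function(i) {
    cells <- vapply(seq_len(n_char(matrix)), function(j)
      cell_to_token(matrix$states[i, j], matrix$inapplicable[i, j], dialect),
      character(1))
    paste0(formatC(labels[i], width = -pad), paste0(cells, collapse = ""))
  }, character(1))
}

# --- shared row parsing ---------------------------------------------------

read_matrix_rows <- function(lines, start, path, nchar, dialect,
                             missing_sym, gap_sym) {
  taxa <- character(0)
  cells <- list()    # per taxon: list(mask = int vec, inapp = logical vec)
  ln <- start - 1L
  for (raw in lines[start:length(lines)]) {
    ln <- ln + 1L
    line <- trimws(raw)
    terminal <- grepl(";", line, fixed = TRUE)
    line <- trimws(sub(";.*$", "", line))
    if (line == "") { if (terminal) break else next }
    m <- regexpr("^'[^']*'|^\"[^\"]*\"|^\\S+", line)
    name_tok <- regmatches(line, m)
    rest <- trimws(substring(line, attr(m, "match.length") + 1L))
    name <- normalize_taxon(gsub("^['\"]|['\"]$", "", name_tok))
    parsed <- parse_state_string(rest, dialect, missing_sym, gap_sym)
    if (is.character(parsed))
      parse_error(path, ln, paste0("taxon '", name, "': ", parsed))
    if (!name %in% taxa) {
      taxa <- c(taxa, name)
      cells[[name]] <- parsed
    } else {
      cells[[name]] <- list(mask = c(cells[[name]]$mask, parsed$mask),
                            inapp = c(cells[[name]]$inapp, parsed$inapp))
    }
    if (length(cells[[name]]$mask) > nchar)
      parse_error(path, ln, paste0("taxon '", name, "' has more than ",
                                   nchar, " characters"))
    if (terminal) break
  }
  list(taxa = taxa, cells = cells, last_line = ln)
}

parse_state_string <- function(s, dialect, missing_sym, gap_sym) {
  chars <- strsplit(gsub("\\s", "", s), "")[[1]]
  mask <- integer(0); inapp <- logical(0)
  open <- c("{" = "}", "(" = ")", "[" = "]")
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == missing_sym) {
      mask <- c(mask, 0L); inapp <- c(inapp, FALSE)
    } else if (ch == gap_sym) {
      mask <- c(mask, 0L); inapp <- c(inapp, TRUE)
    } else if (ch %in% names(open)) {
      closer <- open[[ch]]
      j <- i + 1L; set <- integer(0)
      while (j <= length(chars) && chars[j] != closer) {
        if (!grepl("^[0-9]$", chars[j]))
          return(paste0("bad symbol '", chars[j], "' inside polymorphism"))
        set <- c(set, as.integer(chars[j])); j <- j + 1L
      }
      if (j > length(chars)) return("unterminated polymorphism bracket")
      if (length(set) == 0L) return("empty polymorphism bracket")
      mask <- c(mask, states_mask(set)); inapp <- c(inapp, FALSE)
      i <- j
    } else if (grepl("^[0-9]$", ch)) {
      mask <- c(mask, bitwShiftL(1L, as.integer(ch))); inapp <- c(inapp, FALSE)
    } else {
      return(paste0("unexpected symbol '", ch, "'"))
    }
    i <- i + 1L
  }
  list(mask = mask, inapp = inapp)
}

finish_matrix <- function(rows, ntax, nchar, path) {
  taxa <- rows$taxa
  if (!is.na(ntax) && length(taxa) != ntax)
    parse_error(path, rows$last_line,
                paste0("expected ", ntax, " taxa, found ", length(taxa)))
  lens <- vapply(rows$cells, function(x) length(x$mask), integer(1))
  bad <- which(lens != nchar)
  if (length(bad))
    parse_error(path, rows$last_line,
                paste0("ragged matrix: taxon '", taxa[bad[1]], "' has ",
                       lens[bad[1]], " of ", nchar, " characters"))
  states <- do.call(rbind, lapply(taxa, function(t) rows$cells[[t]]$mask))
  inapp <- do.call(rbind, lapply(taxa, function(t) rows$cells[[t]]$inapp))
  char_matrix(states, taxa = taxa, inapplicable = inapp)
}

parse_error <- function(path, line, msg) {
  rlang::abort(sprintf("%s:%s: %s", path, line, msg),
               class = "maxpars_parse_error")
}

extract_num <- function(line, key) {
  m <- regmatches(toupper(line), regexpr(paste0(key, "\\s*=\\s*[0-9]+"),
                                         toupper(line)))
  if (!length(m)) return(NA_integer_)
  as.integer(sub(".*=\\s*", "", m))
}

extract_sym <- function(line, key) {
  m <- regmatches(toupper(line), regexpr(paste0(key, "\\s*=\\s*\\S"),
                                         toupper(line)))
  if (!length(m)) return(NULL)
  substring(sub(paste0(key, "\\s*=\\s*"), "", m), 1, 1)
}

strip_bracket_comments <- function(lines) gsub("\\[[^]]*\\]", "", lines)
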