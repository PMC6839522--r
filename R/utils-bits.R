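# Internal helpers for state-set bitmasks over the 0-9 alphabet.
# A cell is an integer in [0, 1023]; bit k set means state k is present;
# 0 encodes an empty set (missing or inapplicable).

MAX_STATES <- 10L
FULL_MASK <- 1023L

# popcount lookup for masks 0..1023
.POPCOUNT <- vapply(0:1023, function(m) sum(bitwAnd(bitwShiftR(m, 0:9), 1L)),
                    integer(1))

mask_size <- function(mask) .POPCOUNT[mask + 1L]

mask_states <- function(mask) which(bitwAnd(bitwShiftR(mask, 0:9), 1L) == 1L) - 1L

states_mask <- function(states) {
  if (length(states) == 0L) return(0L)
  stopifnot(all(states >= 0L & states < MAX_STATES))
  as.integer(sum(bitwShiftL(1L, unique(as.integer(states)))))
}

# union of masks in a vector
mask_union <- function(masks) Reduce(bitwOr, masks, accumulate = FALSE, 0L)

# lowest set bit -> state index (smallest state in the set)
mask_min_state <- function(mask) {
  if (mask == 0L) return(NA_integer_)
  mask_states(mask)[1L]
}

cell_to_token <- function(mask, inapplicable, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  if (mask == 0L) return(if (inapplicable) "-" else "?")
  st <- mask_states(mask)
  if (length(st) == 1L) return(as.character(st))
  if (dialect == "tnt") paste0("[", paste0(st, collapse = ""), "]")
  else paste0("{", paste0(st, collapse = ""), "}")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
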