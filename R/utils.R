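# Internal helpers shared across modules.

SINGLE_ENTITY_CLASSES <- c("protein", "chemical", "rna", "dna", "gene")
CONTAINER_CLASSES <- c("complex", "set", "polymer")
ENTITY_CLASSES <- c(SINGLE_ENTITY_CLASSES, CONTAINER_CLASSES)

#' Normalise an identifier for lookup
#'
#' Stored identifiers and queries are trimmed of surrounding whitespace and,
#' unless `case_insensitive = FALSE`, uppercased before any trie operation.
#' UniProt and ChEBI accessions are case-insensitive in practice, so this is
#' the default for every knowledge base.
#'
#' @param x character vector of identifiers.
#' @param case_insensitive uppercase before matching? Default `TRUE`.
#' @return normalised character vector.
#' @export
normalize_identifier <- function(x, case_insensitive = TRUE) {
  x <- trimws(x)
  if (case_insensitive) x <- toupper(x)
  x
}

# Length of the common prefix of two (ASCII) strings, in characters.
common_prefix_len <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq)) neq[[1L]] - 1L else n
}

# A bare environment used as a mutable record / hash map.
new_rec <- function() new.env(parent = emptyenv(), hash = TRUE)

# Sorted set semantics with locale-stable ordering; NULL is the empty set.
sort_c <- function(x) {
  if (is.null(x) || !length(x)) return(character(0))
  sort(unique(x), method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
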