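#' Radix tree (Patricia trie) lookup table
#'
#' The first step of the analysis decides, for every identifier in the user
#' sample, whether it corresponds to one or more curated physical entities.
#' The lookup table is a space-optimised prefix tree: every node with a
#' single child and no stored value is merged with that child, so common
#' accession prefixes (e.g. the `P106..` block of UniProt) are stored once.
#' Seek time is bounded by the length of the queried identifier, and a miss
#' is detected without reading the whole query (unlike hashing).
#'
#' Nodes carry a possibly-empty payload of references into the entity graph;
#' a non-empty payload marks the node's path-string as a stored identifier.
#' One identifier may map to several entities (gene-name style aliases), so
#' payloads are collections keyed by entity id.
#'
#' The trie is a mutable reference structure (environment-based); the
#' knowledge base builds it once and never deletes from it.
#'
#' @return `radix_trie()` returns an empty trie containing only the root.
#' @seealso [trie_insert()], [trie_lookup()], [trie_stats()]
#' @export
radix_trie <- function() {
  t <- new_rec()
  t$root <- .trie_node("")
  t$n_keys <- 0L
  class(t) <- "radix_trie"
  t
}

.trie_node <- function(label) {
  e <- new_rec()
  e$label <- label
  e$children <- list()   # keyed by first character of each child's edge label
  e$payload <- list()    # keyed by entity id -> reference
  e
}

#' Insert an identifier into the trie
#'
#' Inserting may split an existing edge; the compression invariant (no
#' non-root node with exactly one child and an empty payload) is preserved.
#' Re-inserting the same `(key, ref_id)` pair is a no-op.
#'
#' @param trie a [radix_trie()].
#' @param key non-empty identifier string, already normalised
#'   (see [normalize_identifier()]).
#' @param ref the payload reference stored for this key (typically an entity
#'   graph node); defaults to `TRUE` for standalone use.
#' @param ref_id unique id under which `ref` is stored in the payload;
#'   defaults to `key`.
#' @return the trie, invisibly.
#' @export
trie_insert <- function(trie, key, ref = TRUE, ref_id = key) {
  stopifnot(inherits(trie, "radix_trie"), is.character(key), length(key) == 1L)
  if (is.na(key) || !nzchar(key)) {
    stop("trie_insert(): key must be a non-empty string", call. = FALSE)
  }
  node <- trie$root
  k <- key
  while (nzchar(k)) {
    first <- substr(k, 1L, 1L)
    child <- node$children[[first]]
    if (is.null(child)) {
      child <- .trie_node(k)
      node$children[[first]] <- child
      node <- child
      k <- ""
    } else {
      l <- common_prefix_len(k, child$label)
      if (l == nchar(child$label)) {
        node <- child
        k <- substr(k, l + 1L, nchar(k))
      } else {
        # split the child's edge after l shared characters
        mid <- .trie_node(substr(child$label, 1L, l))
        child$label <- substr(child$label, l + 1L, nchar(child$label))
        mid$children[[substr(child$label, 1L, 1L)]] <- child
        node$children[[first]] <- mid
        node <- mid
        k <- substr(k, l + 1L, nchar(k))
      }
    }
  }
  if (length(node$payload) == 0L) trie$n_keys <- trie$n_keys + 1L
  if (is.null(node$payload[[ref_id]])) node$payload[[ref_id]] <- ref
  invisible(trie)
}

#' Look an identifier up in the trie
#'
#' @param trie a [radix_trie()].
#' @param key identifier string (normalise it first with
#'   [normalize_identifier()] when querying a knowledge-base trie).
#' @return the stored payload (a named list keyed by entity id) when `key`
#'   was inserted; `NULL` when the key is absent, including when it is only
#'   a proper prefix of stored keys. Absence is a value, not an error.
#' @export
trie_lookup <- function(trie, key) {
  if (length(key) != 1L || is.na(key) || !nzchar(key)) return(NULL)
  node <- trie$root
  k <- key
  while (nzchar(k)) {
    child <- node$children[[substr(k, 1L, 1L)]]
    if (is.null(child)) return(NULL)
    lab <- child$label
    nl <- nchar(lab)
    if (nchar(k) < nl || substr(k, 1L, nl) != lab) return(NULL)
    k <- substr(k, nl + 1L, nchar(k))
    node <- child
  }
  if (length(node$payload)) node$payload else NULL
}

.trie_walk <- function(node, prefix, fun) {
  fun(node, prefix)
  kids <- names(node$children)
  if (length(kids)) {
    for (first in sort(kids, method = "radix")) {
      child <- node$children[[first]]
      .trie_walk(child, paste0(prefix, child$label), fun)
    }
  }
  invisible(NULL)
}

#' Trie size statistics
#'
#' `stored_characters` is the total number of characters held on edges;
#' because common prefixes are shared it is at most the summed length of the
#' inserted keys.
#'
#' @param trie a [radix_trie()].
#' @return list with `node_count` (including the root), `stored_characters`
#'   and `key_count` (distinct inserted keys).
#' @export
trie_stats <- function(trie) {
  nodes <- 0L
  chars <- 0L
  .trie_walk(trie$root, "", function(node, prefix) {
    nodes <<- nodes + 1L
    chars <<- chars + nchar(node$label)
  })
  list(node_count = nodes, stored_characters = chars, key_count = trie$n_keys)
}

#' All keys stored in the trie
#'
#' @param trie a [radix_trie()].
#' @return sorted character vector of stored identifiers.
#' @export
trie_keys <- function(trie) {
  keys <- character(0)
  .trie_walk(trie$root, "", function(node, prefix) {
    if (length(node$payload)) keys[[length(keys) + 1L]] <<- prefix
  })
  sort_c(keys)
}

#' Check the path-compression invariant
#'
#' A radix tree must contain no non-root node that has exactly one child and
#' an empty payload: such a node should have been merged with its child.
#'
#' @param trie a [radix_trie()].
#' @return character vector of violation descriptions; empty when compressed.
#' @export
trie_check_compression <- function(trie) {
  bad <- character(0)
  root <- trie$root
  .trie_walk(root, "", function(node, prefix) {
    if (!identical(node, root) &&
        length(node$children) == 1L && length(node$payload) == 0L) {
      bad[[length(bad) + 1L]] <<-
        sprintf("uncompressed node at path '%s' (one child, empty payload)", prefix)
    }
  })
  bad
}

#' @export
print.radix_trie <- function(x, ...) {
  s <- trie_stats(x)
  cat(sprintf(
    "<radix_trie> %d keys, %d nodes, %d stored characters\n",
    s$key_count, s$node_count, s$stored_characters
  ))
  invisible(x)
}
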