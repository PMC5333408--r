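#' Double-linked pathway hierarchy tree
#'
#' Pathways are organised per species as a forest of rooted trees (an
#' ontology-like parent/child hierarchy). Every node keeps references both
#' to its parent and to its children, so a hit on a sub-pathway can be
#' propagated recursively up to the top-level pathway: if a protein is
#' present in "Metabolism of carbohydrates" it is also present in
#' "Metabolism". Each node carries the total number of distinct curated
#' single entities in its subtree (`total_entities`, shared across
#' analyses) while per-analysis found sets live in a separate
#' [fresh_analysis_state()] so concurrent analyses over one immutable
#' knowledge base never observe each other's hits.
#'
#' @name pathway_hierarchy
NULL

# Build the forest from validated interchange tables.
.pathway_forest_build <- function(pathways, annotations) {
  f <- new_rec()
  f$nodes <- new_rec()
  f$pathway_ids <- pathways$pathway_id
  f$species <- unique(pathways$species)
  f$roots <- list()
  for (i in seq_len(nrow(pathways))) {
    n <- new_rec()
    n$pathway_id <- pathways$pathway_id[[i]]
    n$name <- pathways$name[[i]]
    n$species <- pathways$species[[i]]
    n$parent_id <- pathways$parent_id[[i]]
    n$children <- character(0)
    n$annotated <- character(0)     # directly annotated entity ids
    n$total_entities <- NA_integer_
    n$total_set <- character(0)
    class(n) <- "pathway_node"
    f$nodes[[n$pathway_id]] <- n
  }
  for (i in seq_len(nrow(pathways))) {
    pid <- pathways$pathway_id[[i]]
    parent <- pathways$parent_id[[i]]
    if (nzchar(parent)) {
      pn <- f$nodes[[parent]]
      pn$children <- c(pn$children, pid)
    } else {
      sp <- pathways$species[[i]]
      f$roots[[sp]] <- c(f$roots[[sp]], pid)
    }
  }
  for (i in seq_len(nrow(annotations))) {
    n <- f$nodes[[annotations$pathway_id[[i]]]]
    n$annotated <- c(n$annotated, annotations$entity_id[[i]])
  }
  f$background_sets <- list()
  f$background <- integer(0)
  class(f) <- "pathway_forest"
  f
}

#' Compute per-pathway curated totals
#'
#' Fills `total_entities` for every node: the number of distinct single
#' entities (by main identifier) annotated anywhere in the node's subtree,
#' with containers flattened down to their single-entity constituents. An
#' entity annotated in two sibling sub-pathways counts once in the parent.
#' Also fills the per-species background: the union of all top-level
#' pathway sets, i.e. every distinct single entity annotated directly or
#' via composition for that species.
#'
#' Called by [load_knowledge_base()]; exported so custom-built forests can
#' be totalled too.
#'
#' @param forest a `pathway_forest`.
#' @param graph the matching `entity_graph`.
#' @return the forest, invisibly (totals filled in place).
#' @export
compute_totals <- function(forest, graph) {
  cache <- new_rec()
  rec <- function(pid) {
    node <- forest$nodes[[pid]]
    direct <- unlist(lapply(node$annotated, flatten_entity, graph = graph, cache = cache),
                     use.names = FALSE)
    child_sets <- lapply(node$children, rec)
    s <- sort_c(c(direct, unlist(child_sets, use.names = FALSE)))
    node$total_set <- s
    node$total_entities <- length(s)
    s
  }
  forest$background_sets <- list()
  bg <- integer(0)
  for (sp in forest$species) {
    root_sets <- lapply(forest$roots[[sp]] %||% character(0), rec)
    u <- sort_c(unlist(root_sets, use.names = FALSE))
    forest$background_sets[[sp]] <- u
    bg[[sp]] <- length(u)
  }
  forest$background <- bg
  invisible(forest)
}

#' Create an empty per-analysis found-state
#'
#' The knowledge base (trie, graph, forest with totals) is immutable after
#' build; everything an individual analysis accumulates — the sets of
#' sample entities found per pathway — lives in this separate state object.
#' Two analyses over the same knowledge base therefore never interfere.
#'
#' @param forest a `pathway_forest` with totals computed.
#' @return an `analysis_state` with an empty found set for every node.
#' @export
fresh_analysis_state <- function(forest) {
  stopifnot(inherits(forest, "pathway_forest"))
  st <- new_rec()
  st$forest <- forest
  st$found <- new_rec()   # pathway_id -> environment used as a string set
  class(st) <- "analysis_state"
  st
}

#' Mark a pathway hit and propagate it to all ancestors
#'
#' Adds the entity's main identifier to the found set of `pathway_id` and,
#' recursively, of every ancestor up to the species root. Idempotent per
#' (pathway, entity): propagation stops early at the first ancestor that
#' already contains the identifier (its ancestors necessarily do too).
#' Found sets are sets of identifiers, not counters — an entity hitting two
#' sibling sub-pathways counts once in their parent.
#'
#' @param state an [fresh_analysis_state()] object.
#' @param pathway_id pathway to mark.
#' @param identifier main identifier of the found single entity.
#' @return the state, invisibly.
#' @export
mark_hit <- function(state, pathway_id, identifier) {
  forest <- state$forest
  pid <- pathway_id
  if (is.null(forest$nodes[[pid]])) {
    stop(sprintf("unknown pathway '%s'", pid), call. = FALSE)
  }
  repeat {
    set <- state$found[[pid]]
    if (is.null(set)) {
      set <- new_rec()
      state$found[[pid]] <- set
    }
    if (!is.null(set[[identifier]])) break
    set[[identifier]] <- TRUE
    parent <- forest$nodes[[pid]]$parent_id
    if (!nzchar(parent)) break
    pid <- parent
  }
  invisible(state)
}

#' Found set of a pathway in an analysis state
#'
#' @param state an `analysis_state`.
#' @param pathway_id pathway id.
#' @return sorted character vector of found main identifiers (possibly empty).
#' @export
found_entities <- function(state, pathway_id) {
  set <- state$found[[pathway_id]]
  if (is.null(set)) character(0) else sort_c(ls(set, all.names = TRUE))
}

#' @export
print.pathway_forest <- function(x, ...) {
  cat(sprintf("<pathway_forest> %d pathways across %d species\n",
              length(x$pathway_ids), length(x$species)))
  for (sp in x$species) {
    cat(sprintf("  %s: %d top-level pathways, background %s\n",
                sp, length(x$roots[[sp]] %||% character(0)),
                if (length(x$background)) x$background[[sp]] else NA))
  }
  invisible(x)
}
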