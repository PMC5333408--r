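#' Directed graph of physical entities
#'
#' The second analysis step models curated physical entities (PEs) — single
#' entities such as proteins and chemicals, and structured entities:
#' complexes, sets and polymers — as a directed graph. Each entity is in
#' memory exactly once; a node carries edges to every structure that
#' contains it (`containers`), the inverse member edges (`members`, in
#' declaration order), symmetric ortholog edges to counterpart entities in
#' other species, and direct links into the pathway hierarchy.
#'
#' Composition follows Reactome semantics: a complex requires all of its
#' components together (AND), a set groups functionally interchangeable
#' alternatives (OR), and a polymer is treated as a container of its repeat
#' unit(s), with complex-like semantics. Containers may nest arbitrarily;
#' the composition relation is a DAG, enforced at load time.
#'
#' @name entity_graph
NULL

# Build the graph from validated interchange tables.
.entity_graph_build <- function(entities, composition, orthologs, annotations) {
  g <- new_rec()
  g$nodes <- new_rec()
  g$entity_ids <- entities$entity_id
  g$species <- unique(entities$species)
  for (i in seq_len(nrow(entities))) {
    n <- new_rec()
    n$entity_id <- entities$entity_id[[i]]
    n$species <- entities$species[[i]]
    n$entity_class <- entities$entity_class[[i]]
    n$main_identifier <- entities$main_identifier[[i]]
    n$containers <- character(0)
    n$members <- character(0)
    n$orthologs <- character(0)
    n$pathways <- character(0)
    n$aliases <- character(0)
    class(n) <- "entity_node"
    g$nodes[[n$entity_id]] <- n
  }
  for (i in seq_len(nrow(composition))) {
    m <- g$nodes[[composition$member_id[[i]]]]
    ct <- g$nodes[[composition$container_id[[i]]]]
    ct$members <- c(ct$members, m$entity_id)
    m$containers <- c(m$containers, ct$entity_id)
  }
  for (i in seq_len(nrow(orthologs))) {
    a <- g$nodes[[orthologs$entity_a[[i]]]]
    b <- g$nodes[[orthologs$entity_b[[i]]]]
    a$orthologs <- c(a$orthologs, b$entity_id)
    b$orthologs <- c(b$orthologs, a$entity_id)
  }
  for (i in seq_len(nrow(annotations))) {
    e <- g$nodes[[annotations$entity_id[[i]]]]
    e$pathways <- c(e$pathways, annotations$pathway_id[[i]])
  }
  class(g) <- "entity_graph"
  g
}

.resolve_entity <- function(graph, x) {
  if (inherits(x, "entity_node")) return(x)
  node <- graph$nodes[[x]]
  if (is.null(node)) stop(sprintf("unknown entity '%s'", x), call. = FALSE)
  node
}

is_single_entity <- function(node) node$entity_class %in% SINGLE_ENTITY_CLASSES

#' Structures containing an entity
#'
#' Follows container edges transitively: starting from a protein that is a
#' component of a complex which is itself a member of a set, all of those
#' structured entities are returned. Terminates because composition is
#' acyclic. The start entity is excluded.
#'
#' @param graph an `entity_graph` (component of a [knowledge_base]).
#' @param entity entity id or entity node.
#' @return sorted character vector of container entity ids (a set).
#' @export
containers_of <- function(graph, entity) {
  start <- .resolve_entity(graph, entity)
  seen <- new_rec()
  queue <- start$containers
  out <- character(0)
  while (length(queue)) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    if (is.null(seen[[id]])) {
      seen[[id]] <- TRUE
      out[[length(out) + 1L]] <- id
      queue <- c(queue, graph$nodes[[id]]$containers)
    }
  }
  sort_c(out)
}

#' Deconstruct a structured entity into its variants
#'
#' Resolves the alternatives a complex or set stands for. A single entity is
#' its own (leaf) variant. A set contributes the concatenation of its
#' members' variants (OR). A complex (or polymer) contributes the cartesian
#' combination of its components' variants (AND), each combination emitted
#' as a nested grouping that preserves member structure — the composition
#' `C2 = {S1, P2}` with `S1 = [P1, {P1,P2}, {P1,P3}]` deconstructs to
#' `[{P1,P2}, {{P1,P2},P2}, {{P1,P3},P2}]`, not to flat member sets.
#'
#' Output order is deterministic: member declaration order, then
#' alternative order, with earlier components varying slowest.
#'
#' @param graph an `entity_graph`.
#' @param entity entity id or node.
#' @return list of variants; a variant is either a main-identifier string
#'   (leaf) or a list of variants of class `entity_variant` (one resolved
#'   complex composition). Render with [variant_format()], flatten with
#'   [variant_flatten()].
#' @export
expand_structure <- function(graph, entity) {
  node <- .resolve_entity(graph, entity)
  cls <- node$entity_class
  if (cls %in% SINGLE_ENTITY_CLASSES) {
    list(node$main_identifier)
  } else if (cls == "set") {
    out <- list()
    for (m in node$members) out <- c(out, expand_structure(graph, m))
    out
  } else {
    # complex / polymer: cartesian product over components
    acc <- list(list())
    for (m in node$members) {
      alts <- expand_structure(graph, m)
      nxt <- vector("list", length(acc) * length(alts))
      k <- 0L
      for (combo in acc) {
        for (v in alts) {
          k <- k + 1L
          nxt[[k]] <- c(combo, list(v))
        }
      }
      acc <- nxt
    }
    lapply(acc, function(combo) structure(combo, class = "entity_variant"))
  }
}

#' Render a structure variant in bracket notation
#'
#' Leaves print as their main identifier, resolved complex compositions as
#' `{...}` with members comma-separated, preserving nesting: `{{P1,P2},P2}`.
#'
#' @param v a variant as returned by [expand_structure()].
#' @return a string.
#' @export
variant_format <- function(v) {
  if (is.character(v)) return(v)
  paste0("{", paste(vapply(v, variant_format, character(1)), collapse = ","), "}")
}

#' Flatten a structure variant to its single-entity leaves
#'
#' @param v a variant as returned by [expand_structure()].
#' @return sorted character vector of distinct main identifiers.
#' @export
variant_flatten <- function(v) {
  if (is.character(v)) return(v)
  sort_c(unlist(lapply(v, variant_flatten), use.names = FALSE))
}

# Flatten an entity to the set of main identifiers of the single entities it
# is (transitively) composed of. Memoised per knowledge base via `cache`.
flatten_entity <- function(graph, entity_id, cache = NULL) {
  if (!is.null(cache)) {
    hit <- cache[[entity_id]]
    if (!is.null(hit)) return(hit)
  }
  node <- graph$nodes[[entity_id]]
  res <- if (is_single_entity(node)) {
    node$main_identifier
  } else {
    sort_c(unlist(lapply(node$members, flatten_entity, graph = graph, cache = cache),
                  use.names = FALSE))
  }
  if (!is.null(cache)) cache[[entity_id]] <- res
  res
}

#' Project entities onto a reference species via ortholog links
#'
#' Species projection lets an analysis submitted with non-human identifiers
#' be collected against the (more completely annotated) reference species.
#' Entities already belonging to the reference species pass through;
#' every other entity is replaced by all of its reference-species ortholog
#' counterparts. Entities without a reference-species ortholog are returned
#' in `unprojected` — they are excluded from the statistics but must be
#' reported, never silently dropped.
#'
#' @param graph an `entity_graph`.
#' @param entities character vector of entity ids (or list of nodes).
#' @param reference_species species name present in the graph.
#' @return list with sorted id vectors `projected` and `unprojected`, and
#'   `map`: named list input id -> reference-species ids it projected to.
#' @export
project_orthologs <- function(graph, entities, reference_species) {
  if (!reference_species %in% graph$species) {
    stop(sprintf("unknown species '%s'", reference_species), call. = FALSE)
  }
  ids <- vapply(entities, function(e) .resolve_entity(graph, e)$entity_id, character(1))
  projected <- character(0)
  unprojected <- character(0)
  map <- list()
  for (id in ids) {
    node <- graph$nodes[[id]]
    if (node$species == reference_species) {
      projected <- c(projected, id)
      map[[id]] <- id
    } else {
      targets <- Filter(
        function(o) graph$nodes[[o]]$species == reference_species,
        node$orthologs
      )
      targets <- as.character(targets)
      if (length(targets)) {
        projected <- c(projected, targets)
        map[[id]] <- sort_c(targets)
      } else {
        unprojected <- c(unprojected, id)
        map[[id]] <- character(0)
      }
    }
  }
  list(projected = sort_c(projected), unprojected = sort_c(unprojected), map = map)
}

#' Collect pathway links for entities, through their containers
#'
#' For each input entity, unions the direct pathway annotations of the
#' entity itself and of every structure reached by [containers_of()]. The
#' result is keyed by the input entity so that downstream aggregation can
#' count distinct curated entities.
#'
#' @param graph an `entity_graph`.
#' @param entities character vector of entity ids (or list of nodes).
#' @return named list: entity id -> sorted character vector of pathway ids.
#' @export
collect_pathway_links <- function(graph, entities) {
  ids <- vapply(entities, function(e) .resolve_entity(graph, e)$entity_id, character(1))
  out <- list()
  for (id in ids) {
    node <- graph$nodes[[id]]
    pids <- node$pathways
    for (cid in containers_of(graph, node)) {
      pids <- c(pids, graph$nodes[[cid]]$pathways)
    }
    out[[id]] <- sort_c(pids)
  }
  out
}

#' @export
print.entity_graph <- function(x, ...) {
  classes <- table(vapply(x$entity_ids, function(id) x$nodes[[id]]$entity_class,
                          character(1)))
  cat(sprintf("<entity_graph> %d entities, %d species\n",
              length(x$entity_ids), length(x$species)))
  cat("  ", paste(sprintf("%s: %d", names(classes), classes), collapse = ", "), "\n")
  invisible(x)
}
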