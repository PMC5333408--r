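#' Knowledge-base interchange format
#'
#' A pathway knowledge base is exchanged as a directory of six UTF-8,
#' tab-separated, LF-terminated files with fixed headers and no quoting:
#'
#' * `entities.tsv` — `entity_id  species  entity_class  main_identifier`;
#'   `entity_class` is one of protein, chemical, rna, dna, gene (single
#'   entities, which carry a curated main identifier) or complex, set,
#'   polymer (containers, whose `main_identifier` is empty).
#' * `xrefs.tsv` — `alias  entity_id  resource`; the cross-references,
#'   synonyms and gene names users may submit. One alias may map to
#'   several entities.
#' * `composition.tsv` — `member_id  container_id  relation` with relation
#'   `complex_component` or `set_member`; must be acyclic.
#' * `orthologs.tsv` — `entity_a  entity_b`, cross-species counterpart
#'   pairs, stored once and treated symmetrically.
#' * `pathways.tsv` — `pathway_id  species  name  parent_id` (empty
#'   `parent_id` marks a top-level pathway); one forest per species.
#' * `annotations.tsv` — `entity_id  pathway_id`, direct entity-to-pathway
#'   links; species of both endpoints must agree.
#'
#' @name kb_format
NULL

KB_FILES <- list(
  entities    = c("entity_id", "species", "entity_class", "main_identifier"),
  xrefs       = c("alias", "entity_id", "resource"),
  composition = c("member_id", "container_id", "relation"),
  orthologs   = c("entity_a", "entity_b"),
  pathways    = c("pathway_id", "species", "name", "parent_id"),
  annotations = c("entity_id", "pathway_id")
)

#' Read the six interchange tables of a knowledge base
#'
#' Performs format-level checks only (files present, headers exact);
#' referential checks are [validate_kb_tables()]'s job.
#'
#' @param directory path containing the six TSV files.
#' @return named list of character data frames
#'   (`entities`, `xrefs`, `composition`, `orthologs`, `pathways`,
#'   `annotations`).
#' @export
read_kb_tables <- function(directory) {
  if (!dir.exists(directory)) {
    stop(sprintf("knowledge-base directory '%s' does not exist", directory),
         call. = FALSE)
  }
  tables <- list()
  for (name in names(KB_FILES)) {
    path <- file.path(directory, paste0(name, ".tsv"))
    if (!file.exists(path)) {
      stop(sprintf("format error: missing file '%s.tsv'", name), call. = FALSE)
    }
    df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            na.strings = NULL, stringsAsFactors = FALSE)
    if (!identical(names(df), KB_FILES[[name]])) {
      stop(sprintf("format error: '%s.tsv' must have header: %s", name,
                   paste(KB_FILES[[name]], collapse = "\t")), call. = FALSE)
    }
    tables[[name]] <- df
  }
  tables
}

# Find one cycle in the composition relation (member -> container), or NULL.
.composition_cycle <- function(composition) {
  adj <- split(composition$container_id, composition$member_id)
  color <- new_rec()   # 1 = on stack, 2 = done
  cycle <- NULL
  visit <- function(id, stack) {
    if (!is.null(cycle)) return()
    st <- color[[id]]
    if (identical(st, 2L)) return()
    if (identical(st, 1L)) {
      at <- match(id, stack)
      cycle <<- c(stack[at:length(stack)], id)
      return()
    }
    color[[id]] <- 1L
    for (nxt in adj[[id]] %||% character(0)) visit(nxt, c(stack, id))
    color[[id]] <- 2L
  }
  for (id in unique(composition$member_id)) {
    visit(id, character(0))
    if (!is.null(cycle)) break
  }
  cycle
}

#' Validate knowledge-base tables against the model invariants
#'
#' Violations are data, not exceptions: the return value is a character
#' vector of human-readable descriptions, each naming the offending record
#' and rule, empty when every invariant holds. [load_knowledge_base()]
#' refuses to build from tables with violations.
#'
#' @param tables list of the six tables, as from [read_kb_tables()].
#' @return character vector of violation descriptions.
#' @export
validate_kb_tables <- function(tables) {
  v <- character(0)
  say <- function(...) v[[length(v) + 1L]] <<- sprintf(...)
  en <- tables$entities

  dup <- en$entity_id[duplicated(en$entity_id)]
  for (d in unique(dup)) say("entities: duplicate entity_id '%s'", d)
  for (i in seq_len(nrow(en))) {
    if (!nzchar(en$entity_id[[i]])) say("entities row %d: empty entity_id", i)
    if (!nzchar(en$species[[i]])) {
      say("entities '%s': empty species", en$entity_id[[i]])
    }
    cls <- en$entity_class[[i]]
    if (!cls %in% ENTITY_CLASSES) {
      say("entities '%s': unknown entity_class '%s'", en$entity_id[[i]], cls)
    } else if (cls %in% SINGLE_ENTITY_CLASSES && !nzchar(en$main_identifier[[i]])) {
      say("entities '%s': single entity requires a main_identifier", en$entity_id[[i]])
    } else if (cls %in% CONTAINER_CLASSES && nzchar(en$main_identifier[[i]])) {
      say("entities '%s': container must have empty main_identifier", en$entity_id[[i]])
    }
  }
  known <- new_rec()
  for (id in en$entity_id) known[[id]] <- TRUE
  species_of <- structure(en$species, names = en$entity_id)
  class_of <- structure(en$entity_class, names = en$entity_id)

  xr <- tables$xrefs
  for (i in seq_len(nrow(xr))) {
    if (!nzchar(xr$alias[[i]])) say("xrefs row %d: empty alias", i)
    if (is.null(known[[xr$entity_id[[i]]]])) {
      say("xrefs row %d: dangling reference to entity '%s'", i, xr$entity_id[[i]])
    }
  }
  dupx <- duplicated(paste(xr$alias, xr$entity_id, sep = "\r"))
  for (i in which(dupx)) {
    say("xrefs row %d: duplicate (alias '%s', entity '%s') pair", i,
        xr$alias[[i]], xr$entity_id[[i]])
  }

  co <- tables$composition
  for (i in seq_len(nrow(co))) {
    m <- co$member_id[[i]]; ct <- co$container_id[[i]]
    if (is.null(known[[m]])) say("composition row %d: dangling member '%s'", i, m)
    if (is.null(known[[ct]])) {
      say("composition row %d: dangling container '%s'", i, ct)
    } else if (!class_of[[ct]] %in% CONTAINER_CLASSES) {
      say("composition row %d: container '%s' has class '%s', not a container",
          i, ct, class_of[[ct]])
    }
    if (!co$relation[[i]] %in% c("complex_component", "set_member")) {
      say("composition row %d: unknown relation '%s'", i, co$relation[[i]])
    }
  }
  if (!any(startsWith(v, "composition"))) {
    cyc <- .composition_cycle(co)
    if (!is.null(cyc)) {
      say("composition: cycle detected: %s", paste(cyc, collapse = " -> "))
    }
    members_of <- split(co$member_id, co$container_id)
    for (id in en$entity_id[en$entity_class %in% CONTAINER_CLASSES]) {
      if (length(members_of[[id]] %||% character(0)) == 0L) {
        say("composition: warning: container '%s' has no members", id)
      }
    }
  }

  ort <- tables$orthologs
  for (i in seq_len(nrow(ort))) {
    a <- ort$entity_a[[i]]; b <- ort$entity_b[[i]]
    if (is.null(known[[a]])) say("orthologs row %d: dangling entity '%s'", i, a)
    else if (is.null(known[[b]])) say("orthologs row %d: dangling entity '%s'", i, b)
    else if (species_of[[a]] == species_of[[b]]) {
      say("orthologs row %d: '%s' and '%s' share species '%s'", i, a, b, species_of[[a]])
    }
  }
  key <- apply(cbind(pmin(ort$entity_a, ort$entity_b),
                     pmax(ort$entity_a, ort$entity_b)), 1L, paste, collapse = "\r")
  for (i in which(duplicated(key))) {
    say("orthologs row %d: duplicate pair ('%s','%s')", i, ort$entity_a[[i]], ort$entity_b[[i]])
  }

  pw <- tables$pathways
  dupp <- pw$pathway_id[duplicated(pw$pathway_id)]
  for (d in unique(dupp)) say("pathways: duplicate pathway_id '%s'", d)
  p_species <- structure(pw$species, names = pw$pathway_id)
  for (i in seq_len(nrow(pw))) {
    parent <- pw$parent_id[[i]]
    if (nzchar(parent)) {
      if (!parent %in% pw$pathway_id) {
        say("pathways '%s': dangling parent '%s'", pw$pathway_id[[i]], parent)
      } else if (p_species[[parent]] != pw$species[[i]]) {
        say("pathways '%s': parent '%s' has different species",
            pw$pathway_id[[i]], parent)
      }
    }
  }
  if (!any(startsWith(v, "pathways"))) {
    # parent links must form a forest: walking up must terminate
    for (pid in pw$pathway_id) {
      seen <- character(0)
      at <- pid
      cycled <- FALSE
      while (nzchar(at)) {
        if (at %in% seen) {
          say("pathways: parent cycle at '%s'", at)
          cycled <- TRUE
          break
        }
        seen <- c(seen, at)
        at <- pw$parent_id[[match(at, pw$pathway_id)]]
      }
      if (cycled) break
    }
  }

  an <- tables$annotations
  for (i in seq_len(nrow(an))) {
    e <- an$entity_id[[i]]; p <- an$pathway_id[[i]]
    if (is.null(known[[e]])) say("annotations row %d: dangling entity '%s'", i, e)
    else if (!p %in% pw$pathway_id) say("annotations row %d: dangling pathway '%s'", i, p)
    else if (species_of[[e]] != p_species[[p]]) {
      say("annotations row %d: entity '%s' (%s) annotated to pathway '%s' (%s)",
          i, e, species_of[[e]], p, p_species[[p]])
    }
  }
  v
}

#' Load a knowledge base into memory
#'
#' Reads the six interchange tables, validates them (any violation aborts
#' the load, naming the offending rows), then assembles the in-memory
#' composite used by the analysis: the radix-trie lookup table over every
#' main identifier and alias, the entity graph with composition, ortholog
#' and pathway edges, and the per-species pathway forests with curated
#' totals and background sizes filled in.
#'
#' @param directory path containing the six TSV files (see [kb_format]).
#' @param case_insensitive normalise identifiers to upper case in the
#'   lookup table (default `TRUE`); queries are normalised the same way.
#' @return a `knowledge_base` object.
#' @export
load_knowledge_base <- function(directory, case_insensitive = TRUE) {
  tables <- read_kb_tables(directory)
  violations <- validate_kb_tables(tables)
  if (length(violations)) {
    stop(sprintf("invalid knowledge base (%d violations):\n%s",
                 length(violations),
                 paste(utils::head(violations, 10L), collapse = "\n")),
         call. = FALSE)
  }
  graph <- .entity_graph_build(tables$entities, tables$composition,
                               tables$orthologs, tables$annotations)
  forest <- .pathway_forest_build(tables$pathways, tables$annotations)
  compute_totals(forest, graph)

  trie <- radix_trie()
  for (i in seq_len(nrow(tables$entities))) {
    main <- tables$entities$main_identifier[[i]]
    if (nzchar(main)) {
      id <- tables$entities$entity_id[[i]]
      trie_insert(trie, normalize_identifier(main, case_insensitive),
                  ref = graph$nodes[[id]], ref_id = id)
    }
  }
  for (i in seq_len(nrow(tables$xrefs))) {
    id <- tables$xrefs$entity_id[[i]]
    alias <- tables$xrefs$alias[[i]]
    trie_insert(trie, normalize_identifier(alias, case_insensitive),
                ref = graph$nodes[[id]], ref_id = id)
    node <- graph$nodes[[id]]
    node$aliases <- unique(c(node$aliases, alias))
  }

  structure(
    list(
      trie = trie,
      graph = graph,
      forest = forest,
      background = forest$background,
      background_sets = forest$background_sets,
      species = unique(c(graph$species, forest$species)),
      case_insensitive = case_insensitive,
      xrefs = tables$xrefs
    ),
    class = "knowledge_base"
  )
}

#' Reconstruct the interchange tables from a loaded knowledge base
#'
#' Row order is the order in which records were loaded, so a
#' write/load cycle is stable.
#'
#' @param kb a `knowledge_base`.
#' @return named list of the six character data frames.
#' @export
as_kb_tables <- function(kb) {
  g <- kb$graph
  f <- kb$forest
  nodes <- lapply(g$entity_ids, function(id) g$nodes[[id]])
  entities <- data.frame(
    entity_id = vapply(nodes, `[[`, character(1), "entity_id"),
    species = vapply(nodes, `[[`, character(1), "species"),
    entity_class = vapply(nodes, `[[`, character(1), "entity_class"),
    main_identifier = vapply(nodes, `[[`, character(1), "main_identifier"),
    stringsAsFactors = FALSE
  )
  comp <- do.call(rbind, c(list(data.frame(member_id = character(0),
                                           container_id = character(0),
                                           relation = character(0))),
    lapply(nodes, function(n) {
      if (!length(n$members)) return(NULL)
      data.frame(
        member_id = n$members,
        container_id = n$entity_id,
        relation = if (n$entity_class == "set") "set_member" else "complex_component",
        stringsAsFactors = FALSE
      )
    })))
  seen <- new_rec()
  oa <- character(0); ob <- character(0)
  for (n in nodes) {
    for (o in n$orthologs) {
      key <- paste(pmin(n$entity_id, o), pmax(n$entity_id, o), sep = "\r")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        oa <- c(oa, n$entity_id); ob <- c(ob, o)
      }
    }
  }
  orthologs <- data.frame(entity_a = oa, entity_b = ob, stringsAsFactors = FALSE)
  pnodes <- lapply(f$pathway_ids, function(id) f$nodes[[id]])
  pathways <- data.frame(
    pathway_id = vapply(pnodes, `[[`, character(1), "pathway_id"),
    species = vapply(pnodes, `[[`, character(1), "species"),
    name = vapply(pnodes, `[[`, character(1), "name"),
    parent_id = vapply(pnodes, `[[`, character(1), "parent_id"),
    stringsAsFactors = FALSE
  )
  annotations <- do.call(rbind, c(list(data.frame(entity_id = character(0),
                                                  pathway_id = character(0))),
    lapply(pnodes, function(n) {
      if (!length(n$annotated)) return(NULL)
      data.frame(entity_id = n$annotated, pathway_id = n$pathway_id,
                 stringsAsFactors = FALSE)
    })))
  xrefs <- kb$xrefs
  rownames(comp) <- rownames(annotations) <- NULL
  list(entities = entities, xrefs = xrefs, composition = comp,
       orthologs = orthologs, pathways = pathways, annotations = annotations)
}

#' Write a knowledge base back to the interchange format
#'
#' @param kb a `knowledge_base`.
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_knowledge_base <- function(kb, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  tables <- as_kb_tables(kb)
  write_kb_tables(tables, directory)
}

#' @rdname write_knowledge_base
#' @param tables named list of the six interchange tables.
#' @export
write_kb_tables <- function(tables, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (name in names(KB_FILES)) {
    df <- tables[[name]]
    stopifnot(identical(names(df), KB_FILES[[name]]))
    utils::write.table(df, file.path(directory, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  }
  invisible(directory)
}

#' Re-validate a loaded knowledge base
#'
#' Reconstructs the interchange tables from the in-memory composite and
#' runs [validate_kb_tables()], plus structural checks on the built
#' composite (trie coverage of identifiers, parent/child double linkage).
#'
#' @param kb a `knowledge_base`.
#' @return character vector of violation descriptions (empty when clean).
#' @export
validate_knowledge_base <- function(kb) {
  v <- validate_kb_tables(as_kb_tables(kb))
  g <- kb$graph
  for (id in g$entity_ids) {
    node <- g$nodes[[id]]
    ids <- c(if (nzchar(node$main_identifier)) node$main_identifier, node$aliases)
    for (key in ids) {
      hit <- trie_lookup(kb$trie, normalize_identifier(key, kb$case_insensitive))
      if (is.null(hit) || is.null(hit[[id]])) {
        v[[length(v) + 1L]] <-
          sprintf("trie: identifier '%s' of entity '%s' not resolvable", key, id)
      }
    }
  }
  f <- kb$forest
  for (pid in f$pathway_ids) {
    node <- f$nodes[[pid]]
    for (ch in node$children) {
      if (!identical(f$nodes[[ch]]$parent_id, pid)) {
        v[[length(v) + 1L]] <-
          sprintf("hierarchy: child '%s' does not point back to '%s'", ch, pid)
      }
    }
  }
  v
}

#' Export a species' pathways as GMT gene sets
#'
#' One line per pathway: pathway id, display name, then the flattened main
#' identifiers of all single entities curated in the pathway or any of its
#' sub-pathways (the per-node curated total set). The standard exchange
#' format of gene-set tools.
#'
#' @param kb a `knowledge_base`.
#' @param species species name present in the knowledge base.
#' @param file optional path; when given the GMT text is written there.
#' @return the GMT text as a single string, invisibly when `file` is given.
#' @export
export_gmt <- function(kb, species, file = NULL) {
  f <- kb$forest
  if (!species %in% f$species) {
    stop(sprintf("unknown species '%s'", species), call. = FALSE)
  }
  lines <- character(0)
  for (pid in f$pathway_ids) {
    node <- f$nodes[[pid]]
    if (node$species != species) next
    lines[[length(lines) + 1L]] <-
      paste(c(pid, node$name, sort_c(node$total_set)), collapse = "\t")
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(lines, file, sep = "\n", useBytes = TRUE)
    return(invisible(text))
  }
  text
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>\n")
  print(x$trie)
  print(x$graph)
  print(x$forest)
  invisible(x)
}
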