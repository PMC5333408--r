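SPECIES_POOL <- c(
  "Homo sapiens", "Mus musculus", "Rattus norvegicus", "Danio rerio",
  "Drosophila melanogaster", "Caenorhabditis elegans", "Saccharomyces cerevisiae"
)

#' Parameters of a synthetic knowledge base
#'
#' Describes a random but structurally Reactome-like knowledge base: single
#' entities with UniProt-style (`P#####`/`Q#####`/`O#####`) and ChEBI-style
#' accessions plus gene-symbol-like aliases (some deliberately shared
#' between entities, exercising one-to-many lookup), nested complexes and
#' sets forming a composition DAG, ortholog links from every non-reference
#' species back to the reference, and a rooted pathway forest per species.
#'
#' Defaults describe a compact but non-trivial world: a few hundred single
#' entities, container nesting up to three levels, two species sharing
#' orthologs for about 60% of entities, and a three-level hierarchy —
#' enough structure to exercise every traversal without slowing tests.
#'
#' @param n_proteins,n_chemicals single entities of the reference species.
#' @param n_complexes,n_sets container entities (a fraction of the
#'   "complexes" are emitted as polymers, which share their semantics).
#' @param max_members maximum members per container (at least 2).
#' @param nesting_depth maximum container nesting level (at least 1).
#' @param n_species number of species; the first is the reference.
#' @param ortholog_fraction probability that a reference single entity has
#'   an ortholog in each non-reference species.
#' @param n_top_pathways top-level pathways per species.
#' @param hierarchy_depth maximum depth of the pathway trees.
#' @param annotations_per_pathway length-2 integer range of direct
#'   annotations drawn per pathway.
#' @param aliases_per_entity length-2 integer range of aliases per single
#'   entity.
#' @param seed integer seed; all draws flow from one generator seeded once.
#' @return a `synthetic_kb_spec` list.
#' @export
synthetic_kb_spec <- function(n_proteins = 300, n_chemicals = 40,
                              n_complexes = 60, n_sets = 30,
                              max_members = 4, nesting_depth = 3,
                              n_species = 2, ortholog_fraction = 0.6,
                              n_top_pathways = 6, hierarchy_depth = 3,
                              annotations_per_pathway = c(3, 10),
                              aliases_per_entity = c(1, 3),
                              seed = 1) {
  spec <- list(
    n_proteins = as.integer(n_proteins), n_chemicals = as.integer(n_chemicals),
    n_complexes = as.integer(n_complexes), n_sets = as.integer(n_sets),
    max_members = as.integer(max_members), nesting_depth = as.integer(nesting_depth),
    n_species = as.integer(n_species), ortholog_fraction = ortholog_fraction,
    n_top_pathways = as.integer(n_top_pathways),
    hierarchy_depth = as.integer(hierarchy_depth),
    annotations_per_pathway = as.integer(annotations_per_pathway),
    aliases_per_entity = as.integer(aliases_per_entity),
    seed = as.integer(seed)
  )
  with(spec, {
    stopifnot(n_proteins >= 0, n_chemicals >= 0, n_complexes >= 0, n_sets >= 0,
              max_members >= 2, nesting_depth >= 1, n_species >= 1,
              ortholog_fraction >= 0, ortholog_fraction <= 1,
              n_top_pathways >= 1, hierarchy_depth >= 1,
              length(annotations_per_pathway) == 2L,
              length(aliases_per_entity) == 2L)
  })
  if ((spec$n_complexes + spec$n_sets) > 0 && (spec$n_proteins + spec$n_chemicals) < 2) {
    stop("infeasible spec: containers require at least two single entities",
         call. = FALSE)
  }
  class(spec) <- "synthetic_kb_spec"
  spec
}

# deterministic draw of distinct 5-digit accession numbers
.draw_accessions <- function(n, prefix_pool) {
  nums <- sample.int(100000L, n) - 1L
  paste0(sample(prefix_pool, n, replace = TRUE), sprintf("%05d", nums))
}

# uniform draw from lo:hi, safe when lo == hi (no sample(n, 1) surprise)
.sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(lo, n) else lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic knowledge base
#'
#' Writes the six interchange TSV files (see [kb_format]) to `directory`.
#' Generation is fully deterministic for a fixed spec (byte-identical
#' files); every generated knowledge base passes
#' [validate_kb_tables()] with zero violations. Containers are nested up to
#' `nesting_depth` by assigning each container a level and drawing its
#' members from strictly lower levels, which guarantees a composition DAG.
#' Containers are generated for the reference species; non-reference
#' species receive ortholog single entities and their own pathway forest.
#'
#' @param spec a [synthetic_kb_spec()].
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
generate_kb <- function(spec, directory) {
  stopifnot(inherits(spec, "synthetic_kb_spec"))
  withr::with_seed(spec$seed, .generate_kb_impl(spec, directory))
}

.generate_kb_impl <- function(spec, directory) {
  species <- c(SPECIES_POOL, sprintf("Species %d", seq_len(spec$n_species)))
  species <- species[seq_len(spec$n_species)]
  reference <- species[[1L]]

  pe_counter <- 0L
  next_pe <- function(n = 1L) {
    ids <- sprintf("PE%06d", pe_counter + seq_len(n))
    pe_counter <<- pe_counter + n
    ids
  }

  n_single <- spec$n_proteins + spec$n_chemicals
  prot_acc_all <- .draw_accessions(spec$n_proteins * spec$n_species, c("P", "Q", "O"))
  chem_nums <- sample.int(100000L, spec$n_chemicals * spec$n_species) - 1L
  chem_acc_all <- sprintf("CHEBI:%05d", chem_nums)

  entities <- list()
  add_entities <- function(ids, sp, cls, mains) {
    entities[[length(entities) + 1L]] <<- data.frame(
      entity_id = ids, species = sp, entity_class = cls,
      main_identifier = mains, stringsAsFactors = FALSE
    )
  }

  # reference species single entities
  ref_prot <- next_pe(spec$n_proteins)
  ref_chem <- next_pe(spec$n_chemicals)
  if (spec$n_proteins) {
    add_entities(ref_prot, reference, "protein", prot_acc_all[seq_len(spec$n_proteins)])
  }
  if (spec$n_chemicals) {
    add_entities(ref_chem, reference, "chemical", chem_acc_all[seq_len(spec$n_chemicals)])
  }
  ref_singles <- c(ref_prot, ref_chem)

  # containers, levelled to guarantee a DAG
  composition <- list(data.frame(member_id = character(0),
                                 container_id = character(0),
                                 relation = character(0),
                                 stringsAsFactors = FALSE))
  n_containers <- spec$n_complexes + spec$n_sets
  container_ids <- next_pe(n_containers)
  container_class <- c(
    rep("complex", spec$n_complexes),
    rep("set", spec$n_sets)
  )
  if (spec$n_complexes >= 7) {
    container_class[seq(7L, spec$n_complexes, by = 7L)] <- "polymer"
  }
  container_level <- if (n_containers) {
    (seq_len(n_containers) - 1L) %% spec$nesting_depth + 1L
  } else integer(0)
  if (n_containers) {
    # shuffle class assignment so complexes and sets occur at every level
    container_class <- container_class[sample.int(n_containers)]
    add_entities(container_ids, reference, container_class,
                 rep("", n_containers))
    for (i in seq_len(n_containers)) {
      pool <- c(ref_singles, container_ids[container_level < container_level[[i]]])
      m <- .sample_range(2L, spec$max_members)
      members <- pool[sample.int(length(pool), min(m, length(pool)))]
      composition[[length(composition) + 1L]] <- data.frame(
        member_id = members,
        container_id = container_ids[[i]],
        relation = if (container_class[[i]] == "set") "set_member" else "complex_component",
        stringsAsFactors = FALSE
      )
    }
  }

  # non-reference species: ortholog single entities
  orthologs <- list(data.frame(entity_a = character(0), entity_b = character(0),
                               stringsAsFactors = FALSE))
  singles_by_species <- list()
  singles_by_species[[reference]] <- ref_singles
  acc_used <- n_single
  for (si in seq_along(species)[-1L]) {
    sp <- species[[si]]
    has_orth <- stats::runif(n_single) < spec$ortholog_fraction
    src <- ref_singles[has_orth]
    if (!length(src)) {
      singles_by_species[[sp]] <- character(0)
      next
    }
    ids <- next_pe(length(src))
    src_is_prot <- src %in% ref_prot
    n_p <- sum(src_is_prot)
    n_c <- sum(!src_is_prot)
    prot_from <- spec$n_proteins * (si - 1L)
    chem_from <- spec$n_chemicals * (si - 1L)
    mains <- character(length(src))
    mains[src_is_prot] <- prot_acc_all[prot_from + seq_len(n_p)]
    mains[!src_is_prot] <- chem_acc_all[chem_from + seq_len(n_c)]
    add_entities(ids, sp, ifelse(src_is_prot, "protein", "chemical"), mains)
    orthologs[[length(orthologs) + 1L]] <- data.frame(
      entity_a = src, entity_b = ids, stringsAsFactors = FALSE
    )
    singles_by_species[[sp]] <- ids
  }

  # pathway forest per species
  pw_counter <- 0L
  pathways <- list()
  annotations <- list(data.frame(entity_id = character(0),
                                 pathway_id = character(0),
                                 stringsAsFactors = FALSE))
  for (sp in species) {
    sp_pool <- singles_by_species[[sp]]
    if (identical(sp, reference)) sp_pool <- c(sp_pool, container_ids)
    if (!length(sp_pool)) next
    level_nodes <- character(0)
    for (d in seq_len(spec$hierarchy_depth)) {
      if (d == 1L) {
        n_new <- spec$n_top_pathways
        parents <- rep("", n_new)
      } else {
        n_children <- vapply(level_nodes, function(p) sample(0:3, 1L), integer(1))
        n_new <- sum(n_children)
        if (!n_new) break
        parents <- rep(level_nodes, n_children)
      }
      ids <- sprintf("PW%05d", pw_counter + seq_len(n_new))
      pw_counter <- pw_counter + n_new
      pathways[[length(pathways) + 1L]] <- data.frame(
        pathway_id = ids, species = sp,
        name = sprintf("Synthetic pathway %s", sub("^PW0*", "", ids)),
        parent_id = parents, stringsAsFactors = FALSE
      )
      level_nodes <- ids
      for (pid in ids) {
        k <- .sample_range(spec$annotations_per_pathway[[1L]],
                           spec$annotations_per_pathway[[2L]])
        ann <- unique(sp_pool[sample.int(length(sp_pool), min(k, length(sp_pool)))])
        annotations[[length(annotations) + 1L]] <- data.frame(
          entity_id = ann, pathway_id = pid, stringsAsFactors = FALSE
        )
      }
    }
  }

  # aliases: gene-symbol style per single entity, plus shared symbols
  entities_df <- do.call(rbind, entities)
  singles_all <- entities_df$entity_id[entities_df$entity_class %in% SINGLE_ENTITY_CLASSES]
  xrefs <- list(data.frame(alias = character(0), entity_id = character(0),
                           resource = character(0), stringsAsFactors = FALSE))
  resources <- c("GeneCards", "Ensembl", "RefSeq")
  if (length(singles_all)) {
    k <- .sample_range(spec$aliases_per_entity[[1L]], spec$aliases_per_entity[[2L]],
                       length(singles_all))
    total <- sum(k)
    if (total > 0L) {
      lm <- matrix(sample(LETTERS, 4L * total, replace = TRUE), nrow = 4L)
      syms <- paste0(lm[1L, ], lm[2L, ], lm[3L, ], lm[4L, ],
                     sample.int(9L, total, replace = TRUE))
      df <- data.frame(
        alias = syms,
        entity_id = rep(singles_all, k),
        resource = sample(resources, total, replace = TRUE),
        stringsAsFactors = FALSE
      )
      df <- df[!duplicated(paste(df$alias, df$entity_id, sep = "\r")), , drop = FALSE]
      xrefs[[length(xrefs) + 1L]] <- df
    }
  }
  if (length(singles_all) >= 2L) {
    n_shared <- max(1L, length(singles_all) %/% 50L)
    for (i in seq_len(n_shared)) {
      pair <- singles_all[sample.int(length(singles_all), 2L)]
      xrefs[[length(xrefs) + 1L]] <- data.frame(
        alias = sprintf("FAM%03dA", i), entity_id = pair,
        resource = "GeneCards", stringsAsFactors = FALSE
      )
    }
  }

  tables <- list(
    entities = entities_df,
    xrefs = do.call(rbind, xrefs),
    composition = do.call(rbind, composition),
    orthologs = do.call(rbind, orthologs),
    pathways = do.call(rbind, pathways),
    annotations = do.call(rbind, annotations)
  )
  if (is.null(tables$pathways)) {
    tables$pathways <- data.frame(pathway_id = character(0), species = character(0),
                                  name = character(0), parent_id = character(0),
                                  stringsAsFactors = FALSE)
  }
  write_kb_tables(tables, directory)
}

#' Generate a sample enriched for one pathway
#'
#' Draws `ceiling(enrichment_fraction * n_sample)` distinct identifiers
#' from the enriched pathway's flattened entity set and the remainder
#' uniformly from the rest of the species background (all without
#' replacement), then swaps each picked main identifier for one of its
#' aliases with probability `alias_prob` — emulating users submitting gene
#' names rather than accessions. Deterministic for a fixed seed.
#'
#' With `enrichment_fraction = 0` this is a pure null sample.
#'
#' @param kb a loaded `knowledge_base`.
#' @param enriched_pathway pathway id to enrich for.
#' @param n_sample sample size (at most the species background size).
#' @param enrichment_fraction fraction of the sample drawn from the pathway.
#' @param seed integer seed.
#' @param alias_prob probability of submitting an alias instead of the main
#'   identifier.
#' @return character vector of `n_sample` identifiers (shuffled).
#' @export
generate_sample <- function(kb, enriched_pathway, n_sample,
                            enrichment_fraction = 0.5, seed = 1,
                            alias_prob = 0.2) {
  stopifnot(inherits(kb, "knowledge_base"),
            enrichment_fraction >= 0, enrichment_fraction <= 1)
  node <- kb$forest$nodes[[enriched_pathway]]
  if (is.null(node)) {
    stop(sprintf("unknown pathway '%s'", enriched_pathway), call. = FALSE)
  }
  bg <- kb$background_sets[[node$species]]
  if (n_sample > length(bg)) {
    stop("n_sample exceeds the species background size", call. = FALSE)
  }
  n_enriched <- as.integer(ceiling(enrichment_fraction * n_sample))
  pset <- node$total_set
  if (length(pset) < n_enriched) {
    stop(sprintf("pathway '%s' has only %d entities, %d required",
                 enriched_pathway, length(pset), n_enriched), call. = FALSE)
  }
  withr::with_seed(seed, {
    enriched <- pset[sample.int(length(pset), n_enriched)]
    rest_pool <- setdiff(bg, enriched)
    n_rest <- n_sample - n_enriched
    rest <- rest_pool[sample.int(length(rest_pool), n_rest)]
    ids <- c(enriched, rest)
    swap <- stats::runif(length(ids)) < alias_prob
    for (i in which(swap)) {
      payload <- trie_lookup(kb$trie, normalize_identifier(ids[[i]], kb$case_insensitive))
      aliases <- sort_c(unlist(lapply(payload, function(node) node$aliases),
                               use.names = FALSE))
      if (length(aliases)) {
        ids[[i]] <- aliases[[sample.int(length(aliases), 1L)]]
      }
    }
    ids[sample.int(length(ids))]
  })
}
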