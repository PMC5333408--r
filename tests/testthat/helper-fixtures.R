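# Fixtures are built in code: small interchange-table constructors, the
# published worked-example knowledge base, and independent brute-force
# oracles (implemented on the raw tables, never through the package's own
# graph/tree traversals).

HS <- "Homo sapiens"

kb_tables_skeleton <- function() {
  list(
    entities = data.frame(entity_id = character(0), species = character(0),
                          entity_class = character(0), main_identifier = character(0),
                          stringsAsFactors = FALSE),
    xrefs = data.frame(alias = character(0), entity_id = character(0),
                       resource = character(0), stringsAsFactors = FALSE),
    composition = data.frame(member_id = character(0), container_id = character(0),
                             relation = character(0), stringsAsFactors = FALSE),
    orthologs = data.frame(entity_a = character(0), entity_b = character(0),
                           stringsAsFactors = FALSE),
    pathways = data.frame(pathway_id = character(0), species = character(0),
                          name = character(0), parent_id = character(0),
                          stringsAsFactors = FALSE),
    annotations = data.frame(entity_id = character(0), pathway_id = character(0),
                             stringsAsFactors = FALSE)
  )
}

make_kb_tables <- function(...) {
  tabs <- kb_tables_skeleton()
  args <- list(...)
  for (n in names(args)) tabs[[n]] <- args[[n]]
  tabs
}

# first pathway whose curated total supports a draw of at least `min_total`
pick_pathway <- function(kb, min_total) {
  totals <- vapply(kb$forest$pathway_ids,
                   function(p) kb$forest$nodes[[p]]$total_entities, integer(1))
  kb$forest$pathway_ids[[which(totals >= min_total)[1]]]
}

make_kb_dir <- function(tables, dir = tempfile("kb")) {
  write_kb_tables(tables, dir)
  dir
}

# The published worked example: proteins P1-P3, set S2 = {P2,P3},
# complex C1 = {P1,S2}, set S1 = {P1,C1}, complex C2 = {S1,P2};
# one pathway W annotated with C2.
fig2_tables <- function(annotations = data.frame(entity_id = "C2", pathway_id = "W",
                                                 stringsAsFactors = FALSE)) {
  make_kb_tables(
    entities = data.frame(
      entity_id = c("P1", "P2", "P3", "S2", "C1", "S1", "C2"),
      species = HS,
      entity_class = c("protein", "protein", "protein", "set", "complex", "set", "complex"),
      main_identifier = c("P1", "P2", "P3", "", "", "", ""),
      stringsAsFactors = FALSE
    ),
    composition = data.frame(
      member_id    = c("P2", "P3", "P1", "S2", "P1", "C1", "S1", "P2"),
      container_id = c("S2", "S2", "C1", "C1", "S1", "S1", "C2", "C2"),
      relation = c("set_member", "set_member", "complex_component", "complex_component",
                   "set_member", "set_member", "complex_component", "complex_component"),
      stringsAsFactors = FALSE
    ),
    pathways = data.frame(pathway_id = "W", species = HS, name = "Pathway W",
                          parent_id = "", stringsAsFactors = FALSE),
    annotations = annotations
  )
}

fig2_kb <- function(...) load_knowledge_base(make_kb_dir(fig2_tables(...)))

# The 17 identifiers of the published radix-tree figure.
FIG1_IDS <- c("P60484", "P60467", "P60468", "P29172", "P11087", "P11086",
              "P10639", "P10636", "P10635", "P10622", "P10620", "P12939",
              "P12938", "P12931", "P05480", "P05386", "PTEN")

# ---- independent oracles on the raw tables ---------------------------------

single_classes <- c("protein", "chemical", "rna", "dna", "gene")

oracle_flatten <- function(tables, id) {
  cls <- tables$entities$entity_class[tables$entities$entity_id == id]
  if (cls %in% single_classes) {
    return(tables$entities$main_identifier[tables$entities$entity_id == id])
  }
  members <- tables$composition$member_id[tables$composition$container_id == id]
  sort(unique(unlist(lapply(members, oracle_flatten, tables = tables))))
}

oracle_containers <- function(tables, id) {
  out <- character(0)
  frontier <- id
  repeat {
    nxt <- unique(tables$composition$container_id[
      tables$composition$member_id %in% frontier])
    nxt <- setdiff(nxt, out)
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

oracle_subtree <- function(tables, pid) {
  out <- pid
  frontier <- pid
  repeat {
    nxt <- tables$pathways$pathway_id[tables$pathways$parent_id %in% frontier]
    nxt <- setdiff(nxt, out)
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

oracle_total_set <- function(tables, pid) {
  subtree <- oracle_subtree(tables, pid)
  ann <- tables$annotations$entity_id[tables$annotations$pathway_id %in% subtree]
  sort(unique(unlist(lapply(unique(ann), oracle_flatten, tables = tables))))
}

# number of structure variants, by direct recursion on the tables
oracle_variant_count <- function(tables, id) {
  cls <- tables$entities$entity_class[tables$entities$entity_id == id]
  if (cls %in% single_classes) return(1)
  members <- tables$composition$member_id[tables$composition$container_id == id]
  counts <- vapply(members, oracle_variant_count, numeric(1), tables = tables)
  if (cls == "set") sum(counts) else prod(counts)
}

small_synth_spec <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_proteins = 120, n_chemicals = 20, n_complexes = 25, n_sets = 12,
         n_species = 2, n_top_pathways = 4, seed = seed),
    list(...)
  )
  do.call(synthetic_kb_spec, args)
}

synth_kb <- function(seed, ...) {
  dir <- tempfile(sprintf("synth%d_", seed))
  generate_kb(small_synth_spec(seed, ...), dir)
  load_knowledge_base(dir)
}
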