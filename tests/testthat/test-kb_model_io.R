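test_that("loading links graph, trie and hierarchy for the worked example", {
  kb <- fig2_kb()
  g <- kb$graph
  expect_identical(g$nodes[["C2"]]$members, c("S1", "P2"))
  expect_identical(g$nodes[["C1"]]$members, c("P1", "S2"))
  expect_identical(g$nodes[["S2"]]$members, c("P2", "P3"))
  expect_setequal(g$nodes[["P1"]]$containers, c("C1", "S1"))
  expect_identical(g$nodes[["C2"]]$pathways, "W")
  # trie holds the main identifiers, resolving to the graph nodes
  payload <- trie_lookup(kb$trie, "P3")
  expect_identical(names(payload), "P3")
  expect_identical(payload[["P3"]]$entity_id, "P3")
  expect_identical(kb$background[[HS]], 3L)
})

test_that("empty annotations give a zero background for every species", {
  tables <- fig2_tables(annotations = kb_tables_skeleton()$annotations)
  kb <- load_knowledge_base(make_kb_dir(tables))
  expect_identical(kb$background[[HS]], 0L)
  expect_identical(kb$forest$nodes[["W"]]$total_entities, 0L)
})

test_that("format errors name the missing file; violations abort the load", {
  dir <- make_kb_dir(fig2_tables())
  file.remove(file.path(dir, "orthologs.tsv"))
  expect_error(load_knowledge_base(dir), "orthologs.tsv")

  bad <- fig2_tables()
  bad$xrefs <- data.frame(alias = "GENE1", entity_id = "GHOST", resource = "x",
                          stringsAsFactors = FALSE)
  expect_error(load_knowledge_base(make_kb_dir(bad)), "GHOST")
})

test_that("validation reports each broken invariant as data", {
  expect_identical(validate_kb_tables(fig2_tables()), character(0))

  # composition self-loop -> exactly one cycle violation
  bad <- fig2_tables()
  bad$composition <- rbind(bad$composition,
                           data.frame(member_id = "C1", container_id = "C1",
                                      relation = "complex_component",
                                      stringsAsFactors = FALSE))
  v <- validate_kb_tables(bad)
  expect_length(grep("cycle", v), 1L)

  # dangling alias -> one dangling-reference violation
  bad <- fig2_tables()
  bad$xrefs <- data.frame(alias = "GENE1", entity_id = "GHOST", resource = "x",
                          stringsAsFactors = FALSE)
  v <- validate_kb_tables(bad)
  expect_length(v, 1L)
  expect_match(v, "dangling")

  # single entity without a main identifier, container with one
  bad <- fig2_tables()
  bad$entities$main_identifier[bad$entities$entity_id == "P1"] <- ""
  bad$entities$main_identifier[bad$entities$entity_id == "C1"] <- "ACC"
  v <- validate_kb_tables(bad)
  expect_length(grep("main_identifier|requires", v), 2L)

  # annotation species mismatch
  bad <- fig2_tables()
  bad$entities <- rbind(bad$entities,
                        data.frame(entity_id = "MX", species = "Mus musculus",
                                   entity_class = "protein", main_identifier = "P99999",
                                   stringsAsFactors = FALSE))
  bad$annotations <- rbind(bad$annotations,
                           data.frame(entity_id = "MX", pathway_id = "W",
                                      stringsAsFactors = FALSE))
  expect_match(validate_kb_tables(bad), "annotated to pathway")

  # ortholog pair within one species
  bad <- fig2_tables()
  bad$orthologs <- data.frame(entity_a = "P1", entity_b = "P2",
                              stringsAsFactors = FALSE)
  expect_match(validate_kb_tables(bad), "share species")
})

test_that("a synthetic knowledge base survives a write -> load round trip", {
  # ~200 entities: 150 proteins + 20 chemicals + 30 containers
  spec <- synthetic_kb_spec(n_proteins = 150, n_chemicals = 20,
                            n_complexes = 20, n_sets = 10, seed = 1)
  dir <- tempfile("round")
  generate_kb(spec, dir)
  kb <- load_knowledge_base(dir)

  dir2 <- tempfile("round2")
  write_knowledge_base(kb, dir2)
  kb2 <- load_knowledge_base(dir2)

  expect_identical(as_kb_tables(kb), as_kb_tables(kb2))
  expect_identical(trie_stats(kb$trie), trie_stats(kb2$trie))
  expect_identical(kb$background, kb2$background)
  expect_identical(kb$background_sets, kb2$background_sets)
  for (pid in kb$forest$pathway_ids) {
    expect_identical(kb$forest$nodes[[pid]]$total_entities,
                     kb2$forest$nodes[[pid]]$total_entities)
  }
})

test_that("in-memory revalidation is clean on loaded knowledge bases", {
  expect_identical(validate_knowledge_base(fig2_kb()), character(0))
  expect_identical(validate_knowledge_base(synth_kb(2)), character(0))
})

test_that("GMT export flattens containers down to single entities", {
  kb <- fig2_kb()   # one pathway annotated with the complex C2 only
  gmt <- export_gmt(kb, HS)
  expect_identical(gmt, "W\tPathway W\tP1\tP2\tP3\n")

  # pathway with no annotations -> empty member list
  tables <- fig2_tables()
  tables$pathways <- rbind(tables$pathways,
                           data.frame(pathway_id = "V", species = HS, name = "Empty V",
                                      parent_id = "", stringsAsFactors = FALSE))
  kb2 <- load_knowledge_base(make_kb_dir(tables))
  lines <- strsplit(export_gmt(kb2, HS), "\n")[[1]]
  expect_identical(lines[[2]], "V\tEmpty V")

  expect_error(export_gmt(kb, "Vulcan"), "unknown species")
})

test_that("a parent pathway's GMT set contains the union of its children's", {
  kb <- synth_kb(1)
  tables <- as_kb_tables(kb)
  gmt <- strsplit(export_gmt(kb, HS), "\n")[[1]]
  sets <- lapply(strsplit(gmt, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(gmt, "\t"), `[[`, character(1), 1L)
  for (i in seq_len(nrow(tables$pathways))) {
    parent <- tables$pathways$parent_id[[i]]
    pid <- tables$pathways$pathway_id[[i]]
    if (nzchar(parent) && pid %in% names(sets) && parent %in% names(sets)) {
      expect_true(all(sets[[pid]] %in% sets[[parent]]), info = pid)
    }
  }
})
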