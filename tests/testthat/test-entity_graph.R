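test_that("container traversal follows composition edges transitively", {
  kb <- fig2_kb()
  g <- kb$graph
  expect_setequal(containers_of(g, "P3"), c("S2", "C1", "S1", "C2"))
  expect_setequal(containers_of(g, "P1"), c("C1", "S1", "C2"))
  expect_setequal(containers_of(g, "P2"), c("S2", "C1", "S1", "C2"))
  expect_identical(containers_of(g, "C2"), character(0))

  # monotonicity: every container reached from m contains strictly fewer
  # reachable structures than m itself
  for (m in c("P1", "P2", "P3", "S2", "C1", "S1")) {
    cm <- containers_of(g, m)
    for (ct in cm) {
      expect_true(all(containers_of(g, ct) %in% cm))
      expect_lt(length(containers_of(g, ct)), length(cm))
    }
  }
})

test_that("structure deconstruction reproduces the published variants", {
  kb <- fig2_kb()
  g <- kb$graph
  fmt <- function(id) vapply(expand_structure(g, id), variant_format, character(1))
  expect_identical(fmt("S2"), c("P2", "P3"))
  expect_identical(fmt("C1"), c("{P1,P2}", "{P1,P3}"))
  expect_identical(fmt("S1"), c("P1", "{P1,P2}", "{P1,P3}"))
  expect_identical(fmt("C2"), c("{P1,P2}", "{{P1,P2},P2}", "{{P1,P3},P2}"))
  # a single entity is its own variant
  expect_identical(fmt("P2"), "P2")
})

test_that("variant counts and leaves match brute-force recursion on synthetic compositions", {
  kb <- synth_kb(3)
  tables <- as_kb_tables(kb)
  containers <- tables$entities$entity_id[
    tables$entities$entity_class %in% c("complex", "set", "polymer")]
  expect_gt(length(containers), 10)
  for (id in containers) {
    variants <- expand_structure(kb$graph, id)
    expect_identical(length(variants), as.integer(oracle_variant_count(tables, id)),
                     info = id)
    # every variant's leaves are composition-reachable single entities
    flat <- oracle_flatten(tables, id)
    for (v in variants) expect_true(all(variant_flatten(v) %in% flat), info = id)
  }
})

test_that("ortholog projection replaces, passes through and reports losses", {
  tables <- make_kb_tables(
    entities = data.frame(
      entity_id = c("HP1", "MP1", "MP2"),
      species = c(HS, "Mus musculus", "Mus musculus"),
      entity_class = "protein",
      main_identifier = c("P10001", "P20001", "P20002"),
      stringsAsFactors = FALSE
    ),
    orthologs = data.frame(entity_a = "HP1", entity_b = "MP1", stringsAsFactors = FALSE),
    pathways = data.frame(pathway_id = "W", species = HS, name = "W", parent_id = "",
                          stringsAsFactors = FALSE),
    annotations = data.frame(entity_id = "HP1", pathway_id = "W", stringsAsFactors = FALSE)
  )
  kb <- load_knowledge_base(make_kb_dir(tables))
  g <- kb$graph

  pr <- project_orthologs(g, c("MP1", "MP2"), HS)
  expect_identical(pr$projected, "HP1")
  expect_identical(pr$unprojected, "MP2")

  # reference-species entities pass through unchanged
  pr2 <- project_orthologs(g, "HP1", HS)
  expect_identical(pr2$projected, "HP1")
  expect_identical(pr2$unprojected, character(0))

  # idempotence: projecting an already-projected set is the identity
  pr3 <- project_orthologs(g, pr$projected, HS)
  expect_identical(pr3$projected, pr$projected)
  expect_identical(pr3$unprojected, character(0))

  expect_error(project_orthologs(g, "HP1", "Vulcan"), "unknown species")
})

test_that("pathway links are collected through all containing structures", {
  kb <- fig2_kb()   # only C2 is annotated, to pathway W
  links <- collect_pathway_links(kb$graph, c("P1", "P2", "P3"))
  expect_identical(links$P1, "W")   # P1 reaches W only via C2
  expect_identical(links$P2, "W")
  expect_identical(links$P3, "W")

  # unannotated entity with unannotated containers yields an empty entry
  tables <- fig2_tables(annotations = data.frame(entity_id = "S2", pathway_id = "W",
                                                 stringsAsFactors = FALSE))
  kb2 <- load_knowledge_base(make_kb_dir(tables))
  links2 <- collect_pathway_links(kb2$graph, "P1")
  expect_identical(links2$P1, character(0))   # P1 is not under S2
})

test_that("collected links agree with an exhaustive-join oracle on a synthetic KB", {
  kb <- synth_kb(3)
  tables <- as_kb_tables(kb)
  singles <- tables$entities$entity_id[tables$entities$entity_class %in% single_classes]
  links <- collect_pathway_links(kb$graph, singles)
  for (id in singles) {
    reach <- c(id, oracle_containers(tables, id))
    expected <- sort(unique(tables$annotations$pathway_id[
      tables$annotations$entity_id %in% reach]))
    expect_identical(links[[id]], expected, info = id)
  }
})
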