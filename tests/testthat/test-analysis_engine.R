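test_that("the four steps compose on the worked example", {
  kb <- fig2_kb()
  res <- run_analysis("P3", kb)
  expect_identical(res$mapping, list(P3 = "P3"))
  expect_identical(res$not_found, character(0))
  expect_identical(nrow(res$rows), 1L)
  expect_identical(res$rows$entities_found, 1L)
  expect_identical(res$rows$matched_identifiers, "P3:P3")
  expect_identical(res$summary$sample_size_submitted, 1L)
  expect_identical(res$summary$sample_size_mapped, 1L)
  expect_identical(res$summary$background_size, list(`Homo sapiens` = 3L))
})

test_that("unknown identifiers are reported, with all-zero rows", {
  kb <- fig2_kb()
  res <- run_analysis(c("NOPE1", "NOPE2"), kb)
  expect_identical(res$not_found, c("NOPE1", "NOPE2"))
  expect_length(res$mapping, 0L)
  expect_true(all(res$rows$entities_found == 0L))
  expect_identical(nrow(res$rows), 1L)   # W is still reported, k = 0
  expect_identical(res$rows$p_value, 1)

  expect_error(run_analysis(character(0), kb), "no identifiers")
})

test_that("every submitted identifier lands in exactly one of mapping / not_found", {
  kb <- synth_kb(8)
  withr::with_seed(8, {
    good <- sample(kb$background_sets[[HS]], 25)
    bad <- sprintf("FAKE%04d", 1:10)
    ids <- sample(c(good, bad))
  })
  res <- run_analysis(ids, kb)
  expect_setequal(c(names(res$mapping), res$not_found), ids)
  expect_identical(length(res$mapping) + length(res$not_found), length(ids))
})

test_that("duplicate and case-variant submissions collapse to one identifier", {
  kb <- fig2_kb()
  a <- run_analysis(c("P3", "P3", " p3 "), kb)
  b <- run_analysis("P3", kb)
  a$mapping <- unname(a$mapping); b$mapping <- unname(b$mapping)
  expect_identical(a$rows, b$rows)
  expect_identical(a$summary, b$summary)
})

test_that("aliases map to their entities; shared aliases map to several", {
  tables <- fig2_tables()
  tables$xrefs <- data.frame(
    alias = c("GENE1", "SHARED", "SHARED"),
    entity_id = c("P1", "P2", "P3"),
    resource = "GeneCards",
    stringsAsFactors = FALSE
  )
  kb <- load_knowledge_base(make_kb_dir(tables))
  res <- run_analysis(c("gene1", "SHARED"), kb)
  expect_identical(res$mapping$gene1, "P1")
  expect_identical(res$mapping$SHARED, c("P2", "P3"))
  expect_identical(res$summary$sample_size_mapped, 3L)
})

test_that("species projection routes statistics through the reference species", {
  tables <- make_kb_tables(
    entities = data.frame(
      entity_id = c("HP1", "HP2", "MP1", "MP2"),
      species = c(HS, HS, "Mus musculus", "Mus musculus"),
      entity_class = "protein",
      main_identifier = c("P10001", "P10002", "P20001", "P20002"),
      stringsAsFactors = FALSE
    ),
    orthologs = data.frame(entity_a = "HP1", entity_b = "MP1", stringsAsFactors = FALSE),
    pathways = data.frame(pathway_id = c("W", "MW"), species = c(HS, "Mus musculus"),
                          name = c("W", "MW"), parent_id = "", stringsAsFactors = FALSE),
    annotations = data.frame(entity_id = c("HP1", "HP2", "MP1", "MP2"),
                             pathway_id = c("W", "W", "MW", "MW"),
                             stringsAsFactors = FALSE)
  )
  kb <- load_knowledge_base(make_kb_dir(tables))

  res <- run_analysis(c("P20001", "P20002"), kb, analysis_options(project = TRUE))
  expect_identical(unique(res$rows$species), HS)
  expect_identical(res$rows$entities_found, 1L)      # MP1 -> HP1 hit in W
  expect_identical(res$unprojected, "P20002")        # MP2 has no human ortholog
  expect_identical(res$summary$sample_size_mapped, 1L)

  # without projection the same sample is analysed per species
  res2 <- run_analysis(c("P20001", "P10001"), kb)
  expect_setequal(res2$rows$species, c(HS, "Mus musculus"))
  expect_identical(res2$unprojected, character(0))
  # pooled FDR across both species' rows
  expect_equal(res2$rows$fdr, bh_adjust(res2$rows$p_value))

  expect_error(run_analysis("P20001", kb, analysis_options(project = TRUE,
                                                           reference_species = "Vulcan")),
               "unknown reference species")
})

test_that("results persist under deterministic content tokens", {
  kb <- synth_kb(9)
  pid <- pick_pathway(kb, 15)
  ids <- generate_sample(kb, pid, 25, 0.4, seed = 3)
  res <- run_analysis(ids, kb)
  store <- tempfile("store")

  tok <- save_result(res, store)
  expect_match(tok$token, "^[0-9a-f]{20}$")
  expect_equal(load_result(tok), res)
  expect_equal(load_result(tok$token, store), res)

  # identical input -> identical token; differing options -> differing token
  tok2 <- save_result(run_analysis(ids, kb), store)
  expect_identical(tok$token, tok2$token)
  res_proj <- run_analysis(ids, kb, analysis_options(project = TRUE))
  tok3 <- save_result(res_proj, store)
  expect_false(identical(tok$token, tok3$token))

  expect_error(load_result("deadbeefdeadbeefdead", store), "unknown token")
})

test_that("result JSON is byte-identical across repeated runs", {
  kb <- synth_kb(9)
  ids <- generate_sample(kb, pick_pathway(kb, 15), 25, 0.4, seed = 3)
  j1 <- pathmem:::result_to_json(run_analysis(ids, kb))
  j2 <- pathmem:::result_to_json(run_analysis(ids, kb))
  expect_identical(j1, j2)
})

test_that("stored results are filtered without recomputation", {
  kb <- synth_kb(9, n_top_pathways = 12)   # enough testable pathways to page over
  ids <- generate_sample(kb, pick_pathway(kb, 20), 30, 0.5, seed = 5)
  res <- run_analysis(ids, kb)
  expect_gte(nrow(res$rows), 25L)   # enough rows to page over
  store <- tempfile("store")
  tok <- save_result(res, store)

  # identity criteria return all rows in original order
  expect_equal(filter_result(tok), res$rows)

  # fdr_max criterion equals the straightforward subset
  flt <- filter_result(tok, fdr_max = 0.5)
  expect_equal(flt, {
    x <- res$rows[res$rows$fdr <= 0.5, , drop = FALSE]; rownames(x) <- NULL; x
  })

  # species and pathway_ids criteria
  some <- res$rows$pathway_id[c(2, 4)]
  expect_identical(filter_result(tok, pathway_ids = some)$pathway_id, some)
  expect_identical(nrow(filter_result(tok, species = "Vulcan")), 0L)

  # paging applied last: rows 11-20 of the filtered list
  pg <- filter_result(tok, page = 2, page_size = 10)
  expect_equal(pg, { x <- res$rows[11:20, , drop = FALSE]; rownames(x) <- NULL; x })
  expect_identical(nrow(filter_result(tok, page = 99, page_size = 10)), 0L)
})

test_that("the result table round-trips through TSV", {
  kb <- fig2_kb()
  res <- run_analysis("P3", kb)
  path <- tempfile(fileext = ".tsv")
  write_result_table(res, path)
  lines <- readLines(path)
  expect_identical(lines[[1]],
    "pathway_id\tpathway_name\tspecies\tentities_found\tentities_total\tsample_mapped\tbackground\tp_value\tfdr\tmatched_identifiers")
  expect_length(lines, 2L)
  back <- read_result_table(path)
  expect_identical(back$entities_found, 1L)
  expect_identical(back$entities_total, 3L)

  # empty rows -> header-only file
  res0 <- res
  res0$rows <- res$rows[0, , drop = FALSE]
  write_result_table(res0, path)
  expect_length(readLines(path), 1L)

  # round trip of a larger table, p-values at >= 6 significant digits
  kb2 <- synth_kb(9)
  ids <- generate_sample(kb2, pick_pathway(kb2, 20), 30, 0.5, seed = 5)
  res2 <- run_analysis(ids, kb2)
  write_result_table(res2, path)
  back2 <- read_result_table(path)
  expect_identical(back2$pathway_id, res2$rows$pathway_id)
  expect_equal(back2$p_value, res2$rows$p_value, tolerance = 1e-5)
  expect_equal(back2$fdr, res2$rows$fdr, tolerance = 1e-5)
  expect_identical(back2$matched_identifiers, res2$rows$matched_identifiers)
})

test_that("sample files are parsed first-column, comments ignored", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "P3\t2.5", "", "P1 0.1 extra", "P2"), path)
  expect_identical(read_sample(path), c("P3", "P1", "P2"))
})

test_that("the command-line layer drives the package end to end", {
  dir <- make_kb_dir(fig2_tables())
  sample_file <- tempfile(fileext = ".txt")
  writeLines(c("P3", "NOPE"), sample_file)
  out <- tempfile(fileext = ".tsv")
  store <- tempfile("clistore")

  expect_output(cli_main(c("build", dir)), "knowledge_base")
  token <- capture.output(
    cli_main(c("analyze", "--kb", dir, "--input", sample_file,
               "--out", out, "--store", store)))
  expect_match(token[length(token)], "^[0-9a-f]{20}$")
  expect_identical(read_result_table(out)$entities_found, 1L)
  expect_output(
    cli_main(c("filter", "--store", store, "--token", token[length(token)],
               "--fdr-max", "1")),
    "pathway_id")
  expect_output(cli_main(c("export-gmt", "--kb", dir, "--species", HS)),
                "P1\tP2\tP3")
})
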