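# File-format parsers: JGI-style KOG/GO/KEGG tables, KEGG link files,
# eggNOG-mapper output, and OBO ontologies.

kog_header <- "#proteinId\tkogId\tkogDefline\tkogClass\tkogLetter"

test_that("KOG parser maps rows to (protein, letter) records", {
  path <- write_lines_tmp(c(
    kog_header,
    "p1\tKOG0001\tsome defline\tMetabolism\tE"
  ))
  recs <- parse_kog_annotation(path)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$protein_id, "p1")
  expect_equal(recs$category_id, "E")
  expect_equal(recs$category_group, "Metabolism")
  expect_equal(recs$source, "kog")
})

test_that("KOG parser collapses duplicates and keeps multi-letter proteins", {
  path <- write_lines_tmp(c(
    kog_header,
    "p1\tKOG0001\td\tMetabolism\tE",
    "p1\tKOG0002\td\tMetabolism\tE",
    "p1\tKOG0003\td\tMetabolism\tG"
  ))
  recs <- parse_kog_annotation(path)
  expect_equal(nrow(recs), 2L)
  expect_setequal(recs$category_id, c("E", "G"))
  expect_true(all(recs$protein_id == "p1"))
})

test_that("KOG parser reports missing columns and empty files", {
  bad <- write_lines_tmp(c("#proteinId\tkogClass", "p1\tMetabolism"))
  expect_error(parse_kog_annotation(bad), "kogLetter")
  empty <- write_lines_tmp(character(0))
  expect_warning(recs <- parse_kog_annotation(empty), "no KOG annotation")
  expect_equal(nrow(recs), 0L)
})

test_that("KOG parser honours column_map overrides and gzip input", {
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "wt")
  writeLines(c("prot\tgrp\tcls", "p1\tE\tMetabolism"), con)
  close(con)
  recs <- parse_kog_annotation(
    path,
    column_map = c(protein_id = "prot", letter = "grp", class = "cls")
  )
  expect_equal(recs$category_id, "E")
  expect_equal(recs$category_group, "Metabolism")
})

go_header <- "#proteinId\tgotermId\tgoName\tgotermType"

test_that("GO parser normalizes accessions and namespaces", {
  path <- write_lines_tmp(c(
    go_header,
    "p1\t8150\tbiological_process\tbiological_process",
    "p2\tGO:0003674\tmolecular_function\tmolecular function",
    "p3\t16020\tmembrane\tcellular component"
  ))
  recs <- parse_go_annotation(path)
  expect_equal(recs$category_id, c("GO:0008150", "GO:0003674", "GO:0016020"))
  expect_equal(
    recs$category_group,
    c("biological_process", "molecular_function", "cellular_component")
  )
  expect_equal(attr(recs, "skipped"), 0L)
})

test_that("GO parser skips malformed accessions with a count", {
  path <- write_lines_tmp(c(
    go_header,
    "p1\t8150\tr\tbiological_process",
    "p2\tGO:12\tbad\tbiological_process",
    "p3\t3674\tr\tmolecular_function",
    "p4\t5575\tr\tcellular_component"
  ))
  expect_warning(recs <- parse_go_annotation(path), "skipped")
  expect_equal(nrow(recs), 3L)
  expect_equal(attr(recs, "skipped"), 1L)
})

kegg_header <- "#proteinId\tecNum\tdefinition\tpathway\tpathway_class\tpathway_type"

test_that("KEGG parser emits one record per aggregation axis", {
  path <- write_lines_tmp(c(
    kegg_header,
    "p1\t1.1.1.1\talcohol dehydrogenase\tGlycolysis\tCarbohydrate metabolism\tMetabolism"
  ))
  recs <- parse_kegg_annotation(path)
  expect_equal(nrow(recs), 4L)
  expect_setequal(
    recs$category_group,
    c("pathway_type", "pathway_class", "pathway_name", "enzyme")
  )
  enzyme <- recs[recs$category_group == "enzyme", ]
  expect_equal(enzyme$category_id, "1.1.1.1")
  expect_equal(enzyme$category_label, "alcohol dehydrogenase")
})

test_that("KEGG rows with EC but no pathway still yield the enzyme record", {
  path <- write_lines_tmp(c(
    kegg_header,
    "p1\t1.1.1.1\talcohol dehydrogenase\t\t\t"
  ))
  recs <- parse_kegg_annotation(path)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$category_group, "enzyme")
})

test_that("KEGG parser returns an empty record set for an empty file", {
  path <- write_lines_tmp(character(0))
  expect_warning(recs <- parse_kegg_annotation(path), "no KEGG")
  expect_equal(nrow(recs), 0L)
})

test_that("KO link parser strips prefixes, dedupes, and skips bad lines", {
  path <- write_lines_tmp(c(
    "tre:TRIREDRAFT_1\tko:K00001",
    "tre:TRIREDRAFT_1\tko:K00001",
    "tre:TRIREDRAFT_2\tko:K00002",
    "no-tab-line",
    "tre:TRIREDRAFT_3\tko:K00003"
  ))
  expect_warning(pairs <- parse_ko_link(path), "without a tab")
  expect_equal(nrow(pairs), 3L)
  expect_equal(pairs$gene_id[[1L]], "TRIREDRAFT_1")
  expect_equal(pairs$ko_id[[1L]], "K00001")
})

eggnog_lines <- function(rows) {
  c(
    "## eggNOG-mapper output",
    "#query\tCOG_category\tGOs\tEC\tKEGG_ko\tKEGG_Pathway",
    rows
  )
}

test_that("eggNOG parser explodes COG letters and strips sentinels", {
  path <- write_lines_tmp(eggnog_lines(c(
    "q1\tEG\tGO:0008150,GO:0003674\t1.1.1.1\tko:K00001,ko:K00002\tmap00010",
    "q2\t-\t-\t-\t-\t-"
  )))
  recs <- parse_eggnog_annotation(path)
  expect_equal(nrow(recs), 2L)
  expect_setequal(recs$cog_letters[[1L]], c("E", "G"))
  expect_setequal(recs$kegg_kos[[1L]], c("K00001", "K00002"))
  expect_setequal(recs$go_ids[[1L]], c("GO:0008150", "GO:0003674"))
  expect_length(recs$cog_letters[[2L]], 0L)
  expect_length(recs$go_ids[[2L]], 0L)
  expect_length(recs$ec_numbers[[2L]], 0L)
})

test_that("eggNOG parser rejects files without the #query header", {
  path <- write_lines_tmp(c("q1\tE\t-\t-\t-\t-"))
  expect_error(parse_eggnog_annotation(path), "#query")
})

obo_stanza <- function(id, ns, is_a = character(), extra = character()) {
  c(
    "[Term]",
    paste0("id: ", id),
    paste0("name: name of ", id),
    paste0("namespace: ", ns),
    paste0("is_a: ", is_a),
    extra,
    ""
  )
}

test_that("OBO parser builds the expected DAG from a chain", {
  path <- write_lines_tmp(c(
    "format-version: 1.2", "",
    obo_stanza("GO:0000001", "biological_process"),
    obo_stanza("GO:0000002", "biological_process", is_a = "GO:0000001 ! root"),
    obo_stanza("GO:0000003", "biological_process", is_a = "GO:0000002")
  ), ext = ".obo")
  dag <- parse_obo(path)
  expect_length(dag$terms, 3L)
  expect_equal(igraph::ecount(dag$graph), 2L)
  expect_setequal(go_ancestors(dag, "GO:0000003"), dag$terms)
})

test_that("OBO parser drops obsolete terms and records part_of and aliases", {
  path <- write_lines_tmp(c(
    obo_stanza("GO:0000001", "biological_process",
      extra = "alt_id: GO:0999999"
    ),
    obo_stanza("GO:0000002", "biological_process",
      extra = "relationship: part_of GO:0000001"
    ),
    obo_stanza("GO:0000004", "biological_process",
      is_a = "GO:0000001", extra = "is_obsolete: true"
    )
  ), ext = ".obo")
  dag <- parse_obo(path)
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002"))
  expect_equal(igraph::E(dag$graph)$relation, "part_of")
  expect_equal(unname(dag$alias[["GO:0999999"]]), "GO:0000001")
  expect_setequal(go_ancestors(dag, "GO:0999999"), c("GO:0000001"))
})

test_that("cyclic ontologies are rejected at construction", {
  path <- write_lines_tmp(c(
    obo_stanza("GO:0000001", "biological_process", is_a = "GO:0000002"),
    obo_stanza("GO:0000002", "biological_process", is_a = "GO:0000001")
  ), ext = ".obo")
  expect_error(parse_obo(path), "cycle")
})

test_that("parsing is order-insensitive and fabricates no identifiers", {
  header <- kog_header
  rows <- c(
    "p1\tKOG1\td\tMetabolism\tE",
    "p2\tKOG2\td\tMetabolism\tG",
    "p3\tKOG3\td\tInformation storage and processing\tJ",
    "p1\tKOG4\td\tMetabolism\tG"
  )
  a <- parse_kog_annotation(write_lines_tmp(c(header, rows)))
  b <- parse_kog_annotation(write_lines_tmp(c(header, rev(rows))))
  key <- function(r) sort(paste(r$protein_id, r$category_id))
  expect_equal(key(a), key(b))
  expect_true(all(a$protein_id %in% c("p1", "p2", "p3")))
  expect_true(all(a$category_id %in% c("E", "G", "J")))
})
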