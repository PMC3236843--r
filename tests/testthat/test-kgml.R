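test_that("parse_kgml represents every element exactly once", {
  empty <- parse_kgml(kgml_fixture())
  expect_equal(nrow(empty$entries), 0L)
  expect_equal(nrow(empty$relations), 0L)

  p <- fixture_pathway()
  # element counts checked against an independent raw-XML scan
  raw <- xml2::read_xml(write_kgml(p))
  expect_equal(nrow(p$entries), length(xml2::xml_find_all(raw, "//entry")))
  expect_equal(nrow(p$relations),
               length(xml2::xml_find_all(raw, "//relation")))
  expect_equal(nrow(p$entries), 5L)
  expect_equal(nrow(p$relations), 2L)

  # multi-KO entry name yields the full KO set
  expect_setequal(p$entries$ko_ids[[2]], c("K00002", "K00003"))
  # compound entries never carry KO ids
  expect_length(p$entries$ko_ids[[4]], 0L)
})

test_that("parse_kgml flags unknown types and broken references", {
  expect_warning(
    p <- parse_kgml(kgml_fixture(entries = entry_xml("1", "x", "widget"))),
    "unknown type"
  )
  expect_equal(p$entries$entry_type, "other")

  expect_error(
    parse_kgml(kgml_fixture(
      entries = entry_xml("1", "ko:K00001"),
      relations = relation_xml("1", "99")
    )),
    "missing entry"
  )
  expect_error(parse_kgml("<notapathway/>"), "pathway")
})

test_that("serialization round-trips the full graph", {
  p <- fixture_pathway()
  again <- parse_kgml(write_kgml(p))
  expect_equal(again$entries, p$entries)
  expect_equal(again$relations, p$relations)
  expect_equal(again$reactions, p$reactions)
  expect_equal(again$pathway_attrs, p$pathway_attrs)

  # and for generated maps with graphics coordinates
  w <- tiny_world(seed = 6)
  for (p in w$pathways) {
    again <- parse_kgml(write_kgml(p))
    expect_equal(again$entries, p$entries)
    expect_equal(again$relations, p$relations)
  }
})

test_that("interaction graphs keep gene-level nodes and drop navigation", {
  only_cpd <- parse_kgml(kgml_fixture(
    entries = paste0(entry_xml("1", "cpd:C00001", "compound"),
                     entry_xml("2", "cpd:C00002", "compound"))
  ))
  expect_equal(nrow(to_interaction_graph(only_cpd)$nodes), 0L)

  chain <- parse_kgml(kgml_fixture(
    entries = paste0(entry_xml("1", "ko:K00001", "gene"),
                     entry_xml("2", "ko:K00002", "gene"),
                     entry_xml("3", "ko:K00003", "gene")),
    relations = paste0(relation_xml("1", "2"), relation_xml("2", "3"))
  ))
  ig <- to_interaction_graph(chain)
  expect_equal(nrow(ig$nodes), 3L)
  expect_equal(nrow(ig$edges), 2L)
  # hand-built adjacency of the fixture
  expect_equal(ig$edges$from, c("1", "2"))
  expect_equal(ig$edges$to, c("2", "3"))
  expect_equal(ig$edges$relation_type, c("PPrel", "PPrel"))

  # maplink relations and map nodes vanish from the interaction graph
  p <- fixture_pathway()
  ig <- to_interaction_graph(p)
  expect_equal(nrow(ig$nodes), 3L)
  expect_true(all(ig$edges$relation_type != "maplink"))
  expect_lte(nrow(ig$nodes), nrow(p$entries))
  expect_true(all(c(ig$edges$from, ig$edges$to) %in% ig$nodes$entry_id))
})

test_that("group entries share their edges with every member", {
  p <- parse_kgml(kgml_fixture(
    entries = paste0(
      entry_xml("1", "ko:K00001", "gene"),
      entry_xml("2", "ko:K00002", "gene"),
      entry_xml("3", "ko:K00003", "gene"),
      entry_xml("10", "undefined", "group", graphics = FALSE,
                components = c("1", "2"))
    ),
    relations = relation_xml("10", "3")
  ))
  ig <- to_interaction_graph(p)
  expect_equal(nrow(ig$nodes), 3L)
  expect_equal(nrow(ig$edges), 2L)
  expect_setequal(ig$edges$from, c("1", "2"))
  expect_equal(unique(ig$edges$to), "3")

  expect_error(
    parse_kgml(kgml_fixture(entries = entry_xml("1", "g", "group",
                                                graphics = FALSE))),
    "component"
  )
})

test_that("reaction co-membership becomes edges on metabolic maps", {
  p <- parse_kgml(kgml_fixture(
    entries = paste0(
      entry_xml("1", "ko:K00001", "ortholog",
                extra = ' reaction="rn:R00001"'),
      entry_xml("2", "ko:K00002", "ortholog",
                extra = ' reaction="rn:R00001"'),
      entry_xml("3", "cpd:C00001", "compound")
    ),
    reactions = paste0(
      '<reaction id="1" name="rn:R00001" type="reversible">',
      '<substrate id="3" name="cpd:C00001"/>',
      '<product id="3" name="cpd:C00001"/></reaction>'
    )
  ))
  ig <- to_interaction_graph(p, include_reactions = TRUE)
  expect_equal(nrow(ig$edges), 1L)
  expect_equal(ig$edges$relation_type, "reaction")
  expect_equal(nrow(to_interaction_graph(p, include_reactions = FALSE)$edges),
               0L)
  # round-trip keeps the reaction block
  again <- parse_kgml(write_kgml(p))
  expect_equal(again$reactions, p$reactions)
})

test_that("pathway classification uses the table, then the number blocks", {
  categories <- tibble::tibble(number = c("00010", "04010"),
                               class = c("Metabolism", "Signal transduction"),
                               subcategory = c("Carbohydrate", "EIP"))
  p <- fixture_pathway()
  expect_equal(classify_pathway(p, categories)$category, "metabolic")

  p$number <- "04010"
  expect_equal(classify_pathway(p, categories)$category, "non-metabolic")

  # fallback: the metabolism numbering block is below 02000
  p$number <- "04010"
  expect_equal(classify_pathway(p)$category, "non-metabolic")
  p$number <- "00010"
  expect_equal(classify_pathway(p)$category, "metabolic")
})

test_that("category tables read with and without a subcategory column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("00010\tMetabolism\tCarbohydrate", "04010\tEIP\tSignal"), f)
  tab <- read_category_table(f)
  expect_equal(tab$number, c("00010", "04010"))
  writeLines(c("00010\tMetabolism", "04010\tEIP"), f)
  expect_equal(read_category_table(f)$subcategory,
               c(NA_character_, NA_character_))
})
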