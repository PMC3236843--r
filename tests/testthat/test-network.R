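test_that("map_queries implements exact KO-set intersection", {
  empty <- map_queries(tibble::tibble(koid = character(),
                                      query_id = character()),
                       list(fixture_pathway()))
  expect_equal(nrow(empty), 0L)

  groups <- tibble::tibble(koid = "K00001", query_id = "est1")
  m <- map_queries(groups, list(fixture_pathway()))
  expect_equal(nrow(m), 1L)
  expect_equal(m$pathway_id, "path:ko00010")
  expect_equal(m$entry_id, "1")
})

test_that("mapping equals the brute-force triple loop on random worlds", {
  for (seed in 1:3) {
    w <- tiny_world(seed = seed, mutation_rate = 0.05, n_kos = 12,
                    n_queries = 40)
    a <- world_assignments(w)
    groups <- ko_groups(a)
    m <- map_queries(groups, w$pathways)

    got <- unique(paste(m$query_id, m$pathway_id))
    exp <- character()
    qk <- split(groups$koid, groups$query_id)
    for (q in names(qk)) {
      for (p in w$pathways) {
        hit <- FALSE
        for (i in seq_len(nrow(p$entries))) {
          if (p$entries$entry_type[i] %in% c("ortholog", "gene", "enzyme") &&
              length(intersect(qk[[q]], p$entries$ko_ids[[i]])) > 0) {
            hit <- TRUE
          }
        }
        if (hit) exp <- c(exp, paste(q, p$pathway_id))
      }
    }
    expect_setequal(got, exp)

    # both directions of the result agree
    byq <- mapping_by_query(m)
    byp <- mapping_by_pathway(m)
    expect_equal(sum(byq$n_pathways > 0), nrow(byq))
    expect_setequal(byp$pathway_id, unique(m$pathway_id))
  }
})

test_that("highlighting marks intersecting nodes and nothing else", {
  p <- fixture_pathway()

  h <- highlight_pathway(p, character())
  expect_length(h$matched_nodes, 0L)

  h <- highlight_pathway(p, "K00002")
  expect_equal(h$matched_nodes, "2")
  expect_equal(h$relabel$koid, "K00002")

  all_kos <- unique(unlist(p$entries$ko_ids))
  h <- highlight_pathway(p, all_kos)
  gene_level <- p$entries$entry_id[
    p$entries$entry_type %in% c("ortholog", "gene", "enzyme")]
  expect_setequal(h$matched_nodes, gene_level)

  # structure preservation: the base graph is untouched
  expect_equal(h$base$entries, p$entries)
  expect_equal(h$base$relations, p$relations)
  expect_equal(h$base$reactions, p$reactions)
})

test_that("relabel picks the smallest matched KO of a multi-KO node", {
  p <- fixture_pathway()
  h <- highlight_pathway(p, c("K00003", "K00002"))
  expect_equal(h$relabel$koid[h$relabel$entry_id == "2"], "K00002")
})

test_that("SIF export is one tab-separated line per edge", {
  empty <- parse_kgml(kgml_fixture())
  f <- withr::local_tempfile(fileext = ".sif")
  export_network(highlight_pathway(empty, character()), "SIF", f)
  expect_length(readLines(f), 0L)

  chain <- parse_kgml(kgml_fixture(
    entries = paste0(entry_xml("1", "ko:K00001", "gene"),
                     entry_xml("2", "ko:K00002", "gene"),
                     entry_xml("3", "ko:K00003", "gene")),
    relations = paste0(relation_xml("1", "2"),
                       relation_xml("2", "3", subtype = "inhibition"))
  ))
  h <- highlight_pathway(chain, "K00001")
  export_network(h, "SIF", f)
  lines <- readLines(f)
  expect_length(lines, nrow(to_interaction_graph(chain)$edges))
  expect_equal(lines[1], "1|K00001\tPPrel:activation\t2|K00002")

  expect_error(export_network(h, "DOT", f), "arg")
})

test_that("exports are byte-identical across repeated runs", {
  w <- tiny_world(seed = 10)
  h <- highlight_pathway(w$pathways[[2]], w$kos[1:3])
  for (fmt in c("SIF", "GraphML", "TSV", "annotated-KGML")) {
    f1 <- withr::local_tempfile()
    f2 <- withr::local_tempfile()
    export_network(h, fmt, f1)
    export_network(h, fmt, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("annotated KGML recolours and relabels only matched nodes", {
  p <- fixture_pathway()
  h <- highlight_pathway(p, "K00002")
  f <- withr::local_tempfile(fileext = ".xml")
  export_network(h, "annotated-KGML", f)
  again <- parse_kgml(f)

  expect_equal(again$entries$graphics[[2]][["bgcolor"]], "red")
  expect_equal(again$entries$display_name[2], "K00002")
  # unmatched entries and all topology survive verbatim
  expect_equal(again$entries$graphics[[1]], p$entries$graphics[[1]])
  expect_equal(again$relations, p$relations)
  expect_equal(again$entries$entry_id, p$entries$entry_id)

  # with nothing matched the document is unchanged
  f0 <- withr::local_tempfile(fileext = ".xml")
  export_network(highlight_pathway(p, character()), "annotated-KGML", f0)
  expect_equal(parse_kgml(f0)$entries, p$entries)
})

test_that("GraphML export carries highlight and KO attributes", {
  p <- fixture_pathway()
  h <- highlight_pathway(p, "K00001")
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(h, "GraphML", f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::vertex_attr_names(g),
                  c("highlighted", "koid", "display_name", "name", "id"))
  v <- igraph::as_data_frame(g, what = "vertices")
  expect_equal(sum(v$highlighted > 0), 1L)
  expect_equal(v$koid[v$highlighted > 0], "K00001")
})

test_that("coverage statistics reproduce the worked category arithmetic", {
  # 88 metabolic + 138 non-metabolic maps; per-query category membership
  # 218 metabolic / 460 non-metabolic / 74 both
  met_paths <- sprintf("met%03d", 1:88)
  non_paths <- sprintf("non%03d", 1:138)
  cats <- tibble::tibble(
    pathway_id = c(met_paths, non_paths),
    category = rep(c("metabolic", "non-metabolic"), c(88, 138))
  )
  q_both <- sprintf("qb%03d", 1:74)
  q_met <- sprintf("qm%03d", 1:144)   # 218 - 74 metabolic-only
  q_non <- sprintf("qn%03d", 1:386)   # 460 - 74 non-metabolic-only
  m <- tibble::tibble(
    query_id = c(q_met, q_both, q_both, q_non),
    koid = "K00001",
    pathway_id = c(rep(met_paths, length.out = 144 + 74),
                   rep(non_paths, length.out = 74 + 386)),
    entry_id = "1"
  )
  class(m) <- c("ko_mapping", class(m))
  assignments <- tibble::tibble(
    query_id = unique(m$query_id),
    koids = list("K00001"),
    primary_koid = "K00001"
  )
  st <- coverage_stats(m, assignments, cats)
  expect_equal(st$n_queries_metabolic, 218)
  expect_equal(st$n_queries_nonmetabolic, 460)
  expect_equal(st$n_queries_both, 74)
  expect_equal(st$n_queries_mapped, 604)
  expect_equal(st$n_pathways_hit, 226)
  expect_equal(st$n_pathways_metabolic, 88)
  expect_equal(st$n_pathways_nonmetabolic, 138)
})

test_that("coverage of an empty mapping is all zero", {
  m <- map_queries(tibble::tibble(koid = character(), query_id = character()),
                   list())
  st <- coverage_stats(m, tibble::tibble(query_id = character(),
                                         koids = list(),
                                         primary_koid = character()),
                       tibble::tibble(pathway_id = character(),
                                      category = character()))
  expect_equal(st$n_pathways_hit, 0L)
  expect_equal(st$n_queries_mapped, 0L)
  expect_equal(st$n_queries_both, 0L)
})

test_that("an uncategorized pathway in the mapping is an error", {
  m <- tibble::tibble(query_id = "q", koid = "K00001",
                      pathway_id = "mystery", entry_id = "1")
  expect_error(
    coverage_stats(m, tibble::tibble(query_id = "q", koids = list("K00001"),
                                     primary_koid = "K00001"),
                   tibble::tibble(pathway_id = "other",
                                  category = "metabolic")),
    "category"
  )
})

test_that("inclusion-exclusion holds on every generated mapping", {
  for (seed in 1:5) {
    w <- tiny_world(seed = seed, mutation_rate = 0.1, n_queries = 35)
    a <- world_assignments(w)
    m <- map_queries(ko_groups(a), w$pathways)
    st <- coverage_stats(m, a, w$pathways)
    expect_equal(st$n_queries_metabolic + st$n_queries_nonmetabolic -
                   st$n_queries_both, st$n_queries_mapped)
    expect_equal(st$n_pathways_metabolic + st$n_pathways_nonmetabolic,
                 st$n_pathways_hit)
  }
})
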