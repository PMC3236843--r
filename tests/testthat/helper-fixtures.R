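# shared in-code fixtures: hit tables, KGML strings, tiny worlds

hit_row <- function(query_id = "q1", subject_id = "org:g1", pident = 90,
                    align_len = 100, mismatch = 10, gapopen = 0,
                    qstart = 1, qend = 300, sstart = 1, send = 100,
                    evalue = 1e-10, bitscore = 180,
                    nident = round(pident * align_len / 100),
                    organism = "org") {
  tibble::tibble(query_id = query_id, organism = organism,
                 subject_id = subject_id, pident = pident,
                 align_len = align_len, mismatch = mismatch,
                 gapopen = gapopen, qstart = qstart, qend = qend,
                 sstart = sstart, send = send, evalue = evalue,
                 bitscore = bitscore, nident = nident)
}

write_hit_file <- function(hits, path, nident_col = FALSE) {
  cols <- c("query_id", "subject_id", "pident", "align_len", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  if (nident_col) cols <- c(cols, "nident")
  lines <- do.call(paste, c(unname(as.list(hits[cols])), sep = "\t"))
  writeLines(lines, path)
  path
}

# random hit tables with deliberate score ties so tie-breaking is exercised
random_hits <- function(n, n_queries = 4, n_orgs = 2) {
  tab <- tibble::tibble(
    query_id = sample(sprintf("q%d", seq_len(n_queries)), n, replace = TRUE),
    organism = sample(sprintf("org%d", seq_len(n_orgs)), n, replace = TRUE),
    subject_id = sprintf("s%03d", sample(999, n)),
    pident = sample(c(40, 60, 80, 95), n, replace = TRUE),
    align_len = sample(c(50L, 100L), n, replace = TRUE),
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L,
    evalue = sample(c(0, 1e-30, 1e-10, 1e-10, 0.5, 5, 15), n, replace = TRUE),
    bitscore = sample(c(50, 80, 80, 120), n, replace = TRUE)
  )
  tab$nident <- round(tab$pident * tab$align_len / 100)
  tab
}

# independent selection oracle: exhaustive sort of all surviving hits
# under the documented key, take the head
oracle_best <- function(hits, cutoff = 10) {
  keep <- hits[hits$evalue <= cutoff, , drop = FALSE]
  if (nrow(keep) == 0L) return(NULL)
  o <- order(keep$evalue, -keep$bitscore, -keep$pident, -keep$nident,
             keep$subject_id)
  keep[o[1L], , drop = FALSE]
}

kgml_fixture <- function(entries = "", relations = "", reactions = "",
                         number = "00010", name = "path:ko00010") {
  sprintf('<pathway name="%s" org="ko" number="%s" title="fixture">%s%s%s</pathway>',
          name, number, entries, relations, reactions)
}

entry_xml <- function(id, name, type = "ortholog", graphics = TRUE,
                      components = character(), extra = "") {
  g <- if (graphics)
    sprintf('<graphics name="lbl%s" type="rectangle" x="10" y="20" fgcolor="#000000" bgcolor="#BFFFBF"/>', id)
  else ""
  comp <- paste(sprintf('<component id="%s"/>', components), collapse = "")
  sprintf('<entry id="%s" name="%s" type="%s"%s>%s%s</entry>',
          id, name, type, extra, g, comp)
}

relation_xml <- function(e1, e2, type = "PPrel",
                         subtype = "activation", value = "-->") {
  st <- if (is.na(subtype)) "" else
    sprintf('<subtype name="%s" value="%s"/>', subtype, value)
  sprintf('<relation entry1="%s" entry2="%s" type="%s">%s</relation>',
          e1, e2, type, st)
}

# five entries (3 gene-level, 1 compound, 1 map), two relations
fixture_pathway <- function() {
  parse_kgml(kgml_fixture(
    entries = paste0(
      entry_xml("1", "ko:K00001", "ortholog"),
      entry_xml("2", "ko:K00002 ko:K00003", "ortholog"),
      entry_xml("3", "ko:K00004", "gene"),
      entry_xml("4", "cpd:C00001", "compound"),
      entry_xml("5", "path:ko00020", "map")
    ),
    relations = paste0(
      relation_xml("1", "2"),
      relation_xml("2", "3", subtype = "inhibition", value = "--|")
    )
  ))
}

tiny_world <- function(seed = 1, mutation_rate = 0, hit_noise = "on",
                       n_kos = 8, n_queries = 30, n_organisms = 3, ...) {
  generate_world(world_params(
    n_kos = n_kos, n_organisms = n_organisms, n_queries = n_queries,
    mutation_rate = mutation_rate, hit_noise = hit_noise,
    n_pathways = 4, kos_per_pathway = 4, seed = seed, ...
  ))
}

# run the select -> assign steps of the pipeline on a world
world_assignments <- function(world, cutoff = 10) {
  hits <- generate_hit_tables(world)
  ann <- dplyr::bind_rows(world$annotations)
  assign_ko(consolidate_best_hits(select_best_hits(hits$hits,
                                                   cutoff = cutoff)), ann)
}
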