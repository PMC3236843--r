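KGML_NODE_TYPES <- c("ortholog", "gene", "enzyme")
KGML_ENTRY_TYPES <- c(KGML_NODE_TYPES, "compound", "map", "group", "other")

#' Parse a KGML pathway map into a pathway graph object
#'
#' Reads one KEGG Markup Language (KGML) document and represents it as a
#' `pathway_graph`: a pathway header plus tidy tables of entries (nodes),
#' relations and reactions (edges). Entry names of the form `ko:K#####`
#' are parsed into KO identifier sets on ortholog/gene/enzyme entries;
#' graphics attributes are kept verbatim so the map can be re-serialized
#' unchanged with [write_kgml()]. Entry types outside the KGML vocabulary
#' are mapped to `"other"` with a warning; unknown attributes are carried
#' through untouched.
#'
#' @param x Path to a KGML file, or a KGML string.
#' @return A `pathway_graph` object: a list with `pathway_id`, `number`,
#'   `title`, `org`, `category` (`NA` until [classify_pathway()]),
#'   `subcategory`, and tibbles `entries`, `relations`, `reactions`.
#' @examples
#' p <- parse_kgml(paste0(
#'   '<pathway name="path:ko00010" org="ko" number="00010" title="demo">',
#'   '<entry id="1" name="ko:K00001" type="ortholog">',
#'   '<graphics name="E1.1.1.1" type="rectangle"/></entry></pathway>'
#' ))
#' p$entries
#' @export
parse_kgml <- function(x) {
  doc <- xml2::read_xml(x)
  if (xml2::xml_name(doc) != "pathway") stop("root element is not <pathway>")
  pattrs <- xml2::xml_attrs(doc)

  entry_nodes <- xml2::xml_find_all(doc, "./entry")
  entries <- purrr::map_dfr(entry_nodes, function(e) {
    a <- xml2::xml_attrs(e)
    type <- a[["type"]]
    if (!type %in% KGML_ENTRY_TYPES) {
      warning(sprintf("entry %s: unknown type '%s' mapped to 'other'",
                      a[["id"]], type), call. = FALSE)
      type <- "other"
    }
    name <- if ("name" %in% names(a)) a[["name"]] else ""
    kos <- character()
    if (type %in% KGML_NODE_TYPES) {
      tok <- strsplit(name, " ", fixed = TRUE)[[1]]
      kos <- sort(unique(sub("^ko:", "", tok[grepl("^ko:K[0-9]{5}$", tok)])))
    }
    g <- xml2::xml_find_first(e, "./graphics")
    graphics <- if (inherits(g, "xml_missing")) NULL else xml2::xml_attrs(g)
    members <- xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id")
    if (type == "group" && length(members) == 0L) {
      stop(sprintf("group entry %s has no component members", a[["id"]]))
    }
    tibble::tibble(
      entry_id = a[["id"]],
      entry_type = type,
      name = name,
      ko_ids = list(kos),
      display_name = if (!is.null(graphics) && "name" %in% names(graphics))
        graphics[["name"]] else NA_character_,
      graphics = list(graphics),
      members = list(members),
      attrs = list(a)
    )
  })
  if (nrow(entries) == 0L) {
    entries <- tibble::tibble(
      entry_id = character(), entry_type = character(), name = character(),
      ko_ids = list(), display_name = character(), graphics = list(),
      members = list(), attrs = list()
    )
  }
  if (anyDuplicated(entries$entry_id)) {
    stop("duplicate entry id: ",
         entries$entry_id[duplicated(entries$entry_id)][1])
  }

  rel_nodes <- xml2::xml_find_all(doc, "./relation")
  relations <- purrr::imap_dfr(as.list(rel_nodes), function(r, i) {
    a <- xml2::xml_attrs(r)
    st <- xml2::xml_find_all(r, "./subtype")
    tibble::tibble(
      entry1 = a[["entry1"]],
      entry2 = a[["entry2"]],
      relation_type = a[["type"]],
      subtypes = list(tibble::tibble(
        name = xml2::xml_attr(st, "name"),
        value = xml2::xml_attr(st, "value")
      ))
    )
  })
  if (nrow(relations) == 0L) {
    relations <- tibble::tibble(entry1 = character(), entry2 = character(),
                                relation_type = character(), subtypes = list())
  }
  unresolved <- !(relations$entry1 %in% entries$entry_id &
                    relations$entry2 %in% entries$entry_id)
  if (any(unresolved)) {
    i <- which(unresolved)[1]
    stop(sprintf("relation %d (%s -> %s) references a missing entry id",
                 i, relations$entry1[i], relations$entry2[i]))
  }

  rxn_nodes <- xml2::xml_find_all(doc, "./reaction")
  reactions <- purrr::map_dfr(rxn_nodes, function(r) {
    a <- xml2::xml_attrs(r)
    tibble::tibble(
      reaction_id = if ("id" %in% names(a)) a[["id"]] else NA_character_,
      name = a[["name"]],
      type = a[["type"]],
      substrates = list(xml2::xml_attr(xml2::xml_find_all(r, "./substrate"), "id")),
      substrate_names = list(xml2::xml_attr(xml2::xml_find_all(r, "./substrate"), "name")),
      products = list(xml2::xml_attr(xml2::xml_find_all(r, "./product"), "id")),
      product_names = list(xml2::xml_attr(xml2::xml_find_all(r, "./product"), "name"))
    )
  })
  if (nrow(reactions) == 0L) {
    reactions <- tibble::tibble(
      reaction_id = character(), name = character(), type = character(),
      substrates = list(), substrate_names = list(),
      products = list(), product_names = list()
    )
  }
  rxn_ends <- unlist(c(reactions$substrates, reactions$products))
  if (length(rxn_ends) > 0L && !all(rxn_ends %in% entries$entry_id)) {
    stop("reaction references a missing entry id: ",
         setdiff(rxn_ends, entries$entry_id)[1])
  }

  structure(
    list(
      pathway_id = if ("name" %in% names(pattrs)) pattrs[["name"]] else NA_character_,
      number = if ("number" %in% names(pattrs)) pattrs[["number"]] else NA_character_,
      title = if ("title" %in% names(pattrs)) pattrs[["title"]] else NA_character_,
      org = if ("org" %in% names(pattrs)) pattrs[["org"]] else NA_character_,
      category = NA_character_,
      subcategory = NA_character_,
      pathway_attrs = pattrs,
      entries = entries,
      relations = relations,
      reactions = reactions
    ),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph %s '%s': %d entries, %d relations, %d reactions%s>\n",
              x$pathway_id, x$title, nrow(x$entries), nrow(x$relations),
              nrow(x$reactions),
              if (is.na(x$category)) "" else paste0(", ", x$category)))
  invisible(x)
}

#' Serialize a pathway graph back to KGML
#'
#' Writes a `pathway_graph` (possibly annotated by [highlight_pathway()]
#' via [export_network()]) as a KGML document. Re-parsing the output
#' yields a graph equal to the input: all entry, graphics, relation and
#' reaction attributes are emitted verbatim.
#'
#' @param p A `pathway_graph`.
#' @param path Output file; if `NULL`, the KGML string is returned.
#' @return `path` invisibly, or the KGML string when `path` is `NULL`.
#' @export
write_kgml <- function(p, path = NULL) {
  stopifnot(inherits(p, "pathway_graph"))
  doc <- xml2::xml_new_root("pathway")
  xml2::xml_set_attrs(doc, p$pathway_attrs)
  for (i in seq_len(nrow(p$entries))) {
    e <- xml2::xml_add_child(doc, "entry")
    xml2::xml_set_attrs(e, p$entries$attrs[[i]])
    g <- p$entries$graphics[[i]]
    if (!is.null(g)) {
      gn <- xml2::xml_add_child(e, "graphics")
      xml2::xml_set_attrs(gn, g)
    }
    for (m in p$entries$members[[i]]) {
      cn <- xml2::xml_add_child(e, "component")
      xml2::xml_set_attr(cn, "id", m)
    }
  }
  for (i in seq_len(nrow(p$relations))) {
    r <- xml2::xml_add_child(doc, "relation")
    xml2::xml_set_attr(r, "entry1", p$relations$entry1[i])
    xml2::xml_set_attr(r, "entry2", p$relations$entry2[i])
    xml2::xml_set_attr(r, "type", p$relations$relation_type[i])
    st <- p$relations$subtypes[[i]]
    for (j in seq_len(nrow(st))) {
      sn <- xml2::xml_add_child(r, "subtype")
      xml2::xml_set_attr(sn, "name", st$name[j])
      xml2::xml_set_attr(sn, "value", st$value[j])
    }
  }
  for (i in seq_len(nrow(p$reactions))) {
    r <- xml2::xml_add_child(doc, "reaction")
    if (!is.na(p$reactions$reaction_id[i])) {
      xml2::xml_set_attr(r, "id", p$reactions$reaction_id[i])
    }
    xml2::xml_set_attr(r, "name", p$reactions$name[i])
    xml2::xml_set_attr(r, "type", p$reactions$type[i])
    subs <- p$reactions$substrates[[i]]
    subn <- p$reactions$substrate_names[[i]]
    for (j in seq_along(subs)) {
      sn <- xml2::xml_add_child(r, "substrate")
      xml2::xml_set_attr(sn, "id", subs[j])
      xml2::xml_set_attr(sn, "name", subn[j])
    }
    prods <- p$reactions$products[[i]]
    prodn <- p$reactions$product_names[[i]]
    for (j in seq_along(prods)) {
      pn <- xml2::xml_add_child(r, "product")
      xml2::xml_set_attr(pn, "id", prods[j])
      xml2::xml_set_attr(pn, "name", prodn[j])
    }
  }
  out <- as.character(doc)
  if (is.null(path)) return(out)
  writeLines(out, path, sep = "")
  invisible(path)
}

#' Read a pathway category table
#'
#' Reads a TSV mapping 5-digit pathway map numbers to their top-level
#' KEGG class (e.g. `Metabolism`, `Human Diseases`) and optional
#' subcategory.
#'
#' @param path TSV with 2 or 3 columns: number, class, subcategory; no
#'   header.
#' @return Tibble with columns `number`, `class`, `subcategory`.
#' @export
read_category_table <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_names = c("number", "class", "subcategory")[
      seq_len(max(2L, length(strsplit(readLines(path, n = 1L), "\t")[[1]])))],
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"subcategory" %in% names(tab)) tab$subcategory <- NA_character_
  tab
}

#' Classify a pathway as metabolic or non-metabolic
#'
#' Looks the pathway's map number up in a category table; a top-level
#' class of `Metabolism` (case-insensitive) means metabolic, anything
#' else non-metabolic. Numbers absent from the table fall back to KEGG's
#' numbering convention: map numbers below 02000 are the metabolism
#' block, all higher blocks (information processing, cellular processes,
#' organismal systems, diseases) are non-metabolic.
#'
#' @param p A `pathway_graph`.
#' @param categories Optional category tibble from [read_category_table()].
#' @return `p` with `category` (`"metabolic"`/`"non-metabolic"`) and
#'   `subcategory` filled in.
#' @export
classify_pathway <- function(p, categories = NULL) {
  stopifnot(inherits(p, "pathway_graph"))
  hit <- if (!is.null(categories)) {
    categories[categories$number == p$number, , drop = FALSE]
  } else {
    NULL
  }
  if (!is.null(hit) && nrow(hit) > 0L) {
    p$category <- if (grepl("^metab", hit$class[1], ignore.case = TRUE))
      "metabolic" else "non-metabolic"
    p$subcategory <- hit$subcategory[1]
  } else {
    num <- suppressWarnings(as.integer(p$number))
    p$category <- if (!is.na(num) && num < 2000L) "metabolic" else "non-metabolic"
    p$subcategory <- NA_character_
  }
  p
}

#' Flatten a pathway map to a regulatory interaction graph
#'
#' Reduces a parsed map to the gene-level graph used for reference
#' network construction: nodes are ortholog/gene/enzyme entries (group
#' entries are expanded to their members, so complex membership shares
#' the complex's edges), and edges are the relations joining two such
#' nodes, labelled with the relation type and first subtype. Compound and
#' map entries, and `maplink` navigation relations, are dropped.
#' Reaction co-membership (two gene nodes catalysing the same reaction)
#' is added as `"reaction"` edges when `include_reactions` is on — by
#' default on metabolic and unclassified maps, off on non-metabolic ones.
#'
#' @param p A `pathway_graph`, ideally classified.
#' @param include_reactions Logical; `NULL` (default) means on unless the
#'   map is classified non-metabolic.
#' @return An `interaction_graph`: list of `nodes` (entry_id, ko_ids,
#'   primary_koid, display_name) and `edges` (from, to, relation_type,
#'   subtype) tibbles.
#' @export
to_interaction_graph <- function(p, include_reactions = NULL) {
  stopifnot(inherits(p, "pathway_graph"))
  if (is.null(include_reactions)) {
    include_reactions <- is.na(p$category) || p$category == "metabolic"
  }
  ent <- p$entries
  node_rows <- ent[ent$entry_type %in% KGML_NODE_TYPES, , drop = FALSE]
  nodes <- tibble::tibble(
    entry_id = node_rows$entry_id,
    ko_ids = node_rows$ko_ids,
    primary_koid = purrr::map_chr(
      node_rows$ko_ids, ~ if (length(.x) == 0L) NA_character_ else .x[[1L]]
    ),
    display_name = node_rows$display_name
  )

  # group expansion map: entry_id -> constituent node ids
  expand <- stats::setNames(as.list(nodes$entry_id), nodes$entry_id)
  for (i in which(ent$entry_type == "group")) {
    expand[[ent$entry_id[i]]] <-
      intersect(ent$members[[i]], nodes$entry_id)
  }
  expand_one <- function(id) {
    v <- expand[[id]]
    if (is.null(v)) character() else v
  }

  rel <- p$relations[p$relations$relation_type != "maplink", , drop = FALSE]
  edges <- purrr::pmap_dfr(
    list(rel$entry1, rel$entry2, rel$relation_type, rel$subtypes),
    function(e1, e2, type, st) {
      a <- expand_one(e1)
      b <- expand_one(e2)
      if (length(a) == 0L || length(b) == 0L) return(NULL)
      sub <- if (nrow(st) > 0L) st$name[1] else NA_character_
      tidyr::expand_grid(from = a, to = b) %>%
        dplyr::mutate(relation_type = type, subtype = sub)
    }
  )

  if (include_reactions && nrow(p$reactions) > 0L) {
    # nodes share a reaction when their entry 'reaction' attribute names it
    rx <- purrr::map_dfr(seq_len(nrow(ent)), function(i) {
      a <- ent$attrs[[i]]
      if (!ent$entry_type[i] %in% KGML_NODE_TYPES ||
          !"reaction" %in% names(a)) return(NULL)
      tibble::tibble(entry_id = ent$entry_id[i],
                     rname = strsplit(a[["reaction"]], " ", fixed = TRUE)[[1]])
    })
    if (nrow(rx) > 0L) {
      rx <- rx[rx$rname %in% unlist(strsplit(p$reactions$name, " ")), ,
               drop = FALSE]
      rxe <- rx %>%
        dplyr::group_by(.data$rname) %>%
        dplyr::summarise(ids = list(sort(unique(.data$entry_id))),
                         .groups = "drop") %>%
        purrr::pmap_dfr(function(rname, ids) {
          if (length(ids) < 2L) return(NULL)
          pairs <- utils::combn(ids, 2L)
          tibble::tibble(from = pairs[1, ], to = pairs[2, ],
                         relation_type = "reaction", subtype = rname)
        })
      edges <- dplyr::bind_rows(edges, rxe)
    }
  }

  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character(),
                            relation_type = character(), subtype = character())
  } else {
    edges <- edges %>%
      dplyr::distinct() %>%
      dplyr::arrange(.data$from, .data$to, .data$relation_type, .data$subtype)
  }
  structure(list(nodes = nodes, edges = edges, pathway_id = p$pathway_id),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph %s: %d nodes, %d edges>\n",
              x$pathway_id, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
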