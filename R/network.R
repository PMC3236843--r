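#' Map KO groups of queries onto pathway maps
#'
#' Intersects each query's KO set with the KO sets of every pathway's
#' gene-level entries: a query maps to a pathway exactly when it shares
#' at least one KO identifier with a node of that map. The result is the
#' long membership table underlying both per-pathway views (which ESTs
#' support this map) and per-query views (which maps this EST touches).
#'
#' @param groups KO membership tibble from [ko_groups()] (columns `koid`,
#'   `query_id`).
#' @param pathways A list of `pathway_graph` objects.
#' @return A `ko_mapping` tibble with columns `query_id`, `koid`,
#'   `pathway_id`, `entry_id`, one row per (query, KO, pathway node)
#'   match.
#' @export
map_queries <- function(groups, pathways) {
  if (inherits(pathways, "pathway_graph")) pathways <- list(pathways)
  node_ko <- purrr::map_dfr(pathways, function(p) {
    ent <- p$entries[p$entries$entry_type %in% KGML_NODE_TYPES, , drop = FALSE]
    if (nrow(ent) == 0L) return(NULL)
    tibble::tibble(pathway_id = p$pathway_id, entry_id = ent$entry_id,
                   ko_ids = ent$ko_ids) %>%
      tidyr::unnest(cols = "ko_ids") %>%
      dplyr::rename(koid = "ko_ids")
  })
  if (nrow(groups) == 0L || nrow(node_ko) == 0L) {
    out <- tibble::tibble(query_id = character(), koid = character(),
                          pathway_id = character(), entry_id = character())
  } else {
    out <- dplyr::inner_join(groups, node_ko, by = "koid",
                             relationship = "many-to-many") %>%
      dplyr::distinct() %>%
      dplyr::arrange(.data$query_id, .data$koid, .data$pathway_id,
                     .data$entry_id) %>%
      dplyr::select("query_id", "koid", "pathway_id", "entry_id")
  }
  class(out) <- c("ko_mapping", class(out))
  out
}

#' Per-pathway summary of a KO mapping
#'
#' @param mapping A `ko_mapping` from [map_queries()].
#' @return Tibble with one row per pathway hit: matched entry count,
#'   matched KO count, contributing EST count.
#' @export
mapping_by_pathway <- function(mapping) {
  mapping %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$pathway_id) %>%
    dplyr::summarise(
      n_entries = dplyr::n_distinct(.data$entry_id),
      n_koids = dplyr::n_distinct(.data$koid),
      n_queries = dplyr::n_distinct(.data$query_id),
      .groups = "drop"
    )
}

#' Per-query summary of a KO mapping
#'
#' @param mapping A `ko_mapping` from [map_queries()].
#' @return Tibble with one row per mapped query and its pathway count.
#' @export
mapping_by_query <- function(mapping) {
  mapping %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$query_id) %>%
    dplyr::summarise(n_pathways = dplyr::n_distinct(.data$pathway_id),
                     pathway_ids = list(sort(unique(.data$pathway_id))),
                     .groups = "drop")
}

#' Highlight the matched KO nodes of a pathway map
#'
#' Marks every gene-level entry whose KO set intersects the matched KO
#' identifiers, the way a reference map is customised for a query
#' organism: matched nodes are flagged for red (by default) colouring and
#' relabelled with their smallest matched KO identifier, while the rest
#' of the map structure is left untouched.
#'
#' @param p A `pathway_graph`.
#' @param matched_koids Character vector of matched KO identifiers.
#' @param color Highlight colour recorded for exports (default "red").
#' @return A `highlighted_pathway`: list with `base` (the unchanged
#'   `pathway_graph`), `matched_nodes` (entry ids), `relabel` (tibble
#'   entry_id -> koid) and `highlight_color`.
#' @export
highlight_pathway <- function(p, matched_koids, color = "red") {
  stopifnot(inherits(p, "pathway_graph"))
  matched_koids <- unique(matched_koids)
  node <- p$entries$entry_type %in% KGML_NODE_TYPES
  hit <- purrr::map_lgl(p$entries$ko_ids,
                        ~ length(intersect(.x, matched_koids)) > 0L) & node
  relabel <- tibble::tibble(
    entry_id = p$entries$entry_id[hit],
    koid = purrr::map_chr(p$entries$ko_ids[hit],
                          ~ min(intersect(.x, matched_koids)))
  )
  structure(
    list(base = p, matched_nodes = p$entries$entry_id[hit],
         relabel = relabel, highlight_color = color),
    class = "highlighted_pathway"
  )
}

#' @export
print.highlighted_pathway <- function(x, ...) {
  cat(sprintf("<highlighted_pathway %s: %d/%d nodes matched>\n",
              x$base$pathway_id, length(x$matched_nodes),
              sum(x$base$entries$entry_type %in% KGML_NODE_TYPES)))
  invisible(x)
}

export_node_ids <- function(nodes) {
  ifelse(is.na(nodes$primary_koid), nodes$entry_id,
         paste0(nodes$entry_id, "|", nodes$primary_koid))
}

#' Export a highlighted pathway as a machine-readable network
#'
#' Writes the reference network in one of four formats with fully
#' deterministic output (stable node and edge ordering, so identical
#' inputs give byte-identical files):
#' \describe{
#'   \item{SIF}{three tab-separated columns `node  relation  node`; the
#'     relation label is `type:subtype` (e.g. `PPrel:activation`).}
#'   \item{GraphML}{node attributes `highlighted`, `koid`,
#'     `display_name`; edge attribute `interaction`.}
#'   \item{TSV}{edge list with a header: from, to, interaction.}
#'   \item{annotated-KGML}{the source KGML with matched nodes' graphics
#'     background set to the highlight colour and their graphics names
#'     rewritten to the matched KO identifier; everything else verbatim.}
#' }
#' Node identifiers in SIF/GraphML/TSV are the pathway-local entry id,
#' suffixed with `|K#####` when the node carries a KO.
#'
#' @param h A `highlighted_pathway` (or a bare `pathway_graph`, exported
#'   with nothing matched).
#' @param format One of `"SIF"`, `"GraphML"`, `"TSV"`, `"annotated-KGML"`.
#' @param path Output file path.
#' @param include_reactions Passed to [to_interaction_graph()].
#' @return `path`, invisibly.
#' @export
export_network <- function(h, format = c("SIF", "GraphML", "TSV", "annotated-KGML"),
                           path, include_reactions = NULL) {
  if (inherits(h, "pathway_graph")) h <- highlight_pathway(h, character())
  stopifnot(inherits(h, "highlighted_pathway"))
  format <- match.arg(format)

  if (format == "annotated-KGML") {
    p <- h$base
    idx <- match(h$matched_nodes, p$entries$entry_id)
    lab <- stats::setNames(h$relabel$koid, h$relabel$entry_id)
    for (i in idx) {
      g <- p$entries$graphics[[i]]
      if (is.null(g)) g <- c(name = unname(lab[p$entries$entry_id[i]]))
      g[["bgcolor"]] <- h$highlight_color
      g[["name"]] <- unname(lab[p$entries$entry_id[i]])
      p$entries$graphics[[i]] <- g
      p$entries$display_name[i] <- g[["name"]]
    }
    return(write_kgml(p, path))
  }

  ig <- to_interaction_graph(h$base, include_reactions = include_reactions)
  nodes <- ig$nodes %>%
    dplyr::mutate(
      export_id = export_node_ids(ig$nodes),
      highlighted = .data$entry_id %in% h$matched_nodes,
      koid = dplyr::coalesce(
        stats::setNames(h$relabel$koid, h$relabel$entry_id)[.data$entry_id],
        .data$primary_koid
      )
    ) %>%
    dplyr::arrange(.data$export_id)
  id_of <- stats::setNames(nodes$export_id, nodes$entry_id)
  edges <- ig$edges %>%
    dplyr::mutate(
      from = unname(id_of[.data$from]),
      to = unname(id_of[.data$to]),
      interaction = ifelse(is.na(.data$subtype), .data$relation_type,
                           paste0(.data$relation_type, ":", .data$subtype))
    ) %>%
    dplyr::arrange(.data$from, .data$interaction, .data$to)

  if (format == "SIF") {
    writeLines(sprintf("%s\t%s\t%s", edges$from, edges$interaction, edges$to),
               path)
  } else if (format == "TSV") {
    readr::write_tsv(edges[, c("from", "to", "interaction")], path,
                     progress = FALSE)
  } else { # GraphML
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to", "interaction")],
      directed = TRUE,
      vertices = data.frame(
        name = nodes$export_id,
        highlighted = nodes$highlighted,
        koid = ifelse(is.na(nodes$koid), "", nodes$koid),
        display_name = ifelse(is.na(nodes$display_name), "",
                              nodes$display_name),
        stringsAsFactors = FALSE
      )
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Pathway coverage statistics for an annotated EST set
#'
#' Counts how much of the query set reaches the pathway collection:
#' totals of queries and KO assignments, pathways hit split into
#' metabolic and non-metabolic, and queries mapped to metabolic maps,
#' non-metabolic maps, or both. Queries mapped to at least one pathway
#' obey the inclusion-exclusion identity
#' `n_queries_metabolic + n_queries_nonmetabolic - n_queries_both`.
#'
#' @param mapping A `ko_mapping` from [map_queries()].
#' @param assignments Assignment tibble from [assign_ko()] (for totals of
#'   queries and assigned queries).
#' @param pathways The classified `pathway_graph` list used in the
#'   mapping, or a tibble with columns `pathway_id`, `category`.
#' @return A one-row `ko_coverage` tibble with columns
#'   `n_queries_total`, `n_queries_assigned`, `n_unique_koids`,
#'   `n_pathways_hit`, `n_pathways_metabolic`, `n_pathways_nonmetabolic`,
#'   `n_queries_metabolic`, `n_queries_nonmetabolic`, `n_queries_both`,
#'   `n_queries_mapped`.
#' @export
coverage_stats <- function(mapping, assignments, pathways) {
  cat_tab <- if (is.data.frame(pathways)) {
    tibble::as_tibble(pathways[, c("pathway_id", "category")])
  } else {
    if (inherits(pathways, "pathway_graph")) pathways <- list(pathways)
    tibble::tibble(
      pathway_id = purrr::map_chr(pathways, "pathway_id"),
      category = purrr::map_chr(pathways, "category")
    )
  }
  m <- tibble::as_tibble(mapping)
  hit_paths <- unique(m$pathway_id)
  known <- cat_tab$pathway_id[!is.na(cat_tab$category)]
  if (length(setdiff(hit_paths, known)) > 0L) {
    stop("pathway without a category: ", setdiff(hit_paths, known)[1])
  }
  m <- dplyr::left_join(m, cat_tab, by = "pathway_id")

  per_query <- m %>%
    dplyr::group_by(.data$query_id) %>%
    dplyr::summarise(met = any(.data$category == "metabolic"),
                     nonmet = any(.data$category == "non-metabolic"),
                     .groups = "drop")
  pathcat <- cat_tab$category[match(hit_paths, cat_tab$pathway_id)]

  out <- tibble::tibble(
    n_queries_total = nrow(assignments),
    n_queries_assigned = sum(!is.na(assignments$primary_koid)),
    n_unique_koids = length(unique(unlist(assignments$koids))),
    n_pathways_hit = length(hit_paths),
    n_pathways_metabolic = sum(pathcat == "metabolic"),
    n_pathways_nonmetabolic = sum(pathcat == "non-metabolic"),
    n_queries_metabolic = sum(per_query$met),
    n_queries_nonmetabolic = sum(per_query$nonmet),
    n_queries_both = sum(per_query$met & per_query$nonmet),
    n_queries_mapped = nrow(per_query)
  )
  class(out) <- c("ko_coverage", class(out))
  out
}
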