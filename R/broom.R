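#' Tidy a KO reassignment benchmark
#'
#' @param x A `ko_benchmark` from [score_reassignment()].
#' @param ... Unused.
#' @return One row per curated gene: `gene`, `curated_koids` (list),
#'   `assigned_koids` (list), `assigned`, `matched`.
#' @exportS3Method generics::tidy
tidy.ko_benchmark <- function(x, ...) {
  x$per_gene %>%
    dplyr::select("gene", "curated_koids", "assigned_koids",
                  "assigned", "matched")
}

#' One-row summary of a KO reassignment benchmark
#'
#' @param x A `ko_benchmark`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ko_benchmark <- function(x, ...) {
  tibble::tibble(n_curated = x$n_curated, n_assigned = x$n_assigned,
                 n_matched = x$n_matched, accuracy_pct = x$accuracy_pct)
}

#' Tidy a KO-to-pathway mapping
#'
#' @param x A `ko_mapping` from [map_queries()].
#' @param ... Unused.
#' @return The underlying long membership tibble.
#' @exportS3Method generics::tidy
tidy.ko_mapping <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a KO-to-pathway mapping
#'
#' @param x A `ko_mapping`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ko_mapping <- function(x, ...) {
  tibble::tibble(
    n_queries = dplyr::n_distinct(x$query_id),
    n_koids = dplyr::n_distinct(x$koid),
    n_pathways = dplyr::n_distinct(x$pathway_id)
  )
}

#' Tidy a pathway graph into its node table
#'
#' @param x A `pathway_graph`.
#' @param ... Unused.
#' @return Entry table with scalar columns plus a `ko_ids` list-column.
#' @exportS3Method generics::tidy
tidy.pathway_graph <- function(x, ...) {
  dplyr::select(x$entries, "entry_id", "entry_type", "name",
                "display_name", "ko_ids")
}

#' One-row summary of a pathway graph
#'
#' @param x A `pathway_graph`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.pathway_graph <- function(x, ...) {
  tibble::tibble(
    pathway_id = x$pathway_id, number = x$number, title = x$title,
    category = x$category,
    n_entries = nrow(x$entries), n_relations = nrow(x$relations),
    n_reactions = nrow(x$reactions),
    n_koids = dplyr::n_distinct(unlist(x$entries$ko_ids))
  )
}
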