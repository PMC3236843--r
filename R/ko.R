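#' Read a gene-to-KO annotation table
#'
#' Reads a two-column TSV linking gene tokens of one organism to KEGG
#' Orthology identifiers (`K#####`). A gene may appear on several lines;
#' its KO set accumulates.
#'
#' @param path Path to a TSV with columns `<gene_token>\t<KOID>` and no
#'   header.
#' @param organism Organism code; defaults to the file name up to the
#'   first dot (`cel.ko.tsv` -> `cel`).
#' @return A tibble with columns `organism`, `gene`, `koid`, one row per
#'   distinct (gene, KOID) pair.
#' @export
read_ko_annotation <- function(path, organism = NULL) {
  stopifnot(file.exists(path))
  if (is.null(organism)) organism <- sub("\\..*$", "", basename(path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble::tibble(organism = character(), gene = character(),
                          koid = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected 2 tab-separated columns", line_no[bad[1]]))
  }
  gene <- vapply(fields, `[[`, "", 1L)
  koid <- vapply(fields, `[[`, "", 2L)
  badko <- which(!is_koid(koid))
  if (length(badko) > 0L) {
    stop(sprintf("line %d: malformed KO identifier '%s' (expected K#####)",
                 line_no[badko[1]], koid[badko[1]]))
  }
  tibble::tibble(organism = organism, gene = gene, koid = koid) %>%
    dplyr::distinct()
}

#' Assign KO groups to selected best hits
#'
#' Looks each best hit's subject gene up in its organism's annotation
#' table and lets the query inherit every KO identifier of that gene. A
#' query whose subject gene is unannotated stays an unassigned EST (empty
#' KO set); there is no fallback to the next-best hit. `primary_koid` is
#' the lexicographically smallest inherited KO, used wherever a single
#' label is needed.
#'
#' @param best Consolidated best hits (one row per query), e.g. from
#'   [consolidate_best_hits()]; per-organism tables from
#'   [select_best_hits()] also work.
#' @param annotations A gene-to-KO annotation tibble covering every
#'   organism present in `best` (bind rows of [read_ko_annotation()]
#'   results).
#' @return `best` with two added columns: `koids`, a list-column of
#'   character vectors (sorted, possibly empty), and `primary_koid`
#'   (`NA` when unassigned).
#' @export
assign_ko <- function(best, annotations) {
  missing_org <- setdiff(unique(best$organism), unique(annotations$organism))
  if (length(missing_org) > 0L) {
    stop("no KO annotation table for organism(s): ",
         paste(missing_org, collapse = ", "))
  }
  ann <- annotations %>%
    dplyr::group_by(.data$organism, .data$gene) %>%
    dplyr::summarise(koids = list(sort(unique(.data$koid))), .groups = "drop")
  # subject tokens are usually organism-prefixed ("cel:F14B4.3"); the
  # annotation tables key on the bare gene token
  out <- best %>%
    dplyr::mutate(.gene = ifelse(
      startsWith(.data$subject_id, paste0(.data$organism, ":")),
      substring(.data$subject_id, nchar(.data$organism) + 2L),
      .data$subject_id
    )) %>%
    dplyr::left_join(ann, by = c("organism", ".gene" = "gene")) %>%
    dplyr::select(-".gene") %>%
    dplyr::mutate(
      koids = purrr::map(.data$koids, ~ if (is.null(.x)) character() else .x),
      primary_koid = purrr::map_chr(
        .data$koids, ~ if (length(.x) == 0L) NA_character_ else .x[[1L]]
      )
    )
  out
}

#' Group assigned queries by KO identifier
#'
#' Inverts the query-to-KO relation: every (KO, query) pair for which the
#' query inherited that KO. Queries with an empty KO set appear in no
#' group; a query with several KOs appears in several groups.
#'
#' @param assignments Tibble from [assign_ko()].
#' @return A tibble with columns `koid`, `query_id`, sorted, one row per
#'   membership pair.
#' @export
ko_groups <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(tibble::tibble(koid = character(), query_id = character()))
  }
  assignments %>%
    dplyr::select("query_id", "koids") %>%
    tidyr::unnest(cols = "koids") %>%
    dplyr::rename(koid = "koids") %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$koid, .data$query_id) %>%
    dplyr::select("koid", "query_id")
}
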