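#' Read a BLAST tabular hit file
#'
#' Reads homology-search results in BLAST tabular format (`-outfmt 6`).
#' Two dialects are supported: `"std12"`, the twelve standard columns
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), and `"std12+nident"`, the same plus a thirteenth
#' `nident` column (`-outfmt "6 std nident"`). For `"std12"` input the
#' identity count is derived as `round(pident * length / 100)` (half away
#' from zero). Comment lines starting with `#` (outfmt 7 headers) are
#' skipped.
#'
#' @param path Path to a tab-separated hit file.
#' @param dialect `"std12"` or `"std12+nident"`.
#' @param organism Organism code to attach to every hit. Defaults to the
#'   prefix of the subject identifiers when they look like `org:gene`
#'   tokens, otherwise the file name without extension.
#' @return A tibble with one row per hit and columns `query_id`,
#'   `subject_id`, `pident`, `align_len`, `mismatch`, `gapopen`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`, `nident`, `organism`,
#'   in file order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines("q1\tcel:g1\t50.00\t100\t50\t0\t1\t100\t1\t100\t1e-20\t90",
#'            f)
#' read_hit_table(f)
#' @export
read_hit_table <- function(path, dialect = c("std12", "std12+nident"),
                           organism = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]

  ncol_expected <- if (dialect == "std12") 12L else 13L
  cols <- c("query_id", "subject_id", "pident", "align_len", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  if (dialect == "std12+nident") cols <- c(cols, "nident")
  num_cols <- setdiff(cols, c("query_id", "subject_id"))

  if (length(lines) == 0L) {
    tab <- tibble::as_tibble(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), length(num_cols))),
      cols
    ))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != ncol_expected)
    if (length(bad) > 0L) {
      stop(sprintf("line %d: expected %d tab-separated columns, found %d",
                   line_no[bad[1]], ncol_expected, lengths(fields)[bad[1]]))
    }
    mat <- matrix(unlist(fields), ncol = ncol_expected, byrow = TRUE)
    colnames(mat) <- cols
    tab <- tibble::as_tibble(mat)
    for (cn in num_cols) {
      v <- suppressWarnings(as.numeric(tab[[cn]]))
      if (anyNA(v)) {
        stop(sprintf("line %d: unparsable number in column %s",
                     line_no[which(is.na(v))[1]], cn))
      }
      tab[[cn]] <- v
    }
    if (any(tab$evalue < 0)) {
      stop(sprintf("line %d: negative evalue",
                   line_no[which(tab$evalue < 0)[1]]))
    }
  }

  if (dialect == "std12") {
    tab$nident <- round_half_away(tab$pident * tab$align_len / 100)
  }
  if (is.null(organism)) {
    pref <- unique(sub(":.*$", "", tab$subject_id[grepl(":", tab$subject_id)]))
    organism <- if (length(pref) == 1L) pref else
      sub("\\.[^.]*$", "", basename(path))
  }
  tab$organism <- organism
  tab[, c("query_id", "organism", "subject_id", "pident", "align_len",
          "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
          "evalue", "bitscore", "nident")]
}

#' Discard hits above an E-value cutoff
#'
#' Keeps exactly the hits with `evalue <= cutoff`: hits strictly above the
#' cutoff carry no statistical support and are dropped, while a hit at
#' exactly the cutoff is retained.
#'
#' @param hits A hit tibble as returned by [read_hit_table()].
#' @param cutoff Positive E-value cutoff; default 10, the conventional
#'   permissive BLAST default.
#' @return The filtered tibble, row order preserved.
#' @export
filter_by_evalue <- function(hits, cutoff = 10) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  dplyr::filter(hits, .data$evalue <= cutoff)
}

# The documented total selection order: E-value ascending, then bitscore,
# pident and nident descending, then subject_id ascending so ties are
# always fully broken and selection is independent of input row order.
hit_order_keys <- function() {
  list(
    rlang::quo(.data$evalue),
    rlang::quo(dplyr::desc(.data$bitscore)),
    rlang::quo(dplyr::desc(.data$pident)),
    rlang::quo(dplyr::desc(.data$nident)),
    rlang::quo(.data$subject_id)
  )
}

#' Select the best hit for every query within each organism
#'
#' Applies the E-value cutoff and then, per `(query_id, organism)` pair,
#' keeps the single hit that is minimal under the selection order: E-value
#' ascending, bitscore descending, percent identity descending, identity
#' count descending, subject identifier ascending. The final lexicographic
#' key makes the order total, so the choice is deterministic and
#' independent of input row order.
#'
#' @param hits A hit tibble (any number of queries and organisms).
#' @param cutoff E-value cutoff applied before selection (default 10); use
#'   `Inf` to rank pre-filtered tables.
#' @return A tibble with one row per `(query_id, organism)` that has at
#'   least one surviving hit.
#' @seealso [consolidate_best_hits()] to merge across organisms.
#' @export
select_best_hits <- function(hits, cutoff = 10) {
  filter_by_evalue(hits, cutoff) %>%
    dplyr::arrange(!!!hit_order_keys()) %>%
    dplyr::distinct(.data$query_id, .data$organism, .keep_all = TRUE) %>%
    dplyr::arrange(.data$query_id, .data$organism)
}

#' Select the best hit among the hits of a single query
#'
#' Single-query counterpart of [select_best_hits()]; all rows must share
#' one `query_id`.
#'
#' @param hits Hit tibble for one query.
#' @param cutoff E-value cutoff (default 10).
#' @return A one-row tibble, or a zero-row tibble if no hit survives.
#' @export
select_best_hit <- function(hits, cutoff = 10) {
  if (nrow(hits) > 0L && length(unique(hits$query_id)) > 1L) {
    stop("hits span more than one query_id")
  }
  filter_by_evalue(hits, cutoff) %>%
    dplyr::arrange(!!!hit_order_keys()) %>%
    dplyr::slice_head(n = 1L)
}

#' Consolidate per-organism best hits into one global best hit per query
#'
#' Given already-selected per-organism candidates (one per query per
#' organism), keeps for each query the global minimum under the same
#' selection order, with ties between organisms broken by organism code.
#' This mirrors running per-organism searches with a shared cutoff and
#' then asking which reference organism supplied the most significant hit.
#'
#' @param best Per-organism best hits from [select_best_hits()].
#' @return A tibble with one row per query.
#' @export
consolidate_best_hits <- function(best) {
  best %>%
    dplyr::arrange(!!!hit_order_keys(), .data$organism) %>%
    dplyr::distinct(.data$query_id, .keep_all = TRUE) %>%
    dplyr::arrange(.data$query_id)
}
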