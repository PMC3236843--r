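#' Score KO reassignment against a curated annotation
#'
#' Compares pipeline KO assignments with a curated gene-to-KO table for
#' the same organism. A curated gene counts as matched when the KO set it
#' received from the pipeline intersects its curated KO set (set
#' `strict = TRUE` to require the primary assigned KO to equal the
#' smallest curated KO instead). Accuracy is the percentage of matched
#' genes among all curated genes — whether or not they received any
#' assignment — reported to one decimal, half away from zero.
#'
#' @param curated Curated annotation tibble (columns `gene`, `koid`;
#'   [read_ko_annotation()] output works).
#' @param assignments Assignment tibble from [assign_ko()], with
#'   `query_id` holding the same gene tokens as `curated$gene`.
#' @param strict Require primary-vs-primary equality instead of set
#'   intersection (default `FALSE`).
#' @return A `ko_benchmark` object; its [glance()] is a one-row tibble
#'   with `n_curated`, `n_assigned`, `n_matched`, `accuracy_pct`, and its
#'   [tidy()] a per-gene table.
#' @export
score_reassignment <- function(curated, assignments, strict = FALSE) {
  if (nrow(curated) == 0L) stop("curated table is empty")
  cur <- curated %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(curated_koids = list(sort(unique(.data$koid))),
                     .groups = "drop")
  asg <- assignments %>%
    dplyr::select(gene = "query_id", assigned_koids = "koids",
                  assigned_primary = "primary_koid") %>%
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  per_gene <- cur %>%
    dplyr::left_join(asg, by = "gene") %>%
    dplyr::mutate(
      assigned_koids = purrr::map(.data$assigned_koids,
                                  ~ if (is.null(.x)) character() else .x),
      assigned = lengths(.data$assigned_koids) > 0L,
      matched = if (strict) {
        purrr::map2_lgl(.data$assigned_primary, .data$curated_koids,
                        ~ !is.na(.x) && .x == .y[[1L]])
      } else {
        purrr::map2_lgl(.data$assigned_koids, .data$curated_koids,
                        ~ length(intersect(.x, .y)) > 0L)
      }
    )
  res <- list(
    per_gene = per_gene,
    n_curated = nrow(per_gene),
    n_assigned = sum(per_gene$assigned),
    n_matched = sum(per_gene$matched),
    strict = strict
  )
  res$accuracy_pct <- round_half_away(100 * res$n_matched / res$n_curated, 1)
  structure(res, class = "ko_benchmark")
}

#' @export
print.ko_benchmark <- function(x, ...) {
  cat(sprintf(
    "<ko_benchmark: %d/%d curated genes matched (%s%.1f%%), %d assigned>\n",
    x$n_matched, x$n_curated, if (x$strict) "strict, " else "",
    x$accuracy_pct, x$n_assigned))
  invisible(x)
}

#' Leave-one-organism-out reassignment benchmark on a synthetic world
#'
#' Reproduces the validation protocol of withholding one curated
#' organism: the ESTs derived from the target organism's genes are run
#' through the full pipeline (E-value filtering, per-organism best-hit
#' selection, cross-organism consolidation, KO assignment) using every
#' other organism as reference, and the resulting KO labels are scored
#' against the target ESTs' ground-truth KO groups.
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @param target_organism Organism code withheld and scored.
#' @param cutoff E-value cutoff (default 10).
#' @param strict Passed to [score_reassignment()].
#' @return A `ko_benchmark`.
#' @export
leave_one_out <- function(world, target_organism, cutoff = 10,
                          strict = FALSE) {
  stopifnot(inherits(world, "synthetic_world"))
  orgs <- world$organisms
  if (length(orgs) < 2L) stop("leave-one-out needs at least 2 organisms")
  if (!target_organism %in% orgs) {
    stop("unknown organism: ", target_organism)
  }
  refs <- setdiff(orgs, target_organism)
  truth <- world$truth[world$truth$source_organism == target_organism, ,
                       drop = FALSE]
  if (nrow(truth) == 0L) {
    stop("no queries derive from organism ", target_organism)
  }
  hits <- generate_hit_tables(world, reference_organisms = refs,
                              query_ids = truth$query_id)
  ann <- purrr::map_dfr(refs, ~ world$annotations[[.x]])
  assignments <- hits$hits %>%
    select_best_hits(cutoff = cutoff) %>%
    consolidate_best_hits() %>%
    assign_ko(ann)
  curated <- tibble::tibble(gene = truth$query_id, koid = truth$koid)
  score_reassignment(curated, assignments, strict = strict)
}

#' Benchmark accuracy across a mutation-rate sweep
#'
#' Regenerates worlds that differ only in the EST mutation rate (and
#' seed), runs [leave_one_out()] on each, and averages accuracy per rate
#' across seeds. Used to check that accuracy degrades monotonically as
#' queries diverge from their source genes.
#'
#' @param params Base [world_params()]; its `mutation_rate` and `seed`
#'   are overridden.
#' @param mutation_rates Numeric vector of per-base substitution rates.
#' @param seeds Integer vector of world seeds averaged over.
#' @param target_organism Organism withheld; default the first.
#' @return Tibble with columns `mutation_rate`, `mean_accuracy_pct`,
#'   `n_runs`.
#' @export
accuracy_sweep <- function(params, mutation_rates = c(0.05, 0.15, 0.30),
                           seeds = 1:3, target_organism = NULL) {
  runs <- tidyr::expand_grid(mutation_rate = mutation_rates, seed = seeds)
  acc <- purrr::pmap_dbl(runs, function(mutation_rate, seed) {
    p <- params
    p$mutation_rate <- mutation_rate
    p$seed <- seed
    w <- generate_world(p)
    tgt <- if (is.null(target_organism)) w$organisms[[1L]] else target_organism
    score <- leave_one_out(w, tgt)
    score$accuracy_pct
  })
  runs$accuracy_pct <- acc
  runs %>%
    dplyr::group_by(.data$mutation_rate) %>%
    dplyr::summarise(mean_accuracy_pct = mean(.data$accuracy_pct),
                     n_runs = dplyr::n(), .groups = "drop")
}
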