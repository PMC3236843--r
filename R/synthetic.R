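DNA <- c("A", "C", "G", "T")

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) sample(DNA, n, replace = TRUE)

mutate_dna <- function(seq_chars, rate) {
  if (rate <= 0) return(seq_chars)
  hit <- stats::runif(length(seq_chars)) < rate
  n <- sum(hit)
  if (n > 0L) {
    # substitute to a uniformly chosen *different* base
    shift <- sample(3L, n, replace = TRUE)
    idx <- match(seq_chars[hit], DNA)
    seq_chars[hit] <- DNA[((idx - 1L + shift) %% 4L) + 1L]
  }
  seq_chars
}

#' Parameters for a synthetic annotation world
#'
#' Bundles and validates the knobs of the synthetic-world generator: the
#' size of the KO universe, the organism panel, gene and EST fragment
#' lengths (900 and 300 nt — typical gene and single-pass EST read
#' sizes), the per-base EST substitution rate, per-organism divergence
#' from the KO ancestral sequence, the pathway collection, and the
#' hit-table noise model.
#'
#' @param n_kos Number of KO groups (>= 1).
#' @param n_organisms Number of reference organisms (>= 2).
#' @param genes_per_ko Genes per KO per organism (>= 1).
#' @param gene_len Gene length in nt.
#' @param n_queries Number of query ESTs.
#' @param fragment_len EST fragment length in nt (<= `gene_len`).
#' @param mutation_rate Per-base substitution probability of an EST
#'   relative to its source gene, in `[0, 1)`.
#' @param divergence Per-base substitution probability of each organism
#'   gene relative to its KO ancestral sequence.
#' @param n_pathways Number of synthetic KGML maps.
#' @param kos_per_pathway KO nodes per map (<= `n_kos`).
#' @param relation_density Probability that an ordered node pair of a map
#'   gets a relation, in `(0, 1]`.
#' @param hit_noise `"on"` adds decoy hits to wrong-KO genes; `"off"`
#'   emits only the true hit per (query, organism).
#' @param decoy_hit_rate Probability of a decoy hit per (query,
#'   organism), in `[0, 1)`.
#' @param revframe_rate Fraction of emitted hit rows with `qstart >
#'   qend` (reverse-frame style coordinates), to exercise consumers.
#' @param seed Integer seed; everything the generator emits is a pure
#'   function of the parameters including the seed.
#' @return A validated `world_params` list.
#' @export
world_params <- function(n_kos = 30, n_organisms = 4, genes_per_ko = 2,
                         gene_len = 900, n_queries = 150,
                         fragment_len = 300, mutation_rate = 0.05,
                         divergence = 0.05, n_pathways = 6,
                         kos_per_pathway = 8, relation_density = 0.3,
                         hit_noise = c("on", "off"), decoy_hit_rate = 0.1,
                         revframe_rate = 0.1, seed = 1) {
  hit_noise <- match.arg(hit_noise)
  p <- list(n_kos = as.integer(n_kos), n_organisms = as.integer(n_organisms),
            genes_per_ko = as.integer(genes_per_ko),
            gene_len = as.integer(gene_len),
            n_queries = as.integer(n_queries),
            fragment_len = as.integer(fragment_len),
            mutation_rate = mutation_rate, divergence = divergence,
            n_pathways = as.integer(n_pathways),
            kos_per_pathway = as.integer(kos_per_pathway),
            relation_density = relation_density, hit_noise = hit_noise,
            decoy_hit_rate = decoy_hit_rate, revframe_rate = revframe_rate,
            seed = as.integer(seed))
  stopifnot(
    p$n_kos >= 1L, p$n_organisms >= 2L, p$genes_per_ko >= 1L,
    p$n_queries >= 1L, p$fragment_len >= 1L,
    p$mutation_rate >= 0, p$mutation_rate < 1,
    p$divergence >= 0, p$divergence < 1,
    p$relation_density > 0, p$relation_density <= 1,
    p$decoy_hit_rate >= 0, p$decoy_hit_rate < 1,
    p$n_pathways >= 0L
  )
  if (p$fragment_len > p$gene_len) {
    stop("fragment_len must not exceed gene_len")
  }
  if (p$n_pathways > 0L && p$kos_per_pathway > p$n_kos) {
    stop("kos_per_pathway must not exceed n_kos")
  }
  structure(p, class = "world_params")
}

write_fasta <- function(ids, seqs, path, width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    body <- gsub(sprintf("(.{%d})", width), "\\1\n", seqs[[i]])
    body <- sub("\n$", "", body)
    writeLines(c(paste0(">", ids[[i]]), body), con)
  }
  invisible(path)
}

#' Generate a synthetic annotation world with recorded ground truth
#'
#' Builds a complete, self-contained test bed for the pipeline: one
#' ancestral gene per KO group; per organism, `genes_per_ko` descendant
#' genes mutated from each ancestor at the divergence rate; query ESTs
#' cut as contiguous fragments from uniformly chosen source genes and
#' point-mutated at `mutation_rate`; per-organism gene-to-KO annotation
#' tables; KGML pathway maps over random KO subsets with relations
#' sampled at `relation_density`; and a category table assigning the
#' maps alternately to the metabolic and non-metabolic classes (so both
#' classes are always populated). Every emitted record is traceable to
#' the `truth` table, and regeneration with the same parameters
#' reproduces identical bytes.
#'
#' @param params A [world_params()] object.
#' @param dir Output directory for the emitted files (created if
#'   needed); defaults to a fresh temporary directory.
#' @return A `synthetic_world`: list with `params`, `organisms`, `kos`,
#'   `genes` (organism/gene/koid/sequence), `queries`, `truth`
#'   (query_id, source organism/gene, KO, fragment coordinates),
#'   `annotations` (per-organism tibbles), `pathways` (classified
#'   `pathway_graph`s), `categories`, `files`, `dir`.
#' @export
generate_world <- function(params = world_params(), dir = NULL) {
  stopifnot(inherits(params, "world_params"))
  if (is.null(dir)) dir <- tempfile("world")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  with_local_seed(params$seed, {
    kos <- sprintf("K%05d", seq_len(params$n_kos))
    organisms <- sprintf("org%02d", seq_len(params$n_organisms))

    ancestors <- lapply(kos, function(k) random_dna(params$gene_len))
    names(ancestors) <- kos

    genes <- tidyr::expand_grid(organism = organisms, koid = kos,
                                copy = seq_len(params$genes_per_ko))
    genes$gene <- sprintf("g%s_%d", genes$koid, genes$copy)
    genes$seq_chars <- purrr::map2(genes$koid, genes$copy, function(k, j) {
      mutate_dna(ancestors[[k]], params$divergence)
    })
    genes$seq <- vapply(genes$seq_chars, paste, "", collapse = "")

    # query ESTs: uniform source gene, contiguous fragment, point mutations
    src <- sample(nrow(genes), params$n_queries, replace = TRUE)
    start <- sample(params$gene_len - params$fragment_len + 1L,
                    params$n_queries, replace = TRUE)
    queries <- tibble::tibble(
      query_id = sprintf("est%04d", seq_len(params$n_queries)),
      seq_chars = purrr::map2(src, start, function(i, s) {
        mutate_dna(genes$seq_chars[[i]][s:(s + params$fragment_len - 1L)],
                   params$mutation_rate)
      })
    )
    queries$seq <- vapply(queries$seq_chars, paste, "", collapse = "")
    truth <- tibble::tibble(
      query_id = queries$query_id,
      source_organism = genes$organism[src],
      source_gene = genes$gene[src],
      koid = genes$koid[src],
      frag_start = start,
      frag_end = start + params$fragment_len - 1L
    )

    # pathway maps over random KO subsets
    pathway_files <- character(0)
    categories <- tibble::tibble(number = character(), class = character(),
                                 subcategory = character())
    for (i in seq_len(params$n_pathways)) {
      number <- sprintf("%05d", i)
      pkos <- sort(sample(kos, params$kos_per_pathway))
      n <- length(pkos)
      ids <- as.character(seq_len(n))
      xml <- xml2::xml_new_root("pathway")
      xml2::xml_set_attrs(xml, c(name = paste0("path:syn", number),
                                 org = "ko", number = number,
                                 title = paste("synthetic pathway", i)))
      for (j in seq_len(n)) {
        e <- xml2::xml_add_child(xml, "entry")
        xml2::xml_set_attrs(e, c(id = ids[j], name = paste0("ko:", pkos[j]),
                                 type = "ortholog"))
        g <- xml2::xml_add_child(e, "graphics")
        xml2::xml_set_attrs(g, c(
          name = pkos[j], type = "rectangle",
          x = as.character(sample(600L, 1L)),
          y = as.character(sample(400L, 1L)),
          width = "46", height = "17", fgcolor = "#000000",
          bgcolor = "#BFFFBF"))
      }
      pair <- tidyr::expand_grid(a = ids, b = ids)
      pair <- pair[pair$a != pair$b, , drop = FALSE]
      keep <- stats::runif(nrow(pair)) < params$relation_density
      pair <- pair[keep, , drop = FALSE]
      for (j in seq_len(nrow(pair))) {
        r <- xml2::xml_add_child(xml, "relation")
        xml2::xml_set_attrs(r, c(entry1 = pair$a[j], entry2 = pair$b[j],
                                 type = "PPrel"))
        st <- xml2::xml_add_child(r, "subtype")
        act <- sample(c("activation", "inhibition"), 1L)
        xml2::xml_set_attrs(st, c(
          name = act, value = if (act == "activation") "-->" else "--|"))
      }
      f <- file.path(dir, paste0("syn", number, ".xml"))
      writeLines(as.character(xml), f, sep = "")
      pathway_files <- c(pathway_files, f)
      categories <- dplyr::bind_rows(categories, tibble::tibble(
        number = number,
        class = if (i %% 2L == 1L) "Metabolism" else "Cellular Processes",
        subcategory = "synthetic"
      ))
    }

    # emit files: gene FASTA + KO annotation TSV per organism, query FASTA,
    # KGML maps, category table
    files <- list(pathways = pathway_files)
    annotations <- list()
    for (o in organisms) {
      og <- genes[genes$organism == o, , drop = FALSE]
      fa <- file.path(dir, paste0(o, ".genes.fasta"))
      write_fasta(paste0(o, ":", og$gene), og$seq, fa)
      ann <- file.path(dir, paste0(o, ".ko.tsv"))
      writeLines(paste(og$gene, og$koid, sep = "\t"), ann)
      files[[paste0(o, ".fasta")]] <- fa
      files[[paste0(o, ".ko")]] <- ann
      annotations[[o]] <- tibble::tibble(organism = o, gene = og$gene,
                                         koid = og$koid)
    }
    qf <- file.path(dir, "queries.fasta")
    write_fasta(queries$query_id, queries$seq, qf)
    files$queries <- qf
    cf <- file.path(dir, "categories.tsv")
    writeLines(paste(categories$number, categories$class,
                     categories$subcategory, sep = "\t"), cf)
    files$categories <- cf

    pathways <- purrr::map(pathway_files,
                           ~ classify_pathway(parse_kgml(.x), categories))

    structure(
      list(params = params, organisms = organisms, kos = kos,
           genes = genes, queries = queries, truth = truth,
           annotations = annotations, pathways = pathways,
           categories = categories, files = files, dir = dir),
      class = "synthetic_world"
    )
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world: %d KOs x %d organisms, %d genes, %d ESTs, %d maps (seed %d)>\n",
    x$params$n_kos, x$params$n_organisms, nrow(x$genes),
    nrow(x$queries), length(x$pathways), x$params$seed))
  invisible(x)
}

# identical positions of an ungapped alignment at a fixed offset
nident_at <- function(frag, gene_chars, start) {
  sum(frag == gene_chars[start:(start + length(frag) - 1L)])
}

# best ungapped offset of frag along gene; returns c(nident, start)
best_offset <- function(frag, gene_chars) {
  L <- length(frag)
  offs <- seq_len(length(gene_chars) - L + 1L)
  sc <- vapply(offs, function(s) nident_at(frag, gene_chars, s), 0L)
  i <- which.max(sc)
  c(sc[i], offs[i])
}

pseudo_hit <- function(query_id, organism, gene, nident, L, sstart,
                       subject_len) {
  bitscore <- 2 * nident
  tibble::tibble(
    query_id = query_id,
    organism = organism,
    subject_id = paste0(organism, ":", gene),
    pident = round(100 * nident / L, 2),
    align_len = L,
    mismatch = L - nident,
    gapopen = 0,
    qstart = 1,
    qend = L,
    sstart = sstart,
    send = sstart + L - 1,
    evalue = max(1e-180, L * subject_len * 2^(-bitscore)),
    bitscore = bitscore,
    nident = nident
  )
}

#' Generate per-organism homology hit tables for a synthetic world
#'
#' Stands in for a translated homology search: for every query and
#' reference organism it emits a "true" hit to the best same-KO gene
#' (identity counted on the ungapped alignment at the fragment's source
#' coordinates) and, when hit noise is on, an occasional decoy hit to a
#' random wrong-KO gene scored at its best ungapped offset. Scores
#' follow a transparent scheme — `bitscore = 2 * nident`,
#' `evalue = query_len * subject_len * 2^(-bitscore)` floored at 1e-180 —
#' monotone in alignment identity, so decoys are strictly inferior to
#' true hits whenever queries are close to their source genes. A
#' fraction of rows gets reverse-frame style swapped query coordinates.
#' Output is deterministic given the world.
#'
#' @param world A `synthetic_world`.
#' @param reference_organisms Organisms to search against (default all).
#' @param query_ids Queries to search (default all).
#' @param dir If non-`NULL`, also writes one 13-column
#'   (`std12+nident`) TSV per organism into `dir`.
#' @return List with `hits` (all rows, tibble in [read_hit_table()]
#'   layout), `true_hits` (query, organism, the ground-truth best
#'   subject), and `files` (paths, when written).
#' @export
generate_hit_tables <- function(world, reference_organisms = NULL,
                                query_ids = NULL, dir = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  p <- world$params
  if (is.null(reference_organisms)) reference_organisms <- world$organisms
  stopifnot(all(reference_organisms %in% world$organisms))
  truth <- world$truth
  if (!is.null(query_ids)) {
    truth <- truth[truth$query_id %in% query_ids, , drop = FALSE]
  }
  qidx <- match(truth$query_id, world$queries$query_id)

  with_local_seed(p$seed + 1L, {
    rows <- vector("list", nrow(truth) * length(reference_organisms) * 2L)
    true_rows <- vector("list", nrow(truth) * length(reference_organisms))
    nr <- 0L
    nt <- 0L
    for (qi in seq_len(nrow(truth))) {
      frag <- world$queries$seq_chars[[qidx[qi]]]
      L <- length(frag)
      for (o in reference_organisms) {
        cand <- which(world$genes$organism == o &
                        world$genes$koid == truth$koid[qi])
        sc <- vapply(cand, function(g) {
          nident_at(frag, world$genes$seq_chars[[g]], truth$frag_start[qi])
        }, 0L)
        best <- cand[order(-sc, world$genes$gene[cand])][1L]
        nr <- nr + 1L
        rows[[nr]] <- pseudo_hit(truth$query_id[qi], o,
                                 world$genes$gene[best], max(sc), L,
                                 truth$frag_start[qi], p$gene_len)
        nt <- nt + 1L
        true_rows[[nt]] <- tibble::tibble(
          query_id = truth$query_id[qi], organism = o,
          subject_id = paste0(o, ":", world$genes$gene[best]))
        if (p$hit_noise == "on" && stats::runif(1) < p$decoy_hit_rate) {
          other <- which(world$genes$organism == o &
                           world$genes$koid != truth$koid[qi])
          if (length(other) > 0L) {
            d <- other[sample(length(other), 1L)]
            bo <- best_offset(frag, world$genes$seq_chars[[d]])
            nr <- nr + 1L
            rows[[nr]] <- pseudo_hit(truth$query_id[qi], o,
                                     world$genes$gene[d], bo[1], L, bo[2],
                                     p$gene_len)
          }
        }
      }
    }
    hits <- dplyr::bind_rows(rows[seq_len(nr)])
    # reverse-frame dress-up: swap query coordinates on a few rows
    if (nrow(hits) > 0L && p$revframe_rate > 0) {
      flip <- stats::runif(nrow(hits)) < p$revframe_rate
      qs <- hits$qstart[flip]
      hits$qstart[flip] <- hits$qend[flip]
      hits$qend[flip] <- qs
    }
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- purrr::map_chr(reference_organisms, function(o) {
        oh <- hits[hits$organism == o, , drop = FALSE]
        f <- file.path(dir, paste0(o, ".hits.tsv"))
        writeLines(sprintf(
          "%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%g\t%d",
          oh$query_id, oh$subject_id, oh$pident, as.integer(oh$align_len),
          as.integer(oh$mismatch), as.integer(oh$gapopen),
          as.integer(oh$qstart), as.integer(oh$qend),
          as.integer(oh$sstart), as.integer(oh$send),
          format(oh$evalue, scientific = TRUE, digits = 6),
          oh$bitscore, as.integer(oh$nident)), f)
        f
      })
      names(files) <- reference_organisms
    }
    list(hits = hits, true_hits = dplyr::bind_rows(true_rows[seq_len(nt)]),
         files = files)
  })
}
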