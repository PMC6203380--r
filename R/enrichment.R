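#' First-degree binding partners of a hit list
#'
#' Returns the non-hit genes of `universe` that interact (one PPI edge) with
#' at least `min_hit_degree` distinct hits. Hits themselves are never
#' returned as partners.
#'
#' @param hits Character vector of hit gene ids (subset of `universe`).
#' @param net Edge tibble (`from`, `to`) of an undirected simple graph, as
#'   from [gen_ppi_network()] or [read_edge_list()].
#' @param universe Character vector of admissible partner genes.
#' @param min_hit_degree Minimum number of distinct hit neighbors (default 2).
#' @return Tibble with `gene` and `n_hit_neighbors`, sorted by decreasing
#'   hit degree then gene id.
#' @export
select_binding_partners <- function(hits, net, universe, min_hit_degree = 2) {
  if (!all(hits %in% universe)) abort("`hits` must be a subset of `universe`")
  net <- as_tibble(net)
  touching <- dplyr::bind_rows(
    tibble(gene = net$from, hit = net$to),
    tibble(gene = net$to, hit = net$from)
  ) |>
    dplyr::filter(.data$hit %in% hits, !.data$gene %in% hits,
                  .data$gene %in% universe) |>
    dplyr::distinct()
  touching |>
    dplyr::count(.data$gene, name = "n_hit_neighbors") |>
    dplyr::filter(.data$n_hit_neighbors >= min_hit_degree) |>
    dplyr::arrange(dplyr::desc(.data$n_hit_neighbors), .data$gene)
}

#' Hypergeometric gene-set over-representation
#'
#' For each term, tests over-representation of the query in the term by the
#' hypergeometric upper tail P(X >= k) (equivalently a one-sided Fisher
#' exact test on the 2x2 table), where X counts query genes in the term
#' under uniform sampling of `|query|` genes from `universe`. Set
#' memberships are intersected with the universe before testing; the
#' expected overlap and a Benjamini-Hochberg FDR across all tested terms are
#' reported alongside the nominal p.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param sets Gene-set collection: tibble with `term`, `description`
#'   (optional) and a `genes` list-column, as from [gen_gene_sets_and_dag()]
#'   or [read_gmt()]; an `annotation_dag` is also accepted.
#' @param universe Character vector: the background gene set (e.g. all
#'   screened genes' orthologs), passed explicitly.
#' @return Tibble with `term`, `n_term`, `n_overlap`, `expected`, `p`,
#'   `fdr`, and `overlap_genes` (list-column), sorted by `p`.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  if (length(universe) == 0) abort("empty universe")
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  if (length(setdiff(query, universe))) abort("query must be a subset of universe")
  if (inherits(sets, "annotation_dag")) {
    sets <- tibble(term = sets$terms, description = sets$terms,
                   genes = unname(sets$annot))
  }
  sets <- as_tibble(sets)
  n_u <- length(universe); n_q <- length(query)
  res <- purrr::map2_dfr(sets$term, sets$genes, function(term, members) {
    members <- intersect(members, universe)
    k <- length(intersect(members, query))
    K <- length(members)
    tibble(
      term = term, n_term = K, n_overlap = k,
      expected = n_q * K / n_u,
      p = phyper(k - 1, K, n_u - K, n_q, lower.tail = FALSE),
      overlap_genes = list(sort(intersect(members, query)))
    )
  })
  res$fdr <- p.adjust(res$p, method = "BH")
  dplyr::arrange(res[, c("term", "n_term", "n_overlap", "expected",
                         "p", "fdr", "overlap_genes")], .data$p, .data$term)
}

#' Filter enrichment results by significance and term size
#'
#' Keeps terms with nominal `p <= alpha` and at most `max_term_size`
#' annotated genes (both boundaries inclusive; terms with more than
#' `max_term_size` genes are discarded as too generic). Optionally also
#' requires a minimum number of query genes in the term.
#'
#' @param results A [hypergeom_enrich()] tibble.
#' @param alpha Nominal p threshold (default 0.05, inclusive).
#' @param max_term_size Largest term kept (default 500, inclusive).
#' @param min_overlap Optional minimum `n_overlap` (default 0, i.e. off; use
#'   3 for a "more than 2 candidate genes" rule).
#' @return The kept rows.
#' @export
filter_enriched_terms <- function(results, alpha = 0.05, max_term_size = 500,
                                  min_overlap = 0) {
  dplyr::filter(as_tibble(results),
                .data$p <= alpha,
                .data$n_term <= max_term_size,
                .data$n_overlap >= min_overlap)
}

#' Assemble a systems map of hits, partners and enriched terms
#'
#' Builds the typed graph underlying a network figure: gene nodes (hits and
#' binding partners) and term nodes (enriched terms), with gene-to-term
#' edges wherever a hit or partner is annotated to an enriched term, and
#' PPI edges wherever the interaction network links two map genes. Hits
#' annotated to no enriched term are flagged `unassigned`.
#'
#' @param hits,partners Character vectors of gene ids.
#' @param enriched Filtered enrichment tibble with `term` and `overlap_genes`
#'   list-column, or with a `genes` list-column of full term memberships.
#' @param net PPI edge tibble (`from`, `to`).
#' @return Object of class `systems_map`: list with `nodes` (tibble `id`,
#'   `type` in {hit, partner, term}, `unassigned`) and `edges` (tibble
#'   `source`, `target`, `type` in {gene_to_term, ppi}).
#' @export
build_systems_map <- function(hits, partners, enriched, net) {
  enriched <- as_tibble(enriched)
  genes <- unique(c(hits, partners))
  member_col <- if ("genes" %in% names(enriched)) "genes" else "overlap_genes"
  g2t <- purrr::map2_dfr(enriched$term, enriched[[member_col]], function(term, members) {
    found <- intersect(genes, members)
    if (length(found)) tibble(source = found, target = term, type = "gene_to_term")
    else NULL
  })
  if (nrow(g2t) == 0) {
    g2t <- tibble(source = character(), target = character(), type = character())
  }
  net <- as_tibble(net)
  ppi <- net |>
    dplyr::filter(.data$from %in% genes, .data$to %in% genes) |>
    dplyr::transmute(source = .data$from, target = .data$to, type = "ppi")
  assigned <- unique(g2t$source)
  nodes <- dplyr::bind_rows(
    tibble(id = unique(hits), type = "hit"),
    tibble(id = setdiff(unique(partners), hits), type = "partner"),
    tibble(id = unique(enriched$term), type = "term")
  )
  nodes$unassigned <- nodes$type == "hit" & !nodes$id %in% assigned
  structure(list(nodes = nodes, edges = dplyr::bind_rows(g2t, ppi)),
            class = "systems_map")
}

#' @export
print.systems_map <- function(x, ...) {
  et <- table(factor(x$edges$type, levels = c("gene_to_term", "ppi")))
  nt <- table(factor(x$nodes$type, levels = c("hit", "partner", "term")))
  cat(sprintf("<systems_map> %d hits, %d partners, %d terms; %d gene-to-term + %d ppi edges; %d unassigned hits\n",
              nt[["hit"]], nt[["partner"]], nt[["term"]],
              et[["gene_to_term"]], et[["ppi"]], sum(x$nodes$unassigned)))
  invisible(x)
}
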