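#' Annotation DAG with gene annotations
#'
#' A directed acyclic graph of annotation terms (edges point child -> parent,
#' as in the Gene Ontology) together with the gene set annotated to each
#' term. Annotation is expected to be upward-closed: a gene annotated to a
#' term is annotated to all of the term's ancestors.
#'
#' @param edges Tibble/data frame with columns `child`, `parent`.
#' @param annot Named list mapping every term id to a character vector of
#'   gene ids (may be empty for purely structural terms).
#' @return An object of class `annotation_dag` with elements `terms`,
#'   `edges` and `annot`.
#' @export
new_annotation_dag <- function(edges, annot) {
  edges <- as_tibble(edges)[, c("child", "parent")]
  terms <- union(unique(c(edges$child, edges$parent)), names(annot))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) abort("annotation graph contains a cycle")
  annot <- annot[terms]
  names(annot) <- terms
  annot <- lapply(annot, function(x) if (is.null(x)) character() else x)
  structure(list(terms = terms, edges = edges, annot = annot),
            class = "annotation_dag")
}

#' @export
print.annotation_dag <- function(x, ...) {
  cat(sprintf("<annotation_dag> %d terms, %d edges, %d annotated genes\n",
              length(x$terms), nrow(x$edges),
              length(unique(unlist(x$annot)))))
  invisible(x)
}

#' Term sizes of an annotation DAG or gene-set collection
#'
#' @param x An `annotation_dag` or a collection tibble with a `genes`
#'   list-column.
#' @return Tibble with `term` and `n_term`.
#' @export
term_sizes <- function(x) {
  if (inherits(x, "annotation_dag")) {
    tibble(term = x$terms, n_term = unname(lengths(x$annot)))
  } else {
    tibble(term = x$term, n_term = unname(lengths(x$genes)))
  }
}

#' Condense an annotation DAG to its significant terms
#'
#' Iteratively removes every non-significant term from the graph,
#' reconnecting the children of each removed term to that term's parents
#' (grandparents and beyond, as removals cascade), until only significant
#' terms remain. Removal proceeds in reverse topological order (parents
#' before their descendants), which does not change the resulting
#' reachability but makes the procedure deterministic. The output is a
#' simple graph: duplicate edges arising from diamond-shaped ancestry are
#' collapsed.
#'
#' @param dag An [new_annotation_dag()] object (or a bare child/parent edge
#'   tibble, in which case annotations are not carried).
#' @param significant Character vector of significant term ids (subset of the
#'   DAG's terms).
#' @return A tibble of condensed edges (`child`, `parent`) whose node set is
#'   exactly `significant`; attribute `"terms"` lists the significant terms
#'   (including isolated ones).
#' @export
#' @examples
#' dag <- new_annotation_dag(
#'   tibble::tibble(child = c("A", "B"), parent = c("B", "C")),
#'   list(A = "g1", B = "g1", C = "g1")
#' )
#' condense_dag(dag, c("A", "C")) # single edge A -> C
condense_dag <- function(dag, significant) {
  edges <- if (inherits(dag, "annotation_dag")) dag$edges else as_tibble(dag)
  if (inherits(dag, "annotation_dag")) {
    terms <- dag$terms
    if (!all(significant %in% terms)) {
      abort("`significant` must be a subset of the DAG's terms")
    }
  } else {
    # bare edge list: significant ids absent from the edges are isolated nodes
    terms <- Reduce(union, list(unique(c(edges$child, edges$parent)),
                                attr(dag, "terms") %||% character(),
                                significant))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) abort("annotation graph contains a cycle")
  # reverse topological order: parents first, leaves last
  ord <- names(igraph::topo_sort(g, mode = "in"))
  parents_of <- split(edges$parent, edges$child)
  children_of <- split(edges$child, edges$parent)
  get0c <- function(lst, k) lst[[k]] %||% character()
  for (v in ord) {
    if (v %in% significant) next
    ps <- setdiff(unique(get0c(parents_of, v)), v)
    cs <- setdiff(unique(get0c(children_of, v)), v)
    # reconnect children to the removed term's parents
    for (ch in cs) {
      parents_of[[ch]] <- setdiff(unique(c(get0c(parents_of, ch), ps)), c(v, ch))
    }
    for (p in ps) {
      children_of[[p]] <- setdiff(unique(c(get0c(children_of, p), cs)), c(v, p))
    }
    parents_of[[v]] <- NULL
    children_of[[v]] <- NULL
    for (p in ps) children_of[[p]] <- setdiff(children_of[[p]], v)
    for (ch in cs) parents_of[[ch]] <- setdiff(parents_of[[ch]], v)
  }
  out <- purrr::imap(parents_of, function(ps, ch) {
    if (length(ps) == 0) NULL else tibble(child = ch, parent = ps)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) out <- tibble(child = character(), parent = character())
  out <- dplyr::distinct(dplyr::arrange(out, .data$child, .data$parent))
  attr(out, "terms") <- sort(intersect(terms, significant))
  out
}
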