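# Small in-code fixtures shared across test files.

tiny_cfg <- function(seed = 1, ...) {
  sim_config(
    seed = seed, n_lines = 60, n_genes = 60, n_tissue_pairs = 3,
    n_tumor = 12, n_normal = 12, planted_set_size = 8, ppi_edges = 120,
    n_patients = 60, ...
  )
}

# A hand-built direction matrix: genes x pairs with known scores.
toy_dm <- function(scores, genes = paste0("g", seq_len(nrow(scores))),
                   pairs = paste0("p", seq_len(ncol(scores)))) {
  dm <- tibble::tibble(gene = genes, n_probes = 1L)
  for (j in seq_along(pairs)) dm[[pairs[j]]] <- scores[, j]
  class(dm) <- c("direction_matrix", class(dm))
  dm
}

# Textbook Welch t-test (two-sided p), independent of stats::t.test.
welch_p_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Exhaustive hypergeometric upper tail by enumeration of all draws.
hyper_tail_oracle <- function(universe_n, term_n, query_n, k_obs) {
  draws <- utils::combn(universe_n, query_n)
  in_term <- colSums(draws <= term_n) # wlog term = first term_n elements
  mean(in_term >= k_obs)
}

# Boolean transitive closure by repeated squaring of the adjacency matrix.
reachability_oracle <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) adj[cbind(edges$child, edges$parent)] <- TRUE
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% adj > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# Random DAG on n nodes: edges only from higher to lower topological index.
random_dag <- function(n, p_edge = 0.15) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  tibble::tibble(child = nodes[pairs[keep, 1]], parent = nodes[pairs[keep, 2]])
}
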