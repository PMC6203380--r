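#' Direction of differential expression for one probe set
#'
#' Welch two-sample t-test (unequal variances, two-sided) comparing the
#' tumor and normal arms of one probe set in one tissue pair. Returns +1
#' when the probe is significantly higher in tumor (p < `alpha` and tumor
#' mean > normal mean), -1 when significantly higher in normal, and 0
#' otherwise. Arms that are degenerate (fewer than two values, or zero
#' variance in both arms) score 0 and are flagged via a message.
#'
#' @param tumor,normal Numeric vectors of expression values.
#' @param alpha Significance level (default 0.01).
#' @return Integer in {-1, 0, +1}.
#' @export
#' @examples
#' probe_direction(rnorm(30, 10), rnorm(30, 5))
probe_direction <- function(tumor, normal, alpha = 0.01) {
  if (anyNA(tumor) || anyNA(normal) || any(!is.finite(c(tumor, normal)))) {
    abort("expression values must be finite and non-missing")
  }
  if (length(tumor) < 2 || length(normal) < 2 ||
      (stats::var(tumor) == 0 && stats::var(normal) == 0)) {
    inform("degenerate probe (too few values or zero variance); direction 0")
    return(0L)
  }
  p <- t.test(tumor, normal, var.equal = FALSE)$p.value
  if (is.na(p) || p >= alpha) return(0L)
  if (mean(tumor) > mean(normal)) 1L else -1L
}

# direction without messages, for bulk panel scoring
probe_direction_quiet <- function(tumor, normal, alpha) {
  if (length(tumor) < 2 || length(normal) < 2) return(0L)
  vt <- stats::var(tumor); vn <- stats::var(normal)
  if (vt == 0 && vn == 0) return(0L)
  p <- t.test(tumor, normal, var.equal = FALSE)$p.value
  if (is.na(p) || p >= alpha) return(0L)
  if (mean(tumor) > mean(normal)) 1L else -1L
}

#' Per-gene, per-pair direction score
#'
#' The sum of a gene's probe-set directions in one tumor/normal tissue pair
#' divided by the number of probe sets, e.g. directions (-1, -1, 0) over
#' three probe sets give -2/3. Always lies in \[-1, 1\].
#'
#' @param probe_directions Nonempty vector of values in {-1, 0, +1}.
#' @return Numeric score in \[-1, 1\].
#' @export
#' @examples
#' gene_pair_score(c(-1, -1, 0)) # -2/3
gene_pair_score <- function(probe_directions) {
  if (length(probe_directions) == 0) {
    abort("gene has no probe sets in this pair (unmeasured)")
  }
  if (!all(probe_directions %in% c(-1L, 0L, 1L))) {
    abort("probe directions must be -1, 0 or +1")
  }
  sum(probe_directions) / length(probe_directions)
}

#' Direction matrix for an expression panel
#'
#' Scores every gene with at least one probe set in every tissue pair:
#' per probe set a Welch-test direction in {-1, 0, +1}
#' ([probe_direction()]), then per gene the probe-normalized score
#' ([gene_pair_score()]). Genes with no probe set on the platform do not
#' appear (they are excluded before scoring, not scored 0).
#'
#' @param panel An `expression_panel` (see [gen_expression_panel()]), or any
#'   list with `probe_to_gene` and `pairs` of tumor/normal matrices.
#' @param alpha Per-probe significance level (default 0.01).
#' @param mode `"array"` tests values as-is; `"rnaseq"` applies log(1 + x)
#'   to both arms before testing (for RSEM-like counts).
#' @return A tibble of class `direction_matrix`: `gene`, `n_probes`, then
#'   one numeric column per tissue pair with scores in \[-1, 1\].
#' @export
direction_scores <- function(panel, alpha = 0.01, mode = c("array", "rnaseq")) {
  mode <- match.arg(mode)
  map <- as_tibble(panel$probe_to_gene)
  out <- tibble(gene = sort(unique(map$gene)))
  probes_by_gene <- split(map$probe_id, map$gene)[out$gene]
  out$n_probes <- unname(lengths(probes_by_gene))
  for (pair_id in names(panel$pairs)) {
    pr <- panel$pairs[[pair_id]]
    tum <- pr$tumor; nor <- pr$normal
    if (mode == "rnaseq") { tum <- log1p(tum); nor <- log1p(nor) }
    dirs <- vapply(seq_len(nrow(tum)), function(i) {
      probe_direction_quiet(tum[i, ], nor[i, ], alpha)
    }, integer(1))
    names(dirs) <- rownames(tum)
    per_gene <- vapply(probes_by_gene, function(pr) {
      gene_pair_score(dirs[pr])
    }, numeric(1))
    out[[pair_id]] <- unname(per_gene)
  }
  class(out) <- c("direction_matrix", class(out))
  out
}

dm_pairs <- function(dm) setdiff(names(dm), c("gene", "n_probes"))

dm_matrix <- function(dm) {
  m <- as.matrix(dm[, dm_pairs(dm), drop = FALSE])
  rownames(m) <- dm$gene
  m
}

#' Tumor-suppressor-oncogene score (TSOS) of a gene list
#'
#' The TSOS of a gene list is the sum of the per-gene, per-pair direction
#' scores over all genes and all tumor/normal tissue pairs, divided by the
#' number of genes. Positive values indicate overall higher expression in
#' tumors, negative values higher expression in normal tissue. Per-tissue
#' contributions (summed over genes only) are returned alongside; they add
#' up to the global score. Genes unmeasured in a pair contribute 0 there.
#'
#' @param genes Nonempty character vector, a subset of `dm$gene`.
#' @param dm A [direction_scores()] tibble.
#' @return List with `global` (numeric) and `per_tissue` (tibble `pair`,
#'   `tsos`).
#' @export
tsos_score <- function(genes, dm) {
  if (length(genes) == 0) abort("empty gene list")
  if (!all(genes %in% dm$gene)) {
    abort(sprintf("gene(s) absent from the direction matrix: %s",
                  toString(head(setdiff(genes, dm$gene), 5))))
  }
  m <- dm_matrix(dm)[genes, , drop = FALSE]
  m[is.na(m)] <- 0
  per <- colSums(m) / length(genes)
  list(global = sum(per), per_tissue = tibble(pair = names(per), tsos = unname(per)))
}

#' Per-gene total direction score over all tissue pairs
#'
#' The row sum of a gene's direction scores across pairs (no division by the
#' pair count); the basis for ranking top tumor-downregulated candidates.
#'
#' @param gene A single gene id present in `dm`.
#' @param dm A [direction_scores()] tibble.
#' @return Numeric total.
#' @export
gene_total_score <- function(gene, dm) {
  if (!gene %in% dm$gene) abort(sprintf("unknown gene '%s'", gene))
  row <- dm_matrix(dm)[gene, ]
  if (all(is.na(row))) {
    warn(sprintf("gene '%s' unmeasured in every pair; total 0", gene))
    return(0)
  }
  sum(row, na.rm = TRUE)
}

#' Rank top tumor-downregulated candidates
#'
#' Sorts genes ascending by total direction score (most tumor-downregulated
#' first), breaking ties lexicographically by gene id, and returns the first
#' `n_top`.
#'
#' @param dm A [direction_scores()] tibble.
#' @param n_top Number of genes to return (default 100).
#' @return Tibble with `rank`, `gene`, `total_score`.
#' @export
rank_top_candidates <- function(dm, n_top = 100) {
  if (nrow(dm) == 0) abort("empty direction matrix")
  m <- dm_matrix(dm)
  totals <- rowSums(m, na.rm = TRUE)
  ord <- order(totals, names(totals))
  if (n_top > length(totals)) {
    warn(sprintf("n_top (%d) exceeds number of genes (%d); returning all",
                 n_top, length(totals)))
    n_top <- length(totals)
  }
  idx <- head(ord, n_top)
  tibble(rank = seq_along(idx), gene = names(totals)[idx],
         total_score = unname(totals[idx]))
}

#' Resampling null distribution of the TSOS
#'
#' Draws `n_samplings` gene sets of size `set_size` uniformly without
#' replacement from `universe` (the human orthologs of all screened fly
#' genes, to avoid selection bias) and computes each set's TSOS. Sampling is
#' without replacement within a draw and independent across draws;
#' deterministic under `seed`.
#'
#' @param universe Character vector of candidate genes (subset of `dm$gene`).
#' @param set_size Genes per draw; must not exceed `length(universe)`.
#' @param n_samplings Number of draws.
#' @param dm A [direction_scores()] tibble.
#' @param seed Integer seed.
#' @return Numeric vector of `n_samplings` TSOS values.
#' @export
sample_null_tsos <- function(universe, set_size, n_samplings, dm, seed) {
  if (set_size > length(universe)) {
    abort("`set_size` cannot exceed the universe size")
  }
  if (!all(universe %in% dm$gene)) {
    abort("universe must be a subset of the direction matrix's genes")
  }
  m <- dm_matrix(dm)[universe, , drop = FALSE]
  m[is.na(m)] <- 0
  totals <- rowSums(m)
  with_stream(seed, "null_tsos", {
    vapply(seq_len(n_samplings), function(i) {
      sum(totals[sample.int(length(totals), set_size)]) / set_size
    }, numeric(1))
  })
}

#' Empirical p-value against a resampling null
#'
#' Lower tail: the fraction of null samples strictly below the observed
#' value (so 7 of 1,000,000 below gives 7e-6); upper tail: strictly above.
#' With `add_one = TRUE` the (k + 1)/(N + 1) variant is used instead.
#'
#' @param observed Observed statistic.
#' @param null_samples Nonempty numeric vector of null draws.
#' @param tail `"lower"` (default) or `"upper"`.
#' @param add_one Use the (k + 1)/(N + 1) convention (default FALSE).
#' @return Empirical p-value in \[0, 1\].
#' @export
#' @examples
#' empirical_pvalue(0, c(-1, 1, 2, 3)) # 0.25
empirical_pvalue <- function(observed, null_samples, tail = c("lower", "upper"),
                             add_one = FALSE) {
  tail <- match.arg(tail)
  if (length(null_samples) == 0) abort("null sample vector is empty")
  k <- if (tail == "lower") sum(null_samples < observed) else sum(null_samples > observed)
  n <- length(null_samples)
  if (add_one) (k + 1) / (n + 1) else k / n
}

#' TSOS significance test for a gene list
#'
#' Computes the observed global and per-tissue TSOS of `genes`, a resampling
#' null of identically sized random sets from `universe`, and the empirical
#' p-value ([empirical_pvalue()]).
#'
#' @inheritParams sample_null_tsos
#' @param genes Query gene list (subset of `dm$gene`).
#' @param tail Tail for the empirical p (default `"lower"`: is the list more
#'   tumor-downregulated than random sets?).
#' @param add_one Passed to [empirical_pvalue()].
#' @return Object of class `tsos_result` with fields `observed`,
#'   `per_tissue`, `null_samples`, `p_empirical`, `n_samplings`, `set_size`,
#'   `seed`, `tail`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
tsos_test <- function(genes, dm, universe, n_samplings = 10000, seed = 1L,
                      tail = c("lower", "upper"), add_one = FALSE) {
  tail <- match.arg(tail)
  obs <- tsos_score(genes, dm)
  null <- sample_null_tsos(universe, length(genes), n_samplings, dm, seed)
  p <- empirical_pvalue(obs$global, null, tail, add_one)
  structure(
    list(observed = obs$global, per_tissue = obs$per_tissue,
         null_samples = null, p_empirical = p,
         n_samplings = n_samplings, set_size = length(genes),
         seed = seed, tail = tail),
    class = "tsos_result"
  )
}

#' @export
print.tsos_result <- function(x, ...) {
  p_show <- if (x$p_empirical == 0) sprintf("< %g", 1 / x$n_samplings) else format(x$p_empirical)
  cat(sprintf("<tsos_result> TSOS = %.4f over %d genes; empirical p (%s tail) = %s [%d samplings]\n",
              x$observed, x$set_size, x$tail, p_show, x$n_samplings))
  invisible(x)
}

#' @rdname tsos_test
#' @param x A `tsos_result`.
#' @param ... Unused.
#' @method tidy tsos_result
#' @export
tidy.tsos_result <- function(x, ...) x$per_tissue

#' @rdname tsos_test
#' @method glance tsos_result
#' @export
glance.tsos_result <- function(x, ...) {
  tibble(observed = x$observed, p_empirical = x$p_empirical,
         null_mean = mean(x$null_samples), null_sd = sd(x$null_samples),
         n_samplings = x$n_samplings, set_size = x$set_size)
}

#' @rdname tsos_test
#' @param object A `tsos_result`.
#' @method autoplot tsos_result
#' @export
autoplot.tsos_result <- function(object, ...) {
  df <- tibble(tsos = object$null_samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tsos)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "TSOS of random gene sets", y = "count",
                  title = sprintf("Observed TSOS %.3f vs %d random sets (p = %g)",
                                  object$observed, object$n_samplings,
                                  object$p_empirical))
}
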