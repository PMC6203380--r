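#' Filter a cohort to samples usable for survival + mutation analysis
#'
#' Retains samples that carry both a mutation call (present in the variant
#' report) and clinical overall-survival information; the retained count and
#' percentage are reported via a message.
#'
#' @param cohort A `patient_cohort` (see [gen_patient_cohort()]).
#' @return The filtered `patient_cohort` (expression/methylation columns
#'   subset to the retained samples).
#' @export
filter_cohort <- function(cohort) {
  keep <- cohort$samples$has_mutation_call & cohort$samples$has_survival
  n <- nrow(cohort$samples)
  if (!any(keep)) abort("no samples with both survival and mutation records")
  # percentage truncated, not rounded: 132/177 reports as 74%
  inform(sprintf("cohort filter: retained %d/%d samples (%d%%)",
                 sum(keep), n, floor(100 * sum(keep) / n)))
  samples <- cohort$samples[keep, ]
  new_patient_cohort(
    samples,
    cohort$expr[, samples$sample, drop = FALSE],
    if (!is.null(cohort$beta)) cohort$beta[, samples$sample, drop = FALSE],
    cohort$signature
  )
}

#' Preprocess RNA-seq expression for clustering
#'
#' Applies log(1 + x) elementwise, then centers and scales each SAMPLE
#' (column) to mean 0 and SD 1 across genes, the preprocessing used before
#' k-means stratification of RSEM-normalized data. Samples with zero
#' variance across genes are set to all zeros with a warning.
#'
#' @param expr Non-negative gene-by-sample matrix.
#' @return Matrix of the same shape, per-sample standardized.
#' @export
preprocess_expression <- function(expr) {
  if (any(expr < 0, na.rm = TRUE)) abort("expression values must be >= 0")
  lg <- log1p(expr)
  scale_sample <- function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) {
      warn("sample with zero variance across genes; scaled to zeros")
      rep(0, length(x))
    } else {
      (x - mean(x)) / s
    }
  }
  out <- apply(lg, 2, scale_sample)
  dimnames(out) <- dimnames(expr)
  out
}

#' Aggregate probe-level methylation to gene level
#'
#' Per gene and sample, the arithmetic mean of the gene's probe beta values,
#' excluding NA probes; a gene whose probes are all NA in a sample yields NA
#' there.
#'
#' @param probe_betas Probe-by-sample matrix of beta values in \[0, 1\].
#' @param probe_to_gene Data frame with `probe_id`, `gene`.
#' @return Gene-by-sample matrix of mean beta values.
#' @export
aggregate_methylation <- function(probe_betas, probe_to_gene) {
  rng <- range(probe_betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) abort("beta values must lie in [0, 1]")
  map <- as_tibble(probe_to_gene)
  if (!all(rownames(probe_betas) %in% map$probe_id)) {
    abort("every probe row must appear in `probe_to_gene`")
  }
  gene_of <- setNames(map$gene, map$probe_id)[rownames(probe_betas)]
  genes <- sort(unique(gene_of))
  out <- do.call(rbind, lapply(genes, function(g) {
    block <- probe_betas[gene_of == g, , drop = FALSE]
    colMeans(block, na.rm = TRUE)
  }))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- genes
  out
}

#' Stratify samples into low/high groups by repeated k-means
#'
#' Runs Lloyd's k-means `reps` times on the sample profiles (samples as
#' observations, signature genes as features), each repetition initialized
#' from `k` distinct samples drawn uniformly. Within each repetition the
#' cluster whose members have the larger average signature value is aligned
#' to "high", resolving the label-switching ambiguity; each sample's final
#' label is its majority label over repetitions. Because per-sample scaling
#' forces every sample mean to zero, the averages used for alignment come
#' from `align_values` (the UNSCALED per-sample mean signature value), not
#' from the clustered matrix. Majority ties are broken by mean distance to
#' the per-repetition "high" centroids (nearer to high wins) and reported.
#'
#' @param mat Gene-by-sample matrix already restricted to the signature and
#'   preprocessed (see [preprocess_expression()]); for methylation, the
#'   per-sample scaled beta matrix.
#' @param k Number of clusters (default 2; labels are only low/high for
#'   k = 2).
#' @param reps Repetitions (default 100).
#' @param seed Integer seed.
#' @param iter_max Lloyd iteration cap (default 300).
#' @param align_values Numeric vector (one value per sample, in column order
#'   of `mat`) of unscaled mean signature values used to label the clusters;
#'   defaults to the column means of `mat`.
#' @return Tibble with `sample`, `label` ("low"/"high"), `n_high` (count of
#'   "high" assignments over repetitions), `tie` (logical).
#' @export
stratify_repeated_kmeans <- function(mat, k = 2, reps = 100, seed = 1L,
                                     iter_max = 300, align_values = colMeans(mat)) {
  n <- ncol(mat)
  if (k > n) abort("more clusters than samples")
  if (length(align_values) != n) abort("`align_values` must have one value per sample")
  x <- t(mat) # samples as rows
  with_stream(seed, "kmeans", {
    n_high <- integer(n)
    dist_high <- numeric(n); dist_low <- numeric(n)
    for (r in seq_len(reps)) {
      centers <- x[sample.int(n, k), , drop = FALSE]
      km <- suppressWarnings(
        kmeans(x, centers = centers, iter.max = iter_max, algorithm = "Lloyd")
      )
      cl_means <- vapply(seq_len(k), function(j) mean(align_values[km$cluster == j]),
                         numeric(1))
      high_cl <- which.max(cl_means)
      n_high <- n_high + (km$cluster == high_cl)
      d <- sqrt(rowSums((x - km$centers[rep(high_cl, n), , drop = FALSE])^2))
      dist_high <- dist_high + d
      low_cl <- which.min(cl_means)
      dist_low <- dist_low + sqrt(rowSums((x - km$centers[rep(low_cl, n), , drop = FALSE])^2))
    }
    tie <- n_high * 2L == reps
    label <- ifelse(n_high * 2L > reps, "high", "low")
    label[tie] <- ifelse(dist_high[tie] <= dist_low[tie], "high", "low")
    if (any(tie)) {
      inform(sprintf("%d sample(s) tied 50/50 over repetitions; assigned by centroid distance",
                     sum(tie)))
    }
    tibble(sample = rownames(x), label = unname(label),
           n_high = unname(as.integer(n_high)), tie = unname(tie))
  })
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square test (1 df) with the usual
#' aggregated-risk-set handling of tied event times; Kaplan-Meier fits per
#' group are attached for plotting.
#'
#' @param labels Character/factor vector of group labels (two groups).
#' @param time Survival/censoring times (>= 0).
#' @param event 1 = death observed, 0 = right-censored.
#' @return List with `chisq`, `df`, `p`, `n` (per-group sizes), and `fit`
#'   (a [survival::survfit] object).
#' @export
logrank_test <- function(labels, time, event) {
  g <- factor(labels)
  if (nlevels(g) != 2) abort("log-rank comparison requires exactly two groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- length(sd_$n) - 1
  list(
    chisq = unname(sd_$chisq), df = df,
    p = pchisq(sd_$chisq, df, lower.tail = FALSE),
    n = setNames(as.numeric(sd_$n), levels(g)),
    fit = survival::survfit(survival::Surv(time, event) ~ g)
  )
}

#' KRAS-G12 enrichment in the low group
#'
#' Aggregates the "other" and "none" mutation categories, builds the 2x2
#' table (low/high x G12/not-G12), and runs a one-sided Fisher exact test
#' for OVER-representation of G12 carriers in one group — by default the
#' low group (for expression stratification, where silenced tumor
#' suppressors mark the G12-enriched stratum); pass `group = "high"` for
#' methylation stratification, where hypermethylation marks that stratum.
#'
#' @param labels "low"/"high" group labels.
#' @param mutation_category Per-sample category in {"G12", "other", "none"}.
#' @param group Group tested for G12 over-representation (default "low").
#' @return List with `p`, `odds_ratio`, `contingency` (2x2 matrix, rows
#'   low/high, columns G12/not_G12), `group`.
#' @export
mutation_enrichment <- function(labels, mutation_category, group = c("low", "high")) {
  group <- match.arg(group)
  if (!all(labels %in% c("low", "high"))) abort("labels must be 'low'/'high'")
  if (!all(mutation_category %in% c("G12", "other", "none"))) {
    abort("mutation categories must be G12/other/none")
  }
  g12 <- mutation_category == "G12"
  tab <- matrix(
    c(sum(labels == "low" & g12), sum(labels == "low" & !g12),
      sum(labels == "high" & g12), sum(labels == "high" & !g12)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("low", "high"), c("G12", "not_G12"))
  )
  test_tab <- if (group == "low") tab else tab[c("high", "low"), ]
  ft <- fisher.test(test_tab, alternative = "greater")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), contingency = tab,
       group = group)
}

#' Gene-signature survival stratification of a cohort
#'
#' The full stratification chain for one cohort and one gene signature:
#' filter to samples with survival + mutation records, restrict the data to
#' the signature genes, preprocess (log(1 + x) and per-sample scaling for
#' expression; per-sample scaling only for methylation beta values), label
#' samples low/high by repeated k-means ([stratify_repeated_kmeans()]), then
#' compare survival between groups (log-rank) and test KRAS-G12 enrichment
#' in the low group (one-sided Fisher).
#'
#' @param cohort A `patient_cohort`.
#' @param signature Gene ids to stratify on; defaults to the cohort's
#'   signature. Genes missing from the data are dropped with a message.
#' @param mode `"rnaseq"` uses the expression matrix, `"methylation"` the
#'   beta matrix.
#' @param reps,seed,k Passed to [stratify_repeated_kmeans()].
#' @param g12_group Group tested for G12 over-representation; default
#'   `"low"` for expression and `"high"` for methylation (where the
#'   silenced, G12-enriched stratum is hypermethylated).
#' @param scale_first If TRUE, per-sample scaling is computed on all genes
#'   before restriction to the signature (default FALSE: restrict first).
#' @return Object of class `stratification_result`: `labels` tibble,
#'   `p_logrank`, `chisq`, `fisher_p_g12`, `odds_ratio`, `contingency`,
#'   `fit` (Kaplan-Meier), `n` per group, `mode`, `signature`. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
stratify_survival <- function(cohort, signature = cohort$signature,
                              mode = c("rnaseq", "methylation"),
                              reps = 100, seed = 1L, k = 2,
                              scale_first = FALSE, g12_group = NULL) {
  mode <- match.arg(mode)
  g12_group <- g12_group %||% if (mode == "rnaseq") "low" else "high"
  cohort <- filter_cohort(cohort)
  dat <- if (mode == "rnaseq") cohort$expr else cohort$beta
  if (is.null(dat)) abort("cohort has no methylation data")
  missing_genes <- setdiff(signature, rownames(dat))
  if (length(missing_genes)) {
    inform(sprintf("%d signature gene(s) not in the cohort data; dropped",
                   length(missing_genes)))
    signature <- intersect(signature, rownames(dat))
  }
  if (length(signature) == 0) abort("no signature genes present in the cohort")
  prep <- function(m) {
    if (mode == "rnaseq") {
      preprocess_expression(m)
    } else {
      # betas are already bounded; per-sample scaling only
      preprocess_scaled_beta(m)
    }
  }
  mat <- if (scale_first) {
    prep(dat)[signature, , drop = FALSE]
  } else {
    prep(dat[signature, , drop = FALSE])
  }
  raw <- dat[signature, , drop = FALSE]
  if (mode == "rnaseq") raw <- log1p(raw)
  labels <- stratify_repeated_kmeans(mat, k = k, reps = reps, seed = seed,
                                     align_values = colMeans(raw, na.rm = TRUE))
  idx <- match(labels$sample, cohort$samples$sample)
  lr <- logrank_test(labels$label, cohort$samples$time[idx], cohort$samples$event[idx])
  me <- mutation_enrichment(labels$label, cohort$samples$mutation_category[idx],
                            group = g12_group)
  structure(
    list(labels = labels, p_logrank = lr$p, chisq = lr$chisq,
         fisher_p_g12 = me$p, odds_ratio = me$odds_ratio,
         contingency = me$contingency, g12_group = me$group,
         fit = lr$fit, n = lr$n,
         time = cohort$samples$time[idx], event = cohort$samples$event[idx],
         mode = mode, signature = signature),
    class = "stratification_result"
  )
}

preprocess_scaled_beta <- function(beta) {
  out <- apply(beta, 2, function(x) {
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x, na.rm = TRUE)) / s
  })
  dimnames(out) <- dimnames(beta)
  out
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("<stratification_result> (%s) low n = %d, high n = %d\n",
              x$mode, sum(x$labels$label == "low"), sum(x$labels$label == "high")))
  cat(sprintf("  log-rank p = %.4g (chisq %.2f); G12 enrichment in %s: Fisher p = %.4g\n",
              x$p_logrank, x$chisq, x$g12_group, x$fisher_p_g12))
  print(x$contingency)
  invisible(x)
}

#' @rdname stratify_survival
#' @param x A `stratification_result`.
#' @param ... Unused.
#' @method tidy stratification_result
#' @export
tidy.stratification_result <- function(x, ...) x$labels

#' @rdname stratify_survival
#' @method glance stratification_result
#' @export
glance.stratification_result <- function(x, ...) {
  tibble(p_logrank = x$p_logrank, chisq = x$chisq,
         fisher_p_g12 = x$fisher_p_g12, odds_ratio = x$odds_ratio,
         n_low = sum(x$labels$label == "low"),
         n_high = sum(x$labels$label == "high"),
         mode = x$mode)
}

#' @rdname stratify_survival
#' @param object A `stratification_result`.
#' @method autoplot stratification_result
#' @export
autoplot.stratification_result <- function(object, ...) {
  fit <- object$fit
  km <- tibble(
    time = fit$time, surv = fit$surv,
    group = rep(sub("^g=", "", names(fit$strata)), fit$strata)
  )
  km <- dplyr::bind_rows(
    tibble(time = 0, surv = 1, group = unique(km$group)), km
  )
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(low = "black", high = "red")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival fraction",
                  colour = sprintf("%s group", object$mode),
                  title = sprintf("log-rank p = %.3g; G12 Fisher p = %.3g",
                                  object$p_logrank, object$fisher_p_g12))
}
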