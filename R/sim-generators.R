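#' Generate a synthetic RNAi screen table
#'
#' Emulates a fly tumor screen read out as percent larval progeny: each RNAi
#' line is crossed once and the fraction of progeny still larval at day 8 and
#' day 12 is recorded. Non-hit lines pupariate like the oncogene-only control
#' (`control_mean` +/- `control_sd`, clamped to \[0, 100\]); planted hit lines
#' have their mean pupariation reduced by `pupariation_effect` percentage
#' points, and a `invasion_rate` subset of them additionally shows mouth-hook
#' invasion or ectopic GFP foci.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with one row per line: `transformant_id`, `construct_id`,
#'   `fly_gene`, `s19_score`, `can_repeats`, `off_targets`, `planted_hit`
#'   (ground truth), `pct_larvae_day8`, `pct_larvae_day12`,
#'   `mouthhook_invasion`, `ectopic_foci`. The control summary is attached as
#'   attribute `"control_stats"` (see [control_stats()]).
#' @export
#' @examples
#' scr <- gen_screen_table(sim_config(seed = 2, n_lines = 20))
#' control_stats(scr)
gen_screen_table <- function(cfg) {
  validate_sim_config(cfg)
  with_stream(cfg$seed, "screen", {
    n <- cfg$n_lines
    planted <- runif(n) < cfg$hit_fraction
    mu <- ifelse(planted, cfg$control_mean - cfg$pupariation_effect, cfg$control_mean)
    pup8 <- clamp01(rnorm(n, mu, cfg$control_sd), 0, 100)
    larvae8 <- 100 - pup8
    # by day 12 most stragglers have pupariated or died; hits retain arrest
    larvae12 <- clamp01(larvae8 * runif(n, 0.4, 0.9), 0, 100)
    inv <- planted & runif(n) < cfg$invasion_rate
    which_flag <- runif(n)
    s19 <- round(ifelse(runif(n) < 0.88, runif(n, 0.8, 1), runif(n, 0.3, 0.8)), 2)
    tbl <- tibble(
      transformant_id = sprintf("TF%05d", seq_len(n)),
      construct_id = sprintf("C%05d", seq_len(n)),
      fly_gene = sprintf("FG%05d", seq_len(n)),
      s19_score = s19,
      can_repeats = rpois(n, 2),
      off_targets = rpois(n, 0.5),
      planted_hit = planted,
      pct_larvae_day8 = larvae8,
      pct_larvae_day12 = larvae12,
      mouthhook_invasion = inv & which_flag < 0.7,
      ectopic_foci = inv & which_flag >= 0.4
    )
    attr(tbl, "control_stats") <- new_control_stats(cfg$control_mean, cfg$control_sd)
    tbl
  })
}

#' Control pupariation statistics
#'
#' `new_control_stats()` builds the control summary (mean and SD of percent
#' pupariation) used by the Z-score; `control_stats()` retrieves the summary
#' attached to a generated screen table.
#'
#' @param mean_pupariation,sd_pupariation Control mean and SD, in percent.
#' @param x A screen table produced by [gen_screen_table()].
#' @return A one-row tibble with columns `mean_pupariation`, `sd_pupariation`.
#' @export
new_control_stats <- function(mean_pupariation, sd_pupariation) {
  if (!is.numeric(sd_pupariation) || sd_pupariation <= 0) {
    abort("control SD must be positive")
  }
  tibble(mean_pupariation = mean_pupariation, sd_pupariation = sd_pupariation)
}

#' @rdname new_control_stats
#' @export
control_stats <- function(x) {
  cs <- attr(x, "control_stats")
  if (is.null(cs)) abort("no control_stats attribute on this table")
  cs
}

clamp01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic paired tumor/normal expression panel
#'
#' Emulates a probe-level microarray compendium: every gene carries one or
#' more probe sets, and every tumor/normal tissue pair contributes a tumor
#' arm and a normal arm of samples per probe set. Two kinds of tumor/normal
#' difference are generated. Every gene receives an incoherent background
#' effect per tissue pair (Gaussian with SD `background_effect_sd`, random
#' sign, shared by the gene's probe sets), emulating the widespread
#' differential expression of real tumor/normal compendia; these effects
#' carry no gene-set structure, so gene-set statistics remain null. On top,
#' genes in `planted_genes` have their tumor mean coherently reduced by
#' `planted_effect` residual SDs (tumor-downregulation) in an
#' `affected_pair_fraction` share of pairs.
#'
#' @param cfg A [sim_config()].
#' @param planted_genes Character vector of gene ids to plant as
#'   tumor-downregulated; must be a subset of the panel's gene universe.
#' @return An object of class `expression_panel`: a list with `genes` (the
#'   universe), `probe_to_gene` (tibble: `probe_id`, `gene`), and `pairs`, a
#'   named list where each element holds `tumor` and `normal` probe-by-sample
#'   matrices for one tissue pair.
#' @export
gen_expression_panel <- function(cfg, planted_genes = character()) {
  validate_sim_config(cfg)
  genes <- panel_gene_universe(cfg)
  if (!all(planted_genes %in% genes)) {
    abort("`planted_genes` must be a subset of the panel gene universe")
  }
  with_stream(cfg$seed, "panel", {
    ks <- as.integer(names(cfg$probe_multiplicity))
    mult <- sample(ks, cfg$n_genes, replace = TRUE,
                   prob = cfg$probe_multiplicity / sum(cfg$probe_multiplicity))
    probe_to_gene <- tibble(
      gene = rep(genes, mult),
      k = unlist(lapply(mult, seq_len))
    )
    probe_to_gene$probe_id <- sprintf("%s_p%d", probe_to_gene$gene, probe_to_gene$k)
    probe_to_gene <- probe_to_gene[, c("probe_id", "gene")]
    n_probe <- nrow(probe_to_gene)
    base_mu <- rnorm(n_probe, 8, 1)
    is_planted_probe <- probe_to_gene$gene %in% planted_genes
    pair_ids <- sprintf("pair%02d", seq_len(cfg$n_tissue_pairs))
    affected <- runif(cfg$n_tissue_pairs) < cfg$affected_pair_fraction
    gene_idx <- match(probe_to_gene$gene, genes)
    pairs <- lapply(seq_len(cfg$n_tissue_pairs), function(i) {
      shift <- if (affected[i]) cfg$planted_effect else 0
      bg <- rnorm(cfg$n_genes, 0, cfg$background_effect_sd)
      tum_mu <- base_mu + bg[gene_idx] - shift * is_planted_probe
      tumor <- matrix(rnorm(n_probe * cfg$n_tumor, tum_mu, 1),
                      nrow = n_probe,
                      dimnames = list(probe_to_gene$probe_id,
                                      sprintf("%s_T%02d", pair_ids[i], seq_len(cfg$n_tumor))))
      normal <- matrix(rnorm(n_probe * cfg$n_normal, base_mu, 1),
                       nrow = n_probe,
                       dimnames = list(probe_to_gene$probe_id,
                                       sprintf("%s_N%02d", pair_ids[i], seq_len(cfg$n_normal))))
      list(tumor = tumor, normal = normal)
    })
    names(pairs) <- pair_ids
    structure(
      list(genes = genes, probe_to_gene = probe_to_gene, pairs = pairs,
           planted_genes = planted_genes),
      class = "expression_panel"
    )
  })
}

#' Gene universe of the synthetic expression platform
#' @param cfg A [sim_config()].
#' @return Character vector of human gene ids measurable on the platform.
#' @export
panel_gene_universe <- function(cfg) sprintf("HG%05d", seq_len(cfg$n_genes))

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d genes, %d probe sets, %d tissue pairs\n",
              length(x$genes), nrow(x$probe_to_gene), length(x$pairs)))
  invisible(x)
}

#' Generate a synthetic ortholog table
#'
#' Emulates a precomputed one-to-one / one-to-many orthology table: each fly
#' gene has exactly one human seed ortholog (no human gene seeds two fly
#' genes), a `one_to_many_rate` fraction additionally carries 1-3 human
#' inparalogs, and mouse columns are generated the same way (they are carried
#' through the pipeline but unused by it).
#'
#' Fly gene `FGk` seeds human gene `HGk`; only the first `n_genes` of these
#' are measurable on the synthetic expression platform, so screens larger
#' than the platform naturally exercise the platform-restriction step.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `fly_gene`, `human_seed`, `human_inparalogs`,
#'   `mouse_seed`, `mouse_inparalogs`; the inparalog columns are list-columns
#'   of character vectors.
#' @export
gen_ortholog_table <- function(cfg) {
  validate_sim_config(cfg)
  with_stream(cfg$seed, "orthologs", {
    n <- cfg$n_lines
    many <- runif(n) < cfg$one_to_many_rate
    n_inp <- ifelse(many, sample(1:3, n, replace = TRUE), 0L)
    inp_ids <- sprintf("HGI%05d", seq_len(sum(n_inp)))
    splits <- rep(seq_len(n), n_inp)
    tibble(
      fly_gene = sprintf("FG%05d", seq_len(n)),
      human_seed = purrr::map(seq_len(n), ~ sprintf("HG%05d", .x)),
      human_inparalogs = unname(split(inp_ids, factor(splits, levels = seq_len(n)))),
      mouse_seed = purrr::map(seq_len(n), ~ sprintf("MG%05d", .x)),
      mouse_inparalogs = purrr::map(n_inp, ~ if (.x > 0) sprintf("MGI%05d", seq_len(.x)) else character())
    )
  })
}

#' Generate a synthetic gene-set collection and annotation DAG
#'
#' Builds a rooted annotation DAG (a tree of depth `dag_depth` and branching
#' `dag_branching`, plus random cross-links giving some terms a second
#' parent) whose leaves annotate random gene sets drawn from the platform
#' universe; annotation is upward-closed, so every term annotates the union
#' of its descendants' genes, and the root annotates every annotated gene.
#' With the default universe the root and the shallow terms exceed 500 genes,
#' exercising the term-size filter. The same term/gene memberships are also
#' returned as a flat collection suitable for GMT export.
#'
#' @param cfg A [sim_config()].
#' @return A list with `collection` (tibble: `term`, `description`, `genes`
#'   list-column) and `dag` (class `annotation_dag`: `edges` tibble
#'   child->parent, plus `annot`, a named list term -> gene ids).
#' @export
gen_gene_sets_and_dag <- function(cfg) {
  validate_sim_config(cfg)
  genes <- panel_gene_universe(cfg)
  with_stream(cfg$seed, "genesets", {
    depth <- cfg$dag_depth
    b <- cfg$dag_branching
    levels <- vector("list", depth + 1)
    levels[[1]] <- "T0_1"
    edges <- list()
    for (d in seq_len(depth)) {
      parents <- levels[[d]]
      kids <- sprintf("T%d_%d", d, seq_len(length(parents) * b))
      levels[[d + 1]] <- kids
      edges[[d]] <- tibble(child = kids, parent = rep(parents, each = b))
    }
    edges <- dplyr::bind_rows(edges)
    # cross-links: some deeper terms gain a second parent one level up
    for (d in if (depth >= 2) 3:(depth + 1) else integer()) {
      for (node in levels[[d]]) {
        if (runif(1) < 0.2) {
          cand <- setdiff(levels[[d - 1]], edges$parent[edges$child == node])
          if (length(cand)) {
            edges <- dplyr::bind_rows(edges, tibble(child = node, parent = sample(cand, 1)))
          }
        }
      }
    }
    leaves <- levels[[depth + 1]]
    direct <- lapply(seq_along(leaves), function(i) {
      size <- max(2L, rpois(1, max(3, 2 * cfg$n_genes / length(leaves))))
      sample(genes, min(size, cfg$n_genes))
    })
    names(direct) <- leaves
    annot <- propagate_annotations(edges, direct)
    dag <- new_annotation_dag(edges, annot)
    collection <- tibble(
      term = names(annot),
      description = sprintf("synthetic term %s", names(annot)),
      genes = unname(annot)
    )
    list(collection = collection, dag = dag)
  })
}

# Upward-close direct annotations along child -> parent edges.
propagate_annotations <- function(edges, direct) {
  terms <- union(unique(c(edges$child, edges$parent)), names(direct))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  ord <- igraph::topo_sort(g, mode = "out") # children before parents
  annot <- setNames(vector("list", length(terms)), terms)
  for (t in terms) annot[[t]] <- direct[[t]] %||% character()
  for (v in names(ord)) {
    for (p in edges$parent[edges$child == v]) {
      annot[[p]] <- union(annot[[p]], annot[[v]])
    }
  }
  lapply(annot, function(g) sort(unique(g)))
}

#' Generate a synthetic protein-protein interaction network
#'
#' Grows an undirected simple graph over the platform gene universe by
#' degree-biased attachment: each new edge joins a uniformly chosen gene to a
#' gene chosen with probability proportional to (degree + 1), giving the
#' right-skewed degree distribution typical of curated interactomes.
#' Self-loops and duplicate edges are rejected.
#'
#' @param cfg A [sim_config()].
#' @param universe Optional character vector of node ids; defaults to the
#'   platform universe.
#' @return A tibble of undirected edges (`from`, `to`) with attribute
#'   `"universe"`.
#' @export
gen_ppi_network <- function(cfg, universe = panel_gene_universe(cfg)) {
  validate_sim_config(cfg)
  with_stream(cfg$seed, "ppi", {
    n <- length(universe)
    m <- cfg$ppi_edges
    deg <- rep(0, n)
    from <- integer(m); to <- integer(m)
    seen <- new.env(hash = TRUE)
    i <- 0L; tries <- 0L
    while (i < m && tries < 50L * m + 100L) {
      tries <- tries + 1L
      a <- sample.int(n, 1L)
      b <- sample.int(n, 1L, prob = deg + 1)
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      i <- i + 1L
      from[i] <- min(a, b); to[i] <- max(a, b)
      deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
    }
    edges <- tibble(from = universe[from[seq_len(i)]], to = universe[to[seq_len(i)]])
    attr(edges, "universe") <- universe
    edges
  })
}

#' Generate a synthetic patient cohort
#'
#' Emulates a tumor cohort carrying RNA-seq (RSEM-like, non-negative),
#' gene-level methylation beta values, overall survival, and a KRAS mutation
#' category. A latent binary group drives the planted structure: the "low"
#' group has signature-gene expression shifted down by `expr_shift_sd` SDs on
#' the log scale, hazard multiplied by `hazard_ratio_low_vs_high`, G12 odds
#' multiplied by `g12_odds_low_vs_high`, and methylation beta values
#' anti-correlated with expression. A `missing_rate` share of samples lacks
#' survival and, independently, mutation records, exercising the cohort
#' filter.
#'
#' @param cfg A [sim_config()].
#' @param signature Nonempty character vector of signature gene ids.
#' @param n_background Number of non-signature genes also measured.
#' @return An object of class `patient_cohort`: `samples` (tibble with
#'   `sample`, `latent_group`, `time`, `event`, `mutation_category`,
#'   `has_survival`, `has_mutation_call`) plus gene-by-sample matrices `expr`
#'   and `beta`, and the `signature`.
#' @export
gen_patient_cohort <- function(cfg, signature, n_background = 20L) {
  validate_sim_config(cfg)
  if (length(signature) == 0) abort("`signature` must be nonempty")
  with_stream(cfg$seed, "cohort", {
    n <- cfg$n_patients
    low <- runif(n) < 0.5
    sample_ids <- sprintf("S%04d", seq_len(n))
    genes <- c(signature, if (n_background > 0) sprintf("BGG%04d", seq_len(n_background)))
    mu <- rnorm(length(genes), 6, 1)
    # per-gene effect sizes vary around the configured mean shift (real
    # signatures are not uniformly depressed; a uniform shift would be
    # removed entirely by per-sample centering)
    gene_shift <- cfg$expr_shift_sd * runif(sum(genes %in% signature), 0.25, 1.75)
    shift <- matrix(0, length(genes), n)
    shift[genes %in% signature, low] <- gene_shift
    log_expr <- matrix(rnorm(length(genes) * n, mu, 1), length(genes), n) - shift
    expr <- exp(log_expr)
    dimnames(expr) <- list(genes, sample_ids)
    # methylation anti-correlated with (centered) log expression
    centered <- log_expr - rowMeans(log_expr)
    beta <- plogis(qlogis(0.4) - centered + matrix(rnorm(length(genes) * n, 0, 0.5),
                                                   length(genes), n))
    dimnames(beta) <- list(genes, sample_ids)
    base_rate <- 1 / 500 # median ~ 350 days in the high group
    time <- rexp(n, base_rate * ifelse(low, cfg$hazard_ratio_low_vs_high, 1))
    event <- rep(1L, n)
    cens <- runif(n) < cfg$censoring_rate
    time[cens] <- runif(sum(cens), 0, time[cens])
    event[cens] <- 0L
    p_g12 <- plogis(qlogis(cfg$g12_base_rate) + log(cfg$g12_odds_low_vs_high) * low)
    is_g12 <- runif(n) < p_g12
    mutation_category <- ifelse(is_g12, "G12", ifelse(runif(n) < 0.4, "other", "none"))
    has_survival <- runif(n) >= cfg$missing_rate
    has_mutation_call <- runif(n) >= cfg$missing_rate
    time[!has_survival] <- NA_real_
    event[!has_survival] <- NA_integer_
    mutation_category[!has_mutation_call] <- NA_character_
    samples <- tibble(
      sample = sample_ids, latent_group = ifelse(low, "low", "high"),
      time = round(time, 1), event = event,
      mutation_category = mutation_category,
      has_survival = has_survival, has_mutation_call = has_mutation_call
    )
    new_patient_cohort(samples, expr, beta, signature)
  })
}

#' Construct a patient cohort object
#'
#' @param samples Tibble with at least `sample`, `time`, `event`,
#'   `mutation_category`, `has_survival`, `has_mutation_call`.
#' @param expr,beta Gene-by-sample matrices (columns named by sample);
#'   `beta` values must lie in \[0, 1\] (NA allowed).
#' @param signature Character vector of signature gene ids.
#' @return An object of class `patient_cohort`.
#' @export
new_patient_cohort <- function(samples, expr, beta = NULL, signature = character()) {
  stopifnot(is.data.frame(samples), is.matrix(expr))
  if (!all(samples$sample %in% colnames(expr))) {
    abort("every sample must have an expression column")
  }
  if (!is.null(beta)) {
    rng <- range(beta, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) abort("beta values must lie in [0, 1]")
  }
  ok_time <- samples$time[!is.na(samples$time)]
  if (any(ok_time < 0)) abort("survival times must be >= 0")
  structure(list(samples = as_tibble(samples), expr = expr, beta = beta,
                 signature = signature),
            class = "patient_cohort")
}

#' @export
print.patient_cohort <- function(x, ...) {
  cat(sprintf("<patient_cohort> %d samples, %d genes (%d signature)%s\n",
              nrow(x$samples), nrow(x$expr), length(x$signature),
              if (is.null(x$beta)) "" else ", with methylation"))
  invisible(x)
}
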