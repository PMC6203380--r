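#' Run the full synthetic screen-to-survival pipeline
#'
#' Orchestrates the whole chain on synthetic inputs generated from one
#' [sim_config()]: simulate the screen and ortholog table; quality-filter
#' lines and call primary hits (Z-score and invasion); expand hits to human
#' orthologs and restrict them to the expression platform; build the
#' direction matrix, compute the query TSOS against a resampling null, and
#' rank the top candidates; simulate and aggregate secondary validation
#' scores; select binding partners, run hypergeometric enrichment, condense
#' the annotation DAG and assemble the systems map; and stratify a synthetic
#' patient cohort on the validated signature (expression and methylation).
#' Every stage writes its outputs as plain TSV under `out_dir`, plus a
#' reproducibility manifest (`manifest.json`: config, config hash, seed,
#' package version, per-stage counts).
#'
#' @param cfg A [sim_config()]; its `seed` drives every stage.
#' @param out_dir Run directory (created if needed).
#' @param params List of analysis thresholds overriding the defaults:
#'   `z_cutoff` (1.65), `alpha_probe` (0.01), `alpha_enrich` (0.05),
#'   `max_term_size` (500), `n_top` (100), `secondary_cutoff` (0.75),
#'   `min_hit_degree` (2), `reps` (100), `n_samplings` (10000).
#' @param stages Character vector of stages to execute, in order; earlier
#'   outputs are re-read from `out_dir` for stages that are skipped. The
#'   full set is `c("simulate", "screen", "orthologs", "tsos", "secondary",
#'   "enrichment", "survival")`.
#' @return Invisibly, a list with the run directory, the manifest, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = tempfile("crosstum_run_"),
                         params = list(), stages = pipeline_stages()) {
  p <- utils::modifyList(list(
    z_cutoff = 1.65, alpha_probe = 0.01, alpha_enrich = 0.05,
    max_term_size = 500, n_top = 100, secondary_cutoff = 0.75,
    min_hit_degree = 2, reps = 100, n_samplings = 10000
  ), params)
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  res <- list()
  stage_msg <- function(name, fmt, ...) inform(sprintf(paste0("[%s] ", fmt), name, ...))
  run_stage <- function(name, code) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  ## simulate -----------------------------------------------------------
  run_stage("simulate", {
    res$screen_table <- gen_screen_table(cfg)
    res$ortho <- gen_ortholog_table(cfg)
    write_screen_table(res$screen_table, file.path(out_dir, "screen_table.tsv"),
                       file.path(out_dir, "control_stats.tsv"))
    write_ortholog_table(res$ortho, file.path(out_dir, "ortholog_table.tsv"))
    counts$lines_screened <- nrow(res$screen_table)
    stage_msg("simulate", "%d lines, %d ortholog rows", nrow(res$screen_table),
              nrow(res$ortho))
  })
  if (is.null(res$screen_table)) {
    res$screen_table <- read_screen_table(file.path(out_dir, "screen_table.tsv"),
                                          file.path(out_dir, "control_stats.tsv"))
    res$ortho <- read_ortholog_table(file.path(out_dir, "ortholog_table.tsv"))
  }

  ## screen -------------------------------------------------------------
  run_stage("screen", {
    ctrl <- control_stats(res$screen_table)
    kept <- filter_rnai_quality(res$screen_table)
    calls <- call_primary_hits(kept, ctrl, z_cutoff = p$z_cutoff)
    res$hit_calls <- calls
    write_tsv_na(calls, file.path(out_dir, "hit_calls.tsv"))
    counts$lines_kept <- nrow(kept)
    counts$primary_hits <- sum(calls$is_hit)
    stage_msg("screen", "%d/%d lines pass quality; %d primary hits",
              nrow(kept), nrow(res$screen_table), sum(calls$is_hit))
  })
  if (is.null(res$hit_calls)) {
    res$hit_calls <- read_screen_table(file.path(out_dir, "hit_calls.tsv"))
  }
  fly_hits <- unique(res$hit_calls$fly_gene[res$hit_calls$is_hit])

  ## orthologs + panel --------------------------------------------------
  run_stage("orthologs", {
    human_hits <- expand_orthologs(fly_hits, res$ortho)
    universe_all <- expand_orthologs(res$hit_calls$fly_gene, res$ortho)
    planted_fly <- unique(res$hit_calls$fly_gene[res$hit_calls$planted_hit])
    planted_human <- intersect(expand_orthologs(planted_fly, res$ortho),
                               panel_gene_universe(cfg))
    res$panel <- gen_expression_panel(cfg, planted_genes = planted_human)
    write_expression_panel(res$panel, file.path(out_dir, "panel"))
    split_hits <- restrict_to_platform(human_hits, res$panel$probe_to_gene)
    split_univ <- restrict_to_platform(universe_all, res$panel$probe_to_gene)
    res$query_genes <- split_hits$measurable
    res$universe <- split_univ$measurable
    writeLines(res$query_genes, file.path(out_dir, "query_genes.txt"))
    writeLines(res$universe, file.path(out_dir, "universe_genes.txt"))
    counts$human_orthologs <- length(human_hits)
    counts$measurable_orthologs <- length(split_hits$measurable)
    stage_msg("orthologs", "%d human orthologs of %d fly hits; %d measurable on platform",
              length(human_hits), length(fly_hits), length(split_hits$measurable))
  })
  if (is.null(res$panel)) {
    res$panel <- read_expression_panel(file.path(out_dir, "panel"))
    res$query_genes <- readLines(file.path(out_dir, "query_genes.txt"))
    res$universe <- readLines(file.path(out_dir, "universe_genes.txt"))
  }

  ## tsos ---------------------------------------------------------------
  run_stage("tsos", {
    dm <- direction_scores(res$panel, alpha = p$alpha_probe)
    res$dm <- dm
    write_direction_matrix(dm, file.path(out_dir, "direction_matrix.tsv"))
    res$tsos <- tsos_test(res$query_genes, dm, res$universe,
                           n_samplings = p$n_samplings,
                           seed = substream_seed(cfg$seed, "tsos_null"))
    jsonlite::write_json(glance(res$tsos), file.path(out_dir, "tsos.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    dm_univ <- dm[dm$gene %in% res$universe, ]
    res$top <- rank_top_candidates(dm_univ, n_top = min(p$n_top, nrow(dm_univ)))
    write_tsv_na(res$top, file.path(out_dir, "top_candidates.tsv"))
    counts$tsos_observed <- res$tsos$observed
    counts$tsos_p <- res$tsos$p_empirical
    stage_msg("tsos", "TSOS %.3f, empirical p %.3g; top %d candidates ranked",
              res$tsos$observed, res$tsos$p_empirical, nrow(res$top))
  })
  if (is.null(res$dm)) {
    res$dm <- read_direction_matrix(file.path(out_dir, "direction_matrix.tsv"))
    res$top <- readr::read_tsv(file.path(out_dir, "top_candidates.tsv"),
                               show_col_types = FALSE)
  }

  ## secondary ----------------------------------------------------------
  run_stage("secondary", {
    scores <- gen_secondary_scores(res$top$gene, res$ortho, res$panel$planted_genes,
                                   seed = cfg$seed)
    val <- validate_secondary(scores, cutoff = p$secondary_cutoff)
    val$human_gene <- human_seed_of(val$fly_gene, res$ortho)
    res$validated <- val
    write_tsv_na(val, file.path(out_dir, "secondary_validation.tsv"))
    counts$validated_genes <- sum(val$validated)
    stage_msg("secondary", "%d/%d genes validated at mean score >= %.2f",
              sum(val$validated), nrow(val), p$secondary_cutoff)
  })
  if (is.null(res$validated)) {
    res$validated <- readr::read_tsv(file.path(out_dir, "secondary_validation.tsv"),
                                     show_col_types = FALSE)
  }
  signature <- sort(unique(res$validated$human_gene[res$validated$validated]))

  ## enrichment + systems map ------------------------------------------
  run_stage("enrichment", {
    gs <- gen_gene_sets_and_dag(cfg)
    net <- gen_ppi_network(cfg)
    write_gmt(gs$collection, file.path(out_dir, "gene_sets.gmt"))
    write_edge_list(gs$dag$edges, file.path(out_dir, "dag_edges.tsv"))
    write_edge_list(net, file.path(out_dir, "ppi_edges.tsv"))
    partners <- select_binding_partners(signature, net, res$universe,
                                        min_hit_degree = p$min_hit_degree)
    enr <- hypergeom_enrich(unique(c(signature, partners$gene)),
                            gs$collection, res$universe)
    keep <- filter_enriched_terms(enr, alpha = p$alpha_enrich,
                                  max_term_size = p$max_term_size)
    condensed <- condense_dag(gs$dag, keep$term)
    write_edge_list(condensed, file.path(out_dir, "condensed_dag.tsv"))
    write_tsv_na(dplyr::select(keep, -"overlap_genes"),
                 file.path(out_dir, "enriched_terms.tsv"))
    smap <- build_systems_map(signature, partners$gene, keep, net)
    write_systems_map(smap, file.path(out_dir, "systems_map_nodes.tsv"),
                      file.path(out_dir, "systems_map_edges.tsv"))
    res$partners <- partners; res$enriched <- keep; res$systems_map <- smap
    counts$binding_partners <- nrow(partners)
    counts$enriched_terms <- nrow(keep)
    counts$gene_to_term_edges <- sum(smap$edges$type == "gene_to_term")
    counts$ppi_map_edges <- sum(smap$edges$type == "ppi")
    stage_msg("enrichment", "%d partners, %d enriched terms, %d+%d map edges",
              nrow(partners), nrow(keep), counts$gene_to_term_edges,
              counts$ppi_map_edges)
  })

  ## survival -----------------------------------------------------------
  run_stage("survival", {
    cohort <- gen_patient_cohort(cfg, signature)
    write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
    strat_e <- stratify_survival(cohort, mode = "rnaseq", reps = p$reps,
                                 seed = substream_seed(cfg$seed, "strat_expr"))
    strat_m <- stratify_survival(cohort, mode = "methylation", reps = p$reps,
                                 seed = substream_seed(cfg$seed, "strat_meth"))
    res$strat_expr <- strat_e; res$strat_meth <- strat_m
    write_tsv_na(strat_e$labels, file.path(out_dir, "strat_labels_expr.tsv"))
    write_tsv_na(strat_m$labels, file.path(out_dir, "strat_labels_meth.tsv"))
    jsonlite::write_json(
      list(rnaseq = glance(strat_e), methylation = glance(strat_m)),
      file.path(out_dir, "survival.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows"
    )
    counts$logrank_p_expr <- strat_e$p_logrank
    counts$fisher_p_expr <- strat_e$fisher_p_g12
    counts$logrank_p_meth <- strat_m$p_logrank
    counts$fisher_p_meth <- strat_m$fisher_p_g12
    stage_msg("survival", "expression log-rank p %.3g, Fisher p %.3g",
              strat_e$p_logrank, strat_e$fisher_p_g12)
  })

  manifest <- list(
    package = "crosstum",
    version = as.character(utils::packageVersion("crosstum")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    params = p,
    stages = stages,
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, manifest = manifest, results = res))
}

#' @rdname run_pipeline
#' @export
pipeline_stages <- function() {
  c("simulate", "screen", "orthologs", "tsos", "secondary", "enrichment",
    "survival")
}

# Simulate secondary rough-eye scores for the top candidates: planted
# tumor-downregulated genes enhance the phenotype, the rest mostly do not.
gen_secondary_scores <- function(top_genes, ortho, planted_human, seed,
                                 lines_per_gene = 2L) {
  seed_of <- vapply(ortho$human_seed, function(v) v[1] %||% NA_character_,
                    character(1))
  fly_of <- setNames(ortho$fly_gene, seed_of)
  with_stream(seed, "secondary", {
    purrr::map_dfr(top_genes, function(g) {
      fly <- fly_of[[g]] %||% g
      planted <- g %in% planted_human
      mu <- if (planted) 1.8 else 0.35
      tibble(fly_gene = fly,
             score = round(clamp01(rnorm(lines_per_gene, mu, 0.5), 0, 3), 2))
    })
  })
}

human_seed_of <- function(fly_genes, ortho) {
  seeds <- vapply(ortho$human_seed, function(v) v[1] %||% NA_character_,
                  character(1))
  setNames(seeds, ortho$fly_gene)[fly_genes]
}

#' Summarize a completed pipeline run
#'
#' Reads the manifest and stage outputs from a run directory and tabulates
#' the funnel (lines screened, kept, primary hits, orthologs, validated
#' genes), the TSOS and its empirical p, enriched-term and systems-map
#' counts, and the survival/mutation p-values. Stages whose outputs are
#' missing are summarized as absent, with a warning. Reading is
#' side-effect-free on the run directory.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return A list of class `pipeline_report` with `manifest`, `funnel`
#'   (tibble stage/quantity/value), and any stage tables found.
#' @export
pipeline_report <- function(run_dir) {
  mf_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf_path)) {
    abort(sprintf("no manifest.json in '%s'; not a completed run directory", run_dir))
  }
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  counts <- manifest$counts
  funnel <- tibble(quantity = names(counts),
                   value = unname(vapply(counts, as.numeric, numeric(1))))
  maybe <- function(f, reader) {
    path <- file.path(run_dir, f)
    if (file.exists(path)) reader(path) else {
      warn(sprintf("stage output '%s' missing from run", f))
      NULL
    }
  }
  structure(list(
    manifest = manifest,
    funnel = funnel,
    top = maybe("top_candidates.tsv", function(p) readr::read_tsv(p, show_col_types = FALSE)),
    enriched = maybe("enriched_terms.tsv", function(p) readr::read_tsv(p, show_col_types = FALSE)),
    survival = maybe("survival.json", function(p) jsonlite::read_json(p, simplifyVector = TRUE))
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> run of %s (seed %s, config %s)\n",
              x$manifest$created, x$manifest$seed, x$manifest$config_hash))
  print(x$funnel, n = Inf)
  invisible(x)
}
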