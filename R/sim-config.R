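#' Simulation configuration for the synthetic screen-to-survival pipeline
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' list. A single integer `seed` fans out to independent per-generator
#' substreams, so the draws of one generator never depend on whether another
#' was called. Defaults describe the study conditions the pipeline is
#' designed around: a fly RNAi screen whose hits depress pupariation by
#' ~35 percentage points against a 98.8 +/- 5 control, a paired tumor/normal
#' expression panel with a planted tumor-downregulated gene set, a
#' scale-free-ish protein-interaction graph, a small annotation DAG, and a
#' patient cohort whose latent low-expression group carries a survival and
#' KRAS-G12 penalty.
#'
#' @param seed Integer master seed; all generator randomness derives from it.
#' @param n_lines Number of RNAi lines screened (one line per fly gene).
#' @param hit_fraction Fraction of lines that are true (planted) hits.
#' @param pupariation_effect Percentage-point drop in mean pupariation for
#'   hit lines.
#' @param control_mean,control_sd Control pupariation distribution (percent);
#'   draws are clamped to \[0, 100\].
#' @param invasion_rate Fraction of planted hits that additionally show
#'   mouth-hook invasion or ectopic GFP foci.
#' @param n_genes Size of the human gene universe measurable on the
#'   expression platform.
#' @param probe_multiplicity Named numeric vector of probabilities over probe
#'   set counts per gene, e.g. `c("1" = .6, "2" = .3, "3" = .1)`.
#' @param n_tissue_pairs Number of tumor/normal tissue pairs in the panel.
#' @param n_tumor,n_normal Samples per arm in each pair.
#' @param planted_set_size Number of genes planted as tumor-downregulated.
#' @param planted_effect Standardized mean difference (normal minus tumor, in
#'   residual SDs) for planted genes.
#' @param background_effect_sd SD of the incoherent per-gene, per-pair
#'   differential-expression effect (random sign, shared by a gene's probe
#'   sets). Real tumor/normal pairs differ for most genes; this density is
#'   what the gene-set resampling null is built for. Set 0 for a fully null
#'   panel.
#' @param affected_pair_fraction Fraction of tissue pairs in which planted
#'   genes carry the effect.
#' @param one_to_many_rate Fraction of fly genes with >= 1 human inparalog.
#' @param ppi_edges Number of undirected protein-interaction edges.
#' @param dag_depth,dag_branching Depth and branching factor of the
#'   annotation DAG below its root.
#' @param n_patients Cohort size.
#' @param hazard_ratio_low_vs_high Multiplicative hazard for the latent
#'   low-expression group.
#' @param g12_odds_low_vs_high Odds multiplier on KRAS-G12 carriage for the
#'   low group.
#' @param g12_base_rate Baseline G12 probability in the high group.
#' @param expr_shift_sd Downward shift (in SDs on the log scale) of signature
#'   expression in the low group.
#' @param censoring_rate Fraction of patients right-censored.
#' @param missing_rate Fraction of patients lacking survival and, independently,
#'   mutation records (exercises the cohort filter).
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_lines = 50, n_genes = 40)
#' cfg$hit_fraction
sim_config <- function(seed = 1L,
                       n_lines = 600L,
                       hit_fraction = 0.05,
                       pupariation_effect = 35,
                       control_mean = 98.8,
                       control_sd = 5,
                       invasion_rate = 0.3,
                       n_genes = 600L,
                       probe_multiplicity = c("1" = 0.6, "2" = 0.3, "3" = 0.1),
                       n_tissue_pairs = 10L,
                       n_tumor = 30L,
                       n_normal = 30L,
                       planted_set_size = 50L,
                       planted_effect = 2,
                       background_effect_sd = 1,
                       affected_pair_fraction = 1,
                       one_to_many_rate = 0.3,
                       ppi_edges = 1500L,
                       dag_depth = 4L,
                       dag_branching = 3L,
                       n_patients = 200L,
                       hazard_ratio_low_vs_high = 3,
                       g12_odds_low_vs_high = 4,
                       g12_base_rate = 0.5,
                       expr_shift_sd = 1.5,
                       censoring_rate = 0.3,
                       missing_rate = 0.1) {
  cfg <- list(
    seed = seed, n_lines = n_lines, hit_fraction = hit_fraction,
    pupariation_effect = pupariation_effect, control_mean = control_mean,
    control_sd = control_sd, invasion_rate = invasion_rate,
    n_genes = n_genes, probe_multiplicity = probe_multiplicity,
    n_tissue_pairs = n_tissue_pairs, n_tumor = n_tumor, n_normal = n_normal,
    planted_set_size = planted_set_size, planted_effect = planted_effect,
    background_effect_sd = background_effect_sd,
    affected_pair_fraction = affected_pair_fraction,
    one_to_many_rate = one_to_many_rate, ppi_edges = ppi_edges,
    dag_depth = dag_depth, dag_branching = dag_branching,
    n_patients = n_patients,
    hazard_ratio_low_vs_high = hazard_ratio_low_vs_high,
    g12_odds_low_vs_high = g12_odds_low_vs_high,
    g12_base_rate = g12_base_rate, expr_shift_sd = expr_shift_sd,
    censoring_rate = censoring_rate, missing_rate = missing_rate
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_lines", "n_genes", "n_tissue_pairs", "n_tumor", "n_normal",
              "planted_set_size", "dag_depth", "dag_branching", "n_patients")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v)) {
      abort(sprintf("`%s` must be a single integer >= 1 (got %s)", nm, toString(v)))
    }
  }
  fracs <- c("hit_fraction", "invasion_rate", "affected_pair_fraction",
             "one_to_many_rate", "g12_base_rate", "censoring_rate",
             "missing_rate")
  for (nm in fracs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a fraction in [0, 1] (got %s)", nm, toString(v)))
    }
  }
  if (cfg$control_sd <= 0) abort("`control_sd` must be positive")
  if (cfg$background_effect_sd < 0) abort("`background_effect_sd` must be >= 0")
  if (cfg$hazard_ratio_low_vs_high <= 0 || cfg$g12_odds_low_vs_high <= 0) {
    abort("hazard ratio and G12 odds must be positive")
  }
  pm <- cfg$probe_multiplicity
  if (is.null(names(pm)) || any(is.na(suppressWarnings(as.integer(names(pm))))) ||
      any(pm < 0) || sum(pm) <= 0) {
    abort("`probe_multiplicity` must be named probabilities over counts {1,2,...}")
  }
  if (cfg$ppi_edges < 0) abort("`ppi_edges` must be >= 0")
  if (cfg$planted_set_size > cfg$n_genes) {
    abort("`planted_set_size` cannot exceed `n_genes`")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  screen : %d lines, %.0f%% hits, effect %.0f pts (control %.1f +/- %.1f)\n",
              x$n_lines, 100 * x$hit_fraction, x$pupariation_effect,
              x$control_mean, x$control_sd))
  cat(sprintf("  panel  : %d genes x %d pairs, %d/%d per arm, %d planted @ %.1f SD\n",
              x$n_genes, x$n_tissue_pairs, x$n_tumor, x$n_normal,
              x$planted_set_size, x$planted_effect))
  cat(sprintf("  cohort : %d patients, HR %.1f, G12 odds %.1f, %.0f%% censoring\n",
              x$n_patients, x$hazard_ratio_low_vs_high,
              x$g12_odds_low_vs_high, 100 * x$censoring_rate))
  invisible(x)
}
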