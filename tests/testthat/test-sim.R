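test_that("sim_config validates counts, fractions and distributions", {
  expect_s3_class(tiny_cfg(), "sim_config")
  expect_error(sim_config(n_lines = 0), "n_lines")
  expect_error(sim_config(hit_fraction = 1.2), "hit_fraction")
  expect_error(sim_config(control_sd = 0), "control_sd")
  expect_error(sim_config(probe_multiplicity = c(0.5, 0.5)), "probe_multiplicity")
  expect_error(sim_config(planted_set_size = 100, n_genes = 50), "planted_set_size")
})

test_that("generators are bit-identical under the same seed and differ across seeds", {
  cfg <- tiny_cfg(seed = 42)
  expect_identical(gen_screen_table(cfg), gen_screen_table(cfg))
  expect_identical(gen_ortholog_table(cfg), gen_ortholog_table(cfg))
  expect_identical(gen_ppi_network(cfg), gen_ppi_network(cfg))
  expect_identical(gen_gene_sets_and_dag(cfg), gen_gene_sets_and_dag(cfg))
  p1 <- gen_expression_panel(cfg)
  expect_identical(p1, gen_expression_panel(cfg))
  coh <- gen_patient_cohort(cfg, c("SIG1", "SIG2"))
  expect_identical(coh, gen_patient_cohort(cfg, c("SIG1", "SIG2")))
  cfg2 <- tiny_cfg(seed = 43)
  expect_false(identical(gen_screen_table(cfg), gen_screen_table(cfg2)))
})

test_that("screen generator plants the configured arrest effect", {
  cfg0 <- sim_config(seed = 5, n_lines = 2000, hit_fraction = 0)
  scr0 <- gen_screen_table(cfg0)
  expect_false(any(scr0$planted_hit))
  # all-null lines: mean pupariation matches the clamped-normal expectation,
  # E[min(X, 100)] = mu - sd * (phi(a) - a * (1 - Phi(a))), a = (100 - mu)/sd
  a <- (100 - cfg0$control_mean) / cfg0$control_sd
  exp_mean <- cfg0$control_mean -
    cfg0$control_sd * (dnorm(a) - a * (1 - pnorm(a)))
  expect_lt(abs(mean(100 - scr0$pct_larvae_day8) - exp_mean), 0.5)
  cfg1 <- sim_config(seed = 5, n_lines = 400, hit_fraction = 0.5)
  scr1 <- gen_screen_table(cfg1)
  pup <- 100 - scr1$pct_larvae_day8
  gap <- mean(pup[!scr1$planted_hit]) - mean(pup[scr1$planted_hit])
  expect_gt(gap, cfg1$pupariation_effect - 5)
  expect_true(all(scr1$pct_larvae_day8 >= 0 & scr1$pct_larvae_day8 <= 100))
  # invasion flags only on planted hits
  flagged <- scr1$mouthhook_invasion | scr1$ectopic_foci
  expect_true(all(scr1$planted_hit[flagged]))
})

test_that("expression panel has the declared structure and plants direction", {
  cfg <- tiny_cfg(seed = 9, planted_effect = 2)
  planted <- panel_gene_universe(cfg)[1:8]
  panel <- gen_expression_panel(cfg, planted)
  expect_setequal(unique(panel$probe_to_gene$gene), panel$genes)
  expect_length(panel$pairs, cfg$n_tissue_pairs)
  expect_equal(ncol(panel$pairs[[1]]$tumor), cfg$n_tumor)
  expect_equal(ncol(panel$pairs[[1]]$normal), cfg$n_normal)
  expect_error(gen_expression_panel(cfg, "NOT_A_GENE"), "subset")
  dm <- direction_scores(panel)
  pair_cols <- setdiff(names(dm), c("gene", "n_probes"))
  mean_planted <- mean(as.matrix(dm[dm$gene %in% planted, pair_cols]))
  expect_lt(mean_planted, 0)
})

test_that("ortholog generator respects one-to-many structure", {
  cfg <- tiny_cfg(seed = 3, one_to_many_rate = 0)
  tab <- gen_ortholog_table(cfg)
  expect_true(all(lengths(tab$human_inparalogs) == 0))
  cfg2 <- sim_config(seed = 3, n_lines = 100, one_to_many_rate = 0.3)
  tab2 <- gen_ortholog_table(cfg2)
  seeds <- unlist(tab2$human_seed)
  expect_false(any(duplicated(seeds))) # no human gene seeds two fly genes
  expanded <- expand_orthologs(tab2$fly_gene, tab2)
  n_inp <- sum(lengths(tab2$human_inparalogs))
  expect_gte(length(expanded), 100)
  expect_lte(length(expanded), 100 + n_inp)
  expect_false(any(duplicated(expanded)))
})

test_that("annotation DAG is upward-closed with an all-encompassing root", {
  cfg <- tiny_cfg(seed = 7, dag_depth = 4, dag_branching = 3)
  gs <- gen_gene_sets_and_dag(cfg)
  dag <- gs$dag
  for (i in seq_len(nrow(dag$edges))) {
    child <- dag$edges$child[i]; parent <- dag$edges$parent[i]
    expect_true(all(dag$annot[[child]] %in% dag$annot[[parent]]))
  }
  all_genes <- sort(unique(unlist(dag$annot)))
  expect_identical(dag$annot[["T0_1"]], all_genes)
  # tree + cross-links: reproducible node count under seed
  expect_identical(gen_gene_sets_and_dag(cfg)$dag$terms, dag$terms)
  expect_gte(length(dag$terms), sum(3^(0:4)))
})

test_that("large universes produce terms beyond the 500-gene filter", {
  cfg <- sim_config(seed = 1, n_genes = 700)
  gs <- gen_gene_sets_and_dag(cfg)
  expect_gt(max(term_sizes(gs$dag)$n_term), 500)
})

test_that("ppi generator yields a simple right-skewed graph on the universe", {
  cfg <- tiny_cfg(seed = 2)
  net <- gen_ppi_network(cfg)
  expect_true(all(c(net$from, net$to) %in% panel_gene_universe(cfg)))
  expect_false(any(net$from == net$to))
  key <- paste(pmin(net$from, net$to), pmax(net$from, net$to))
  expect_false(any(duplicated(key)))
  empty <- gen_ppi_network(sim_config(seed = 2, ppi_edges = 0))
  expect_equal(nrow(empty), 0)
  # right-skew: max degree well above mean degree, consistently across seeds
  ratios <- vapply(1:5, function(s) {
    net <- gen_ppi_network(sim_config(seed = s, n_genes = 300, ppi_edges = 900))
    deg <- table(c(net$from, net$to))
    max(deg) / mean(deg)
  }, numeric(1))
  expect_true(all(ratios > 3))
})

test_that("patient cohort carries the planted group structure", {
  cfg <- tiny_cfg(seed = 8)
  expect_error(gen_patient_cohort(cfg, character()), "nonempty")
  coh <- gen_patient_cohort(cfg, sprintf("SG%02d", 1:10))
  expect_true(all(coh$beta >= 0 & coh$beta <= 1))
  expect_true(all(coh$samples$time[coh$samples$has_survival] >= 0))
  expect_true(any(!coh$samples$has_survival) || cfg$missing_rate == 0)
  # low group has lower signature expression on the log scale
  lg <- coh$samples$latent_group
  sig_mean <- colMeans(log(coh$expr[coh$signature, , drop = FALSE]))
  expect_lt(mean(sig_mean[lg == "low"]), mean(sig_mean[lg == "high"]))
  # methylation anti-correlated with expression for signature genes
  cors <- vapply(coh$signature, function(g) {
    stats::cor(log(coh$expr[g, ]), coh$beta[g, ])
  }, numeric(1))
  expect_lt(mean(cors), -0.3)
})
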