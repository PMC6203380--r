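# 80-gene signatures mirror the validated-gene-set size the stratification
# is designed around.
cohort_fixture <- function(seed = 1, n = 60, hr = 3, odds = 4, ...) {
  cfg <- sim_config(seed = seed, n_patients = n,
                    hazard_ratio_low_vs_high = hr,
                    g12_odds_low_vs_high = odds, ...)
  gen_patient_cohort(cfg, sprintf("SG%02d", 1:80))
}

test_that("cohort filter keeps exactly the doubly-annotated samples", {
  coh <- cohort_fixture(seed = 2, n = 100, missing_rate = 0.2)
  expect_message(f <- filter_cohort(coh), "retained")
  brute <- coh$samples$sample[coh$samples$has_survival & coh$samples$has_mutation_call]
  expect_identical(f$samples$sample, brute)
  expect_identical(colnames(f$expr), brute)
  # all-complete cohort: identity
  full <- cohort_fixture(seed = 3, missing_rate = 0)
  expect_message(f2 <- filter_cohort(full), "100%")
  expect_identical(f2$samples, full$samples)
  none <- cohort_fixture(seed = 3)
  none$samples$has_survival <- FALSE
  expect_error(filter_cohort(none), "no samples")
})

test_that("expression preprocessing is log1p then per-sample standardization", {
  set.seed(4)
  m <- matrix(rexp(200, 1 / 100), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  out <- preprocess_expression(m)
  expect_equal(unname(colMeans(out)), rep(0, 10))
  expect_equal(unname(apply(out, 2, sd)), rep(1, 10))
  # arithmetic oracle to 1e-12
  oracle <- apply(log(1 + m), 2, function(x) (x - mean(x)) / sd(x))
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_error(preprocess_expression(-m), ">= 0")
  # all-zero sample scales to zeros with a warning
  m[, 1] <- 0
  expect_warning(out2 <- preprocess_expression(m), "zero variance")
  expect_equal(unname(out2[, 1]), rep(0, 20))
})

test_that("methylation aggregation averages probes per gene, NA-aware", {
  pb <- matrix(c(0.2, 0.4, 0.9, NA, 0.5, NA), nrow = 3,
               dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- tibble::tibble(probe_id = c("p1", "p2", "p3"), gene = c("gA", "gA", "gB"))
  out <- aggregate_methylation(pb, map)
  expect_equal(out["gA", "s1"], 0.3) # (0.2 + 0.4) / 2
  expect_equal(out["gA", "s2"], 0.5) # NA probe excluded
  expect_equal(out["gB", "s1"], 0.9) # single-probe gene: identity
  expect_true(is.na(out["gB", "s2"])) # all probes NA
  expect_error(aggregate_methylation(pb * 2, map), "0, 1")
  # group-by-mean oracle on random input
  set.seed(9)
  pb2 <- matrix(runif(60), nrow = 12,
                dimnames = list(sprintf("q%02d", 1:12), paste0("s", 1:5)))
  map2 <- tibble::tibble(probe_id = rownames(pb2),
                         gene = rep(c("x", "y", "z"), each = 4))
  out2 <- aggregate_methylation(pb2, map2)
  for (g in c("x", "y", "z")) {
    expect_equal(out2[g, ], colMeans(pb2[map2$gene == g, ]))
  }
})

test_that("repeated k-means recovers separated groups, aligned and order-invariant", {
  set.seed(6)
  # two point-masses far apart
  m <- cbind(matrix(rnorm(40, -5, 0.1), 4, 10), matrix(rnorm(40, 5, 0.1), 4, 10))
  colnames(m) <- sprintf("s%02d", 1:20)
  lab <- stratify_repeated_kmeans(m, reps = 10, seed = 1)
  expect_equal(lab$label, rep(c("low", "high"), each = 10))
  expect_true(all(lab$n_high %in% c(0L, 10L)))
  # permuting sample order permutes, but does not change, labels
  perm <- sample(20)
  lab_p <- stratify_repeated_kmeans(m[, perm], reps = 10, seed = 1)
  expect_equal(lab_p$label[match(lab$sample, lab_p$sample)], lab$label)
  expect_error(stratify_repeated_kmeans(m[, 1:1, drop = FALSE], k = 2), "clusters")
})

test_that("planted cohorts are recovered with >= 95% agreement", {
  agree <- vapply(1:5, function(s) {
    coh <- cohort_fixture(seed = s, n = 200)
    res <- suppressMessages(stratify_survival(coh, reps = 25, seed = s))
    truth <- coh$samples$latent_group[match(res$labels$sample, coh$samples$sample)]
    mean(res$labels$label == truth)
  }, numeric(1))
  expect_true(all(agree >= 0.95))
})

test_that("log-rank test behaves at null and under planted hazard, matching a permutation oracle", {
  set.seed(8)
  time <- rexp(40, 1 / 100); event <- rbinom(40, 1, 0.8)
  labels <- rep(c("low", "high"), 20)
  lr <- logrank_test(labels, time, event)
  expect_gt(lr$p, 0.05) # labels independent of survival
  # permutation oracle: chi-square statistic rank among label shuffles
  obs <- lr$chisq
  perm <- vapply(1:2000, function(i) {
    logrank_test(sample(labels), time, event)$chisq
  }, numeric(1))
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_perm - lr$p), 0.05)
  # zero-event group still yields a defined p
  ev0 <- event; ev0[labels == "low"] <- 0
  expect_true(is.finite(logrank_test(labels, time, ev0)$p))
  expect_error(logrank_test(rep("low", 10), time[1:10], event[1:10]), "two groups")
})

test_that("mutation enrichment matches the hypergeometric tail with fixed margins", {
  labels <- rep(c("low", "high"), each = 10)
  cat_ <- c(rep("G12", 8), rep("other", 2), rep("G12", 2), rep("none", 8))
  me <- mutation_enrichment(labels, cat_)
  expect_equal(unname(me$contingency["low", ]), c(8, 2))
  # enumeration oracle: P(X >= 8), X ~ Hypergeom(N=20, K=10 G12, n=10 low)
  expect_equal(me$p, phyper(7, 10, 10, 10, lower.tail = FALSE))
  # zero G12 in the tested group: p = 1
  me0 <- mutation_enrichment(labels, c(rep("none", 10), rep("G12", 10)))
  expect_equal(me0$p, 1)
  # group = "high" mirrors the table
  meh <- mutation_enrichment(labels, cat_, group = "high")
  expect_equal(meh$p, phyper(1, 10, 10, 10, lower.tail = FALSE))
  expect_error(mutation_enrichment(labels, rep("g12", 20)), "categories")
})

test_that("full stratification flags planted cohorts and is label-symmetric", {
  coh <- cohort_fixture(seed = 10, n = 200)
  res <- suppressMessages(stratify_survival(coh, reps = 25, seed = 2))
  expect_lt(res$p_logrank, 0.05)
  expect_lt(res$fisher_p_g12, 0.05)
  expect_s3_class(autoplot(res), "ggplot")
  expect_equal(nrow(tidy(res)), sum(coh$samples$has_survival & coh$samples$has_mutation_call))
  # relabeling low<->high leaves the log-rank statistic unchanged
  flipped <- ifelse(res$labels$label == "low", "high", "low")
  lr_f <- logrank_test(flipped, res$time, res$event)
  expect_equal(lr_f$chisq, res$chisq)
  # methylation mode finds the mirrored structure
  resm <- suppressMessages(stratify_survival(coh, mode = "methylation",
                                             reps = 25, seed = 2))
  expect_lt(resm$p_logrank, 0.05)
  expect_lt(resm$fisher_p_g12, 0.05)
})
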