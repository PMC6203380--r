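test_that("binding partner selection counts distinct hit neighbors", {
  # star graph: center adjacent to 3 hits; leaves adjacent to 1
  net <- tibble::tibble(from = c("c", "c", "c", "c"),
                        to = c("h1", "h2", "h3", "x1"))
  uni <- c("c", "h1", "h2", "h3", "x1")
  p <- select_binding_partners(c("h1", "h2", "h3"), net, uni)
  expect_equal(p$gene, "c")
  expect_equal(p$n_hit_neighbors, 3)
  p1 <- select_binding_partners(c("h1", "h2", "h3"), net, uni, min_hit_degree = 1)
  expect_setequal(p1$gene, "c") # x1 touches no hit; c is the only neighbor
  # hits never returned as partners even when adjacent to other hits
  net2 <- tibble::tibble(from = c("h1", "h1"), to = c("h2", "h3"))
  expect_equal(nrow(select_binding_partners(c("h1", "h2", "h3"), net2, uni)), 0)
  expect_error(select_binding_partners("zz", net, uni), "subset")
})

test_that("partner selection matches a brute-force adjacency count", {
  cfg <- sim_config(seed = 19, n_genes = 200, ppi_edges = 600)
  net <- gen_ppi_network(cfg)
  uni <- panel_gene_universe(cfg)
  hits <- sample(uni, 80)
  p <- select_binding_partners(hits, net, uni, min_hit_degree = 2)
  # oracle: per-node count of distinct hit neighbors
  nbrs <- function(g) unique(c(net$to[net$from == g], net$from[net$to == g]))
  brute <- Filter(function(g) length(intersect(nbrs(g), hits)) >= 2,
                  setdiff(uni, hits))
  expect_setequal(p$gene, brute)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  uni <- sprintf("u%02d", 1:10)
  sets <- tibble::tibble(term = "t1", description = "d",
                         genes = list(uni[1:4]))
  query <- c(uni[1:3], uni[8:9]) # overlap 3 of term 4
  res <- hypergeom_enrich(query, sets, uni)
  expect_equal(res$p, hyper_tail_oracle(10, 4, 5, 3))
  expect_equal(res$expected, 5 * 4 / 10)
  expect_equal(res$overlap_genes[[1]], uni[1:3])
  # term = universe forces p = 1; zero overlap gives p = 1
  sets2 <- tibble::tibble(term = c("all", "none"), description = "",
                          genes = list(uni, c("zz1", "zz2")))
  res2 <- hypergeom_enrich(query, sets2, uni)
  expect_equal(res2$p[res2$term == "all"], 1)
  expect_equal(res2$p[res2$term == "none"], 1)
  expect_error(hypergeom_enrich(query, sets, character()), "empty")
})

test_that("enrichment p is monotone in overlap and FDR matches p.adjust", {
  # fixed margins, increasing overlap => decreasing p
  ps <- vapply(0:5, function(k) {
    phyper(k - 1, 10, 40, 5, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  set.seed(5)
  uni <- sprintf("u%03d", 1:100)
  sets <- tibble::tibble(
    term = sprintf("t%d", 1:20), description = "",
    genes = lapply(1:20, function(i) sample(uni, sample(5:40, 1)))
  )
  res <- hypergeom_enrich(sample(uni, 15), sets, uni)
  expect_equal(res$fdr, p.adjust(res$p, "BH"))
})

test_that("null queries are enriched in ~5% of terms at p <= 0.05", {
  set.seed(11)
  uni <- sprintf("u%03d", 1:200)
  sets <- tibble::tibble(
    term = sprintf("t%d", 1:40), description = "",
    genes = lapply(1:40, function(i) sample(uni, 50))
  )
  frac <- mean(vapply(1:60, function(i) {
    res <- hypergeom_enrich(sample(uni, 30), sets, uni)
    mean(res$p <= 0.05)
  }, numeric(1)))
  # hypergeometric p is discrete, so the attained rate sits below the nominal level
  expect_lt(frac, 0.08)
  expect_gt(frac, 0.01)
})

test_that("term filtering applies inclusive boundaries", {
  res <- tibble::tibble(
    term = c("a", "b", "c", "d"),
    n_term = c(500, 501, 10, 10),
    n_overlap = c(3, 3, 2, 3),
    p = c(0.05, 0.001, 0.049, 0.051)
  )
  kept <- filter_enriched_terms(res)
  expect_setequal(kept$term, c("a", "c")) # 500 @ 0.05 kept; 501 dropped
  kept2 <- filter_enriched_terms(res, min_overlap = 3)
  expect_setequal(kept2$term, "a")
  # predicate oracle on random tables
  set.seed(2)
  rnd <- tibble::tibble(term = as.character(1:200),
                        n_term = sample(1:800, 200, TRUE),
                        n_overlap = sample(0:5, 200, TRUE),
                        p = runif(200))
  expect_equal(filter_enriched_terms(rnd)$term,
               rnd$term[rnd$p <= 0.05 & rnd$n_term <= 500])
})

test_that("systems map types nodes and edges and flags unassigned hits", {
  hits <- c("h1", "h2", "h3")
  partners <- c("p1", "p2")
  enriched <- tibble::tibble(term = c("T1", "T2"),
                             genes = list(c("h1", "p1", "zz"), c("h2", "p1")))
  net <- tibble::tibble(from = c("h1", "h1", "zz", "p1"),
                        to = c("p1", "h2", "p2", "p2"))
  map <- build_systems_map(hits, partners, enriched, net)
  g2t <- map$edges[map$edges$type == "gene_to_term", ]
  expect_equal(nrow(g2t), 4) # h1-T1, p1-T1, h2-T2, p1-T2
  ppi <- map$edges[map$edges$type == "ppi", ]
  expect_equal(nrow(ppi), 3) # h1-p1, h1-h2, p1-p2 (zz outside map)
  expect_true(all(ppi$source %in% c(hits, partners) & ppi$target %in% c(hits, partners)))
  expect_equal(map$nodes$id[map$nodes$unassigned], "h3")
  # no enriched terms: only gene nodes, ppi edges, all hits unassigned
  map0 <- build_systems_map(hits, partners, enriched[0, ], net)
  expect_true(all(map0$edges$type == "ppi"))
  expect_true(all(map0$nodes$unassigned[map0$nodes$type == "hit"]))
})

test_that("systems map edge counts equal brute-force enumeration", {
  cfg <- tiny_cfg(seed = 41)
  gs <- gen_gene_sets_and_dag(cfg)
  net <- gen_ppi_network(cfg)
  uni <- panel_gene_universe(cfg)
  hits <- sample(uni, 15)
  partners <- select_binding_partners(hits, net, uni, min_hit_degree = 1)$gene
  enr <- hypergeom_enrich(c(hits, partners), gs$collection, uni)
  keep <- filter_enriched_terms(enr, alpha = 0.5)
  keep$genes <- lapply(keep$term, function(t) gs$dag$annot[[t]])
  map <- build_systems_map(hits, partners, keep, net)
  genes <- union(hits, partners)
  brute_g2t <- sum(vapply(keep$genes, function(m) length(intersect(m, genes)),
                          numeric(1)))
  brute_ppi <- sum(net$from %in% genes & net$to %in% genes)
  expect_equal(sum(map$edges$type == "gene_to_term"), brute_g2t)
  expect_equal(sum(map$edges$type == "ppi"), brute_ppi)
})
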