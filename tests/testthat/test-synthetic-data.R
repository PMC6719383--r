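cfg_small <- sim_config(seed = 11, n_genes = 100, network_nodes = 60)

test_that("synthetic genome respects counts, ordering and determinism", {
  g <- generate_genome(cfg_small)
  expect_equal(nrow(g), 100)
  for (a in unique(g$arm)) {
    sub <- g[g$arm == a, ]
    expect_true(all(diff(sub$midpoint) > 0))
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))  # no overlaps
  }
  expect_identical(generate_genome(cfg_small), g)
  g0 <- generate_genome(sim_config(seed = 1, n_genes = 0))
  expect_equal(nrow(g0), 0)
  expect_error(generate_genome(sim_config(seed = 1, n_genes = 100,
                                          arms = c(A = 5e4))),
               "too large")
})

test_that("planted clusters occupy the planned rank structure and are recoverable", {
  g <- mk_genome(c(A1 = 60, A2 = 60))
  pl <- plant_clustered_gene_set(g, n_clusters = 5, cluster_size = 4,
                                 max_internal_gap = 0, background_rate = 0,
                                 seed = 3)
  expect_equal(length(pl$test_set), 20)
  expect_equal(as.integer(table(pl$truth$truth_cluster)), rep(4L, 5))
  rk <- genome_ranks(g)
  for (cl in split(pl$truth$gene_id[pl$truth$truth_planted],
                   pl$truth$truth_cluster[pl$truth$truth_planted])) {
    r <- sort(rk$rank[match(cl, rk$gene_id)])
    expect_equal(diff(r), rep(1L, 3))  # gap 0 -> consecutive ranks
  }
  # detection at max_gap >= planted gap recovers all planted clusters
  rep5 <- quiet(find_max_gap_clusters(pl$test_set, g, max_gap = 5))
  expect_equal(rep5$n_clusters, 5)
  expect_equal(rep5$percent_clustered, 100)
  # empty plan
  pl0 <- plant_clustered_gene_set(g, 0, 2, 0, background_rate = 0, seed = 1)
  expect_equal(length(pl0$test_set), 0)
})

test_that("NB counts carry planted effects and hit the Poisson limit", {
  g <- generate_genome(cfg_small)
  cc <- generate_counts(g, cfg_small)
  expect_equal(dim(cc$counts), c(100, nrow(cc$meta)))
  expect_true(all(c("haplotype", "species", "gxg") %in% cc$truth$truth_effect))
  expect_identical(generate_counts(g, cfg_small)$counts, cc$counts)
  # dispersion -> 0: variance ~ mean within a group (Poisson limit)
  cfgp <- sim_config(seed = 12, n_genes = 200, dispersion = 0,
                     effect_gene_fraction = 0)
  gp <- generate_genome(cfgp)
  ccp <- generate_counts(gp, cfgp)
  grp <- ccp$meta$sample_id[ccp$meta$sex == "F" & ccp$meta$mito == "hap1" &
                              ccp$meta$nuc == "N1"]
  # normalize out the log-normal library factors before the var/mean check
  sf <- colSums(ccp$counts[, grp]) / mean(colSums(ccp$counts[, grp]))
  sub <- sweep(ccp$counts[, grp], 2, sf, "/")
  ratio <- apply(sub, 1, stats::var) / rowMeans(sub)
  expect_lt(abs(median(ratio) - 1), 0.25)
  expect_error(generate_counts(g, sim_config(seed = 1, dispersion = -1)))
})

test_that("scale-free networks are heavy-tailed; degenerate sizes behave", {
  cfg <- sim_config(seed = 13, network_nodes = 1000)
  ns <- generate_network_with_hotspots(cfg)
  met <- network_metrics(ns$network)
  expect_gt(max(met$degree), 5 * median(met$degree))
  expect_equal(length(ns$network$nodes), 1000)
  ns1 <- generate_network_with_hotspots(sim_config(seed = 1, network_nodes = 1))
  expect_equal(length(ns1$network$nodes), 1)
  expect_equal(nrow(ns1$network$edges), 0)
})

test_that("module labels realize the requested improper enrichment", {
  ids <- sprintf("g%05d", 1:8000)
  sens <- withr::with_seed(42, sample(ids, 300))
  # neutral factor -> fold ~ 1 within binomial error
  m1 <- generate_module_labels(ids, sens, improper_fraction = 0.2,
                               enrichment_factor = 1, seed = 5)
  k <- sum(m1$truth$truth_improper & m1$truth$truth_sensitive)
  expected <- 300 * 0.2
  expect_lt(abs(k - expected) / sqrt(300 * 0.2 * 0.8), 3.5)
  expect_error(generate_module_labels(ids, sens, improper_fraction = 1.2,
                                      enrichment_factor = 1))
  expect_error(generate_module_labels(ids, sens, improper_fraction = 0.3,
                                      enrichment_factor = 5), "infeasible")
})

test_that("developmental blocks are separable and deterministic", {
  ids <- sprintf("g%03d", 1:40)
  dv <- generate_dev_expression(ids, n_stages = 10, n_blocks = 2,
                                noise_sd = 0.3, seed = 6)
  expect_identical(generate_dev_expression(ids, 10, 2, 0.3, seed = 6)$expr,
                   dv$expr)
  # hierarchical clustering separates the two blocks perfectly
  dend <- hclust_expression(dv$expr)
  cut2 <- stats::cutree(stats::hclust(stats::as.dist(1 - cor(t(dv$expr))),
                                      "complete"), k = 2)
  expect_equal(length(unique(tapply(dv$truth$truth_block, cut2, function(b)
    length(unique(b))))), 1)
  expect_true(all(tapply(dv$truth$truth_block, cut2,
                         function(b) length(unique(b))) == 1))
  expect_error(generate_dev_expression(ids, n_stages = 1), "n_stages")
})
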