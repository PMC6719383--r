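test_that("max-gap clusters match the worked rank examples", {
  g <- mk_genome(c(A = 30))
  ids <- function(r) sprintf("A_g%02d", r)
  # consecutive ranks 5,6,7 -> one cluster of 3, 100% clustered
  r1 <- find_max_gap_clusters(ids(c(5, 6, 7)), g, max_gap = 5)
  expect_equal(r1$n_clusters, 1)
  expect_equal(r1$percent_clustered, 100)
  # ranks {1,8,9,20}: gap(1->8)=6 breaks; only {8,9} clusters
  r2 <- find_max_gap_clusters(ids(c(1, 8, 9, 20)), g, max_gap = 5)
  expect_equal(r2$n_clusters, 1)
  expect_equal(sort(r2$clusters$rank), c(8, 9))
  expect_equal(r2$percent_clustered, 50)
  expect_equal(unname(unclass(r2$size_distribution)["2"]), 1L)
  # empty set
  r0 <- find_max_gap_clusters(character(0), g)
  expect_equal(r0$n_clusters, 0)
  expect_equal(r0$percent_clustered, 0)
  # missing genes excluded with a message
  expect_message(find_max_gap_clusters(c(ids(5), "nope"), g), "absent")
})

test_that("clustering agrees with the exhaustive-scan oracle on small genomes", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    g <- mk_genome(stats::setNames(n, "A"))
    k <- sample(2:n, 1)
    test_ranks <- sort(sample(n, k))
    gap <- sample(0:4, 1)
    got <- find_max_gap_clusters(sprintf("A_g%02d", test_ranks), g, gap)
    want <- oracle_max_gap(list(A = test_ranks), gap)
    expect_equal(got$n_clusters, length(want))
    expect_equal(got$n_clustered, sum(lengths(want)))
  }
})

test_that("percent clustered is monotone in max_gap and rank-invariant", {
  set.seed(32)
  g <- mk_genome(c(A = 50, B = 50))
  test <- sample(g$gene_id, 20)
  pc <- vapply(0:8, function(gp)
    find_max_gap_clusters(test, g, gp)$percent_clustered, 0)
  expect_true(all(diff(pc) >= 0))
  # bp coordinates are irrelevant at fixed ranks
  g2 <- g
  g2$start <- g2$start * 17 + 3
  g2$end <- g2$start + 1
  g2 <- genome_table(as.data.frame(g2)[, 1:6])
  r_a <- find_max_gap_clusters(test, g, 3)
  r_b <- find_max_gap_clusters(test, g2, 3)
  expect_equal(r_a$n_clusters, r_b$n_clusters)
  expect_equal(sort(r_a$clusters$gene_id), sort(r_b$clusters$gene_id))
})

test_that("KS uniformity matches the closed-form D oracle", {
  # single midpoint at the arm centre
  k1 <- ks_uniformity(50, 100)
  expect_equal(k1$D, 0.5)
  # evenly spread triple
  k3 <- ks_uniformity(c(0.25, 0.5, 0.75) * 1000, 1000)
  expect_equal(k3$D, 0.25)
  # exact uniform grid approaches 1/(2n)
  n <- 40
  kg <- ks_uniformity((seq_len(n) - 0.5) / n, 1)
  expect_equal(kg$D, 1 / (2 * n), tolerance = 1e-9)
  expect_error(ks_uniformity(numeric(0), 1), "no positions")
  expect_error(ks_uniformity(5, c(0, 1)), "outside")
})

test_that("randomization null is exact on enumerable cases and +1 corrected", {
  g <- mk_genome(c(A = 10))
  # whole genome as test set: every draw identical, p = 1
  rn_all <- randomization_null(g$gene_id, g, max_gap = 0, n_iter = 30, seed = 1)
  expect_equal(rn_all$p_percent, 1)
  # list_size 2, max_gap 0: exact null over C(10,2) draws
  # percent clustered is 100 iff the two genes are adjacent: 9/45 draws
  adj <- find_max_gap_clusters(sprintf("A_g%02d", c(4, 5)), g, 0)
  expect_equal(adj$percent_clustered, 100)
  rn <- randomization_null(sprintf("A_g%02d", c(4, 5)), g, max_gap = 0,
                           n_iter = 2000, seed = 2)
  exact <- 9 / 45
  mc_se <- sqrt(exact * (1 - exact) / 2000)
  expect_lt(abs(rn$p_percent - exact), 3 * mc_se + 1 / 2001)
  expect_gte(rn$p_percent, 1 / 2001)
  expect_error(randomization_null(g$gene_id[1:2], g, n_iter = 0), "n_iter")
})

test_that("erosion scan localizes planted signal in the first window", {
  g <- mk_genome(c(A = 120, B = 120))
  pl <- plant_clustered_gene_set(g, n_clusters = 4, cluster_size = 5,
                                 max_internal_gap = 1, background_rate = 0,
                                 seed = 33)
  # synthesize a ranked result table: planted genes first, the rest in
  # random order (genome order would itself be perfectly clustered)
  others <- withr::with_seed(35, sample(setdiff(g$gene_id, pl$test_set)))
  res <- data.frame(gene_id = c(pl$test_set, others),
                    p_value = seq(1e-6, 1, length.out = nrow(g)))
  scan <- quiet(clustering_erosion_scan(res, g, window = 40, n_iter = 199,
                                        seed = 34))
  expect_equal(nrow(scan), 6)
  expect_lt(scan$p[1], median(scan$p[-1]))
  expect_warning(clustering_erosion_scan(res, g, window = 200, n_iter = 19),
                 "one window")
  expect_error(clustering_erosion_scan(res[1:10, ], g, window = 200), "fewer")
})
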