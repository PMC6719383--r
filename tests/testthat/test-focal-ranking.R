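test_that("preprocessing inverts, filters miRNA and drops unscored edges", {
  raw <- data.frame(source = c("A", "A", "C", "M"),
                    target = c("B", "B", "D", "A"),
                    confidence = c(0.9, 0.9, NA, 0.8))
  bio <- c(A = "protein_coding", B = "protein_coding", C = "protein_coding",
           D = "protein_coding", M = "miRNA")
  net <- quiet(preprocess_interactions(raw, bio))
  expect_setequal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$edges), 1)  # undirected A-B covers both directions
  g <- as_igraph(net)
  expect_setequal(names(igraph::neighbors(g, "A")), "B")
  expect_setequal(names(igraph::neighbors(g, "B")), "A")
})

test_that("focal scores are neighbor means, filtered and tie-broken", {
  net <- quiet(preprocess_interactions(data.frame(
    source = c("A", "A", "B", "X"), target = c("B", "C", "C", "Y"),
    confidence = 1)))
  lr <- c(A = 1, B = 2, C = 4, X = 3)  # Y unscored
  sc <- quiet(score_focal_genes(net, lr))
  expect_equal(sc$mean_lr[sc$gene_id == "A"], 3)       # mean(B=2, C=4)
  expect_equal(sc$n_interactors[sc$gene_id == "A"], 2)
  expect_equal(sc$mean_lr[sc$gene_id == "Y"], 3)       # X is scored
  # X's only neighbor (Y) lacks an LR value -> excluded, logged
  expect_false("X" %in% sc$gene_id)
  expect_equal(sc$rank, seq_len(nrow(sc)))
  # focal gene's own LR is irrelevant
  lr2 <- lr; lr2["A"] <- 1000
  sc2 <- quiet(score_focal_genes(net, lr2))
  expect_equal(sc2$mean_lr[sc2$gene_id == "A"],
               sc$mean_lr[sc$gene_id == "A"])
  # interactor-count filter
  sc3 <- quiet(score_focal_genes(net, lr, min_interactors = 2))
  expect_false("Y" %in% sc3$gene_id)
  expect_error(quiet(score_focal_genes(net, c(Z = 1))), "no focal gene")
})

test_that("top-rank intersection behaves on identical, disjoint and planted lists", {
  sc <- data.frame(gene_id = paste0("g", 1:10), mean_lr = 10:1,
                   n_interactors = 2, rank = 1:10)
  expect_equal(intersect_top_ranks(sc, sc, 5)$size, 5)
  sc2 <- sc; sc2$gene_id <- paste0("h", 1:10)
  expect_equal(intersect_top_ranks(sc, sc2, 5)$size, 0)
  expect_error(intersect_top_ranks(sc, sc, 11), "top_n")
})

test_that("interactor-count sensitivity reports stability and correlation", {
  sc <- data.frame(gene_id = sprintf("g%02d", 1:20),
                   mean_lr = seq(2, 40, by = 2), n_interactors = 1:20)
  sc <- sc[order(-sc$mean_lr), ]; sc$rank <- 1:20
  out <- interactor_count_sensitivity(sc, thresholds = c(1, 5), top_n = 10)
  expect_equal(out$cor$r, 1, tolerance = 1e-12)   # constructed monotone linear
  expect_equal(out$cor$df, 18)
  expect_equal(out$stability$jaccard_top[1], 1)
  flat <- sc; flat$mean_lr <- 5
  expect_true(interactor_count_sensitivity(flat)$cor$flagged)
  expect_error(interactor_count_sensitivity(sc[1:2, ]), ">= 3")
  # exchangeable null: |r| small at n = 5000
  set.seed(51)
  big <- data.frame(gene_id = sprintf("g%05d", 1:5000),
                    mean_lr = stats::rexp(5000),
                    n_interactors = sample(1:50, 5000, TRUE))
  big <- big[order(-big$mean_lr), ]; big$rank <- seq_len(nrow(big))
  expect_lt(abs(interactor_count_sensitivity(big)$cor$r), 3 / sqrt(5000))
})

test_that("genes beside planted high-LR neighborhoods rank at the top", {
  # pooled across replicate generators: genes whose scored interactors are
  # mostly boosted must land above the 90th rank percentile, and mere
  # adjacency to a boosted gene must shift the rank distribution upward
  dominated_pct <- c()
  shift_p <- c()
  for (s in 1:10) {
    ns <- generate_network_with_hotspots(sim_config(seed = 520 + s),
                                         n_hotspots = 5, boost = 8)
    net <- preprocess_interactions(ns$network$edges)
    sc <- quiet(score_focal_genes(net, ns$attributes))
    hot <- ns$truth$gene_id[ns$truth$truth_hotspot]
    g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
    nb <- igraph::adjacent_vertices(g, igraph::V(g))
    share <- vapply(nb, function(v) mean(names(v) %in% hot), 0)
    names(share) <- igraph::V(g)$name
    pctile <- 1 - (sc$rank - 1) / nrow(sc)
    dom <- intersect(names(share)[share >= 0.5], sc$gene_id)
    dominated_pct <- c(dominated_pct, pctile[match(dom, sc$gene_id)])
    adj <- intersect(names(share)[share > 0], sc$gene_id)
    non <- setdiff(sc$gene_id, adj)
    shift_p <- c(shift_p, stats::wilcox.test(
      pctile[match(adj, sc$gene_id)], pctile[match(non, sc$gene_id)],
      alternative = "greater")$p.value)
  }
  expect_gte(length(dominated_pct), 5)
  expect_gte(mean(dominated_pct > 0.9), 0.9)
  # adjacency shifts ranks upward in every replicate
  expect_lt(max(shift_p), 0.01)
})
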