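test_that("expression clustering merges identical profiles first and flags constants", {
  expr <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2 + 0.001,
                c = c(4, 3, 2, 1))
  # a and b are perfectly correlated -> cophenetic distance ~0 (first merge)
  d <- hclust_expression(expr)
  co <- as.matrix(stats::cophenetic(d))
  expect_lt(co["a", "b"], 1e-6)
  expect_gt(min(co["a", "c"], co["b", "c"]), 1)
  expr2 <- rbind(expr, flat = c(5, 5, 5, 5))
  expect_message(d2 <- hclust_expression(expr2), "zero-variance")
  expect_equal(attr(d2, "excluded"), "flat")
  expect_error(hclust_expression(expr[1:1, , drop = FALSE]), ">= 2")
})

test_that("entanglement matches the direct formula on worked cases", {
  t1 <- random_dend(6, 71)
  expect_equal(entanglement(t1, t1), 0)
  # exactly reversed leaf order scores 1
  rev_d <- stats::as.dendrogram(rev(t1))
  expect_equal(entanglement(t1, rev_d), 1, tolerance = 1e-12)
  # 3 leaves, orders (A,B,C) vs (A,C,B), L = 1.5 -> 2 / (2*2^1.5)
  ta <- mk_chain_dend(c("A", "B", "C")); tb <- mk_chain_dend(c("A", "C", "B"))
  expect_equal(labels(ta), c("A", "B", "C"))
  expect_equal(labels(tb), c("A", "C", "B"))
  expect_equal(entanglement(ta, tb), 2 / (2 * 2^1.5), tolerance = 1e-12)
  tx <- random_dend(4, 72)
  expect_error(entanglement(t1, tx), "leaf sets differ")
})

test_that("step2side never increases entanglement and solves easy flips", {
  t1 <- random_dend(4, 73)
  # flipping the root of a copy is undone by one rotation
  t2 <- stats::as.dendrogram(rev(t1))
  u <- untangle_step2side(t1, t2)
  expect_equal(u$entanglement, 0)
  expect_equal(untangle_step2side(t1, t1)$entanglement, 0)
  set.seed(74)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    a <- random_dend(n)
    b <- random_dend(n)  # same label set L01..Ln by construction
    e0 <- entanglement(a, b)
    expect_lte(untangle_step2side(a, b)$entanglement, e0)
  }
})

test_that("gamma equals brute force on small trees and 1 on identity", {
  t1 <- random_dend(5, 75)
  expect_equal(gk_gamma(t1, t1), 1)
  set.seed(76)
  for (rep in 1:10) {
    n <- sample(4:5, 1)
    a <- random_dend(n)
    b <- random_dend(n)
    expect_equal(gk_gamma(a, b), oracle_gk_gamma(a, b), tolerance = 1e-12)
  }
  expect_error(gk_gamma(random_dend(3, 1)[[1]], random_dend(3, 1)[[1]]))
})

test_that("gamma permutation test is seeded and centred near zero under shuffling", {
  a <- random_dend(40, 77)
  b <- random_dend(40, 78)
  g1 <- gamma_permutation_test(a, b, n_perm = 30, seed = 9)
  g2 <- gamma_permutation_test(a, b, n_perm = 30, seed = 9)
  expect_identical(g1$null, g2$null)
  se <- stats::sd(g1$null) / sqrt(30)
  expect_lt(abs(g1$null_mean), 3 * se + 0.02)
  # identical trees: observed gamma = 1 sits far above the null
  gi <- gamma_permutation_test(a, a, n_perm = 30, seed = 10)
  expect_equal(gi$observed, 1)
  expect_lt(gi$p_vs_observed, 0.01)
  expect_error(gamma_permutation_test(a, b, n_perm = 0), "n_perm")
})

test_that("cophenetic correlation matches hand computation and flags degeneracy", {
  t1 <- random_dend(7, 79)
  expect_equal(cophenetic_correlation(t1, t1), 1)
  t2 <- random_dend(7, 80)
  ca <- as.matrix(stats::cophenetic(t1)); cb <- as.matrix(stats::cophenetic(t2))
  lab <- sort(rownames(ca))
  hand <- stats::cor(ca[lab, lab][upper.tri(ca)], cb[lab, lab][upper.tri(cb)])
  expect_equal(cophenetic_correlation(t1, t2), hand, tolerance = 1e-12)
  # single-height tree: zero variance -> flagged NA
  x <- matrix(c(0, 2), ncol = 1, dimnames = list(c("A", "B"), NULL))
  single <- stats::as.dendrogram(stats::hclust(stats::dist(x)))
  flagged <- cophenetic_correlation(single, single)
  expect_true(is.na(flagged))
  expect_true(attr(flagged, "flagged"))
})

test_that("rolling sums follow the direct-summation oracle", {
  out <- rolling_membership_scan(c("a", "b", "c", "d", "e"),
                                 c("a", "c", "d"), window = 2)
  expect_equal(out$sums, c(1, 1, 2, 1))
  all_in <- rolling_membership_scan(paste0("g", 1:60), paste0("g", 1:60), 50)
  expect_true(all(all_in$sums == 50))
  none <- rolling_membership_scan(paste0("g", 1:10), character(0), 3)
  expect_true(all(none$sums == 0))
  expect_error(rolling_membership_scan(paste0("g", 1:10), "g1", 11), "window")
  # conservation: each position i is covered by min(w, n-w+1, i, n-i+1) windows
  set.seed(81)
  ord <- sprintf("g%02d", 1:30)
  members <- sample(ord, 12)
  w <- 7
  scan <- rolling_membership_scan(ord, members, w)
  cover <- vapply(seq_along(ord), function(i)
    min(w, length(ord) - w + 1, i, length(ord) - i + 1), 0)
  expect_equal(sum(scan$sums), sum(cover * (ord %in% members)))
})
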