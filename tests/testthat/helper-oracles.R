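# Independent oracles and tiny fixture builders shared across the suite.
# Oracles deliberately use brute force / direct definitions, never package
# internals, so they stay independent of the code paths they check.

# A genome table with one gene per rank on the given arms (unit spacing).
mk_genome <- function(n_per_arm, arms = names(n_per_arm)) {
  if (is.null(arms)) arms <- paste0("A", seq_along(n_per_arm))
  df <- do.call(rbind, lapply(seq_along(arms), function(i) {
    n <- n_per_arm[i]
    data.frame(
      gene_id = sprintf("%s_g%02d", arms[i], seq_len(n)),
      arm = arms[i],
      start = (seq_len(n) - 1) * 1000,
      end = (seq_len(n) - 1) * 1000 + 500,
      stringsAsFactors = FALSE)
  }))
  genome_table(df)
}

# Brute-force max-gap clustering: exhaustive scan over runs of test ranks.
oracle_max_gap <- function(test_ranks_by_arm, max_gap, min_size = 2) {
  clusters <- list()
  for (a in names(test_ranks_by_arm)) {
    r <- sort(test_ranks_by_arm[[a]])
    if (!length(r)) next
    cur <- r[1]
    for (x in r[-1]) {
      if (x - cur[length(cur)] - 1 <= max_gap) cur <- c(cur, x)
      else {
        if (length(cur) >= min_size) clusters[[length(clusters) + 1]] <- cur
        cur <- x
      }
    }
    if (length(cur) >= min_size) clusters[[length(clusters) + 1]] <- cur
  }
  clusters
}

# Step-up BH by its literal definition: q(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# All permutations of 1..n (n <= 7).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exact SAFE per-node p by full enumeration of attribute permutations.
oracle_safe_exact <- function(edges, attrs, radius = 1) {
  nodes <- sort(unique(c(edges$source, edges$target, names(attrs))))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$source[i], edges$target[i]] <- TRUE
    adj[edges$target[i], edges$source[i]] <- TRUE
  }
  ball <- diag(n) > 0
  reach <- ball
  for (d in seq_len(radius)) {
    reach <- reach | (reach %*% adj) > 0
  }
  a <- attrs[nodes]
  obs <- as.numeric(reach %*% a)
  perms <- all_perms(n)
  counts <- integer(n)
  tol <- 1e-9 * (1 + max(abs(obs)))
  for (r in seq_len(nrow(perms))) {
    counts <- counts + (as.numeric(reach %*% a[perms[r, ]]) >= obs - tol)
  }
  stats::setNames(counts / nrow(perms), nodes)
}

# Brute-force Goodman-Kruskal gamma over all pairs of leaf pairs.
oracle_gk_gamma <- function(dend_a, dend_b) {
  ca <- as.matrix(stats::cophenetic(dend_a))
  cb <- as.matrix(stats::cophenetic(dend_b))
  lab <- sort(rownames(ca))
  ca <- ca[lab, lab]; cb <- cb[lab, lab]
  ut <- upper.tri(ca)
  x <- ca[ut]; y <- cb[ut]
  C <- D <- 0
  m <- length(x)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
    if (sx == 0 || sy == 0) next
    if (sx == sy) C <- C + 1 else D <- D + 1
  }
  if (C + D == 0) return(NA_real_)
  (C - D) / (C + D)
}

# Left-deep caterpillar dendrogram with the exact leaf order given:
# ((l1, l2), l3), l4) ... with merge heights 1, 2, 3, ...
mk_chain_dend <- function(labs) {
  mk_leaf <- function(i, lab) {
    structure(i, members = 1L, height = 0, label = lab, leaf = TRUE,
              class = "dendrogram")
  }
  node <- mk_leaf(1L, labs[1])
  for (i in seq_along(labs)[-1]) {
    node <- structure(list(node, mk_leaf(i, labs[i])),
                      members = i, height = i - 1, class = "dendrogram")
  }
  node
}

# Random ultrametric dendrogram over n labelled leaves.
random_dend <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rnorm(n * 6), n)
  rownames(x) <- sprintf("L%02d", seq_len(n))
  stats::as.dendrogram(stats::hclust(stats::dist(x), method = "complete"))
}

# Exhaustive minimum entanglement over all child-order choices of both trees.
oracle_min_entanglement <- function(dend_a, dend_b, L = 1.5) {
  variants <- function(node) {
    if (is.leaf(node)) return(list(node))
    kids <- lapply(node, variants)
    out <- list()
    for (left in kids[[1]]) for (right in kids[[2]]) {
      for (flip in c(FALSE, TRUE)) {
        v <- if (flip) list(right, left) else list(left, right)
        attributes(v) <- attributes(node)
        out[[length(out) + 1]] <- v
      }
    }
    out
  }
  best <- Inf
  for (va in variants(dend_a)) for (vb in variants(dend_b)) {
    best <- min(best, entanglement(va, vb, L))
  }
  best
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
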