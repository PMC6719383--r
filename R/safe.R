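#' Network neighborhood enrichment (SAFE-style)
#'
#' Each node's neighborhood is the unweighted shortest-path ball of radius
#' `d` (default 1, always containing the focal node). The neighborhood sum
#' of a -log10(p) attribute is compared with a permutation null that
#' shuffles attribute values over nodes; the per-node empirical p (with +1
#' correction) is converted to a heat score `-log10 p`.
#'
#' @name network-enrichment
NULL

#' Shortest-path ball neighborhoods
#'
#' @param net an [interaction_network()].
#' @param d radius (>= 0); d = 0 gives `{self}` everywhere.
#' @return named list of character vectors (each includes the focal node).
#' @export
neighborhoods <- function(net, d = 1L) {
  stopifnot(inherits(net, "interaction_network"), d >= 0)
  g <- as_igraph(net)
  out <- lapply(igraph::ego(g, order = d, nodes = igraph::V(g), mode = "all"),
                names)
  names(out) <- igraph::V(g)$name
  out[net$nodes]
}

#' SAFE-style permutation enrichment field
#'
#' @param net an [interaction_network()].
#' @param attributes named numeric vector of -log10 p attributes; nodes
#'   missing from it are imputed as 0 with a logged count.
#' @param radius neighborhood radius (default 1).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param alpha flagging level on the raw empirical p (a BH-adjusted column
#'   is also returned for stricter selections).
#' @return data.frame: gene_id, n_neighbors, sum, p, fdr, heat (-log10 p),
#'   enriched.
#' @export
safe_enrichment <- function(net, attributes, radius = 1L, n_perm = 1000L,
                            seed = 1L, alpha = 0.05) {
  if (n_perm <= 0) stop("n_perm must be >= 1")
  nodes <- net$nodes
  n <- length(nodes)
  miss <- setdiff(nodes, names(attributes))
  if (length(miss)) {
    msg("safe: %d node(s) missing attributes, imputed 0", length(miss))
    attributes[miss] <- 0
  }
  a <- unname(attributes[nodes])
  if (any(!is.finite(a))) stop("attributes must be finite")
  nb <- neighborhoods(net, radius)
  # sparse membership matrix: M[i, j] = 1 if node i in neighborhood of j
  j <- rep(seq_len(n), lengths(nb[nodes]))
  i <- match(unlist(nb[nodes], use.names = FALSE), nodes)
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  obs <- as.numeric(Matrix::crossprod(M, a))
  with_seed(seed, {
    exceed <- integer(n)
    tol <- 1e-9 * (1 + max(abs(obs)))  # tied sums must count as exceedances
    for (b in seq_len(n_perm)) {
      perm <- as.numeric(Matrix::crossprod(M, sample(a)))
      exceed <- exceed + (perm >= obs - tol)
    }
    p <- (1 + exceed) / (n_perm + 1)
    fdr <- bh_adjust(p)
    data.frame(gene_id = nodes, n_neighbors = lengths(nb[nodes]),
               sum = obs, p = p, fdr = fdr, heat = -log10(p),
               enriched = p <= alpha, stringsAsFactors = FALSE)
  })
}

#' Per-node degree and neighborhood connectivity
#'
#' Neighborhood connectivity of a node is the mean degree of its direct
#' neighbors (NA for isolated nodes).
#'
#' @param net an [interaction_network()].
#' @return data.frame: gene_id, degree, neighborhood_connectivity.
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (!length(net$nodes)) stop("empty network")
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  deg <- igraph::degree(g)
  nc <- suppressWarnings(igraph::knn(g)$knn)
  nc[deg == 0] <- NA_real_
  data.frame(gene_id = igraph::V(g)$name, degree = unname(deg),
             neighborhood_connectivity = unname(nc),
             stringsAsFactors = FALSE)[match(net$nodes, igraph::V(g)$name), ]
}

#' Welch two-sample comparison of a node metric between gene groups
#'
#' @param values named numeric vector (e.g. degree per gene).
#' @param group_a,group_b character id vectors (>= 2 finite values each).
#' @return list(t, df, p, mean_a, mean_b).
#' @export
compare_groups_welch <- function(values, group_a, group_b) {
  va <- values[names(values) %in% group_a]
  vb <- values[names(values) %in% group_b]
  va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
  if (length(va) < 2 || length(vb) < 2) stop("each group needs >= 2 values")
  if (stats::var(va) == 0 && stats::var(vb) == 0) {
    if (mean(va) == mean(vb)) {
      return(list(t = 0, df = NA_real_, p = 1,
                  mean_a = mean(va), mean_b = mean(vb)))
    }
    stop("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(va, vb, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(va), mean_b = mean(vb))
}
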