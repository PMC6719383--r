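#' Max-gap physical clustering along chromosome arms
#'
#' A cluster is a maximal run of >= `min_size` test-set genes on one arm in
#' which consecutive members are separated by at most `max_gap` intervening
#' non-member genes. Gaps are counted in gene ranks, not base pairs, so the
#' statistic is invariant to coordinate rescaling at fixed gene order.
#' Uniformity of the test genes' physical positions is assessed per arm with
#' a two-sided Kolmogorov-Smirnov test on midpoints scaled by the arm span,
#' and overall clustering against a null of randomly drawn gene lists of the
#' same size.
#'
#' @name genome-clustering
NULL

#' Find max-gap clusters of a gene list
#'
#' @param test_set character vector of gene ids.
#' @param genome a [genome_table()].
#' @param max_gap maximum number of non-member genes between consecutive
#'   members of a cluster (default 5).
#' @param min_size minimum genes per cluster (default 2; singletons are not
#'   clusters).
#' @return a `cluster_report` list: `clusters` (data.frame cluster, arm,
#'   gene_id, rank), `n_clusters`, `n_clustered`, `percent_clustered`,
#'   `size_distribution` (table), `n_test`, `n_missing`.
#' @export
find_max_gap_clusters <- function(test_set, genome, max_gap = 5L, min_size = 2L) {
  stopifnot(inherits(genome, "genome_table"), max_gap >= 0, min_size >= 1)
  rk <- genome_ranks(genome)
  test_set <- unique(as.character(test_set))
  n_missing <- sum(!(test_set %in% rk$gene_id))
  if (n_missing > 0) msg("clustering: %d test gene(s) absent from genome, excluded",
                         n_missing)
  hit <- rk[rk$gene_id %in% test_set, , drop = FALSE]
  clusters <- list(); cl_id <- 0L
  for (a in unique(hit$arm)) {
    r <- sort(hit$rank[hit$arm == a])
    if (!length(r)) next
    run_id <- cumsum(c(1L, diff(r) - 1L > max_gap))
    for (run in split(r, run_id)) {
      if (length(run) >= min_size) {
        cl_id <- cl_id + 1L
        ids <- rk$gene_id[rk$arm == a][match(run, rk$rank[rk$arm == a])]
        clusters[[cl_id]] <- data.frame(cluster = cl_id, arm = a,
                                        gene_id = ids, rank = run,
                                        stringsAsFactors = FALSE)
      }
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters)
              else data.frame(cluster = integer(), arm = character(),
                              gene_id = character(), rank = integer())
  n_test <- length(test_set) - n_missing
  n_clustered <- nrow(clusters)
  sizes <- if (cl_id > 0) table(table(clusters$cluster)) else table(integer(0))
  structure(list(
    clusters = clusters, n_clusters = cl_id, n_clustered = n_clustered,
    percent_clustered = if (n_test > 0) 100 * n_clustered / n_test else 0,
    size_distribution = sizes, n_test = n_test, n_missing = n_missing,
    max_gap = max_gap, min_size = min_size), class = "cluster_report")
}

#' @export
#' @method print cluster_report
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: %d clusters, %d/%d genes clustered (%.1f%%), max_gap=%d\n",
              x$n_clusters, x$n_clustered, x$n_test, x$percent_clustered,
              x$max_gap))
  invisible(x)
}

#' KS test of positional uniformity along one arm
#'
#' @param positions bp midpoints of test genes on the arm.
#' @param extent arm extent; either a single length or `c(lo, hi)`.
#' @return list(D, p) from a two-sided one-sample KS test against
#'   Uniform(0,1) after scaling (exact p for n <= 100).
#' @export
ks_uniformity <- function(positions, extent) {
  if (!length(positions)) stop("no positions supplied")
  if (length(extent) == 1L) extent <- c(0, extent)
  if (any(positions < extent[1] | positions > extent[2])) {
    stop("positions outside arm extent")
  }
  x <- (positions - extent[1]) / diff(extent)
  kt <- suppressWarnings(stats::ks.test(x, "punif"))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Per-arm KS uniformity for a test set
#' @param test_set gene ids.
#' @param genome a [genome_table()].
#' @return data.frame arm, n, D, p (arms with no test genes omitted).
#' @export
ks_uniformity_by_arm <- function(test_set, genome) {
  g <- genome[genome$gene_id %in% test_set, , drop = FALSE]
  do.call(rbind, lapply(unique(g$arm), function(a) {
    span <- range(genome$midpoint[genome$arm == a])
    kt <- ks_uniformity(g$midpoint[g$arm == a], span)
    data.frame(arm = a, n = sum(g$arm == a), D = kt$D, p = kt$p)
  }))
}

#' Randomization null for clustering statistics
#'
#' Draws `n_iter` random gene lists of the observed size from the genome and
#' recomputes percent clustered and cluster count; empirical p uses the +1
#' correction so it is never exactly zero and is bounded below by
#' `1/(n_iter+1)`.
#'
#' @param test_set observed gene list.
#' @param genome a [genome_table()].
#' @param max_gap,min_size as in [find_max_gap_clusters()].
#' @param n_iter number of random lists (default 1000).
#' @param seed integer seed.
#' @return list: observed report, `p_percent`, `p_nclusters`, and the null
#'   draws (`null_percent`, `null_nclusters`).
#' @export
randomization_null <- function(test_set, genome, max_gap = 5L, min_size = 2L,
                               n_iter = 1000L, seed = 1L) {
  if (n_iter <= 0) stop("n_iter must be >= 1")
  obs <- find_max_gap_clusters(test_set, genome, max_gap, min_size)
  list_size <- obs$n_test
  if (list_size > nrow(genome)) stop("list size exceeds genome size")
  ids <- genome$gene_id
  with_seed(seed, {
    null_percent <- numeric(n_iter); null_ncl <- integer(n_iter)
    for (i in seq_len(n_iter)) {
      rep_i <- find_max_gap_clusters(sample(ids, list_size), genome,
                                     max_gap, min_size)
      null_percent[i] <- rep_i$percent_clustered
      null_ncl[i] <- rep_i$n_clusters
    }
    list(observed = obs,
         p_percent = (1 + sum(null_percent >= obs$percent_clustered)) / (n_iter + 1),
         p_nclusters = (1 + sum(null_ncl >= obs$n_clusters)) / (n_iter + 1),
         null_percent = null_percent, null_nclusters = null_ncl,
         n_iter = n_iter)
  })
}

#' Clustering erosion across p-value-ranked windows
#'
#' Splits p-ranked genes into sequential windows (default 200 genes) and
#' reports the randomization p of percent clustered for each window; in a
#' signal-bearing list the early windows cluster and later windows decay to
#' the null.
#'
#' @param results DE results (gene_id, p_value) for one contrast/sex.
#' @param genome a [genome_table()].
#' @param window genes per window.
#' @param max_gap,min_size,n_iter,seed forwarded to [randomization_null()].
#' @return data.frame window, from_rank, to_rank, percent_clustered, p.
#' @export
clustering_erosion_scan <- function(results, genome, window = 200L,
                                    max_gap = 5L, min_size = 2L,
                                    n_iter = 1000L, seed = 1L) {
  res <- results[!is.na(results$p_value), , drop = FALSE]
  n_windows <- floor(nrow(res) / window)
  if (n_windows < 1) stop("fewer genes than one window")
  if (n_windows == 1) warning("only one window; erosion scan degenerates")
  ord <- top_n_by_pvalue(res, n_windows * window)
  do.call(rbind, lapply(seq_len(n_windows), function(k) {
    idx <- ((k - 1) * window + 1):(k * window)
    rn <- randomization_null(ord[idx], genome, max_gap, min_size, n_iter,
                             seed = child_seed(seed, paste0("window", k)))
    data.frame(window = k, from_rank = idx[1], to_rank = idx[length(idx)],
               percent_clustered = rn$observed$percent_clustered,
               p = rn$p_percent)
  }))
}
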