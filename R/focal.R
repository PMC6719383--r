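#' Focal-gene neighborhood scoring
#'
#' Scores each focal gene by the mean likelihood-ratio statistic of its
#' direct interactors in a preprocessed protein-interaction network; high
#' scores mark genes whose immediate network context is dense in
#' mtDNA-sensitive genes even when the focal gene itself is not. Top-ranked
#' lists are intersected across sexes to find conserved hubs of sensitivity.
#'
#' @name focal-ranking
NULL

#' Preprocess a raw scored interaction list
#'
#' Reciprocally inverts edges (A->B implies B->A), removes edges incident to
#' miRNA genes, removes edges without a confidence score, and collapses
#' duplicates. The result is an undirected network whose neighbor sets equal
#' the direct-interactor sets of the inverted directed network.
#'
#' @param edges data.frame source, target, confidence (NA = unscored).
#' @param biotypes named character vector gene_id -> biotype; edges touching
#'   `miRNA` genes are dropped.
#' @return an [interaction_network()] (undirected).
#' @export
preprocess_interactions <- function(edges, biotypes = character(0)) {
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  n0 <- nrow(edges)
  if (!("confidence" %in% names(edges))) edges$confidence <- NA_real_
  keep <- !is.na(edges$confidence)
  if (any(!keep)) msg("preprocess: removed %d unscored edge(s)", sum(!keep))
  edges <- edges[keep, , drop = FALSE]
  if (length(biotypes)) {
    mirna <- names(biotypes)[biotypes == "miRNA"]
    hit <- edges$source %in% mirna | edges$target %in% mirna
    if (any(hit)) msg("preprocess: removed %d miRNA-incident edge(s)", sum(hit))
    edges <- edges[!hit, , drop = FALSE]
  }
  interaction_network(edges, directed = FALSE)
}

#' Score focal genes by mean interactor LR
#'
#' @param net a preprocessed [interaction_network()].
#' @param lr named numeric vector gene_id -> likelihood ratio.
#' @param min_interactors minimum scored interactors to keep a focal gene.
#' @return data.frame gene_id, mean_lr, n_interactors, rank (descending
#'   mean_lr, ties broken lexicographically by gene_id).
#' @export
score_focal_genes <- function(net, lr, min_interactors = 1L) {
  stopifnot(inherits(net, "interaction_network"), min_interactors >= 1)
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  nb <- igraph::adjacent_vertices(g, igraph::V(g))
  scores <- vapply(nb, function(v) {
    vals <- lr[names(v)]
    vals <- vals[!is.na(vals)]
    c(mean_lr = if (length(vals)) mean(vals) else NA_real_,
      n = length(vals))
  }, c(mean_lr = 0, n = 0))
  tab <- data.frame(gene_id = igraph::V(g)$name,
                    mean_lr = scores["mean_lr", ],
                    n_interactors = as.integer(scores["n", ]),
                    stringsAsFactors = FALSE)
  dropped <- sum(is.na(tab$mean_lr) | tab$n_interactors < min_interactors)
  if (dropped) msg("focal: excluded %d gene(s) with < %d scored interactor(s)",
                   dropped, min_interactors)
  tab <- tab[!is.na(tab$mean_lr) & tab$n_interactors >= min_interactors, ,
             drop = FALSE]
  if (!nrow(tab)) stop("no focal gene passes the interactor filter")
  tab <- tab[order(-tab$mean_lr, tab$gene_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Intersect top-ranked focal genes across two score tables
#'
#' @param scores_a,scores_b tables from [score_focal_genes()].
#' @param top_n list depth (default 200).
#' @return list: `shared` (sorted gene ids), `size`.
#' @export
intersect_top_ranks <- function(scores_a, scores_b, top_n = 200L) {
  if (top_n > nrow(scores_a) || top_n > nrow(scores_b)) {
    stop("top_n exceeds a score table")
  }
  shared <- sort(intersect(scores_a$gene_id[seq_len(top_n)],
                           scores_b$gene_id[seq_len(top_n)]))
  list(shared = shared, size = length(shared))
}

#' Sensitivity of the ranking to the interactor-count filter
#'
#' For each threshold, recomputes the ranking restricted to focal genes with
#' at least that many scored interactors and reports the Jaccard overlap of
#' its top-`top_n` set with the threshold-1 baseline, plus the Pearson
#' correlation between interactor count and mean LR (df = n - 2).
#'
#' @param scores table from [score_focal_genes()] at min_interactors = 1.
#' @param thresholds integer vector of minimum interactor counts.
#' @param top_n list depth for the stability comparison.
#' @return list: `stability` (data.frame threshold, n_genes, jaccard_top),
#'   `cor` (list r, df, p; r is NA with a flag when mean_lr is constant).
#' @export
interactor_count_sensitivity <- function(scores, thresholds = c(1L, 2L, 5L, 10L),
                                         top_n = 200L) {
  if (nrow(scores) < 3) stop("need >= 3 scored focal genes")
  base_top <- scores$gene_id[seq_len(min(top_n, nrow(scores)))]
  stability <- do.call(rbind, lapply(thresholds, function(th) {
    sub <- scores[scores$n_interactors >= th, , drop = FALSE]
    top <- sub$gene_id[seq_len(min(top_n, nrow(sub)))]
    data.frame(threshold = th, n_genes = nrow(sub),
               jaccard_top = length(intersect(top, base_top)) /
                 length(union(top, base_top)))
  }))
  if (stats::sd(scores$mean_lr) == 0 || stats::sd(scores$n_interactors) == 0) {
    corr <- list(r = NA_real_, df = nrow(scores) - 2L, p = NA_real_,
                 flagged = TRUE)
  } else {
    ct <- stats::cor.test(scores$n_interactors, scores$mean_lr)
    corr <- list(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value, flagged = FALSE)
  }
  list(stability = stability, cor = corr)
}
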