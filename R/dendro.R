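#' Dendrogram concordance statistics
#'
#' Tools for asking whether two hierarchical clusterings of the same genes
#' (e.g. adult mtDNA-sensitivity profiles vs a developmental time course)
#' sort the genes concordantly: entanglement of the leaf orders, a greedy
#' step2side untangling that only rotates children, Goodman-Kruskal gamma on
#' cophenetic merge ranks with a leaf-shuffling permutation null, cophenetic
#' correlation, and a rolling membership scan along the leaf order.
#'
#' @name temporal-concordance
NULL

#' Hierarchical clustering of expression profiles
#'
#' Distance is `1 - Pearson correlation` between gene profiles (rows) by
#' default, with complete linkage. Zero-variance profiles cannot be
#' correlated and are excluded with their ids logged.
#'
#' @param expr genes x conditions numeric matrix with rownames.
#' @param distance "pearson" (1 - r) or "euclidean".
#' @param linkage agglomeration method for [stats::hclust()].
#' @return a [stats::dendrogram]; excluded gene ids in attr "excluded".
#' @export
hclust_expression <- function(expr, distance = c("pearson", "euclidean"),
                              linkage = "complete") {
  distance <- match.arg(distance)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  v <- apply(expr, 1, stats::var)
  excl <- rownames(expr)[v == 0 | is.na(v)]
  if (length(excl)) {
    msg("hclust: excluded %d zero-variance profile(s): %s", length(excl),
        paste(utils::head(excl, 3), collapse = ", "))
    expr <- expr[!(rownames(expr) %in% excl), , drop = FALSE]
  }
  if (nrow(expr) < 2) stop("need >= 2 genes with variable profiles")
  d <- if (distance == "pearson") stats::as.dist(1 - stats::cor(t(expr)))
       else stats::dist(expr)
  dend <- stats::as.dendrogram(stats::hclust(d, method = linkage))
  attr(dend, "excluded") <- excl
  dend
}

leaf_positions <- function(dend) {
  lab <- labels(dend)
  stats::setNames(seq_along(lab), lab)
}

#' Entanglement between two leaf orders
#'
#' With leaf ranks r^A, r^B (positions 1..n of each shared label in the two
#' trees' left-to-right orders), entanglement is
#' `sum |r^A - r^B|^L / sum |i - (n+1-i)|^L`: 0 for identical orders, 1 for
#' exactly reversed orders.
#'
#' @param dend_a,dend_b dendrograms over the same leaf set.
#' @param L norm exponent (default 1.5).
#' @return entanglement in \[0,1\].
#' @export
entanglement <- function(dend_a, dend_b, L = 1.5) {
  pa <- leaf_positions(dend_a); pb <- leaf_positions(dend_b)
  if (!setequal(names(pa), names(pb))) {
    diffs <- c(setdiff(names(pa), names(pb)), setdiff(names(pb), names(pa)))
    stop("leaf sets differ: ", paste(utils::head(diffs, 5), collapse = ", "))
  }
  n <- length(pa)
  num <- sum(abs(pa - pb[names(pa)])^L)
  den <- sum(abs(seq_len(n) - (n + 1 - seq_len(n)))^L)
  if (den == 0) return(0)
  num / den
}

internal_node_paths <- function(node, prefix = integer(0)) {
  if (is.leaf(node)) return(list())
  out <- list(prefix)
  for (i in seq_along(node)) {
    out <- c(out, internal_node_paths(node[[i]], c(prefix, i)))
  }
  out
}

flip_children_at <- function(dend, path) {
  if (!length(path)) {
    at <- attributes(dend)
    out <- dend[rev(seq_along(dend))]
    attributes(out) <- at
    return(out)
  }
  dend[[path[1]]] <- flip_children_at(dend[[path[1]]], path[-1])
  dend
}

#' Greedy step2side untangling
#'
#' Alternates single-side passes: every internal node's children are flipped
#' if (and only if) the flip strictly lowers entanglement, sweeping side A
#' then side B until a sweep yields no improvement. When single flips stall
#' and the trees are small enough (`joint_max_leaves`), a joint phase tries
#' flipping one node in each tree simultaneously to escape local optima that
#' one-sided rotation cannot leave. Topology and merge heights are
#' untouched; only child order changes, so the result never has higher
#' entanglement than the input.
#'
#' @param dend_a,dend_b dendrograms over the same leaf set.
#' @param L norm exponent.
#' @param max_rounds maximum A+B sweep rounds.
#' @param joint_max_leaves joint-flip escape is attempted only below this
#'   leaf count (it costs O(n^2) entanglement evaluations per round).
#' @return list(dend_a, dend_b, entanglement).
#' @export
untangle_step2side <- function(dend_a, dend_b, L = 1.5, max_rounds = 20L,
                               joint_max_leaves = 200L) {
  best <- entanglement(dend_a, dend_b, L)
  n_leaves <- length(labels(dend_a))
  sweep_side <- function(side) {
    tree <- if (side == "a") dend_a else dend_b
    # re-enumerate after every accepted flip: child indices in deeper
    # paths go stale once an ancestor's children are reversed
    repeat {
      flipped <- FALSE
      for (path in internal_node_paths(tree)) {
        cand <- flip_children_at(tree, path)
        e <- if (side == "a") entanglement(cand, dend_b, L)
             else entanglement(dend_a, cand, L)
        if (e < best) {
          best <<- e
          tree <- cand
          flipped <- TRUE
          break
        }
      }
      if (!flipped) break
    }
    if (side == "a") dend_a <<- tree else dend_b <<- tree
  }
  for (round in seq_len(max_rounds)) {
    before <- best
    sweep_side("a")
    sweep_side("b")
    if (best < before) next
    if (n_leaves > joint_max_leaves) break
    # joint escape: one flip on each side at once
    jumped <- FALSE
    for (pa in internal_node_paths(dend_a)) {
      cand_a <- flip_children_at(dend_a, pa)
      for (pb in internal_node_paths(dend_b)) {
        e <- entanglement(cand_a, flip_children_at(dend_b, pb), L)
        if (e < best) {
          best <- e
          dend_a <- cand_a
          dend_b <- flip_children_at(dend_b, pb)
          jumped <- TRUE
          break
        }
      }
      if (jumped) break
    }
    if (!jumped) break
  }
  list(dend_a = dend_a, dend_b = dend_b, entanglement = best)
}

cophenetic_aligned <- function(dend_a, dend_b) {
  ca <- as.matrix(stats::cophenetic(dend_a))
  cb <- as.matrix(stats::cophenetic(dend_b))
  if (!setequal(rownames(ca), rownames(cb))) stop("leaf sets differ")
  lab <- sort(rownames(ca))
  ca <- ca[lab, lab]; cb <- cb[lab, lab]
  ut <- upper.tri(ca)
  list(x = ca[ut], y = cb[ut])
}

# Concordant-minus-discordant counts from an ordinal contingency table.
gamma_from_table <- function(tab) {
  r <- nrow(tab); s <- ncol(tab)
  if (r < 2 || s < 2) return(list(C = 0, D = 0))
  # prefix[i, j] = sum of tab[1:i, 1:j]
  prefix <- apply(apply(tab, 2, cumsum), 1, cumsum)
  prefix <- t(prefix)
  total <- prefix[r, s]
  C <- D <- 0
  for (i in seq_len(r)) for (j in seq_len(s)) {
    nij <- tab[i, j]
    if (nij == 0) next
    below_left <- if (i > 1 && j > 1) prefix[i - 1, j - 1] else 0
    above_right <- total - prefix[i, s] - prefix[r, j] + prefix[i, j]
    below_right <- if (i > 1) prefix[i - 1, s] - prefix[i - 1, j] else 0
    above_left <- if (j > 1) prefix[r, j - 1] - prefix[i, j - 1] else 0
    C <- C + nij * (below_left + above_right)
    D <- D + nij * (below_right + above_left)
  }
  list(C = C / 2, D = D / 2)  # each unordered pair-of-pairs counted twice
}

#' Goodman-Kruskal gamma between two dendrograms
#'
#' Every leaf pair gets a cophenetic merge height in each tree; gamma is
#' `(C - D) / (C + D)` over all pairs of leaf pairs, counting a pair of
#' pairs concordant (C) when the two trees order their heights the same way
#' and discordant (D) when opposite; ties on either side are skipped.
#' Computed via an ordinal contingency table over the (at most n-1) distinct
#' merge heights per tree, which is exactly equivalent to the O(m^2)
#' pair-of-pairs enumeration.
#'
#' @param dend_a,dend_b dendrograms over the same >= 3 leaves.
#' @return gamma in \[-1,1\]; NA with attribute `flagged` when C + D = 0.
#' @export
gk_gamma <- function(dend_a, dend_b) {
  al <- cophenetic_aligned(dend_a, dend_b)
  if (length(labels(dend_a)) < 3) stop("need >= 3 shared leaves")
  tab <- table(factor(al$x, levels = sort(unique(al$x))),
               factor(al$y, levels = sort(unique(al$y))))
  cd <- gamma_from_table(tab)
  if (cd$C + cd$D == 0) return(structure(NA_real_, flagged = TRUE))
  (cd$C - cd$D) / (cd$C + cd$D)
}

relabel_leaves <- function(dend, new_labels) {
  env <- new.env(parent = emptyenv()); env$i <- 0L
  stats::dendrapply(dend, function(n) {
    if (is.leaf(n)) {
      env$i <- env$i + 1L
      attr(n, "label") <- new_labels[env$i]
    }
    n
  })
}

#' Permutation test for Goodman-Kruskal gamma
#'
#' The null model shuffles the leaf labels of one tree (heights and topology
#' kept) and recomputes gamma against the other; reported are the null
#' sample with mean and 95 percent CI, a one-sided t-test of the null sample
#' against gamma = 1 (perfect alignment) and against the observed gamma.
#'
#' @param dend_a,dend_b dendrograms over the same leaves.
#' @param n_perm permutations (default 100).
#' @param seed integer seed.
#' @param side which tree's leaves to shuffle ("a", "b", or "both").
#' @return list: observed, null (vector), null_mean, ci (length 2),
#'   p_vs_perfect, p_vs_observed.
#' @export
gamma_permutation_test <- function(dend_a, dend_b, n_perm = 100L, seed = 1L,
                                   side = c("a", "b", "both")) {
  if (n_perm <= 0) stop("n_perm must be >= 1")
  side <- match.arg(side)
  observed <- gk_gamma(dend_a, dend_b)
  lab_a <- labels(dend_a); lab_b <- labels(dend_b)
  with_seed(seed, {
    null_g <- vapply(seq_len(n_perm), function(i) {
      da <- if (side %in% c("a", "both")) relabel_leaves(dend_a, sample(lab_a))
            else dend_a
      db <- if (side %in% c("b", "both")) relabel_leaves(dend_b, sample(lab_b))
            else dend_b
      as.numeric(gk_gamma(da, db))
    }, 0)
  })
  tt1 <- stats::t.test(null_g, mu = 1, alternative = "less")
  tt2 <- stats::t.test(null_g, mu = observed)
  ci <- stats::t.test(null_g)$conf.int
  list(observed = observed, null = null_g, null_mean = mean(null_g),
       ci = as.numeric(ci), p_vs_perfect = tt1$p.value,
       p_vs_observed = tt2$p.value)
}

#' Cophenetic correlation between two dendrograms
#'
#' Pearson correlation of the upper triangles of the two cophenetic distance
#' matrices over the shared, identically ordered leaf set.
#'
#' @param dend_a,dend_b dendrograms over the same leaves.
#' @return r in \[-1,1\]; NA with attribute `flagged` when either matrix has
#'   zero variance (e.g. all merges at one height).
#' @export
cophenetic_correlation <- function(dend_a, dend_b) {
  al <- cophenetic_aligned(dend_a, dend_b)
  sx <- stats::sd(al$x); sy <- stats::sd(al$y)
  if (length(al$x) < 2 || is.na(sx) || is.na(sy) || sx == 0 || sy == 0) {
    return(structure(NA_real_, flagged = TRUE))
  }
  stats::cor(al$x, al$y)
}

#' Rolling membership sum along a leaf order
#'
#' Scores each window of `window` consecutive leaves by how many belong to
#' the membership set; used to localize temporally co-expressed hotspots of
#' sensitive genes along a clustered gene order.
#'
#' @param leaves a dendrogram or a character vector giving the leaf order.
#' @param membership character vector of member gene ids.
#' @param window window width in genes (default 50).
#' @return list: `leaf_order`, `indicator`, `sums` (length n - window + 1),
#'   `window`, `peak` (start positions attaining the maximum sum).
#' @export
rolling_membership_scan <- function(leaves, membership, window = 50L) {
  ord <- if (inherits(leaves, "dendrogram")) labels(leaves) else as.character(leaves)
  n <- length(ord)
  if (window > n) stop("window exceeds number of leaves")
  ind <- as.integer(ord %in% membership)
  cs <- cumsum(ind)
  sums <- cs[window:n] - c(0, cs)[seq_len(n - window + 1)]
  list(leaf_order = ord, indicator = ind, sums = sums, window = window,
       peak = which(sums == max(sums)))
}
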