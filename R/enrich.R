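#' Gene-set overlap enrichment
#'
#' Exact hypergeometric over/under-representation of a test gene list in an
#' annotated set within an explicit universe, with a matched
#' sampling-without-replacement permutation null. Both tails are always
#' computed; the headline tail is inferred from the fold direction
#' (fold >= 1 reports the upper tail) since enrichment and depletion are
#' both of interest (improper-module excess, housekeeping deficit).
#'
#' @name set-enrichment
NULL

#' Exact hypergeometric overlap test
#'
#' With `X ~ Hypergeometric(N, K, n)`: `p_upper = P(X >= k)`,
#' `p_lower = P(X <= k)`, `expected = n K / N`, `fold = k / expected`.
#' Test list and annotated set are restricted to the universe before
#' counting; ids outside the universe never affect any count.
#'
#' @param test_list character gene ids.
#' @param annotated_set character gene ids.
#' @param universe character gene ids (explicit; never inferred).
#' @return an `overlap_test` list: N, K, n, k, expected, fold, p_upper,
#'   p_lower, p (headline tail), tail.
#' @export
hypergeom_overlap <- function(test_list, annotated_set, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  test <- intersect(unique(test_list), universe)
  if (!length(test)) stop("test list is empty within the universe")
  set <- intersect(unique(annotated_set), universe)
  N <- length(universe); K <- length(set); n <- length(test)
  k <- length(intersect(test, set))
  expected <- n * K / N
  fold <- if (expected > 0) k / expected else NA_real_
  p_upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_lower <- stats::phyper(k, K, N - K, n)
  structure(list(N = N, K = K, n = n, k = k, expected = expected,
                 fold = fold, p_upper = p_upper, p_lower = p_lower,
                 p = if (!is.na(fold) && fold >= 1) p_upper else p_lower,
                 tail = if (!is.na(fold) && fold >= 1) "upper" else "lower"),
            class = "overlap_test")
}

#' @export
#' @method print overlap_test
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap_test: k=%d of n=%d vs K=%d/N=%d; expected=%.2f fold=%.3f p_%s=%.3g\n",
    x$k, x$n, x$K, x$N, x$expected, x$fold, x$tail, x$p))
  invisible(x)
}

#' Permutation null for a set overlap
#'
#' Draws `n_iter` random gene lists of size n from the universe (without
#' replacement) and compares their overlaps with the annotated set to the
#' observed overlap. Empirical p-values carry the +1 correction.
#'
#' @param test_list,annotated_set,universe as in [hypergeom_overlap()].
#' @param n_iter number of permutations (default 10000).
#' @param seed integer seed.
#' @return list: observed [hypergeom_overlap()], `null_overlap` draws,
#'   `mean_overlap`, `p_upper`, `p_lower`, `p_two_sided`.
#' @export
permutation_overlap_null <- function(test_list, annotated_set, universe,
                                     n_iter = 10000L, seed = 1L) {
  if (n_iter <= 0) stop("n_iter must be >= 1")
  obs <- hypergeom_overlap(test_list, annotated_set, universe)
  universe <- unique(as.character(universe))
  set <- intersect(unique(annotated_set), universe)
  with_seed(seed, {
    null_k <- vapply(seq_len(n_iter), function(i) {
      length(intersect(sample(universe, obs$n), set))
    }, 0L)
    p_up <- (1 + sum(null_k >= obs$k)) / (n_iter + 1)
    p_lo <- (1 + sum(null_k <= obs$k)) / (n_iter + 1)
    list(observed = obs, null_overlap = null_k, mean_overlap = mean(null_k),
         p_upper = p_up, p_lower = p_lo,
         p_two_sided = min(1, 2 * min(p_up, p_lo)), n_iter = n_iter)
  })
}

#' Enrichment battery over lists x sets
#'
#' One hypergeometric row per (test list, annotated set) pair with BH-FDR
#' across the battery's headline p-values. Sets with empty intersection with
#' the universe are flagged, not dropped.
#'
#' @param test_lists named list of character vectors.
#' @param annotated_sets named list of character vectors.
#' @param universe explicit shared universe.
#' @return data.frame: list, set, N, K, n, k, expected, fold, p_upper,
#'   p_lower, p, fdr, flagged.
#' @export
enrichment_battery <- function(test_lists, annotated_sets, universe) {
  stopifnot(length(test_lists) > 0, length(annotated_sets) > 0)
  rows <- list()
  for (ln in names(test_lists)) for (sn in names(annotated_sets)) {
    set_u <- intersect(annotated_sets[[sn]], universe)
    if (!length(set_u)) {
      rows[[paste(ln, sn)]] <- data.frame(
        list = ln, set = sn, N = length(unique(universe)), K = 0L,
        n = length(intersect(test_lists[[ln]], universe)), k = 0L,
        expected = 0, fold = NA_real_, p_upper = NA_real_,
        p_lower = NA_real_, p = NA_real_, flagged = TRUE)
      next
    }
    ht <- hypergeom_overlap(test_lists[[ln]], annotated_sets[[sn]], universe)
    rows[[paste(ln, sn)]] <- data.frame(
      list = ln, set = sn, N = ht$N, K = ht$K, n = ht$n, k = ht$k,
      expected = ht$expected, fold = ht$fold, p_upper = ht$p_upper,
      p_lower = ht$p_lower, p = ht$p, flagged = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
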