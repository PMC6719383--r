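#' Differential-expression contrasts
#'
#' Per-gene negative-binomial GLM likelihood-ratio tests with a log link and
#' library-size offsets. Three canonical contrasts mirror the mitonuclear
#' design: a haplotype ANODEV (all haplotype groups vs a common mean, df =
#' n_haplotypes - 1), a species contrast (the two haplotypes of each species
#' pooled, df = 1), and a GxG interaction (a haplotype pair contrasted across
#' two nuclear backgrounds, df = 1). Dispersion is a per-gene
#' method-of-moments estimate floored at 1e-8; at the floor the fit reduces
#' to Poisson.
#'
#' @name de-stats
NULL

#' Build a contrast specification
#'
#' @param name contrast name.
#' @param full,reduced design matrices (samples x coefficients); the reduced
#'   design must be nested in the full design.
#' @return a `contrast_spec` with `df = rank(full) - rank(reduced)`.
#' @export
contrast_spec <- function(name, full, reduced) {
  full <- as.matrix(full); reduced <- as.matrix(reduced)
  stopifnot(nrow(full) == nrow(reduced))
  rf <- qr(full)$rank; rr <- qr(reduced)$rank
  # nestedness: augmenting full with reduced must not raise its rank
  if (qr(cbind(full, reduced))$rank > rf) {
    stop("reduced design is not nested in full design")
  }
  df <- rf - rr
  if (df < 1) stop("contrast has df < 1")
  structure(list(name = name, full = full, reduced = reduced, df = df),
            class = "contrast_spec")
}

#' Group-factor contrast (full = one mean per group, reduced = common mean)
#' @param name contrast name.
#' @param groups factor or character vector, one entry per sample.
#' @return a [contrast_spec()].
#' @export
contrast_groups <- function(name, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  contrast_spec(name, stats::model.matrix(~g), matrix(1, length(g), 1))
}

#' Interaction (GxG) contrast: full = mito * nuc, reduced = mito + nuc
#' @param name contrast name.
#' @param mito,nuc factors per sample (typically two levels each).
#' @return a [contrast_spec()].
#' @export
contrast_interaction <- function(name, mito, nuc) {
  mito <- factor(mito); nuc <- factor(nuc)
  contrast_spec(name, stats::model.matrix(~ mito * nuc),
                stats::model.matrix(~ mito + nuc))
}

#' Method-of-moments NB dispersion for one gene
#'
#' On offset-normalized counts, within-group variance in excess of the
#' Poisson expectation is attributed to the quadratic NB term:
#' `phi_g = (v_g - m_g * mean(1/s)) / m_g^2`, pooled over groups with
#' weights (n_g - 1) and floored at 1e-8.
#'
#' @param y integer counts for one gene.
#' @param groups group labels.
#' @param offsets log library-size offsets (default 0).
#' @return dispersion estimate (>= 1e-8); attribute `flagged` is TRUE for
#'   all-zero rows.
#' @export
estimate_dispersion <- function(y, groups, offsets = rep(0, length(y))) {
  stopifnot(length(y) == length(groups), length(offsets) == length(y))
  g <- factor(groups)
  sizes <- tabulate(g)
  if (all(sizes < 2)) stop("no group has >= 2 samples; dispersion unidentifiable")
  if (all(y == 0)) return(structure(1e-8, flagged = TRUE))
  s <- exp(offsets)
  yn <- y / s
  ests <- w <- numeric(0)
  for (lev in levels(g)[sizes >= 2]) {
    i <- g == lev
    m <- mean(yn[i]); v <- stats::var(yn[i])
    if (m > 0) {
      ests <- c(ests, (v - m * mean(1 / s[i])) / m^2)
      w <- c(w, sum(i) - 1)
    }
  }
  if (!length(ests)) return(structure(1e-8, flagged = TRUE))
  structure(max(sum(ests * w) / sum(w), 1e-8), flagged = FALSE)
}

nb_loglik <- function(y, mu, dispersion) {
  if (dispersion <= 1e-8) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / dispersion, mu = mu, log = TRUE))
}

fit_nb <- function(y, X, offsets, dispersion) {
  fam <- if (dispersion <= 1e-8) stats::poisson()
         else MASS::negative.binomial(theta = 1 / dispersion)
  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = y, offset = offsets, family = fam,
                   control = list(maxit = 50)))
  list(loglik = nb_loglik(y, fit$fitted.values, dispersion),
       converged = fit$converged)
}

#' Likelihood-ratio test for one gene
#'
#' `lr = 2 (l_full - l_reduced)` clipped at zero; p from the upper chi-square
#' tail with the contrast's df. Non-convergence yields `p = NaN` and
#' `flagged = TRUE` so callers can exclude the gene with a logged count.
#'
#' @param y counts for one gene.
#' @param contrast a [contrast_spec()].
#' @param offsets log library-size offsets.
#' @param dispersion NB dispersion (>= 0).
#' @return data.frame row: gene fields left to the caller; columns lr, df,
#'   p_value, flagged.
#' @export
lrt_contrast <- function(y, contrast, offsets = rep(0, length(y)),
                         dispersion = 0) {
  stopifnot(inherits(contrast, "contrast_spec"), dispersion >= 0,
            length(y) == nrow(contrast$full))
  ok <- TRUE
  res <- tryCatch({
    f <- fit_nb(y, contrast$full, offsets, dispersion)
    r <- fit_nb(y, contrast$reduced, offsets, dispersion)
    ok <- f$converged && r$converged
    max(2 * (f$loglik - r$loglik), 0)
  }, error = function(e) { ok <<- FALSE; NA_real_ })
  if (!ok || is.na(res)) {
    return(data.frame(lr = NA_real_, df = contrast$df, p_value = NaN,
                      flagged = TRUE))
  }
  data.frame(lr = res, df = contrast$df,
             p_value = stats::pchisq(res, contrast$df, lower.tail = FALSE),
             flagged = FALSE)
}

#' Benjamini-Hochberg step-up FDR
#'
#' Direct step-up implementation: `q(i) = min_{j >= i} p(j) * m / j`, capped
#' at 1. NaN/NA inputs are excluded from m and reinserted as NA.
#'
#' @param p numeric p-values in \[0,1\] (NA/NaN allowed).
#' @return FDR-adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0,1]")
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  q <- pmin(1, cummin(pv[o] * m / seq(m, 1)))
  out[ok][o] <- q
  out
}

#' Top-n genes by p-value
#'
#' @param results data.frame with gene_id and p_value columns.
#' @param n how many genes (must not exceed available non-NaN results).
#' @return character vector of gene ids, ascending p, ties broken
#'   lexicographically by gene_id.
#' @export
top_n_by_pvalue <- function(results, n) {
  if (n <= 0) stop("n must be positive")
  res <- results[!is.na(results$p_value), , drop = FALSE]
  if (n > nrow(res)) stop("requested ", n, " of ", nrow(res), " results")
  res$gene_id[order(res$p_value, res$gene_id)][seq_len(n)]
}

#' Library-size offsets by the median-of-ratios method
#'
#' Per-sample size factors are the median across genes of the ratio to the
#' per-gene geometric mean (computed over genes expressed in every sample),
#' which is robust to a minority of strongly differential genes that would
#' bias plain total-count offsets; falls back to total counts when fewer
#' than two genes are everywhere-expressed. Returned on the log scale,
#' centred at zero.
#'
#' @param counts genes x samples matrix.
#' @return numeric offset per sample (log scale, mean 0).
#' @export
library_size_offsets <- function(counts) {
  pos <- counts[apply(counts > 0, 1, all), , drop = FALSE]
  if (nrow(pos) >= 2) {
    gm <- exp(rowMeans(log(pos)))
    sf <- apply(pos / gm, 2, stats::median)
  } else {
    sf <- colSums(counts)
  }
  offs <- log(sf)
  offs - mean(offs)
}

#' Run the standard contrast battery over a count matrix
#'
#' For each sex: the haplotype ANODEV and species contrast within the first
#' nuclear background, and (when two backgrounds are present) the GxG
#' interaction for the `gxg_pair` haplotypes. Genes failing the low-count
#' filter (CPM-equivalent >= `min_cpm` in >= smallest-group-size samples)
#' are dropped before testing, with a logged count.
#'
#' @param counts genes x samples integer matrix.
#' @param meta SampleMeta data.frame (sample_id, sex, mito, nuc, replicate).
#' @param contrasts subset of c("haplotype", "species", "gxg").
#' @param gxg_pair two haplotype labels for the interaction contrast.
#' @param min_cpm low-count filter threshold (counts per million).
#' @return data.frame: gene_id, contrast, sex, lr, df, p_value, fdr.
#' @export
de_analysis <- function(counts, meta,
                        contrasts = c("haplotype", "species", "gxg"),
                        gxg_pair = NULL, min_cpm = 1) {
  stopifnot(is.matrix(counts), nrow(meta) == ncol(counts),
            all(meta$sample_id == colnames(counts)))
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  haps <- sort(unique(meta$mito))
  species_of <- stats::setNames(
    rep(c("spA", "spB"), each = ceiling(length(haps) / 2))[seq_along(haps)], haps)
  if (is.null(gxg_pair)) gxg_pair <- haps[c(1, length(haps))]
  nucs <- unique(meta$nuc)
  out <- list()
  for (sex in unique(meta$sex)) {
    sel0 <- meta$sex == sex & meta$nuc == nucs[1]
    plans <- list()
    if ("haplotype" %in% contrasts) {
      plans$haplotype <- list(sel = sel0,
                              spec = contrast_groups("haplotype", meta$mito[sel0]))
    }
    if ("species" %in% contrasts) {
      plans$species <- list(sel = sel0,
                            spec = contrast_groups("species",
                                                   species_of[meta$mito[sel0]]))
    }
    if ("gxg" %in% contrasts && length(nucs) > 1) {
      selg <- meta$sex == sex & meta$mito %in% gxg_pair
      plans$gxg <- list(sel = selg,
                        spec = contrast_interaction("gxg", meta$mito[selg],
                                                    meta$nuc[selg]))
    }
    for (cname in names(plans)) {
      sel <- plans[[cname]]$sel
      cts <- counts[, sel, drop = FALSE]
      offs <- library_size_offsets(cts)
      # low-count filter (edgeR-style convention, threshold configurable)
      grp <- apply(plans[[cname]]$spec$full, 1, paste, collapse = "/")
      min_n <- min(table(grp))
      cpm <- t(t(cts) / colSums(cts)) * 1e6
      keep <- rowSums(cpm >= min_cpm) >= min_n
      if (any(!keep)) msg("%s/%s: dropped %d low-count gene(s)", cname, sex,
                          sum(!keep))
      cts <- cts[keep, , drop = FALSE]
      rows <- lapply(rownames(cts), function(gid) {
        y <- cts[gid, ]
        disp <- estimate_dispersion(y, grp, offs)
        cbind(gene_id = gid,
              lrt_contrast(y, plans[[cname]]$spec, offs, as.numeric(disp)))
      })
      tab <- do.call(rbind, rows)
      n_flag <- sum(tab$flagged)
      if (n_flag) msg("%s/%s: %d non-converged fit(s) flagged", cname, sex, n_flag)
      tab$fdr <- bh_adjust(tab$p_value)
      tab$contrast <- cname
      tab$sex <- sex
      out[[paste(cname, sex)]] <-
        tab[, c("gene_id", "contrast", "sex", "lr", "df", "p_value", "fdr")]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
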