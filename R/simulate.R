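#' Synthetic data with planted, recoverable structure
#'
#' Every input the pipeline consumes can be generated here with known truth:
#' a gene map over chromosome arms, negative-binomial counts under a
#' haplotype x sex x nuclear-background design with planted haplotype /
#' species / GxG effects, a scale-free interaction network with planted
#' low-degree hot neighborhoods, co-expression module labels with a planted
#' improper-module enrichment, and stage-structured developmental expression
#' blocks. All generators are deterministic under a fixed seed; one master
#' seed spawns stage-keyed child seeds (see [child_seed()]).
#'
#' @name simulate
NULL

#' Simulation configuration
#'
#' Defaults emulate the experimental design the pipeline was built around:
#' four mtDNA haplotypes (two per species) crossed onto nuclear backgrounds,
#' two sexes, four biological replicates, five Drosophila-like chromosome
#' arms, an improper-module fraction of 0.204 and a 3.5x planted enrichment.
#'
#' @param seed master seed.
#' @param n_genes number of genes in the synthetic genome.
#' @param arms named numeric vector of arm lengths in bp.
#' @param n_haplotypes number of mtDNA haplotypes (first half = species A).
#' @param n_replicates biological replicates per genotype/sex.
#' @param sexes sex labels.
#' @param nucs nuclear background labels (2 needed for GxG effects).
#' @param effect_gene_fraction fraction of genes carrying a planted effect.
#' @param fold_change planted fold change on effect genes.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param n_clusters,cluster_size,max_internal_gap planted physical-cluster plan.
#' @param network_nodes,network_model,network_param interaction network plan.
#' @param improper_fraction fraction of genes in the improper module.
#' @param improper_enrichment_factor planted fold enrichment of sensitive
#'   genes in the improper module.
#' @param n_stages developmental stages.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       arms = c("2L" = 23.5e6, "2R" = 25.3e6, "3L" = 28.1e6,
                                "3R" = 32.1e6, "X" = 23.5e6),
                       n_haplotypes = 4L,
                       n_replicates = 4L,
                       sexes = c("F", "M"),
                       nucs = c("N1", "N2"),
                       effect_gene_fraction = 0.1,
                       fold_change = 4,
                       dispersion = 0.1,
                       n_clusters = 5L,
                       cluster_size = 4L,
                       max_internal_gap = 2L,
                       network_nodes = 1000L,
                       network_model = c("scale_free", "erdos_renyi"),
                       network_param = 2,
                       improper_fraction = 0.204,
                       improper_enrichment_factor = 3.5,
                       n_stages = 12L) {
  network_model <- match.arg(network_model)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes), arms = arms,
              n_haplotypes = as.integer(n_haplotypes),
              n_replicates = as.integer(n_replicates), sexes = sexes, nucs = nucs,
              effect_gene_fraction = effect_gene_fraction,
              fold_change = fold_change, dispersion = dispersion,
              n_clusters = as.integer(n_clusters),
              cluster_size = as.integer(cluster_size),
              max_internal_gap = as.integer(max_internal_gap),
              network_nodes = as.integer(network_nodes),
              network_model = network_model, network_param = network_param,
              improper_fraction = improper_fraction,
              improper_enrichment_factor = improper_enrichment_factor,
              n_stages = as.integer(n_stages))
  stopifnot(all(cfg$arms > 0), cfg$dispersion >= 0, cfg$fold_change > 0,
            cfg$effect_gene_fraction >= 0, cfg$effect_gene_fraction <= 1,
            cfg$improper_fraction > 0, cfg$improper_fraction < 1,
            cfg$improper_enrichment_factor >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic genome table
#'
#' Genes are apportioned to arms proportionally to arm length; within an arm
#' each gene occupies a random sub-interval of its own equal-width slot, so
#' intervals never overlap and per-arm midpoint order equals slot order.
#'
#' @param config a [sim_config()].
#' @param min_gene_length minimum gene length in bp.
#' @return a [genome_table()] with gene ids `g0001...`.
#' @export
generate_genome <- function(config, min_gene_length = 500) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L) {
    return(genome_table(data.frame(gene_id = character(), arm = character(),
                                   start = integer(), end = integer())))
  }
  arms <- config$arms
  n_arm <- floor(n * arms / sum(arms))
  rem <- n - sum(n_arm)
  if (rem > 0) n_arm[seq_len(rem)] <- n_arm[seq_len(rem)] + 1L
  if (any(n_arm * 2 * min_gene_length > arms)) {
    stop("n_genes too large for arm lengths at minimum gene size")
  }
  with_seed(child_seed(config$seed, "genome"), {
    recs <- lapply(names(arms), function(a) {
      k <- n_arm[[a]]
      if (k == 0) return(NULL)
      slot <- arms[[a]] / k
      len <- pmin(round(stats::rlnorm(k, log(2000), 0.6)) + min_gene_length,
                  floor(slot) - 1)
      start <- floor((seq_len(k) - 1) * slot +
                       stats::runif(k) * (slot - len - 1))
      data.frame(arm = a, start = start, end = start + len,
                 strand = sample(c("+", "-"), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
    df$gene_id <- sprintf("g%04d", sample.int(nrow(df)))
    genome_table(df)
  })
}

#' Plant a physically clustered test gene set
#'
#' Planted clusters are runs of `cluster_size` test genes at consecutive arm
#' ranks with at most `max_internal_gap` non-members between consecutive
#' members; Bernoulli background singletons are added on top. Cluster spans
#' are separated widely enough that they cannot merge at detection gap
#' `<= max_internal_gap`.
#'
#' @param genome a [genome_table()].
#' @param n_clusters,cluster_size,max_internal_gap the cluster plan.
#' @param background_rate per-gene probability of joining the set as noise.
#' @param seed integer seed.
#' @return list with `test_set` (gene ids) and `truth` (data.frame gene_id,
#'   planted flag, cluster id or NA).
#' @export
plant_clustered_gene_set <- function(genome, n_clusters, cluster_size,
                                     max_internal_gap = 2L,
                                     background_rate = 0.01, seed = 1L) {
  stopifnot(inherits(genome, "genome_table"),
            cluster_size >= 2, max_internal_gap >= 0,
            background_rate >= 0, background_rate <= 1)
  rk <- genome_ranks(genome)
  arm_sizes <- table(rk$arm)
  span_max <- cluster_size + (cluster_size - 1) * max_internal_gap
  if (n_clusters > 0 && span_max > max(arm_sizes)) {
    stop("cluster span exceeds genes available on every arm")
  }
  with_seed(seed, {
    planted <- character(0); cluster_id <- integer(0)
    if (n_clusters > 0) {
      # place clusters round-robin on arms large enough, spaced apart
      arms_ok <- names(arm_sizes)[arm_sizes >= span_max]
      sep <- max_internal_gap * 2L + 5L
      placed <- 0L; guard <- 0L
      occupied <- lapply(stats::setNames(nm = arms_ok), function(a) integer(0))
      while (placed < n_clusters) {
        guard <- guard + 1L
        if (guard > 1000L * n_clusters) stop("could not place clusters; arms too small")
        a <- sample(arms_ok, 1L)
        n_a <- as.integer(arm_sizes[[a]])
        start <- sample.int(n_a - span_max + 1L, 1L)
        gaps <- sample.int(max_internal_gap + 1L, cluster_size - 1L, replace = TRUE) - 1L
        ranks <- start + c(0L, cumsum(gaps + 1L))
        span <- seq(max(1L, min(ranks) - sep), min(n_a, max(ranks) + sep))
        if (length(intersect(span, occupied[[a]]))) next
        occupied[[a]] <- c(occupied[[a]], span)
        ids <- rk$gene_id[rk$arm == a][ranks]
        planted <- c(planted, ids)
        cluster_id <- c(cluster_id, rep(placed + 1L, cluster_size))
        placed <- placed + 1L
      }
    }
    noise <- rk$gene_id[stats::runif(nrow(rk)) < background_rate]
    noise <- setdiff(noise, planted)
    truth <- data.frame(gene_id = c(planted, noise),
                        truth_planted = c(rep(TRUE, length(planted)),
                                          rep(FALSE, length(noise))),
                        truth_cluster = c(cluster_id, rep(NA_integer_, length(noise))),
                        stringsAsFactors = FALSE)
    list(test_set = truth$gene_id, truth = truth)
  })
}

#' Build the sample design table
#'
#' @param config a [sim_config()].
#' @return a SampleMeta data.frame (sample_id, sex, mito, nuc, replicate).
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  haps <- paste0("hap", seq_len(config$n_haplotypes))
  g <- expand.grid(replicate = seq_len(config$n_replicates), mito = haps,
                   nuc = config$nucs, sex = config$sexes,
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_%s_r%d", g$sex, g$mito, g$nuc, g$replicate)
  g[, c("sample_id", "sex", "mito", "nuc", "replicate")]
}

#' Generate NB counts with planted haplotype / species / GxG effects
#'
#' Counts are NB(mean = baseline x library factor x planted fold, dispersion)
#' with log-normal library-size factors (sigma = 0.2). Effect genes are split
#' evenly between three classes: `haplotype` (one haplotype shifted),
#' `species` (the first half of haplotypes shifted jointly) and `gxg`
#' (equal-magnitude, opposite-sign haplotype shifts in the two nuclear
#' backgrounds). Effects apply in both sexes.
#'
#' @param genome a [genome_table()] (or any table with gene_id).
#' @param config a [sim_config()].
#' @param meta optional design table from [generate_design()].
#' @param effect_genes optional character vector forcing which genes carry
#'   effects (e.g. a planted-cluster test set).
#' @return list: `counts` (genes x samples integer matrix), `meta`,
#'   `truth` (gene_id, truth_effect in none/haplotype/species/gxg, truth_fold).
#' @export
generate_counts <- function(genome, config, meta = generate_design(config),
                            effect_genes = NULL) {
  stopifnot(inherits(config, "sim_config"), config$dispersion >= 0,
            config$fold_change > 0)
  ids <- genome$gene_id
  n <- length(ids)
  with_seed(child_seed(config$seed, "counts"), {
    if (is.null(effect_genes)) {
      n_eff <- round(config$effect_gene_fraction * n)
      effect_genes <- sample(ids, n_eff)
    } else {
      stopifnot(all(effect_genes %in% ids))
    }
    classes <- c("haplotype", "species", "gxg")
    eff_class <- rep("none", n); names(eff_class) <- ids
    if (length(effect_genes)) {
      eff_class[effect_genes] <- rep(classes, length.out = length(effect_genes))
    }
    baseline <- stats::rlnorm(n, log(100), 1)
    libf <- stats::rlnorm(nrow(meta), 0, 0.2)
    lf <- log(config$fold_change)
    species_a <- paste0("hap", seq_len(ceiling(config$n_haplotypes / 2)))
    hap1 <- "hap1"
    nuc2 <- if (length(unique(meta$nuc)) > 1) unique(meta$nuc)[2] else NA
    # per-gene, per-sample log-fold offsets
    eta <- matrix(0, n, nrow(meta))
    hit_hap <- eff_class == "haplotype"
    hit_sp <- eff_class == "species"
    hit_gg <- eff_class == "gxg"
    in_hap1 <- meta$mito == hap1
    in_spA <- meta$mito %in% species_a
    eta[hit_hap, in_hap1] <- lf
    eta[hit_sp, in_spA] <- lf
    if (!is.na(nuc2)) {
      sgn <- ifelse(meta$nuc == nuc2, -1, 1)
      eta[hit_gg, ] <- rep(sgn * ifelse(in_hap1, 1, 0) * lf,
                           each = sum(hit_gg))
    }
    mu <- outer(baseline, libf) * exp(eta)
    counts <- matrix(
      if (config$dispersion > 0)
        stats::rnbinom(n * nrow(meta), mu = mu, size = 1 / config$dispersion)
      else stats::rpois(n * nrow(meta), lambda = mu),
      n, nrow(meta))
    dimnames(counts) <- list(ids, meta$sample_id)
    truth <- data.frame(gene_id = ids, truth_effect = unname(eff_class),
                        truth_fold = ifelse(eff_class == "none", 1,
                                            config$fold_change),
                        stringsAsFactors = FALSE)
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Generate an interaction network with planted hot neighborhoods
#'
#' The graph is scale-free (Barabasi-Albert preferential attachment) or
#' Erdos-Renyi. Node attributes are -log10 of Uniform(0,1) p-values; inside
#' `n_hotspots` radius-1 balls seeded at low-degree nodes the attribute is
#' raised by `boost` (the planted signal of a DE-dense, poorly connected
#' neighborhood).
#'
#' @param config a [sim_config()].
#' @param n_hotspots number of planted neighborhoods.
#' @param boost attribute increment inside hotspots (default 3 = each member
#'   resembling a p ~ 1e-3 gene on top of its null draw).
#' @return list: `network`, `attributes` (named -log10 p), `truth`
#'   (gene_id, truth_hotspot flag).
#' @export
generate_network_with_hotspots <- function(config, n_hotspots = 3L, boost = 3) {
  stopifnot(inherits(config, "sim_config"), config$network_nodes >= 1)
  n <- config$network_nodes
  with_seed(child_seed(config$seed, "network"), {
    if (n == 1L) {
      net <- interaction_network(data.frame(source = character(),
                                            target = character()))
      net$nodes <- "n0001"
      return(list(network = net,
                  attributes = c(n0001 = -log10(stats::runif(1))),
                  truth = data.frame(gene_id = "n0001", truth_hotspot = FALSE)))
    }
    g <- if (config$network_model == "scale_free") {
      igraph::sample_pa(n, m = config$network_param, directed = FALSE)
    } else {
      igraph::sample_gnp(n, p = config$network_param / n)
    }
    ids <- sprintf("n%04d", seq_len(n))
    igraph::V(g)$name <- ids
    el <- igraph::as_data_frame(g, what = "edges")
    net <- interaction_network(
      data.frame(source = el$from, target = el$to,
                 confidence = round(stats::runif(nrow(el), 0.5, 1), 3)))
    net$nodes <- sort(ids)  # keep isolated ER nodes
    attrs <- -log10(stats::runif(n)); names(attrs) <- ids
    hot <- character(0)
    if (n_hotspots > 0) {
      deg <- igraph::degree(g)
      med <- stats::quantile(deg, 0.5)
      # seed in the low-degree stratum, and keep membership there too: in a
      # scale-free graph low-degree nodes often hang off hubs, and a hub
      # inside a "poorly connected" hotspot would contradict the planted
      # truth the downstream Welch comparison is meant to recover
      knn <- suppressWarnings(igraph::knn(g)$knn)
      med_knn <- stats::median(knn, na.rm = TRUE)
      low <- ids[deg <= med & deg >= 1 & !is.na(knn) & knn <= med_knn]
      seeds <- sample(low, min(n_hotspots, length(low)))
      ball <- unique(unlist(lapply(
        igraph::ego(g, order = 1, nodes = seeds), names)))
      hot <- intersect(ball, ids[deg <= med & !is.na(knn) & knn <= med_knn])
      if (length(hot) > n) stop("hotspot size exceeds n_nodes")
      attrs[hot] <- attrs[hot] + boost
    }
    list(network = net, attributes = attrs,
         truth = data.frame(gene_id = ids, truth_hotspot = ids %in% hot,
                            stringsAsFactors = FALSE))
  })
}

#' Generate module labels with a planted improper-module enrichment
#'
#' Genes fall into `n_modules` proper co-expression modules plus one improper
#' (low/zero connectivity) module covering `improper_fraction` of genes in
#' expectation. Sensitive genes enter the improper module with probability
#' `enrichment_factor * improper_fraction` so the realized overlap fold is
#' `enrichment_factor` in expectation.
#'
#' @param gene_ids character vector (the universe).
#' @param sensitive_set character vector of sensitive genes.
#' @param improper_fraction overall improper-module fraction.
#' @param enrichment_factor target overlap fold for sensitive genes.
#' @param n_modules number of proper modules.
#' @param seed integer seed.
#' @return list: `modules` (data.frame gene_id, module), `truth`.
#' @export
generate_module_labels <- function(gene_ids, sensitive_set,
                                   improper_fraction = 0.204,
                                   enrichment_factor = 3.5,
                                   n_modules = 16L, seed = 1L) {
  stopifnot(improper_fraction > 0, improper_fraction < 1,
            enrichment_factor >= 0)
  p_s <- enrichment_factor * improper_fraction
  if (p_s > 1) {
    stop(sprintf(
      "requested fold infeasible: enrichment_factor must be <= %.3f at improper_fraction %.3f",
      1 / improper_fraction, improper_fraction))
  }
  N <- length(gene_ids); n_s <- sum(gene_ids %in% sensitive_set)
  # keep the overall improper fraction on target despite the boosted subset
  p_o <- (improper_fraction * N - p_s * n_s) / (N - n_s)
  if (p_o < 0) stop("sensitive set too large for requested improper_fraction")
  with_seed(seed, {
    sens <- gene_ids %in% sensitive_set
    in_improper <- stats::runif(N) < ifelse(sens, p_s, p_o)
    module <- ifelse(in_improper, "improper",
                     paste0("M", sample.int(n_modules, N, replace = TRUE)))
    list(modules = data.frame(gene_id = gene_ids, module = module,
                              stringsAsFactors = FALSE),
         truth = data.frame(gene_id = gene_ids, truth_sensitive = sens,
                            truth_improper = in_improper,
                            stringsAsFactors = FALSE))
  })
}

#' Generate stage-structured developmental expression profiles
#'
#' Genes are grouped into blocks; each block is active (high mean) over a
#' contiguous window of stages and near-silent elsewhere, plus Gaussian
#' noise, so within-block correlation exceeds between-block correlation and
#' hierarchical clustering recovers the blocks.
#'
#' @param gene_ids character vector.
#' @param n_stages number of developmental stages (>= 2).
#' @param n_blocks number of expression blocks.
#' @param noise_sd Gaussian noise sd on log-expression.
#' @param seed integer seed.
#' @return list: `expr` (genes x stages matrix), `truth` (gene_id, truth_block).
#' @export
generate_dev_expression <- function(gene_ids, n_stages = 12L, n_blocks = 5L,
                                    noise_sd = 0.5, seed = 1L) {
  if (n_stages < 2) stop("n_stages must be >= 2")
  n <- length(gene_ids)
  with_seed(seed, {
    block <- sort(rep_len(seq_len(n_blocks), n))
    # contiguous active stage windows, tiled across the time course
    bounds <- floor(seq(0, n_stages, length.out = n_blocks + 1))
    expr <- matrix(0, n, n_stages,
                   dimnames = list(gene_ids,
                                   sprintf("stage%02d", seq_len(n_stages))))
    for (b in seq_len(n_blocks)) {
      active <- (bounds[b] + 1):max(bounds[b + 1], bounds[b] + 1)
      rows <- which(block == b)
      base <- matrix(1, length(rows), n_stages)
      base[, active] <- 8
      expr[rows, ] <- base
    }
    expr <- expr + matrix(stats::rnorm(n * n_stages, 0, noise_sd), n, n_stages)
    list(expr = expr,
         truth = data.frame(gene_id = gene_ids, truth_block = block,
                            stringsAsFactors = FALSE))
  })
}
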