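#' End-to-end pipeline orchestration
#'
#' [run_pipeline()] drives every stage off a single validated configuration
#' (a named list or JSON file): simulate inputs, run the DE contrasts,
#' cluster the top genes along the genome, compute the SAFE enrichment
#' field, rank focal genes, test module enrichment, and measure dendrogram
#' concordance. All randomness derives from one master seed through
#' stage-keyed child seeds, so reruns are byte-identical and stage order is
#' irrelevant; a JSON manifest records parameters, seeds and output hashes.
#'
#' @name cli-pipeline
NULL

pipeline_defaults <- function() {
  list(out_dir = "mitoarch_out", seed = 1L, n_genes = 600L,
       stages = c("simulate", "de", "cluster", "safe", "rank", "enrich",
                  "concord"),
       max_gap = 5L, min_size = 2L, cluster_iters = 200L,
       radius = 1L, n_perm = 200L, top_n = 50L, window = 20L,
       improper_fraction = 0.204, improper_enrichment_factor = 3.5,
       network_nodes = 300L, n_stages = 12L, alpha = 0.05)
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and checks stage names.
#'
#' @param config named list, or path to a JSON file of overrides.
#' @return validated config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config error: no such file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("config error: unknown key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad)) stop("config error: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline
#'
#' @param config see [pipeline_config()].
#' @return invisibly, the manifest list (also written as
#'   `manifest.json` in the output directory).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) { paths[length(paths) + 1] <<- p; p }
  sim <- sim_config(seed = cfg$seed, n_genes = cfg$n_genes,
                    network_nodes = cfg$network_nodes,
                    improper_fraction = cfg$improper_fraction,
                    improper_enrichment_factor = cfg$improper_enrichment_factor,
                    n_stages = cfg$n_stages)

  genome <- generate_genome(sim)
  counts <- generate_counts(genome, sim)
  if ("simulate" %in% cfg$stages) {
    add(write_gene_table(genome, file.path(cfg$out_dir, "genome.bed")))
    add(write_tsv(data.frame(gene_id = rownames(counts$counts),
                             counts$counts, check.names = FALSE),
                  file.path(cfg$out_dir, "counts.tsv")))
    add(write_tsv(counts$meta, file.path(cfg$out_dir, "samples.tsv")))
    add(write_tsv(counts$truth, file.path(cfg$out_dir, "truth_counts.tsv")))
  }

  de <- NULL
  if (any(c("de", "cluster", "safe", "rank", "enrich") %in% cfg$stages)) {
    de <- de_analysis(counts$counts, counts$meta)
    if ("de" %in% cfg$stages) {
      add(write_tsv(de, file.path(cfg$out_dir, "de_results.tsv")))
    }
  }
  de_hapF <- if (!is.null(de)) de[de$contrast == "haplotype" & de$sex == "F", ]

  if ("cluster" %in% cfg$stages) {
    top <- top_n_by_pvalue(de_hapF, min(cfg$top_n, nrow(de_hapF)))
    rn <- randomization_null(top, genome, cfg$max_gap, cfg$min_size,
                             cfg$cluster_iters,
                             seed = child_seed(cfg$seed, "cluster"))
    add(write_tsv(rn$observed$clusters,
                  file.path(cfg$out_dir, "clusters.tsv")))
    add(write_tsv(data.frame(percent_clustered = rn$observed$percent_clustered,
                             n_clusters = rn$observed$n_clusters,
                             p_percent = rn$p_percent,
                             p_nclusters = rn$p_nclusters),
                  file.path(cfg$out_dir, "cluster_summary.tsv")))
    add(write_tsv(ks_uniformity_by_arm(top, genome),
                  file.path(cfg$out_dir, "cluster_ks.tsv")))
  }

  netsim <- generate_network_with_hotspots(sim)
  if ("safe" %in% cfg$stages) {
    field <- safe_enrichment(netsim$network, netsim$attributes, cfg$radius,
                             cfg$n_perm, seed = child_seed(cfg$seed, "safe"),
                             alpha = cfg$alpha)
    add(write_tsv(merge(field, network_metrics(netsim$network), by = "gene_id"),
                  file.path(cfg$out_dir, "safe_field.tsv")))
    add(write_tsv(netsim$truth, file.path(cfg$out_dir, "truth_hotspots.tsv")))
  }

  if ("rank" %in% cfg$stages) {
    net <- preprocess_interactions(netsim$network$edges)
    de_hap <- de[de$contrast == "haplotype", ]
    lr_by_sex <- lapply(split(de_hap, de_hap$sex), function(d) {
      # synthetic network node ids map onto the gene universe by rank
      stats::setNames(d$lr, sprintf("n%04d", match(d$gene_id, sort(d$gene_id))))
    })
    scores <- lapply(lr_by_sex, function(lr) score_focal_genes(net, lr))
    for (sx in names(scores)) {
      add(write_tsv(scores[[sx]],
                    file.path(cfg$out_dir, paste0("focal_", sx, ".tsv"))))
    }
    if (length(scores) >= 2) {
      shared <- intersect_top_ranks(scores[[1]], scores[[2]],
                                    min(cfg$top_n, nrow(scores[[1]]),
                                        nrow(scores[[2]])))
      add(write_tsv(data.frame(gene_id = shared$shared),
                    file.path(cfg$out_dir, "focal_shared.tsv")))
    }
  }

  if ("enrich" %in% cfg$stages) {
    sens <- top_n_by_pvalue(de_hapF, min(cfg$top_n, nrow(de_hapF)))
    mods <- generate_module_labels(genome$gene_id, sens,
                                   cfg$improper_fraction,
                                   cfg$improper_enrichment_factor,
                                   seed = child_seed(cfg$seed, "modules"))
    improper <- mods$modules$gene_id[mods$modules$module == "improper"]
    bat <- enrichment_battery(list(sensitive = sens),
                              list(improper = improper),
                              universe = genome$gene_id)
    add(write_tsv(bat, file.path(cfg$out_dir, "enrichment.tsv")))
    add(write_tsv(mods$modules, file.path(cfg$out_dir, "modules.tsv")))
  }

  if ("concord" %in% cfg$stages) {
    ng <- min(cfg$n_genes, 150L)
    ids <- genome$gene_id[seq_len(ng)]
    dev <- generate_dev_expression(ids, sim$n_stages,
                                   seed = child_seed(cfg$seed, "dev"))
    dend_dev <- hclust_expression(dev$expr)
    adult <- generate_dev_expression(ids, sim$n_stages,
                                     seed = child_seed(cfg$seed, "adult"))
    dend_adult <- hclust_expression(adult$expr)
    ent0 <- entanglement(dend_dev, dend_adult)
    unt <- untangle_step2side(dend_dev, dend_adult)
    gam <- gamma_permutation_test(dend_dev, dend_adult, n_perm = 50L,
                                  seed = child_seed(cfg$seed, "gamma"))
    members <- dev$truth$gene_id[dev$truth$truth_block == 1]
    scan <- rolling_membership_scan(dend_dev, members,
                                    window = min(cfg$window, ng))
    add(write_newick(dend_dev, file.path(cfg$out_dir, "dend_dev.nwk")))
    add(write_newick(unt$dend_a, file.path(cfg$out_dir, "dend_dev_untangled.nwk")))
    add(write_tsv(data.frame(entanglement_raw = ent0,
                             entanglement_untangled = unt$entanglement,
                             gamma = gam$observed,
                             gamma_null_mean = gam$null_mean,
                             cophenetic_r = cophenetic_correlation(dend_dev,
                                                                   dend_adult)),
                  file.path(cfg$out_dir, "concordance.tsv")))
    add(write_tsv(data.frame(window_start = seq_along(scan$sums),
                             rolling_sum = scan$sums),
                  file.path(cfg$out_dir, "rolling_sum.tsv")))
  }

  manifest <- list(package = "mitoarch",
                   version = as.character(utils::packageVersion("mitoarch")),
                   config = cfg,
                   files = as.list(tools::md5sum(sort(paths))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `all` (run the full pipeline) or any single stage name, plus
#' `--config path.json`, `--seed N`, `--out dir`. Returns (invisibly) 0 on
#' success, 2 on a configuration/usage error, 1 on a stage failure.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit code, invisibly.
#' @export
mitoarch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: mitoarch <simulate|de|cluster|safe|rank|enrich|concord|all> [--config FILE] [--seed N] [--out DIR]"
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]; rest <- args[-1]
  stages_all <- pipeline_defaults()$stages
  if (!(cmd %in% c(stages_all, "all"))) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(2L))
  }
  opt <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[i]
    if (!(key %in% c("--config", "--seed", "--out")) || i == length(rest)) {
      message("unknown or incomplete flag: ", key, "\n", usage)
      return(invisible(2L))
    }
    val <- rest[i + 1L]; i <- i + 2L
    if (key == "--config") opt <- pipeline_config(val)
    if (key == "--seed") opt$seed <- as.integer(val)
    if (key == "--out") opt$out_dir <- val
  }
  if (cmd != "all") opt$stages <- cmd
  code <- tryCatch({ run_pipeline(opt); 0L },
                   error = function(e) {
                     message("stage failure: ", conditionMessage(e))
                     if (grepl("^config error", conditionMessage(e))) 2L else 1L
                   })
  invisible(code)
}
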