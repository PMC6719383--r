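#' Gene tables: coordinate conventions and readers
#'
#' Internal coordinates are 0-based half-open, as in BED. GFF3 input (1-based,
#' closed) is shifted on read: `start_internal = start_gff - 1`. All genome
#' linearization downstream uses the gene midpoint `(start + end) / 2`.
#'
#' A genome table is a data.frame with columns `gene_id`, `arm`, `start`,
#' `end`, `strand`, `biotype`, `midpoint`, sorted within arm by midpoint
#' (ties broken lexicographically by `gene_id`), carrying class
#' `"genome_table"`.
#'
#' @name gene-table
NULL

VALID_BIOTYPES <- c("protein_coding", "ncRNA", "miRNA", "other")

#' Construct a genome table from its columns
#'
#' @param df data.frame with at least gene_id, arm, start, end; optional
#'   strand and biotype.
#' @return a `genome_table` data.frame sorted per arm by midpoint.
#' @export
genome_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("gene_id", "arm", "start", "end") %in% names(df)))
  df$gene_id <- as.character(df$gene_id)
  df$arm <- as.character(df$arm)
  if (is.null(df$strand)) df$strand <- rep(".", nrow(df))
  if (is.null(df$biotype)) df$biotype <- rep("protein_coding", nrow(df))
  df$strand <- as.character(df$strand)
  if (anyNA(match(df$biotype, VALID_BIOTYPES))) {
    df$biotype[!(df$biotype %in% VALID_BIOTYPES)] <- "other"
  }
  if (any(df$start >= df$end)) {
    stop("invalid interval (start >= end) for gene(s): ",
         paste(utils::head(df$gene_id[df$start >= df$end], 5), collapse = ", "))
  }
  if (any(!nzchar(df$arm))) stop("empty arm label")
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) stop("duplicate gene_id: ", paste(utils::head(dup, 5), collapse = ", "))
  df$midpoint <- (df$start + df$end) / 2
  ord <- order(df$arm, df$midpoint, df$gene_id, method = "radix")
  df <- df[ord, c("gene_id", "arm", "start", "end", "strand", "biotype", "midpoint")]
  rownames(df) <- NULL
  class(df) <- c("genome_table", "data.frame")
  df
}

#' Read a gene coordinate table from BED or GFF3
#'
#' BED is taken as-is (0-based half-open); GFF3 coordinates are converted from
#' 1-based closed to the internal convention. For GFF3, rows with
#' `type == "gene"` are used when present (otherwise all rows); the gene id is
#' taken from the `ID`, `gene_id` or `Name` attribute, in that order, and a
#' `gene_biotype`/`biotype` attribute is honoured when present.
#'
#' @param path file path.
#' @param format "BED" or "GFF3" (default: inferred from extension).
#' @return a [genome_table()].
#' @export
read_gene_table <- function(path, format = c("auto", "BED", "GFF3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "GFF3" else "BED"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "BED") "bed" else "gff3"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  mc <- S4Vectors::mcols(gr)
  if (format == "GFF3" && !is.null(mc$type) && any(mc$type == "gene")) {
    gr <- gr[mc$type == "gene"]
    mc <- S4Vectors::mcols(gr)
  }
  id <- NULL
  for (col in c("name", "ID", "gene_id", "Name")) {
    if (!is.null(mc[[col]])) { id <- as.character(mc[[col]]); break }
  }
  if (is.null(id) || anyNA(id)) stop("could not determine gene ids from ", path)
  biotype <- rep("protein_coding", length(gr))
  for (col in c("gene_biotype", "biotype")) {
    if (!is.null(mc[[col]])) { biotype <- as.character(mc[[col]]); break }
  }
  biotype[is.na(biotype)] <- "protein_coding"
  # GRanges is 1-based closed regardless of source format; shift back.
  genome_table(data.frame(
    gene_id = id,
    arm = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype,
    stringsAsFactors = FALSE
  ))
}

#' Write a genome table as BED
#'
#' @param genome a [genome_table()].
#' @param path output path.
#' @export
write_gene_table <- function(genome, path) {
  stopifnot(inherits(genome, "genome_table"))
  strand <- ifelse(genome$strand %in% c("+", "-"), genome$strand, ".")
  utils::write.table(
    data.frame(genome$arm, genome$start, genome$end, genome$gene_id, 0L, strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-arm gene ranks (1-based, by midpoint order)
#'
#' @param genome a [genome_table()].
#' @return data.frame gene_id, arm, rank.
#' @export
genome_ranks <- function(genome) {
  stopifnot(inherits(genome, "genome_table"))
  rk <- stats::ave(seq_len(nrow(genome)), genome$arm, FUN = seq_along)
  data.frame(gene_id = genome$gene_id, arm = genome$arm, rank = rk,
             stringsAsFactors = FALSE)
}
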