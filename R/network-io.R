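#' Interaction networks
#'
#' An `interaction_network` is a light S3 wrapper around a deduplicated edge
#' table (`source`, `target`, optional `confidence`) plus the node set and a
#' `directed` flag. Graph algorithms convert to igraph on demand via
#' [as_igraph()].
#'
#' @name interaction-network
NULL

#' Construct an interaction network from an edge table
#'
#' @param edges data.frame with columns source, target and optionally
#'   confidence in \[0,1\].
#' @param directed logical; undirected networks store each edge once.
#' @param allow_self_loops drop (with a reported count) or keep self loops.
#' @return an `interaction_network`.
#' @export
interaction_network <- function(edges, directed = FALSE, allow_self_loops = FALSE) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0) {
    edges <- data.frame(source = character(), target = character())
  }
  stopifnot(all(c("source", "target") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if ("confidence" %in% names(edges)) {
    if (!is.numeric(edges$confidence)) stop("non-numeric confidence score")
  }
  n_loops <- sum(edges$source == edges$target)
  if (!allow_self_loops && n_loops > 0) {
    msg("dropped %d self-loop edge(s)", n_loops)
    edges <- edges[edges$source != edges$target, , drop = FALSE]
  }
  # canonicalize undirected pairs so dedup is order-insensitive
  key <- if (directed) paste(edges$source, edges$target, sep = "\r")
         else paste(pmin(edges$source, edges$target),
                    pmax(edges$source, edges$target), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) edges <- edges[!dup, , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         nodes = sort(unique(c(edges$source, edges$target))),
         directed = directed),
    class = "interaction_network")
}

#' @export
#' @method print interaction_network
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d %s edges\n",
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Read a TSV/SIF edge list
#'
#' TSV columns: source, target, optional confidence (header optional, detected
#' by non-numeric third field named "confidence" or a header line). SIF lines
#' are `source relation target...`.
#'
#' @param path file path.
#' @param directed logical.
#' @return an [interaction_network()].
#' @export
read_edge_list <- function(path, directed = FALSE) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty edge list: ", path)
    return(interaction_network(data.frame(source = character(), target = character()),
                               directed = directed))
  }
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    fields <- strsplit(readLines(path), "[\t ]+")
    edges <- do.call(rbind, lapply(fields, function(f) {
      if (length(f) < 3) stop("malformed SIF line: ", paste(f, collapse = " "))
      data.frame(source = f[1], target = f[-(1:2)], stringsAsFactors = FALSE)
    }))
    return(interaction_network(edges, directed = directed))
  }
  has_header <- grepl("^source\t", first)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[1:2] <- c("source", "target")
    if (ncol(df) >= 3) names(df)[3] <- "confidence"
  }
  if ("confidence" %in% names(df) && !is.numeric(df$confidence)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$confidence))) &
                   !is.na(df$confidence))
    stop("non-numeric confidence at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  interaction_network(df, directed = directed)
}

#' Write an edge list as TSV
#' @param net an [interaction_network()].
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert to igraph
#' @param net an [interaction_network()].
#' @return an igraph graph with vertex names = gene ids.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  igraph::graph_from_data_frame(net$edges, directed = net$directed,
                                vertices = data.frame(name = net$nodes))
}
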