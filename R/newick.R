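#' Newick I/O for dendrograms
#'
#' Merge trees are carried as base [stats::dendrogram] objects (the container
#' `hclust` output converts to): nested lists with `height`, `members` and
#' leaf `label` attributes. Newick text is parsed with ape and converted so
#' that a node's height is its maximum distance to a descendant leaf; writing
#' emits branch lengths `height(parent) - height(child)` (leaves at height 0
#' for ultrametric trees), so read(write(tree)) preserves topology, heights
#' and leaf order.
#'
#' @name newick
NULL

#' Read a Newick tree as a dendrogram
#'
#' @param path path to a Newick file (branch lengths required).
#' @return a [stats::dendrogram].
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy)) stop("Newick parse error in ", path)
  phylo_to_dendrogram(phy)
}

#' Write a dendrogram as Newick
#'
#' @param dend a [stats::dendrogram].
#' @param path output path.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "dendrogram"))
  writeLines(paste0(dend_to_newick(dend, attr(dend, "height")), ";"), path)
  invisible(path)
}

dend_to_newick <- function(node, parent_height) {
  h <- attr(node, "height")
  bl <- sprintf("%.10g", parent_height - h)
  if (is.leaf(node)) return(paste0(attr(node, "label"), ":", bl))
  inner <- vapply(node, dend_to_newick, "", parent_height = h)
  paste0("(", paste(inner, collapse = ","), "):", bl)
}

#' Convert an ape phylo tree to a dendrogram
#'
#' Node heights are reconstructed as the maximum root-path distance from the
#' node down to any descendant leaf, which inverts the convention used by
#' [write_newick()].
#'
#' @param phy an `ape::phylo` object with edge lengths.
#' @return a [stats::dendrogram].
#' @export
phylo_to_dendrogram <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("Newick tree lacks branch lengths")
  ntip <- length(phy$tip.label)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  counter <- new.env(parent = emptyenv()); counter$i <- 0L

  build <- function(node) {
    if (node <= ntip) {
      counter$i <- counter$i + 1L
      leaf <- counter$i
      attributes(leaf) <- list(members = 1L, height = 0,
                               label = phy$tip.label[node], leaf = TRUE)
      class(leaf) <- "dendrogram"
      return(leaf)
    }
    rows <- children[[as.character(node)]]
    kids <- lapply(seq_along(rows), function(j) {
      kid <- build(phy$edge[rows[j], 2])
      attr(kid, ".blen") <- phy$edge.length[rows[j]]
      kid
    })
    h <- max(vapply(kids, function(k) attr(k, "height") + attr(k, ".blen"), 0))
    kids <- lapply(kids, function(k) { attr(k, ".blen") <- NULL; k })
    out <- kids
    attributes(out) <- list(members = sum(vapply(kids, attr, 1L, "members")),
                            height = h, class = "dendrogram")
    out
  }
  build(ntip + 1L)
}

#' Left-to-right leaf labels of a dendrogram
#' @param dend a [stats::dendrogram].
#' @return character vector of leaf labels in display order.
#' @export
leaf_order <- function(dend) {
  stopifnot(inherits(dend, "dendrogram"))
  labels(dend)
}
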