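#' Construct a directed gene network
#'
#' @param genes character vector of unique gene identifiers; its order is
#'   the node order used throughout.
#' @param edges two-column character matrix or data.frame of directed edges
#'   `(from, to)`; `NULL` or zero rows for the empty network. Duplicate rows
#'   are an error (use [readNetwork()] for lenient file input).
#' @return a [GeneNetwork-class].
#' @examples
#' net <- geneNetwork(c("v1", "v2", "v3"),
#'                    rbind(c("v1", "v1"), c("v1", "v3"), c("v2", "v3")))
#' parents(net, "v3")
#' @export
geneNetwork <- function(genes, edges = NULL) {
  genes <- as.character(genes)
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(0), ncol = 2)
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
    em <- matrix(as.character(edges), ncol = 2)
  }
  colnames(em) <- c("from", "to")
  new("GeneNetwork", genes = genes, edges = em)
}

#' @describeIn geneNetwork the empty network over a gene set.
#' @export
emptyNetwork <- function(genes) geneNetwork(genes, NULL)

#' @rdname genes
#' @export
setMethod("genes", "GeneNetwork", function(x) x@genes)

#' @rdname edges
#' @export
setMethod("edges", "GeneNetwork", function(x) x@edges)

#' @rdname nGenes
#' @export
setMethod("nGenes", "GeneNetwork", function(x) length(x@genes))

#' @rdname parents
#' @export
setMethod("parents", "GeneNetwork", function(x, node) {
  stopifnot(node %in% x@genes)
  p <- x@edges[x@edges[, 2] == node, 1]
  # return in gene order for deterministic enumeration downstream
  x@genes[sort(match(p, x@genes))]
})

#' @rdname inDegree
#' @export
setMethod("inDegree", "GeneNetwork", function(x, node) {
  stopifnot(node %in% x@genes)
  sum(x@edges[, 2] == node)
})

#' Number of edges in a network
#'
#' @param network a [GeneNetwork-class].
#' @return integer.
#' @export
nEdges <- function(network) nrow(network@edges)

#' Test whether specific edges are present
#'
#' @param network a [GeneNetwork-class].
#' @param from,to character vectors (recycled) of edge endpoints.
#' @return logical vector.
#' @export
hasEdge <- function(network, from, to) {
  key <- paste(network@edges[, 1], network@edges[, 2], sep = "\r")
  paste(from, to, sep = "\r") %in% key
}

#' Add and delete edges of a network
#'
#' Applies a modification: `deleted` edges must be present, `added` edges
#' absent. Used both by the completion traceback and by the synthetic
#' modification protocol.
#'
#' @param network a [GeneNetwork-class].
#' @param added,deleted two-column character matrices (or `NULL`).
#' @return the modified [GeneNetwork-class].
#' @export
applyModification <- function(network, added = NULL, deleted = NULL) {
  em <- network@edges
  if (!is.null(deleted) && nrow(deleted) > 0) {
    key <- paste(em[, 1], em[, 2], sep = "\r")
    dkey <- paste(deleted[, 1], deleted[, 2], sep = "\r")
    if (!all(dkey %in% key))
      stop("cannot delete an edge that is not present")
    em <- em[!(key %in% dkey), , drop = FALSE]
  }
  if (!is.null(added) && nrow(added) > 0) {
    key <- paste(em[, 1], em[, 2], sep = "\r")
    akey <- paste(added[, 1], added[, 2], sep = "\r")
    if (any(akey %in% key) || anyDuplicated(akey))
      stop("cannot add an edge that is already present")
    em <- rbind(em, matrix(as.character(added), ncol = 2))
  }
  geneNetwork(network@genes, em)
}

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork: %d genes, %d directed edges (%d self-loops)\n",
              nGenes(object), nEdges(object),
              sum(object@edges[, 1] == object@edges[, 2])))
  if (nEdges(object) > 0) {
    shown <- utils::head(seq_len(nEdges(object)), 8)
    cat("  ", paste(sprintf("%s->%s", object@edges[shown, 1],
                            object@edges[shown, 2]), collapse = " "),
        if (nEdges(object) > 8) " ..." else "", "\n", sep = "")
  }
})
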