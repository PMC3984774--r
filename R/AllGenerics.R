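#' Gene identifiers of an object
#'
#' @param x a [GeneNetwork-class], [ExpressionMatrix-class] or
#'   [EquationSystem-class].
#' @return character vector of gene identifiers, in the object's order.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Edge set of a network-like object
#'
#' @param x a [GeneNetwork-class], [EquationSystem-class] or
#'   [CompletionResult-class].
#' @return two-column character matrix (`from`, `to`).
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Parent set (incoming regulators) of a gene
#'
#' @param x a [GeneNetwork-class].
#' @param node a gene identifier.
#' @return character vector of genes with an edge into `node`, in gene
#'   order.
#' @export
setGeneric("parents", function(x, node) standardGeneric("parents"))

#' In-degree of a gene
#'
#' @inheritParams parents
#' @return integer, the number of incoming edges (self-loops count).
#' @export
setGeneric("inDegree", function(x, node) standardGeneric("inDegree"))

#' Number of genes
#'
#' @param x a [GeneNetwork-class], [ExpressionMatrix-class] or
#'   [EquationSystem-class].
#' @return integer.
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' Number of samples
#'
#' @param x an [ExpressionMatrix-class].
#' @return integer.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Expression values as a base matrix
#'
#' @param x an [ExpressionMatrix-class].
#' @return numeric genes-by-samples matrix with gene rownames.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Gold-standard network induced by a synthetic system
#'
#' @param x an [EquationSystem-class].
#' @return the induced [GeneNetwork-class]: a self-loop per source gene and
#'   one edge per derived-rule parent.
#' @export
setGeneric("goldStandard", function(x) standardGeneric("goldStandard"))
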