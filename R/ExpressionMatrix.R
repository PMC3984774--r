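#' Construct a static expression matrix
#'
#' @param values numeric matrix, genes in rows, samples in columns. Rownames
#'   are the gene identifiers (required, unique); missing colnames are
#'   filled with `s1, s2, ...`.
#' @return an [ExpressionMatrix-class].
#' @examples
#' m <- matrix(c(2, 3, 5, 2, -2, -5), nrow = 3,
#'             dimnames = list(c("v1", "v2", "v3"), NULL))
#' expressionMatrix(m)
#' @export
expressionMatrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  new("ExpressionMatrix", values = values)
}

#' @rdname genes
#' @export
setMethod("genes", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname nGenes
#' @export
setMethod("nGenes", "ExpressionMatrix", function(x) nrow(x@values))

#' @rdname nSamples
#' @export
setMethod("nSamples", "ExpressionMatrix", function(x) ncol(x@values))

#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(object@values), ncol(object@values)))
  cat(sprintf("  genes: %s%s\n",
              paste(utils::head(rownames(object@values), 6), collapse = ", "),
              if (nrow(object@values) > 6) ", ..." else ""))
  rng <- range(object@values)
  cat(sprintf("  value range: [%.4g, %.4g]\n", rng[1], rng[2]))
})
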