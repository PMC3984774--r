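# File formats: expression TSV (first column = gene id, header row = sample
# ids), edge-list TSV (two columns: source, target) and SIF (source,
# interaction label, target; the label is written as "regulates" and
# ignored on read). Numeric parsing and writing are locale-independent.

#' Read a static expression matrix from TSV
#'
#' Tab-separated text with sample identifiers in the first (header) row and
#' gene identifiers in the first column. Gene order follows first
#' appearance in the file, and is the node order used by the dynamic
#' program downstream.
#'
#' @param path file path.
#' @return an [ExpressionMatrix-class].
#' @export
readExpression <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  if (length(samples) < 1) stop("expression file has no sample columns: ", path)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != length(header)))
    stop("ragged expression file: row(s) ",
         paste(which(widths != length(header)), collapse = ", "),
         " do not have ", length(header), " fields")
  geneIds <- vapply(body, `[[`, "", 1)
  if (anyDuplicated(geneIds))
    stop("duplicate gene identifier(s): ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(v))) stop("non-numeric expression value in row for gene ",
                            f[[1]])
    v
  }, numeric(length(samples)))
  m <- matrix(vals, ncol = length(samples), byrow = TRUE,
              dimnames = list(geneIds, samples))
  expressionMatrix(m)
}

#' Write a static expression matrix to TSV
#'
#' @param expr an [ExpressionMatrix-class].
#' @param path output file path.
#' @param digits significant digits for serialization (default 12).
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path, digits = 12) {
  v <- exprValues(expr)
  lines <- c(paste(c("gene", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i],
                       formatC(v[i, ], digits = digits, format = "g")),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed network from edge-list or SIF text
#'
#' Edge-list dialect: two tab-separated columns `source`, `target`, with an
#' optional `source<TAB>target`-style header. SIF dialect: `source`,
#' interaction label (ignored), `target`. Genes not in `genes` are declared
#' implicitly, with a warning; duplicate edges are deduplicated with a
#' warning. An empty file yields the empty network (a valid inference
#' seed).
#'
#' @param path file path.
#' @param dialect `"edgelist"` (default) or `"sif"`.
#' @param genes optional character vector fixing the gene universe and
#'   order (e.g. from the expression file).
#' @return a [GeneNetwork-class].
#' @export
readNetwork <- function(path, dialect = c("edgelist", "sif"), genes = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  want <- if (dialect == "sif") 3L else 2L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && dialect == "edgelist" &&
      identical(tolower(fields[[1]][1]), "source"))
    fields <- fields[-1]
  if (length(fields) && any(lengths(fields) != want))
    stop("malformed ", dialect, " file: expected ", want,
         " tab-separated fields per line")
  em <- if (length(fields)) {
    t(vapply(fields, function(f)
      if (want == 3L) c(f[1], f[3]) else c(f[1], f[2]), character(2)))
  } else matrix(character(0), ncol = 2)
  key <- edgeKey(em[, 1], em[, 2])
  if (anyDuplicated(key)) {
    warning("duplicate edge(s) deduplicated in ", path)
    em <- em[!duplicated(key), , drop = FALSE]
  }
  seen <- unique(as.vector(t(em)))
  if (is.null(genes)) {
    genes <- seen
  } else if (!all(seen %in% genes)) {
    warning("edge file declares gene(s) absent from the given universe: ",
            paste(setdiff(seen, genes), collapse = ", "))
    genes <- c(genes, setdiff(seen, genes))
  }
  geneNetwork(genes, em)
}

#' Write a directed network to edge-list or SIF text
#'
#' The writer's output re-reads (with [readNetwork()]) to an identical edge
#' set; the SIF interaction label is written as `"regulates"`.
#'
#' @param network a [GeneNetwork-class].
#' @param path output file path.
#' @param dialect `"edgelist"` (default) or `"sif"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path, dialect = c("edgelist", "sif")) {
  dialect <- match.arg(dialect)
  em <- edges(network)
  lines <- if (dialect == "sif") {
    sprintf("%s\t%s\t%s", em[, 1], "regulates", em[, 2])
  } else {
    c("source\ttarget", sprintf("%s\t%s", em[, 1], em[, 2]))
  }
  writeLines(lines, path)
  invisible(path)
}
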