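#' @import methods
NULL

#' Directed gene regulatory network
#'
#' A directed graph over a fixed, ordered set of genes. Edges are ordered
#' pairs `(source, target)`; self-loops (autoregulation) are permitted.
#' Duplicate edges are not, and every edge endpoint must be a listed gene.
#'
#' @slot genes character vector of unique gene identifiers; the order fixes
#'   the node order used by the dynamic program (the optimum is
#'   order-invariant, but argmin tie-breaking is stated in terms of gene
#'   positions).
#' @slot edges two-column character matrix with columns `from`, `to`; zero
#'   rows encode the empty network.
#'
#' @seealso [geneNetwork()], [parents()], [inDegree()], [completeNetwork()]
#' @export
setClass("GeneNetwork",
  representation(genes = "character", edges = "matrix"),
  prototype(genes = character(0),
            edges = matrix(character(0), ncol = 2,
                           dimnames = list(NULL, c("from", "to")))))

setValidity("GeneNetwork", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "gene identifiers must be unique")
  if (any(is.na(object@genes)) || any(object@genes == ""))
    msgs <- c(msgs, "gene identifiers must be non-missing and non-empty")
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2) {
    msgs <- c(msgs, "edges must be a two-column character matrix")
  } else {
    if (nrow(e) > 0) {
      if (!all(e %in% object@genes))
        msgs <- c(msgs, "every edge endpoint must be a listed gene")
      if (anyDuplicated(paste(e[, 1], e[, 2], sep = "\r")))
        msgs <- c(msgs, "duplicate edges are not allowed")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Static expression matrix
#'
#' Genes-by-samples matrix of real-valued steady-state expression levels.
#' Each column is one sample's observation of the stationary regulatory
#' state; no preprocessing (centering, scaling, log transform) is applied by
#' the package.
#'
#' @slot values numeric matrix, genes in rows (unique rownames), samples in
#'   columns; all entries finite, at least one sample.
#'
#' @seealso [expressionMatrix()], [readExpression()], [fitNode()]
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (ncol(v) < 1) msgs <- c(msgs, "at least one sample is required")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "rows must carry unique gene identifiers")
  if (is.numeric(v) && length(v) && !all(is.finite(v)))
    msgs <- c(msgs, "all expression values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Per-gene quadratic regulation model
#'
#' The stationary expression of a gene is modelled as
#' \deqn{x = a_0 + \sum_j a_j x_{p_j} + \sum_{j \le k} a_{jk} x_{p_j} x_{p_k},}
#' a quadratic polynomial in the expression of its ordered parents
#' \eqn{p_1, \dots, p_h} (pure squares included). The additive noise term of
#' the generative model is never a fitted coefficient; it is absorbed into
#' the least-squares residual.
#'
#' @slot node gene identifier of the modelled target.
#' @slot parents ordered character vector of parent genes (length `h`).
#' @slot intercept the constant term \eqn{a_0}.
#' @slot linear numeric vector of length `h`, linear coefficients aligned to
#'   `parents`.
#' @slot quadratic numeric vector of length `h(h+1)/2`, coefficients of the
#'   pairwise products in the fixed order `(1,1), (1,2), ..., (1,h), (2,2),
#'   ..., (h,h)` (the order produced by [designRow()]).
#'
#' @seealso [fitNode()], [designRow()]
#' @export
setClass("NodeModel",
  representation(node = "character", parents = "character",
                 intercept = "numeric", linear = "numeric",
                 quadratic = "numeric"))

setValidity("NodeModel", function(object) {
  h <- length(object@parents)
  msgs <- character(0)
  if (length(object@intercept) != 1) msgs <- c(msgs, "intercept must be scalar")
  if (length(object@linear) != h)
    msgs <- c(msgs, "one linear coefficient per parent is required")
  if (length(object@quadratic) != h * (h + 1) / 2)
    msgs <- c(msgs, "quadratic coefficients must number h(h+1)/2")
  if (anyDuplicated(object@parents)) msgs <- c(msgs, "parents must be distinct")
  if (length(msgs)) msgs else TRUE
})

#' Result of a least-squares node fit
#'
#' @slot model the fitted [NodeModel-class].
#' @slot residualError nonnegative sum of squared residuals over samples
#'   (the minimised objective value).
#' @slot rankDeficient `TRUE` when the design matrix was rank deficient and
#'   the minimum-norm solution was returned.
#'
#' @seealso [fitNode()]
#' @export
setClass("FitResult",
  representation(model = "NodeModel", residualError = "numeric",
                 rankDeficient = "logical"))

setValidity("FitResult", function(object) {
  if (length(object@residualError) != 1 || is.na(object@residualError) ||
      object@residualError < 0)
    return("residualError must be a single nonnegative number")
  TRUE
})

#' Budgets and caps for network completion
#'
#' Total modification budgets and per-gene caps. Exactly `k` edges are added
#' and `h` deleted in a feasible completion; no single gene may receive more
#' than `K` additions or `H` deletions. The per-gene enumeration is
#' \eqn{O(n^K)} per gene, so caps above 3 are refused unless `override` is
#' set at construction.
#'
#' @slot k total number of edge additions (nonnegative integer).
#' @slot h total number of edge deletions (nonnegative integer).
#' @slot K per-gene addition cap.
#' @slot H per-gene deletion cap.
#'
#' @seealso [completionSpec()], [completeNetwork()]
#' @export
setClass("CompletionSpec",
  representation(k = "integer", h = "integer", K = "integer", H = "integer"))

setValidity("CompletionSpec", function(object) {
  for (s in c("k", "h", "K", "H")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 0)
      return(sprintf("'%s' must be a single nonnegative integer", s))
  }
  TRUE
})

#' Per-gene minimal-error table over modification budgets
#'
#' For every gene `j` and every per-gene budget pair `(k_j <= K, h_j <= H)`,
#' the minimum least-squares error attainable by adding `k_j` parents (from
#' the candidate set) and deleting `h_j` current parents, together with the
#' argmin added/deleted sets. Infeasible cells hold `Inf` and empty sets.
#'
#' @slot genes gene identifiers, in network order.
#' @slot entries list, one element per gene, each holding the value matrix
#'   (`(K+1) x (H+1)`) and argmin edge sets (internal layout).
#' @slot K,H the caps the table was computed under.
#' @slot nFits number of least-squares fits performed while filling the
#'   table (instrumentation; see the complexity discussion in the vignette).
#'
#' @seealso [sigmaTable()], [sigmaEntry()]
#' @export
setClass("SigmaTable",
  representation(genes = "character", entries = "list",
                 K = "integer", H = "integer", nFits = "integer"))

#' Dynamic-programming table over cumulative budgets
#'
#' `D[k', h', i]` is the minimum total error over the first `i` genes when
#' exactly `k'` additions and `h'` deletions are spent among them. Split
#' records store, for each cell, the per-gene budget assigned to gene `i`,
#' enabling traceback of the optimal modification.
#'
#' @slot D numeric array `(k+1) x (h+1) x n` of cumulative minima.
#' @slot splitK,splitH integer arrays of the same shape: budget spent on
#'   gene `i` at each cell.
#' @slot genes gene order the table was filled in.
#'
#' @seealso [dpAddDel()], [tracebackCompletion()]
#' @export
setClass("DPTable",
  representation(D = "array", splitK = "array", splitH = "array",
                 genes = "character"))

#' Result of a network completion
#'
#' @slot completed the completed [GeneNetwork-class] (meaningful only when
#'   `feasible`).
#' @slot added two-column character matrix of added edges.
#' @slot deleted two-column character matrix of deleted edges.
#' @slot totalError the optimum `D[k, h, n]`; equals the sum of per-gene
#'   least-squares errors under the completed parent sets.
#' @slot feasible `FALSE` when no decomposition of the budgets satisfies the
#'   per-gene caps and degree constraints.
#'
#' @seealso [completeNetwork()], [inferNetwork()]
#' @export
setClass("CompletionResult",
  representation(completed = "GeneNetwork", added = "matrix",
                 deleted = "matrix", totalError = "numeric",
                 feasible = "logical"))

#' Synthetic quadratic fixed-point equation system
#'
#' A triangular system of `n` quadratic fixed-point equations over genes
#' `v1..vn`. Source genes obey `x = x^2 - c` with two distinct integer
#' roots; derived genes are degree-at-most-2 polynomials in strictly
#' lower-indexed genes, so every choice of source roots extends uniquely to
#' an exact solution and the system has `2^s` enumerable solutions for `s`
#' sources. The induced gold-standard network carries one self-loop per
#' source and one edge per derived-rule parent.
#'
#' @slot genes gene identifiers `v1..vn`.
#' @slot sources integer indices of source genes.
#' @slot roots list of numeric length-2 root vectors, one per source.
#' @slot rules list, one per gene, each a list with elements `parents`
#'   (integer indices), `intercept`, `linear`, `quadratic` (same layout as
#'   [NodeModel-class]).
#' @slot network the induced gold-standard [GeneNetwork-class].
#' @slot seed the generator seed (`NA` for hand-built systems).
#'
#' @seealso [generateSystem()], [exemplarSystem()], [enumerateSolutions()]
#' @export
setClass("EquationSystem",
  representation(genes = "character", sources = "integer", roots = "list",
                 rules = "list", network = "GeneNetwork", seed = "integer"))

setValidity("EquationSystem", function(object) {
  n <- length(object@genes)
  if (length(object@rules) != n) return("one rule per gene is required")
  for (i in seq_len(n)) {
    p <- object@rules[[i]]$parents
    if (i %in% object@sources) {
      if (!identical(as.integer(p), i))
        return("source rules must be self-quadratics")
    } else if (length(p) && any(p >= i)) {
      return("derived rules may reference only lower-indexed genes")
    }
  }
  if (length(object@roots) != length(object@sources))
    return("one root pair per source is required")
  TRUE
})

#' Accuracy report from a benchmark run
#'
#' @slot mode `"completion"` or `"inference"`.
#' @slot matchingMode `"directed"` or `"undirected"` edge matching.
#' @slot runs data.frame with one row per run: seed, accuracy, feasibility,
#'   wall time in seconds (informational only).
#' @slot meanAccuracy mean accuracy over feasible runs.
#' @slot config list echoing the resolved benchmark configuration.
#'
#' @seealso [runBenchmark()]
#' @export
setClass("AccuracyReport",
  representation(mode = "character", matchingMode = "character",
                 runs = "data.frame", meanAccuracy = "numeric",
                 config = "list"))
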