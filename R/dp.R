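#' Dynamic program for completion by edge addition only
#'
#' Fills the table \eqn{D^+[k', i]}: the minimum total least-squares error
#' over the first `i` genes when exactly `k'` edges are added among them,
#' by the recurrence
#' \eqn{D^+[k', j+1] = \min_{k'' } \{ D^+[k'-k'', j] + \sigma^+_{k'', j+1} \}.}
#' The optimum \eqn{D^+[k, n]} does not depend on the gene ordering.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param network a [GeneNetwork-class].
#' @param k total addition budget.
#' @param spec a [CompletionSpec-class] with `h = 0` and `H = 0` (addition
#'   only).
#' @param allowSelfLoops passed to [candidateParents()].
#' @param sigma optional precomputed [SigmaTable-class] for this instance.
#' @return a [DPTable-class] with a singleton deletion dimension.
#' @export
dpAdd <- function(expr, network, k, spec = completionSpec(k, 0, K = 2, H = 0),
                  allowSelfLoops = FALSE, sigma = NULL) {
  stopifnot(spec@H == 0L, spec@h == 0L)
  spec@k <- as.integer(k)
  if (is.null(sigma)) sigma <- sigmaTable(expr, network, spec, allowSelfLoops)
  g <- genes(network)
  n <- length(g)
  D <- array(Inf, dim = c(k + 1L, 1L, n))
  splitK <- array(NA_integer_, dim = dim(D))
  splitH <- array(0L, dim = dim(D))
  for (kp in 0:k) {
    e <- sigmaEntry(sigma, g[1], kp, 0L)
    D[kp + 1L, 1L, 1L] <- e$value
    splitK[kp + 1L, 1L, 1L] <- kp
  }
  if (n > 1) for (i in 2:n) for (kp in 0:k) {
    for (kpp in 0:kp) {
      v <- D[kp - kpp + 1L, 1L, i - 1L] + sigmaEntry(sigma, g[i], kpp, 0L)$value
      if (v < D[kp + 1L, 1L, i]) {
        D[kp + 1L, 1L, i] <- v
        splitK[kp + 1L, 1L, i] <- kpp
      }
    }
  }
  new("DPTable", D = D, splitK = splitK, splitH = splitH, genes = g)
}

#' Dynamic program for completion by edge addition and deletion
#'
#' Fills the table `D[k', h', i]`: the minimum total least-squares error
#' over the first `i` genes when exactly `k'` additions and `h'` deletions
#' are spent among them, by the two-budget recurrence
#' \eqn{D[k', h', j+1] = \min_{k'' , h''} \{ D[k'-k'', h'-h'', j] +
#' \sigma_{k'', h'', j+1} \}.}
#' `D[k, h, n]` is the completion optimum; split records are stored for
#' traceback. Among equal-value splits the smallest `k''`, then the
#' smallest `h''`, is recorded.
#'
#' @inheritParams dpAdd
#' @param spec a [CompletionSpec-class] carrying `k`, `h`, `K`, `H`.
#' @return a [DPTable-class].
#' @export
dpAddDel <- function(expr, network, spec, allowSelfLoops = FALSE,
                     sigma = NULL) {
  if (is.null(sigma)) sigma <- sigmaTable(expr, network, spec, allowSelfLoops)
  g <- genes(network)
  n <- length(g)
  k <- spec@k
  h <- spec@h
  D <- array(Inf, dim = c(k + 1L, h + 1L, n))
  splitK <- array(NA_integer_, dim = dim(D))
  splitH <- array(NA_integer_, dim = dim(D))
  for (kp in 0:k) for (hp in 0:h) {
    e <- sigmaEntry(sigma, g[1], kp, hp)
    D[kp + 1L, hp + 1L, 1L] <- e$value
    splitK[kp + 1L, hp + 1L, 1L] <- kp
    splitH[kp + 1L, hp + 1L, 1L] <- hp
  }
  if (n > 1) for (i in 2:n) {
    ent <- sigma@entries[[match(g[i], sigma@genes)]]$value
    kTop <- min(k, nrow(ent) - 1L)
    hTop <- min(h, ncol(ent) - 1L)
    for (kp in 0:k) for (hp in 0:h) {
      for (kpp in 0:min(kp, kTop)) for (hpp in 0:min(hp, hTop)) {
        s <- ent[kpp + 1L, hpp + 1L]
        if (!is.finite(s)) next
        prev <- D[kp - kpp + 1L, hp - hpp + 1L, i - 1L]
        if (!is.finite(prev)) next
        v <- prev + s
        if (v < D[kp + 1L, hp + 1L, i]) {
          D[kp + 1L, hp + 1L, i] <- v
          splitK[kp + 1L, hp + 1L, i] <- kpp
          splitH[kp + 1L, hp + 1L, i] <- hpp
        }
      }
    }
  }
  new("DPTable", D = D, splitK = splitK, splitH = splitH, genes = g)
}

#' Recover the optimal completion from the DP table
#'
#' Walks the split records from the final cell `(k, h, n)` down to the
#' first gene, collecting each gene's argmin added and deleted edge sets
#' from the sigma table, and applies them to the network. When the optimum
#' is infinite the instance is infeasible and the input network is returned
#' unmodified with `feasible = FALSE` (never a partial completion).
#'
#' @param table a [DPTable-class].
#' @param sigma the [SigmaTable-class] the DP consumed.
#' @param network the original [GeneNetwork-class].
#' @param k,h the total budgets the table was filled for (defaults: the
#'   table's maxima).
#' @return a [CompletionResult-class]; `@totalError` equals `D[k, h, n]`.
#' @export
tracebackCompletion <- function(table, sigma, network,
                                k = dim(table@D)[1] - 1L,
                                h = dim(table@D)[2] - 1L) {
  g <- table@genes
  n <- length(g)
  opt <- table@D[k + 1L, h + 1L, n]
  emptyEdges <- matrix(character(0), ncol = 2,
                       dimnames = list(NULL, c("from", "to")))
  if (!is.finite(opt)) {
    return(new("CompletionResult", completed = network, added = emptyEdges,
               deleted = emptyEdges, totalError = Inf, feasible = FALSE))
  }
  added <- NULL
  deleted <- NULL
  kp <- as.integer(k)
  hp <- as.integer(h)
  for (i in n:1) {
    kpp <- table@splitK[kp + 1L, hp + 1L, i]
    hpp <- table@splitH[kp + 1L, hp + 1L, i]
    e <- sigmaEntry(sigma, g[i], kpp, hpp)
    if (length(e$added))
      added <- rbind(added, cbind(e$added, g[i]))
    if (length(e$deleted))
      deleted <- rbind(deleted, cbind(e$deleted, g[i]))
    kp <- kp - kpp
    hp <- hp - hpp
  }
  stopifnot(kp == 0L, hp == 0L)
  if (is.null(added)) added <- emptyEdges
  if (is.null(deleted)) deleted <- emptyEdges
  colnames(added) <- colnames(deleted) <- c("from", "to")
  completed <- applyModification(network, added = added, deleted = deleted)
  new("CompletionResult", completed = completed, added = added,
      deleted = deleted, totalError = opt, feasible = TRUE)
}

#' Complete a network against steady-state expression data
#'
#' Modifies the given network by exactly `spec@k` edge additions and
#' `spec@h` edge deletions so that the sum over genes of least-squares
#' errors of the quadratic regulation model is minimised, subject to the
#' per-gene caps `K` and `H`. Computes the per-gene minimal-error table,
#' runs the two-budget dynamic program and tracebacks the optimal edge
#' sets. The returned optimum is exact within the capped search space, and
#' deterministic (ties are broken lexicographically).
#'
#' @param expr an [ExpressionMatrix-class] whose genes include the
#'   network's.
#' @param network the initial [GeneNetwork-class].
#' @param spec a [CompletionSpec-class].
#' @param allowSelfLoops permit self-loop additions (off by default: the
#'   candidate rule excludes a gene from its own candidates).
#' @return a [CompletionResult-class].
#' @examples
#' sys <- exemplarSystem()
#' expr <- perturbSolutions(enumerateSolutions(sys), replicates = 50, seed = 1)
#' res <- completeNetwork(expr, goldStandard(sys), completionSpec(0, 0))
#' res@totalError
#' @export
completeNetwork <- function(expr, network, spec, allowSelfLoops = FALSE) {
  if (!all(genes(network) %in% genes(expr)))
    stop("expression data must cover every network gene")
  sig <- sigmaTable(expr, network, spec, allowSelfLoops)
  tab <- dpAddDel(expr, network, spec, allowSelfLoops, sigma = sig)
  res <- tracebackCompletion(tab, sig, network, spec@k, spec@h)
  res
}

#' Infer a network from steady-state expression data
#'
#' Network completion starting from the empty network: exactly `k` edges
#' are added (no deletions), each gene receiving at most `K`. The
#' convention used for the synthetic benchmarks is `K = 2`, `H = 0`.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param k total number of edges to add.
#' @param K per-gene addition cap.
#' @param allowSelfLoops permit self-loop additions.
#' @return a [CompletionResult-class] over `expr`'s genes.
#' @export
inferNetwork <- function(expr, k, K = 2, allowSelfLoops = FALSE) {
  net <- emptyNetwork(genes(expr))
  completeNetwork(expr, net, completionSpec(k, 0, K = K, H = 0),
                  allowSelfLoops = allowSelfLoops)
}

setMethod("show", "DPTable", function(object) {
  d <- dim(object@D)
  cat(sprintf("DPTable: budgets k=%d, h=%d over %d genes; optimum %.6g\n",
              d[1] - 1L, d[2] - 1L, d[3],
              object@D[d[1], d[2], d[3]]))
})

setMethod("show", "CompletionResult", function(object) {
  if (!object@feasible) {
    cat("CompletionResult: infeasible budgets\n")
    return(invisible(NULL))
  }
  cat(sprintf("CompletionResult: %d added, %d deleted, total error %.6g\n",
              nrow(object@added), nrow(object@deleted), object@totalError))
  if (nrow(object@added))
    cat("  added:  ", paste(sprintf("%s->%s", object@added[, 1],
                                    object@added[, 2]), collapse = " "), "\n")
  if (nrow(object@deleted))
    cat("  deleted:", paste(sprintf("%s->%s", object@deleted[, 1],
                                    object@deleted[, 2]), collapse = " "), "\n")
})

#' @rdname edges
#' @export
setMethod("edges", "CompletionResult", function(x) edges(x@completed))
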