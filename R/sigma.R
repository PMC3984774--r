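#' Budgets and caps constructor
#'
#' @param k,h total addition and deletion budgets.
#' @param K,H per-gene caps (defaults 2, the setting used throughout the
#'   completion benchmarks; inference uses `H = 0`).
#' @param override set `TRUE` to permit caps above 3. Per-gene enumeration
#'   grows as \eqn{\binom{n}{K}\binom{d}{H}}, so large caps (or dense
#'   initial networks) are refused by default.
#' @return a [CompletionSpec-class].
#' @export
completionSpec <- function(k, h = 0, K = 2, H = 2, override = FALSE) {
  if (!override && (K > 3 || H > 3))
    stop("per-gene caps above 3 are exponential to enumerate; ",
         "pass override = TRUE to force")
  new("CompletionSpec", k = as.integer(k), h = as.integer(h),
      K = as.integer(K), H = as.integer(H))
}

#' Candidate parents for edge addition
#'
#' Edges may be added to a gene only from genes that are not already its
#' parents; by default the gene itself is also excluded, so self-loops
#' cannot be added (they can still be deleted, since deletions draw from the
#' current parent set). Setting `allowSelfLoops` lifts the exclusion.
#'
#' @param network a [GeneNetwork-class].
#' @param node a gene of the network.
#' @param allowSelfLoops logical; permit adding a self-loop.
#' @return character vector of candidate source genes, in gene order.
#' @export
candidateParents <- function(network, node, allowSelfLoops = FALSE) {
  stopifnot(node %in% genes(network))
  excl <- parents(network, node)
  if (!allowSelfLoops) excl <- union(excl, node)
  setdiff(genes(network), excl)
}

# shared feasibility rule for a sigma cell
sigmaInfeasible <- function(kj, hj, deg, n, K, H, nCand) {
  kj > K || hj > H ||
    (kj - hj + deg) >= n || (kj - hj + deg) < 0 ||
    kj > nCand || hj > deg
}

#' Minimal least-squares error for one gene under a modification budget
#'
#' Exhaustively enumerates every way of deleting `hj` current parents of
#' `node` and adding `kj` candidate parents (the two sets are disjoint by
#' construction since candidates exclude current parents), fits each
#' resulting parent set by least squares, and returns the minimum error with
#' its argmin sets. Returns `Inf` (with empty sets) when the cell is
#' infeasible: `kj` above the cap `K`, `hj` above `H`, the modified
#' in-degree reaching `n` or falling below 0, or no choice existing.
#'
#' Ties are broken toward the lexicographically smallest deleted set (by
#' gene position), then the smallest added set, so results are
#' deterministic.
#'
#' @param expr an [ExpressionMatrix-class] covering the network's genes.
#' @param network a [GeneNetwork-class].
#' @param node a gene of the network.
#' @param kj,hj per-gene addition and deletion counts.
#' @param spec a [CompletionSpec-class] (supplies the caps `K`, `H`).
#' @param allowSelfLoops passed to [candidateParents()].
#' @return list with elements `value` (numeric, possibly `Inf`), `added`
#'   and `deleted` (character vectors of source genes).
#' @export
sigmaNode <- function(expr, network, node, kj, hj, spec,
                      allowSelfLoops = FALSE) {
  stopifnot(node %in% genes(network))
  g <- genes(network)
  n <- length(g)
  par0 <- parents(network, node)
  cand <- candidateParents(network, node, allowSelfLoops)
  if (sigmaInfeasible(kj, hj, length(par0), n, spec@K, spec@H, length(cand)))
    return(list(value = Inf, added = character(0), deleted = character(0)))
  best <- list(value = Inf, added = character(0), deleted = character(0))
  for (del in chooseSets(seq_along(par0), hj)) {
    for (add in chooseSets(seq_along(cand), kj)) {
      ps <- c(par0[setdiff(seq_along(par0), del)], cand[add])
      err <- nodeError(expr, node, ps)
      if (err < best$value)
        best <- list(value = err, added = cand[add], deleted = par0[del])
    }
  }
  best
}

#' Per-gene minimal-error table for the dynamic program
#'
#' Computes [sigmaNode()] for every gene and every budget pair
#' `(kj <= min(K, k), hj <= min(H, h))` over one shared product-moment
#' cache, so each candidate fit is solved from precomputed cross-products
#' rather than from the raw samples. Entries are mutually independent (the
#' enumeration for one gene never depends on another's), which is what
#' makes the table reusable across all DP cells.
#'
#' @inheritParams sigmaNode
#' @return a [SigmaTable-class]; `@nFits` counts the least-squares fits
#'   performed.
#' @export
sigmaTable <- function(expr, network, spec, allowSelfLoops = FALSE) {
  g <- genes(network)
  n <- length(g)
  if (!all(g %in% genes(expr)))
    stop("expression data must cover every network gene")
  cache <- makeFitCache(expr)
  gi <- match(g, cache$genes)
  kMax <- min(spec@K, spec@k)
  hMax <- min(spec@H, spec@h)
  nFits <- 0L
  entries <- vector("list", n)
  for (j in seq_len(n)) {
    par0 <- parents(network, g[j])
    cand <- candidateParents(network, g[j], allowSelfLoops)
    deg <- length(par0)
    val <- matrix(Inf, kMax + 1L, hMax + 1L)
    sets <- vector("list", (kMax + 1L) * (hMax + 1L))
    dim(sets) <- c(kMax + 1L, hMax + 1L)
    for (kj in 0:kMax) for (hj in 0:hMax) {
      sets[[kj + 1L, hj + 1L]] <-
        list(added = character(0), deleted = character(0))
      if (sigmaInfeasible(kj, hj, deg, n, spec@K, spec@H, length(cand)))
        next
      for (del in chooseSets(seq_along(par0), hj)) {
        keepPar <- match(par0[setdiff(seq_along(par0), del)], cache$genes)
        for (add in chooseSets(seq_along(cand), kj)) {
          pidx <- c(keepPar, match(cand[add], cache$genes))
          err <- cachedNodeError(cache, gi[j], pidx)
          nFits <- nFits + 1L
          if (err < val[kj + 1L, hj + 1L]) {
            val[kj + 1L, hj + 1L] <- err
            sets[[kj + 1L, hj + 1L]] <-
              list(added = cand[add], deleted = par0[del])
          }
        }
      }
    }
    entries[[j]] <- list(value = val, sets = sets)
  }
  new("SigmaTable", genes = g, entries = entries,
      K = spec@K, H = spec@H, nFits = nFits)
}

#' Read one cell of a [SigmaTable-class]
#'
#' @param table a [SigmaTable-class].
#' @param node a gene.
#' @param kj,hj per-gene budgets. Cells beyond the caps the table was built
#'   under are infeasible by definition and return `Inf`.
#' @return list with `value`, `added`, `deleted` as in [sigmaNode()].
#' @export
sigmaEntry <- function(table, node, kj, hj) {
  j <- match(node, table@genes)
  if (is.na(j)) stop("unknown gene: ", node)
  e <- table@entries[[j]]
  if (kj + 1L > nrow(e$value) || hj + 1L > ncol(e$value))
    return(list(value = Inf, added = character(0), deleted = character(0)))
  c(list(value = e$value[kj + 1L, hj + 1L]), e$sets[[kj + 1L, hj + 1L]])
}

setMethod("show", "SigmaTable", function(object) {
  cat(sprintf(
    "SigmaTable: %d genes, budgets up to (K=%d, H=%d), %d least-squares fits\n",
    length(object@genes), object@K, object@H, object@nFits))
})
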