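# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's fitting and DP code paths: least squares goes through stats::lm
# on an explicitly assembled data frame, and completion optima through
# exhaustive enumeration of modification sets.

# genes-by-samples matrix of the exemplar's four exact solutions
exemplarSolutions <- function() {
  matrix(c(2, 3, 5, 2, -2, -5, -1, 3, -4, -1, -2, 1), nrow = 3,
         dimnames = list(c("v1", "v2", "v3"), paste0("sol", 1:4)))
}

# independent least-squares residual: quadratic design assembled by hand,
# solved by stats::lm (QR), never by the package's solver
lmNodeError <- function(values, node, parentSet) {
  y <- values[node, ]
  df <- data.frame(y = y)
  ps <- as.character(parentSet)
  for (p in ps) df[[paste0("L", p)]] <- values[p, ]
  if (length(ps)) {
    for (a in seq_along(ps)) for (b in a:length(ps)) {
      df[[paste0("Q", ps[a], ".", ps[b])]] <- values[ps[a], ] * values[ps[b], ]
    }
  }
  fit <- stats::lm(y ~ ., data = df)
  sum(stats::residuals(fit)^2)
}

# exhaustive completion optimum: enumerate every way of adding exactly k
# absent candidate edges and deleting exactly h present edges subject to
# the per-node caps and degree constraints, scoring each completed network
# by the sum of per-node least-squares errors
bruteForceCompletion <- function(expr, network, k, h, K, H,
                                 allowSelfLoops = FALSE) {
  g <- genes(network)
  n <- length(g)
  present <- edges(network)
  addCand <- NULL
  for (v in g) {
    cand <- candidateParents(network, v, allowSelfLoops)
    if (length(cand)) addCand <- rbind(addCand, cbind(cand, v))
  }
  pick <- function(total, size) {
    if (size == 0) return(list(integer(0)))
    if (total < size) return(list())
    cm <- utils::combn(total, size)
    lapply(seq_len(ncol(cm)), function(i) cm[, i])
  }
  deg <- vapply(g, function(v) inDegree(network, v), integer(1))
  best <- Inf
  bestNet <- NULL
  for (aset in pick(NROW(addCand), k)) {
    addM <- addCand[aset, , drop = FALSE]
    kj <- table(factor(addM[, 2], levels = g))
    if (any(kj > K)) next
    for (dset in pick(nrow(present), h)) {
      delM <- present[dset, , drop = FALSE]
      hj <- table(factor(delM[, 2], levels = g))
      if (any(hj > H)) next
      newdeg <- deg + as.integer(kj) - as.integer(hj)
      if (any(newdeg >= n) || any(newdeg < 0)) next
      tot <- 0
      for (v in g) {
        ps <- union(setdiff(parents(network, v), delM[delM[, 2] == v, 1]),
                    addM[addM[, 2] == v, 1])
        tot <- tot + lmNodeError(exprValues(expr), v, ps)
      }
      if (tot < best) {
        best <- tot
        bestNet <- applyModification(network, added = addM, deleted = delM)
      }
    }
  }
  list(value = best, network = bestNet)
}

# small random instance: n genes, random edges, uniform random expression
randomInstance <- function(n, m, edgeProb = 0.3, seed) {
  set.seed(seed)
  g <- paste0("g", seq_len(n))
  pairs <- expand.grid(from = g, to = g, stringsAsFactors = FALSE)
  take <- stats::runif(nrow(pairs)) < edgeProb
  net <- geneNetwork(g, pairs[take, , drop = FALSE])
  vals <- matrix(stats::runif(n * m, -3, 3), nrow = n,
                 dimnames = list(g, NULL))
  list(network = net, expr = expressionMatrix(vals))
}

# expression data generated from a known quadratic model for one node
modelData <- function(coefIntercept, coefLinear, coefQuad, parentValues) {
  h <- ncol(parentValues)
  X <- cbind(1, parentValues)
  if (h > 0) {
    for (a in seq_len(h)) for (b in a:h) {
      X <- cbind(X, parentValues[, a] * parentValues[, b])
    }
  }
  as.numeric(X %*% c(coefIntercept, coefLinear, coefQuad))
}
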