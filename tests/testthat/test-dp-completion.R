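test_that("candidateParents excludes current parents and (by default) self", {
  net <- geneNetwork(c("v1", "v2", "v3"), NULL)
  expect_equal(candidateParents(net, "v3"), c("v1", "v2"))
  expect_equal(candidateParents(net, "v3", allowSelfLoops = TRUE),
               c("v1", "v2", "v3"))
  net2 <- geneNetwork(c("v1", "v2", "v3"),
                      rbind(c("v1", "v3"), c("v2", "v3")))
  expect_equal(candidateParents(net2, "v3"), character(0))
})

test_that("completionSpec guards exponential caps", {
  expect_error(completionSpec(1, 1, K = 4), "override")
  expect_s4_class(completionSpec(1, 1, K = 4, override = TRUE),
                  "CompletionSpec")
  expect_error(completionSpec(-1, 0), "nonnegative")
})

test_that("sigma honours caps, feasibility rules and the zero-budget case", {
  expr <- expressionMatrix(exemplarSolutions())
  net <- goldStandard(exemplarSystem())
  spec <- completionSpec(2, 2, K = 2, H = 2)
  # zero budget: current parent set, no modifications
  s00 <- sigmaNode(expr, net, "v3", 0, 0, spec)
  expect_equal(s00$value, nodeError(expr, "v3", parents(net, "v3")),
               tolerance = 1e-9)
  expect_length(s00$added, 0)
  # beyond the per-gene cap
  expect_identical(sigmaNode(expr, net, "v3", 3, 0, spec)$value, Inf)
  expect_identical(sigmaNode(expr, net, "v3", 0, 3, spec)$value, Inf)
  # modified in-degree would reach n
  expect_identical(sigmaNode(expr, net, "v3", 1, 0, spec)$value, Inf)
})

test_that("sigma finds the exemplar's true parents from the empty network", {
  sols <- exemplarSolutions()
  expr <- perturbSolutions(sols, replicates = 100, halfWidth = 0,
                           seed = 5)  # noiseless replication
  net <- emptyNetwork(rownames(sols))
  spec <- completionSpec(2, 0, K = 2, H = 0)
  s <- sigmaNode(expr, net, "v3", 2, 0, spec)
  expect_equal(sort(s$added), c("v1", "v2"))
  expect_equal(s$value, 0, tolerance = 1e-8)
  # single additions cannot reach zero
  expect_gt(sigmaNode(expr, net, "v3", 1, 0, spec)$value, 1)
})

test_that("sigma is non-increasing in the addition budget while finite", {
  for (seed in 1:4) {
    inst <- randomInstance(5, 30, edgeProb = 0.2, seed = seed)
    spec <- completionSpec(3, 0, K = 3, H = 0, override = FALSE)
    for (v in genes(inst$network)) {
      vals <- vapply(0:3, function(kj)
        sigmaNode(inst$expr, inst$network, v, kj, 0, spec)$value, 0)
      fin <- is.finite(vals)
      expect_true(all(diff(vals[fin]) <= 1e-8))
    }
  }
})

test_that("sigmaTable agrees with sigmaNode and counts its fits", {
  inst <- randomInstance(4, 25, seed = 2)
  spec <- completionSpec(2, 1, K = 2, H = 1)
  tab <- sigmaTable(inst$expr, inst$network, spec)
  expected <- 0L
  for (v in genes(inst$network)) {
    deg <- inDegree(inst$network, v)
    nc <- length(candidateParents(inst$network, v))
    for (kj in 0:2) for (hj in 0:1) {
      e <- sigmaEntry(tab, v, kj, hj)
      s <- sigmaNode(inst$expr, inst$network, v, kj, hj, spec)
      expect_equal(e$value, s$value, tolerance = 1e-7)
      if (is.finite(e$value)) {
        # the recorded argmin sets achieve the recorded value
        ps <- union(setdiff(parents(inst$network, v), e$deleted), e$added)
        expect_equal(nodeError(inst$expr, v, ps), e$value, tolerance = 1e-7)
        expect_length(e$added, kj)
        expect_length(e$deleted, hj)
      }
      feas <- !(kj > 2 || hj > 1 || kj - hj + deg >= 4 ||
                  kj - hj + deg < 0 || kj > nc || hj > deg)
      if (feas) expected <- expected + choose(deg, hj) * choose(nc, kj)
    }
  }
  # instrumentation matches the combinatorial fit count of the enumeration
  expect_identical(tab@nFits, as.integer(expected))
})

test_that("addition-only DP equals brute-force decomposition minimum", {
  inst <- randomInstance(3, 20, edgeProb = 0, seed = 6)
  spec <- completionSpec(2, 0, K = 2, H = 0)
  tab <- dpAdd(inst$expr, inst$network, 2, spec)
  sig <- sigmaTable(inst$expr, inst$network, spec)
  # all 6 decompositions of k = 2 over 3 genes
  g <- genes(inst$network)
  decomp <- expand.grid(k1 = 0:2, k2 = 0:2, k3 = 0:2)
  decomp <- decomp[rowSums(decomp) == 2, ]
  direct <- min(apply(decomp, 1, function(d)
    sum(vapply(1:3, function(j) sigmaEntry(sig, g[j], d[j], 0)$value, 0))))
  expect_equal(tab@D[3, 1, 3], direct, tolerance = 1e-9)
})

test_that("deletion budget zero collapses the two-budget DP to addition-only", {
  inst <- randomInstance(4, 25, edgeProb = 0.25, seed = 8)
  specA <- completionSpec(2, 0, K = 2, H = 0)
  tabA <- dpAdd(inst$expr, inst$network, 2, specA)
  tabB <- dpAddDel(inst$expr, inst$network, specA)
  expect_equal(tabB@D[, 1, ], tabA@D[, 1, ], tolerance = 1e-9)
})

test_that("DP optimum is invariant to gene ordering", {
  inst <- randomInstance(6, 30, edgeProb = 0.25, seed = 10)
  spec <- completionSpec(2, 1, K = 2, H = 2)
  ref <- dpAddDel(inst$expr, inst$network, spec)@D[3, 2, 6]
  set.seed(99)
  for (r in 1:10) {
    perm <- sample(genes(inst$network))
    pnet <- geneNetwork(perm, edges(inst$network))
    pexpr <- expressionMatrix(exprValues(inst$expr)[perm, , drop = FALSE])
    val <- dpAddDel(pexpr, pnet, spec)@D[3, 2, 6]
    expect_equal(val, ref, tolerance = 1e-9)
  }
})

test_that("zero-budget completion returns the input network at its own error", {
  inst <- randomInstance(4, 25, edgeProb = 0.3, seed = 12)
  res <- completeNetwork(inst$expr, inst$network, completionSpec(0, 0))
  expect_true(res@feasible)
  expect_equal(edges(res), edges(inst$network))
  direct <- sum(vapply(genes(inst$network), function(v)
    nodeError(inst$expr, v, parents(inst$network, v)), 0))
  expect_equal(res@totalError, direct, tolerance = 1e-7)
})

test_that("DP optimum and traceback match exhaustive search on small instances", {
  cases <- expand.grid(seed = 1:5, k = 0:2, h = 0:1)
  cases <- cases[cases$k + cases$h >= 1, ]
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    inst <- randomInstance(4, 20, edgeProb = 0.3, seed = cs$seed)
    spec <- completionSpec(cs$k, cs$h, K = 2, H = 2)
    res <- completeNetwork(inst$expr, inst$network, spec)
    bf <- bruteForceCompletion(inst$expr, inst$network, cs$k, cs$h, 2, 2)
    if (!is.finite(bf$value)) {
      expect_false(res@feasible)
      next
    }
    expect_true(res@feasible)
    expect_equal(res@totalError, bf$value, tolerance = 1e-6)
    # exactly k additions and h deletions
    expect_identical(nrow(res@added), as.integer(cs$k))
    expect_identical(nrow(res@deleted), as.integer(cs$h))
    # the returned network achieves the reported optimum
    achieved <- sum(vapply(genes(res@completed), function(v)
      nodeError(inst$expr, v, parents(res@completed, v)), 0))
    expect_equal(achieved, res@totalError, tolerance = 1e-6)
  }
})

test_that("over-budget instances are flagged infeasible, never partial", {
  inst <- randomInstance(3, 15, edgeProb = 0, seed = 3)
  # k > n * K: no decomposition exists
  res <- completeNetwork(inst$expr, inst$network,
                         completionSpec(7, 0, K = 2, H = 0))
  expect_false(res@feasible)
  expect_identical(res@totalError, Inf)
  expect_equal(edges(res@completed), edges(inst$network))
})

test_that("inference from the empty network recovers the exemplar's derived edges", {
  sols <- exemplarSolutions()
  expr <- perturbSolutions(sols, replicates = 400, seed = 21)
  res <- inferNetwork(expr, k = 2, K = 2)
  expect_true(res@feasible)
  expect_true(all(hasEdge(res@completed, c("v1", "v2"), c("v3", "v3"))))
  # k = 0 returns the empty network
  res0 <- inferNetwork(expr, k = 0, K = 2)
  expect_identical(nEdges(res0@completed), 0L)
})
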