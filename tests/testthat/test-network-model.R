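test_that("designRow expands intercept, linear and ordered quadratic terms", {
  expect_equal(designRow(c(2, 3)), c(1, 2, 3, 4, 6, 9))
  expect_equal(designRow(numeric(0)), 1)
  expect_length(designRow(c(1, 2, 3)), 10)  # 1 + 3 + 6
  # documented pair order (1,1), (1,2), ..., (h,h)
  expect_equal(designRow(c(5, 7))[4:6], c(25, 35, 49))
})

test_that("GeneNetwork validity and accessors behave as a directed graph", {
  net <- geneNetwork(c("a", "b", "c"),
                     rbind(c("a", "a"), c("a", "c"), c("b", "c")))
  expect_equal(parents(net, "c"), c("a", "b"))
  expect_equal(parents(net, "b"), character(0))
  expect_equal(inDegree(net, "a"), 1L)
  expect_equal(nEdges(net), 3L)
  expect_error(geneNetwork(c("a", "a"), NULL), "unique")
  expect_error(geneNetwork(c("a", "b"), rbind(c("a", "z"))), "listed gene")
  expect_error(geneNetwork(c("a", "b"),
                           rbind(c("a", "b"), c("a", "b"))), "duplicate")
})

test_that("ExpressionMatrix rejects non-finite values and unnamed rows", {
  m <- matrix(1:6, nrow = 2, dimnames = list(c("a", "b"), NULL))
  expect_s4_class(expressionMatrix(m), "ExpressionMatrix")
  m2 <- m
  m2[1, 1] <- NA
  expect_error(expressionMatrix(m2), "finite")
  expect_error(expressionMatrix(matrix(1:6, nrow = 2)), "gene identifiers")
})

test_that("the exemplar's product gene fits exactly and sub-models do not", {
  expr <- expressionMatrix(exemplarSolutions())
  fit <- fitNode(expr, "v3", c("v1", "v2"))
  expect_equal(fit@residualError, 0, tolerance = 1e-12)
  # 1-parent fit cannot represent the product rule; value checked against
  # the independent lm oracle
  e1 <- nodeError(expr, "v3", "v1")
  expect_gt(e1, 0)
  expect_equal(e1, lmNodeError(exemplarSolutions(), "v3", "v1"),
               tolerance = 1e-10)
})

test_that("fitNode matches an independent least-squares oracle on random data", {
  for (seed in 1:5) {
    inst <- randomInstance(4, 50, seed = seed)
    vals <- exprValues(inst$expr)
    for (ps in list(character(0), "g1", c("g1", "g2"), c("g2", "g3", "g4"))) {
      expect_equal(nodeError(inst$expr, "g3", ps),
                   lmNodeError(vals, "g3", ps),
                   tolerance = 1e-8)
    }
  }
})

test_that("intercept-only error equals the centered sum of squares", {
  inst <- randomInstance(3, 40, seed = 9)
  y <- exprValues(inst$expr)["g2", ]
  expect_equal(nodeError(inst$expr, "g2", character(0)),
               sum((y - mean(y))^2), tolerance = 1e-10)
})

test_that("residual error is permutation-invariant and monotone in parents", {
  inst <- randomInstance(5, 60, seed = 4)
  e12 <- nodeError(inst$expr, "g5", c("g1", "g2"))
  e21 <- nodeError(inst$expr, "g5", c("g2", "g1"))
  expect_equal(e12, e21, tolerance = 1e-10)
  # nested model classes: supersets never fit worse
  for (seed in 1:5) {
    inst <- randomInstance(5, 30, seed = seed)
    sets <- list(character(0), "g1", c("g1", "g3"), c("g1", "g3", "g4"))
    errs <- vapply(sets, function(s) nodeError(inst$expr, "g2", s), 0)
    expect_true(all(diff(errs) <= 1e-8))
  }
})

test_that("fitNode recovers generating coefficients on noiseless full-rank data", {
  set.seed(31)
  m <- 80
  pv <- matrix(runif(2 * m, -2, 2), ncol = 2)
  beta <- c(1.5, -2, 0.5, 0.25, -1, 2)  # a0, a1, a2, a11, a12, a22
  y <- modelData(beta[1], beta[2:3], beta[4:6], pv)
  vals <- rbind(t(pv), y)
  rownames(vals) <- c("p1", "p2", "tgt")
  fit <- fitNode(expressionMatrix(vals), "tgt", c("p1", "p2"))
  expect_equal(fit@residualError, 0, tolerance = 1e-12)
  expect_false(fit@rankDeficient)
  expect_equal(fit@model@intercept, beta[1], tolerance = 1e-8)
  expect_equal(fit@model@linear, beta[2:3], tolerance = 1e-8)
  expect_equal(fit@model@quadratic, beta[4:6], tolerance = 1e-8)
  # predictNode reproduces the data from the recovered model
  expect_equal(predictNode(fit@model, pv), y, tolerance = 1e-8)
})

test_that("rank-deficient designs return minimum-norm fits without failing", {
  # four replicated samples: design has fewer distinct rows than columns
  vals <- exemplarSolutions()[, c(1, 1, 1, 1)]
  fit <- fitNode(expressionMatrix(vals), "v3", c("v1", "v2"))
  expect_true(fit@rankDeficient)
  expect_equal(fit@residualError, 0, tolerance = 1e-10)
})

test_that("fit errors on unknown genes and duplicate parents", {
  expr <- expressionMatrix(exemplarSolutions())
  expect_error(fitNode(expr, "nope", "v1"), "absent")
  expect_error(fitNode(expr, "v3", c("v1", "v1")), "duplicate")
  expect_error(fitNode(expr, "v3", c("v1", "vX")), "unknown parent")
})
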