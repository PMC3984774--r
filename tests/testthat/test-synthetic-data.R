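test_that("the exemplar system enumerates its four known solutions", {
  sys <- exemplarSystem()
  sols <- enumerateSolutions(sys)
  expect_equal(dim(sols), c(3L, 4L))
  got <- apply(sols, 2, paste, collapse = ",")
  want <- c("2,3,5", "2,-2,-5", "-1,3,-4", "-1,-2,1")
  expect_setequal(got, want)
  net <- goldStandard(sys)
  expect_equal(nGenes(net), 3L)
  expect_equal(nEdges(net), 4L)
  expect_equal(sum(edges(net)[, 1] == edges(net)[, 2]), 2L)
})

test_that("generated systems are deterministic with enumerable solutions", {
  s1 <- generateSystem(8, 4, 2, seed = 5)
  s2 <- generateSystem(8, 4, 2, seed = 5)
  expect_identical(s1@rules, s2@rules)
  expect_identical(s1@roots, s2@roots)
  sols <- enumerateSolutions(s1)
  expect_equal(ncol(sols), 2^4)  # one solution per source-root combination
  # edge count: one self-loop per source plus one edge per derived parent
  nparents <- sum(lengths(lapply(s1@rules[-(1:4)], `[[`, "parents")))
  expect_equal(nEdges(goldStandard(s1)), nparents + 4L)
  # every solution satisfies every rule to machine precision
  for (j in seq_len(ncol(sols))) {
    for (i in seq_len(8)) {
      expect_lt(abs(sols[i, j] -
                      GRNcomplete:::evalRule(s1@rules[[i]], sols[, j])), 1e-12)
    }
  }
})

test_that("source rules have integer roots r and 1 - r with r in 2..5", {
  sys <- generateSystem(12, 6, 2, seed = 17)
  for (rt in sys@roots) {
    expect_equal(sum(rt), 1)
    expect_true(max(rt) %in% 2:5)
    expect_equal(rt, round(rt))
  }
})

test_that("fitting true parents on unperturbed solution data is exact", {
  sys <- generateSystem(10, 4, 2, seed = 23)
  sols <- enumerateSolutions(sys)
  expr <- expressionMatrix(sols)
  for (i in seq_len(10)) {
    ps <- sys@genes[sys@rules[[i]]$parents]
    expect_lt(nodeError(expr, sys@genes[i], ps), 1e-9)
  }
})

test_that("perturbation respects counts, bounds and determinism", {
  sols <- exemplarSolutions()
  expr <- perturbSolutions(sols, replicates = 400, halfWidth = 0.5,
                           includeExact = TRUE, seed = 1)
  expect_equal(nSamples(expr), 4 * 401)  # 1604
  # every value within the uniform support of its source solution
  v <- exprValues(expr)
  blocks <- rep(seq_len(4), each = 401)
  dev <- abs(v - sols[, blocks])
  expect_lte(max(dev), 0.5)
  # exact solutions retained as the first column of each block
  expect_equal(v[, blocks == 2][, 1], sols[, 2])
  # determinism and the degenerate noiseless case
  e2 <- perturbSolutions(sols, replicates = 400, seed = 1)
  expect_identical(exprValues(expr), exprValues(e2))
  e0 <- perturbSolutions(sols, replicates = 3, halfWidth = 0, seed = 2)
  expect_true(all(exprValues(e0) %in% sols))
  eNoExact <- perturbSolutions(sols, replicates = 10, includeExact = FALSE,
                               seed = 3)
  expect_equal(nSamples(eNoExact), 40)
})

test_that("modifyNetwork samples valid, recoverable, seeded modifications", {
  net <- goldStandard(generateSystem(10, 4, 2, seed = 3))
  mod <- modifyNetwork(net, kAdd = 3, hDel = 2, seed = 7)
  expect_equal(nrow(mod$added), 3L)
  expect_equal(nrow(mod$deleted), 2L)
  # added edges were absent, deleted edges present
  expect_false(any(hasEdge(net, mod$added[, 1], mod$added[, 2])))
  expect_true(all(hasEdge(net, mod$deleted[, 1], mod$deleted[, 2])))
  # recoverable: no self-loops touched
  expect_true(all(mod$added[, 1] != mod$added[, 2]))
  expect_true(all(mod$deleted[, 1] != mod$deleted[, 2]))
  # determinism and identity
  mod2 <- modifyNetwork(net, kAdd = 3, hDel = 2, seed = 7)
  expect_identical(mod$added, mod2$added)
  expect_identical(mod$deleted, mod2$deleted)
  id <- modifyNetwork(net, 0, 0, seed = 1)
  expect_equal(edges(id$network), edges(net))
  expect_error(modifyNetwork(net, kAdd = 1000, hDel = 0, seed = 1),
               "not enough")
})

test_that("generator rejects impossible parameter combinations", {
  expect_error(generateSystem(5, 0, 2, seed = 1))
  expect_error(generateSystem(5, 6, 2, seed = 1))
  expect_error(generateSystem(20, 13, 2, seed = 1), "4096")
})
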