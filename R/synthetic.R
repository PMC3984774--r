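# Synthetic quadratic fixed-point systems.
#
# Source genes satisfy x = x^2 - c with c = r(r-1), giving the two integer
# roots r and 1 - r (root sum 1). Derived genes are degree-<=2 polynomials
# in strictly lower-indexed genes, so the system is triangular: every
# assignment of source roots extends uniquely to an exact solution and the
# solution count is the product of root counts over sources.

evalRule <- function(rule, sol) {
  p <- rule$parents
  x <- sol[p]
  h <- length(p)
  v <- rule$intercept + sum(rule$linear * x)
  if (h) {
    pr <- upperPairs(h)
    v <- v + sum(rule$quadratic * x[pr[, 1]] * x[pr[, 2]])
  }
  v
}

ruleNetwork <- function(genes, sources, rules) {
  e <- NULL
  for (i in seq_along(genes)) {
    for (p in rules[[i]]$parents) e <- rbind(e, c(genes[p], genes[i]))
  }
  geneNetwork(genes, e)
}

sourceRule <- function(i, r) {
  # x = x^2 - c with roots r and 1 - r, i.e. c = r(r-1)
  list(parents = as.integer(i), intercept = -r * (r - 1),
       linear = 0, quadratic = 1)
}

#' The three-gene exemplar system
#'
#' The hand-built triangular system
#' \deqn{x_1 = x_1^2 - 2,\quad x_2 = x_2^2 - 6,\quad x_3 = x_1 x_2 - 1,}
#' whose four exact solutions are `(2, 3, 5)`, `(2, -2, -5)`,
#' `(-1, 3, -4)` and `(-1, -2, 1)`. Its gold-standard network has 3 genes
#' and 4 edges, two of them self-loops.
#'
#' @return an [EquationSystem-class].
#' @export
exemplarSystem <- function() {
  genes <- c("v1", "v2", "v3")
  rules <- list(
    sourceRule(1L, 2),
    sourceRule(2L, 3),
    list(parents = c(1L, 2L), intercept = -1, linear = c(0, 0),
         quadratic = c(0, 1, 0)))  # pairs (1,1), (1,2), (2,2)
  new("EquationSystem", genes = genes, sources = c(1L, 2L),
      roots = list(c(2, -1), c(3, -2)), rules = rules,
      network = ruleNetwork(genes, c(1L, 2L), rules), seed = NA_integer_)
}

# exact-solution least-squares residual of `vals` fitted on the quadratic
# design over rows `pset` of the solution matrix
exactFitResidual <- function(vals, sols, pset) {
  X <- quadDesign(t(sols[pset, , drop = FALSE]))
  svdLstsq(X, vals)$rss
}

# |d f / d x_p| of a rule at each exact solution, for every parent
ruleGradients <- function(rule, sols) {
  p <- rule$parents
  h <- length(p)
  x <- sols[p, , drop = FALSE]
  g <- matrix(rule$linear, nrow = h, ncol = ncol(sols))
  if (h) {
    pr <- upperPairs(h)
    for (t in seq_len(nrow(pr))) {
      a <- rule$quadratic[t]
      if (a == 0) next
      j <- pr[t, 1]; k <- pr[t, 2]
      if (j == k) {
        g[j, ] <- g[j, ] + 2 * a * x[j, ]
      } else {
        g[j, ] <- g[j, ] + a * x[k, ]
        g[k, ] <- g[k, ] + a * x[j, ]
      }
    }
  }
  abs(g)
}

#' Generate a random triangular quadratic fixed-point system
#'
#' The first `nSources` genes are sources `x = x^2 - c` with integer roots
#' `r` and `1 - r`, `r` drawn from `{2, ..., 5}`. Each remaining gene draws
#' 1 to `maxParents` lower-indexed parents and a rule that is a parent
#' product, an integer-coefficient linear combination, or a bilinear
#' combination (linear terms plus the product), with an integer intercept
#' in `[-6, 6]`; single-parent rules may carry a square term.
#'
#' Candidate rules are rejection-sampled so that the system is
#' *identifiable by construction*, mirroring hand-built systems with
#' obvious solutions: a rule is accepted only if, across the exact
#' solutions, (a) its values stay within `valueBound` and are non-constant,
#' (b) the partial derivative with respect to every parent stays within
#' `gradientBound` (bounding the observation noise propagated through
#' fitted coefficients), and (c) no alternative parent set of up to two
#' genes other than the true parents can reproduce the gene's values to
#' within `margin` mean squared error per solution — the condition that
#' makes modifications recoverable under per-gene caps of 2. A closure
#' check re-validates all earlier genes' margins against pairs involving
#' the new gene, so a later gene can never become an exact surrogate for
#' an existing regulator (which a purely linear rule would otherwise
#' create by inversion). See the package vignette for the reasoning behind
#' the default constants.
#'
#' @param n number of genes (at least 1).
#' @param nSources number of source genes, `1 <= nSources <= min(n, 12)`;
#'   the system has `2^nSources` exact solutions. At least 4 sources are
#'   needed in practice: a quadratic in two genes spans 6 of the
#'   `2^nSources` dimensions of the solution-grid function space, so
#'   smaller grids leave no room for the identifiability margins.
#' @param maxParents maximum parents per derived gene (1 or 2).
#' @param seed integer seed; the system is a deterministic function of the
#'   arguments.
#' @param valueBound maximum absolute derived value across solutions.
#' @param gradientBound maximum absolute rule gradient per parent.
#' @param margin minimum mean squared exact-solution residual (per
#'   solution) of any same-size alternative parent set.
#' @param restarts maximum number of whole-system restarts (from
#'   deterministically derived seeds) before giving up; rule rejection can
#'   paint a draw into a corner, e.g. when an accepted gene makes one of
#'   its parents unusable for all later genes.
#' @return an [EquationSystem-class].
#' @export
generateSystem <- function(n, nSources, maxParents = 2, seed,
                           valueBound = 30, gradientBound = 6, margin = 2,
                           restarts = 25) {
  stopifnot(n >= 1, nSources >= 1, nSources <= n, maxParents %in% c(1, 2))
  if (nSources > 12)
    stop("more than 12 sources would enumerate over 4096 solutions")
  # rejection sampling at the system level: if a draw cannot be extended to
  # a fully identifiable system, restart from a deterministically derived
  # seed, so the result is still a pure function of `seed`
  for (r in 0:restarts) {
    sys <- buildSystem(n, nSources, maxParents, seed + r * 100003L,
                       valueBound, gradientBound, margin)
    if (!is.null(sys)) {
      sys@seed <- as.integer(seed)
      return(sys)
    }
  }
  stop("could not generate an identifiable system for n = ", n,
       ", nSources = ", nSources, "; try other parameters")
}

buildSystem <- function(n, nSources, maxParents, seed,
                        valueBound, gradientBound, margin) {
  genes <- paste0("v", seq_len(n))
  withSeed(seed, {
    rules <- vector("list", n)
    roots <- vector("list", nSources)
    for (i in seq_len(nSources)) {
      r <- sample(2:5, 1)
      rules[[i]] <- sourceRule(as.integer(i), r)
      roots[[i]] <- c(r, 1 - r)
    }
    # source solution grid: rows = genes so far, cols = solutions
    grid <- as.matrix(expand.grid(rev(roots)))[, rev(seq_len(nSources)),
                                               drop = FALSE]
    sols <- matrix(t(grid), nrow = nSources)
    nsol <- ncol(sols)
    marginRss <- margin * nsol

    # Margin of one gene's rule against every alternative parent set of up
    # to two genes from the pool that does not cover the true parents.
    # Pairs suffice: any smaller alternative is a subset of some checked
    # pair and fits no better, so its residual is also above the margin.
    marginOK <- function(vals, P, pool) {
      if (stats::var(vals) * (nsol - 1) < marginRss) return(FALSE)
      if (length(pool) < 2) return(TRUE)
      cmb <- utils::combn(pool, 2)
      for (c2 in seq_len(ncol(cmb))) {
        A <- cmb[, c2]
        if (all(P %in% A)) next  # covers P: fits exactly by nesting
        if (exactFitResidual(vals, sols, A) < marginRss) return(FALSE)
      }
      TRUE
    }

    if (n > nSources) for (i in (nSources + 1):n) {
      accepted <- NULL
      # parents weighted toward small-magnitude genes so that products and
      # their gradients stay within the bounds; two-parent rules dominate
      # because a source gene takes only two values across solutions, so a
      # single-parent transform of it is affine-equivalent to the source
      # itself and can never be identifiable
      pw <- 1 / (1 + apply(abs(sols), 1, max))
      for (attempt in seq_len(400)) {
        npar <- if (i - 1 >= 2 && maxParents == 2) {
          sample(1:2, 1, prob = c(0.25, 0.75))
        } else {
          sample(seq_len(min(maxParents, i - 1)), 1)
        }
        par <- sort(sample(seq_len(i - 1), npar, prob = pw))
        cand <- makeDerivedRule(par, a0 = sample(-6:6, 1))
        v <- apply(sols, 2, function(s) evalRule(cand, c(s, NA)))
        if (max(abs(v)) > valueBound) next
        if (stats::var(v) < 0.5) next
        if (max(ruleGradients(cand, sols)) > gradientBound) next
        # identifiability of the new rule among existing genes
        if (!marginOK(v, par, seq_len(i - 1))) next
        # closure: no pair involving the new gene may explain an earlier
        # derived gene's values, so earlier margins survive the addition
        solsExt <- rbind(sols, v)
        broken <- FALSE
        for (e in setdiff(seq_len(i - 1), seq_len(nSources))) {
          Pe <- rules[[e]]$parents
          for (q in setdiff(seq_len(i - 1), e)) {
            A <- c(q, i)
            if (all(Pe %in% A)) next
            if (exactFitResidual(solsExt[e, ], solsExt, A) < marginRss) {
              broken <- TRUE
              break
            }
          }
          if (broken) break
        }
        if (broken) next
        accepted <- list(rule = cand, vals = v)
        break
      }
      if (is.null(accepted)) return(NULL)
      rules[[i]] <- accepted$rule
      sols <- rbind(sols, accepted$vals)
    }
    new("EquationSystem", genes = genes, sources = seq_len(nSources),
        roots = roots, rules = rules,
        network = ruleNetwork(genes, seq_len(nSources), rules),
        seed = as.integer(seed))
  })
}

# A random derived rule over parent indices `par` (length 1 or 2). Every
# rule carries a quadratic component (square or product): a rule affine in
# a parent would be exactly invertible within the model class, making the
# child an exact surrogate for that parent and the system unidentifiable.
makeDerivedRule <- function(par, a0) {
  h <- length(par)
  sgn <- function() sample(c(-1, 1), 1)
  coefPool <- c(-3:-1, 1:3)
  if (h == 1) {
    # square, or linear-plus-square
    lin <- if (sample(2, 1) == 1) 0 else sample(coefPool, 1)
    list(parents = as.integer(par), intercept = a0, linear = lin,
         quadratic = sgn())
  } else {
    # quadratic pairs over 2 parents: (1,1), (1,2), (2,2)
    if (sample(2, 1) == 1) {  # pure product
      list(parents = as.integer(par), intercept = a0, linear = c(0, 0),
           quadratic = c(0, sgn(), 0))
    } else {                  # bilinear: linear terms plus product
      list(parents = as.integer(par), intercept = a0,
           linear = c(sample(coefPool, 1), sample(coefPool, 1)),
           quadratic = c(0, sgn(), 0))
    }
  }
}

#' Enumerate the exact solutions of a triangular system
#'
#' Takes the Cartesian product of root choices over the source genes and
#' evaluates derived genes in index order; every returned vector is an
#' exact fixed point of all `n` equations (verified to `1e-9`). With `s`
#' sources the solution count is `2^s`.
#'
#' @param system an [EquationSystem-class].
#' @return numeric matrix, genes in rows, one column per exact solution.
#' @examples
#' enumerateSolutions(exemplarSystem())
#' @export
enumerateSolutions <- function(system) {
  n <- length(system@genes)
  s <- length(system@sources)
  grid <- as.matrix(expand.grid(rev(system@roots)))[, rev(seq_len(s)),
                                                    drop = FALSE]
  nsol <- nrow(grid)
  sols <- matrix(NA_real_, nrow = n, ncol = nsol,
                 dimnames = list(system@genes,
                                 paste0("sol", seq_len(nsol))))
  sols[system@sources, ] <- t(grid)
  derived <- setdiff(seq_len(n), system@sources)
  for (i in derived[order(derived)]) {
    sols[i, ] <- apply(sols, 2, function(s) evalRule(system@rules[[i]], s))
  }
  # exactness check against every rule
  for (i in seq_len(n)) {
    resid <- abs(sols[i, ] -
                   apply(sols, 2, function(s) evalRule(system@rules[[i]], s)))
    stopifnot(all(resid < 1e-9))
  }
  sols
}

#' Perturb exact solutions into a synthetic expression matrix
#'
#' Replicates each exact solution `replicates` times with independent
#' uniform noise on `[-halfWidth, +halfWidth]` added to every gene of every
#' replicate, optionally keeping the unperturbed solutions as additional
#' samples (on by default). With 4 solutions, 400 replicates and the exact
#' solutions kept, the matrix has `4 * 401 = 1604` samples.
#'
#' @param solutions numeric genes-by-solutions matrix as returned by
#'   [enumerateSolutions()].
#' @param replicates perturbed copies per solution (default 400).
#' @param halfWidth half-width of the uniform noise (default 0.5).
#' @param includeExact keep the exact solutions as samples (default TRUE).
#' @param seed integer seed; output is a deterministic function of inputs.
#' @return an [ExpressionMatrix-class] with
#'   `ncol = nsol * (replicates + includeExact)` samples.
#' @export
perturbSolutions <- function(solutions, replicates = 400, halfWidth = 0.5,
                             includeExact = TRUE, seed) {
  stopifnot(ncol(solutions) >= 1, replicates >= 0, halfWidth >= 0)
  n <- nrow(solutions)
  nsol <- ncol(solutions)
  withSeed(seed, {
    blocks <- lapply(seq_len(nsol), function(s) {
      noise <- matrix(stats::runif(n * replicates, -halfWidth, halfWidth),
                      nrow = n)
      b <- solutions[, s] + noise
      if (includeExact) b <- cbind(solutions[, s], b)
      b
    })
    m <- do.call(cbind, blocks)
    rownames(m) <- rownames(solutions)
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    expressionMatrix(m)
  })
}

#' Randomly modify a network by edge additions and deletions
#'
#' Samples `kAdd` absent edges to add and `hDel` present edges to delete,
#' uniformly and without replacement, returning the modified network
#' together with the ground-truth modification sets. With
#' `recoverableOnly` (the default) the modification is restricted to what
#' the completion procedure could later reverse: deleted edges exclude
#' self-loops (a deleted self-loop could never be re-added, since the
#' candidate rule excludes a gene from its own candidates) and added edges
#' exclude self-loops for the same reason.
#'
#' @param network a [GeneNetwork-class].
#' @param kAdd,hDel numbers of edges to add and delete.
#' @param seed integer seed.
#' @param recoverableOnly restrict to reversible modifications (default
#'   TRUE).
#' @return list with elements `network` (the modified [GeneNetwork-class]),
#'   `added` and `deleted` (two-column character matrices).
#' @export
modifyNetwork <- function(network, kAdd, hDel, seed, recoverableOnly = TRUE) {
  g <- genes(network)
  present <- edges(network)
  key <- edgeKey(present[, 1], present[, 2])
  allPairs <- expand.grid(from = g, to = g, stringsAsFactors = FALSE)
  absent <- allPairs[!(edgeKey(allPairs$from, allPairs$to) %in% key), ,
                     drop = FALSE]
  delPool <- present
  if (recoverableOnly) {
    absent <- absent[absent$from != absent$to, , drop = FALSE]
    delPool <- present[present[, 1] != present[, 2], , drop = FALSE]
  }
  if (kAdd > nrow(absent))
    stop("not enough absent candidate edges to add ", kAdd)
  if (hDel > nrow(delPool))
    stop("not enough deletable edges to delete ", hDel)
  withSeed(seed, {
    addIdx <- if (kAdd > 0) sample(nrow(absent), kAdd) else integer(0)
    delIdx <- if (hDel > 0) sample(nrow(delPool), hDel) else integer(0)
    added <- matrix(as.character(as.matrix(absent[addIdx, , drop = FALSE])),
                    ncol = 2, dimnames = list(NULL, c("from", "to")))
    deleted <- matrix(delPool[delIdx, , drop = FALSE],
                      ncol = 2, dimnames = list(NULL, c("from", "to")))
    list(network = applyModification(network, added = added,
                                     deleted = deleted),
         added = added, deleted = deleted)
  })
}

#' @rdname genes
#' @export
setMethod("genes", "EquationSystem", function(x) x@genes)

#' @rdname nGenes
#' @export
setMethod("nGenes", "EquationSystem", function(x) length(x@genes))

#' @rdname edges
#' @export
setMethod("edges", "EquationSystem", function(x) edges(x@network))

#' @rdname goldStandard
#' @export
setMethod("goldStandard", "EquationSystem", function(x) x@network)

setMethod("show", "EquationSystem", function(object) {
  cat(sprintf(
    "EquationSystem: %d genes, %d sources (%d exact solutions), %d edges\n",
    length(object@genes), length(object@sources),
    2^length(object@sources), nEdges(object@network)))
})
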