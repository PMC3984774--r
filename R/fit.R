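#' Quadratic design-row expansion
#'
#' Expands the expression values of `h` parents into the regression row of
#' the quadratic regulation model: an intercept, the linear terms, then all
#' pairwise products \eqn{x_j x_k} with \eqn{j \le k} (pure squares
#' included) in the fixed order `(1,1), (1,2), ..., (1,h), (2,2), ...,
#' (h,h)`. The row has length `1 + h + h(h+1)/2`.
#'
#' @param parentValues numeric vector of length `h` (may be empty, giving
#'   the intercept-only row `c(1)`).
#' @return numeric vector of length `1 + h + h(h+1)/2`.
#' @examples
#' designRow(c(2, 3))  # 1, 2, 3, 4, 6, 9
#' designRow(numeric(0))
#' @export
designRow <- function(parentValues) {
  parentValues <- as.numeric(parentValues)
  stopifnot(all(is.finite(parentValues)))
  h <- length(parentValues)
  if (h == 0) return(1)
  pr <- upperPairs(h)
  c(1, parentValues, parentValues[pr[, 1]] * parentValues[pr[, 2]])
}

# Minimum-norm least squares via SVD of the design matrix.
# Singular values below rcond * max(sv) are treated as zero.
svdLstsq <- function(X, y, rcond = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > rcond * max(sv$d, 0)
  if (!any(keep)) {
    beta <- rep(0, ncol(X))
  } else {
    beta <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep])
  }
  res <- y - X %*% beta
  list(beta = as.numeric(beta),
       rss = max(sum(res^2), 0),
       rankDeficient = sum(keep) < min(dim(X)))
}

# Design matrix of the quadratic model for given parent rows of Y (m x h)
quadDesign <- function(parentRows) {
  m <- nrow(parentRows)
  h <- ncol(parentRows)
  if (h == 0) return(matrix(1, nrow = m, ncol = 1))
  pr <- upperPairs(h)
  cbind(1, parentRows,
        parentRows[, pr[, 1], drop = FALSE] *
        parentRows[, pr[, 2], drop = FALSE])
}

#' Least-squares fit of a gene's quadratic regulation model
#'
#' Fits the quadratic model of [designRow()] for `node` as a function of the
#' expression of `parents`, minimising the sum over samples of squared
#' deviations between observed and modelled expression. The fit is exact
#' linear least squares in the coefficients. Rank-deficient designs (fewer
#' samples than coefficients, or collinear samples such as replicated exact
#' solutions) return the minimum-norm solution, flagged via
#' `rankDeficient`; singular values below `1e-10` of the largest are treated
#' as zero. The generative model's noise term is not estimated; it is
#' absorbed into the residual.
#'
#' The residual error is invariant under permutation of `parents`
#' (coefficients are relabelled accordingly), and non-increasing as parents
#' are added (nested model classes).
#'
#' @param expr an [ExpressionMatrix-class].
#' @param node gene identifier of the target.
#' @param parents character vector of duplicate-free parent genes (possibly
#'   empty: intercept-only fit).
#' @return a [FitResult-class].
#' @examples
#' sols <- matrix(c(2, 3, 5, 2, -2, -5, -1, 3, -4, -1, -2, 1), nrow = 3,
#'                dimnames = list(c("v1", "v2", "v3"), NULL))
#' fitNode(expressionMatrix(sols), "v3", c("v1", "v2"))@residualError  # 0
#' @export
fitNode <- function(expr, node, parents = character(0)) {
  Y <- exprValues(expr)
  if (!node %in% rownames(Y)) stop("node '", node, "' absent from expression data")
  parents <- as.character(parents)
  if (anyDuplicated(parents)) stop("parents must be duplicate-free")
  if (!all(parents %in% rownames(Y)))
    stop("unknown parent gene(s): ",
         paste(setdiff(parents, rownames(Y)), collapse = ", "))
  X <- quadDesign(t(Y[parents, , drop = FALSE]))
  fit <- svdLstsq(X, Y[node, ])
  h <- length(parents)
  model <- new("NodeModel", node = node, parents = parents,
               intercept = fit$beta[1],
               linear = if (h) fit$beta[2:(h + 1)] else numeric(0),
               quadratic = if (h) fit$beta[(h + 2):length(fit$beta)] else numeric(0))
  new("FitResult", model = model, residualError = fit$rss,
      rankDeficient = fit$rankDeficient)
}

#' Least-squares error of a parent set
#'
#' The minimised objective value of [fitNode()] for `node` under
#' `parentSet`: the quantity the completion dynamic program sums and
#' minimises. Infinity never originates here; `Inf` entries in the
#' per-gene tables mark configurations ruled infeasible by the caps and
#' degree constraints.
#'
#' @inheritParams fitNode
#' @param parentSet character vector of parent genes (treated as a set).
#' @return nonnegative numeric scalar.
#' @export
nodeError <- function(expr, node, parentSet = character(0)) {
  fitNode(expr, node, parentSet)@residualError
}

#' Evaluate a fitted node model
#'
#' @param model a [NodeModel-class].
#' @param parentValues numeric matrix with one row per sample and one
#'   column per model parent (or a vector for a single sample).
#' @return numeric vector of modelled expression values.
#' @export
predictNode <- function(model, parentValues) {
  if (is.null(dim(parentValues)))
    parentValues <- matrix(parentValues, nrow = 1)
  stopifnot(ncol(parentValues) == length(model@parents))
  X <- quadDesign(parentValues)
  as.numeric(X %*% c(model@intercept, model@linear, model@quadratic))
}

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: node %s ~ {%s}; residual error %.6g%s\n",
              object@model@node,
              paste(object@model@parents, collapse = ", "),
              object@residualError,
              if (object@rankDeficient) " (rank deficient)" else ""))
})

# ---- cached fitting over a precomputed product dictionary ----------------
#
# All candidate designs are column subsets of one dictionary
# Z = [1, x_1..x_n, x_j x_k (j <= k)], so X'X and X'y for any parent set are
# submatrices of Z'Z and Z'Y, computed once per expression matrix. A single
# fit then costs O(p^3) with p <= 1 + h + h(h+1)/2 instead of O(m p^2).
# Residuals use rss = y'y - c'beta with beta the minimum-norm solution of
# the Gram system (eigendecomposition; relative eigenvalue cutoff 1e-12,
# i.e. a relative singular-value cutoff of 1e-6 appropriate to the squared
# conditioning of normal equations).
makeFitCache <- function(expr) {
  Y <- exprValues(expr)
  n <- nrow(Y)
  m <- ncol(Y)
  pr <- upperPairs(n)
  Z <- cbind(1, t(Y), t(Y)[, pr[, 1], drop = FALSE] * t(Y)[, pr[, 2], drop = FALSE])
  list(genes = rownames(Y),
       n = n, m = m,
       G = crossprod(Z),
       ZtY = crossprod(Z, t(Y)),
       yty = rowSums(Y^2))
}

# least-squares error for gene index `ti` with parent gene indices `pidx`
cachedNodeError <- function(cache, ti, pidx) {
  n <- cache$n
  h <- length(pidx)
  cols <- 1L
  if (h) {
    pr <- upperPairs(h)
    cols <- c(1L, 1L + pidx,
              pairColumn(pmin(pidx[pr[, 1]], pidx[pr[, 2]]),
                         pmax(pidx[pr[, 1]], pidx[pr[, 2]]), n))
  }
  A <- cache$G[cols, cols, drop = FALSE]
  cvec <- cache$ZtY[cols, ti]
  eg <- eigen(A, symmetric = TRUE)
  keep <- eg$values > max(eg$values[1], 0) * 1e-12
  if (!any(keep)) return(cache$yty[ti])
  beta <- eg$vectors[, keep, drop = FALSE] %*%
    (crossprod(eg$vectors[, keep, drop = FALSE], cvec) / eg$values[keep])
  max(cache$yty[ti] - sum(cvec * beta), 0)
}
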