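asEdgeMatrix <- function(x) {
  if (is(x, "GeneNetwork")) return(edges(x))
  if (is(x, "CompletionResult")) return(edges(x))
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.matrix(x), ncol(x) == 2)
  matrix(as.character(x), ncol = 2)
}

#' Completion accuracy
#'
#' Scores a completed network against the original by
#' \deqn{\frac{h + k + |E_{org} \cap E_{cmp}| - |E_{org}|}{h + k},}
#' which is 1 when all `k` added and `h` deleted edges are correct and 0
#' when none are. The value can fall outside `[0, 1]` only when the inputs
#' violate the modification-budget assumptions (e.g. the completed network
#' does not differ from the original by exactly `k` additions and `h`
#' deletions); a warning is attached in that case.
#'
#' @param original,completed edge sets: [GeneNetwork-class],
#'   [CompletionResult-class], or two-column matrices.
#' @param k,h the modification budgets used; `k + h` must be at least 1.
#' @return numeric scalar.
#' @examples
#' org <- rbind(c("a", "b"), c("b", "c"))
#' completionAccuracy(org, org, k = 1, h = 1)  # 1
#' @export
completionAccuracy <- function(original, completed, k, h) {
  if (k + h < 1) stop("completion accuracy is undefined for k + h = 0")
  eo <- asEdgeMatrix(original)
  ec <- asEdgeMatrix(completed)
  inter <- sum(edgeKey(eo[, 1], eo[, 2]) %in% edgeKey(ec[, 1], ec[, 2]))
  acc <- (h + k + inter - nrow(eo)) / (h + k)
  if (acc < 0 || acc > 1)
    warning("accuracy outside [0, 1]: edge sets do not differ by exactly ",
            "k additions and h deletions")
  acc
}

#' Inference accuracy
#'
#' The fraction of the original network's edges that were correctly
#' inferred. In `directed` mode an original edge is correct only if
#' inferred with its orientation; in `undirected` mode an original edge
#' counts as correct if either orientation of its gene pair was inferred
#' (the convention used when scoring tools that output undirected
#' associations). Each original edge is credited at most once, so the
#' accuracy never exceeds 1, and undirected accuracy is never below
#' directed accuracy on the same inputs.
#'
#' @param original,inferred edge sets as in [completionAccuracy()];
#'   `original` must be nonempty.
#' @param mode `"directed"` (default) or `"undirected"`.
#' @return numeric scalar in `[0, 1]`.
#' @export
inferenceAccuracy <- function(original, inferred,
                              mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  eo <- asEdgeMatrix(original)
  ei <- asEdgeMatrix(inferred)
  if (nrow(eo) == 0) stop("the original edge set must be nonempty")
  if (mode == "directed") {
    hit <- edgeKey(eo[, 1], eo[, 2]) %in% edgeKey(ei[, 1], ei[, 2])
  } else {
    und <- function(e) edgeKey(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    hit <- und(eo) %in% und(ei)
  }
  sum(hit) / nrow(eo)
}

#' Benchmark the completion or inference pipeline on synthetic systems
#'
#' Generates one triangular quadratic fixed-point system, perturbs its
#' exact solutions into an expression matrix, and then, for each of
#' `nRuns` seeds, either (completion mode) randomly modifies the
#' gold-standard network by `k` recoverable additions and `h` recoverable
#' deletions and completes it back, scoring with [completionAccuracy()];
#' or (inference mode) infers a network of `k` edges from the empty
#' network, scoring with [inferenceAccuracy()]. Per-run wall time is
#' recorded as informational output only.
#'
#' @param n,nSources,maxParents system size parameters; see
#'   [generateSystem()].
#' @param systemSeed seed for system generation and perturbation.
#' @param k,h modification budgets (completion) or `k` edges to add
#'   (inference; `h` ignored).
#' @param K,H per-gene caps; inference forces `H = 0`.
#' @param nRuns number of benchmark runs (default 5).
#' @param seeds optional integer vector of per-run seeds (length `nRuns`);
#'   default `systemSeed + 1:nRuns`.
#' @param mode `"completion"` (default) or `"inference"`.
#' @param matchingMode edge-matching mode for inference scoring.
#' @param replicates,halfWidth,includeExact perturbation parameters; see
#'   [perturbSolutions()].
#' @param allowSelfLoops permit self-loop additions during completion.
#' @return an [AccuracyReport-class].
#' @export
runBenchmark <- function(n = 10, nSources = 6, maxParents = 2,
                         systemSeed = 1, k = 1, h = 1, K = 2, H = 2,
                         nRuns = 5, seeds = NULL,
                         mode = c("completion", "inference"),
                         matchingMode = c("directed", "undirected"),
                         replicates = 400, halfWidth = 0.5,
                         includeExact = TRUE, allowSelfLoops = FALSE) {
  mode <- match.arg(mode)
  matchingMode <- match.arg(matchingMode)
  if (mode == "completion" && k + h < 1)
    stop("a completion benchmark needs k + h >= 1 (accuracy undefined)")
  if (nRuns < 1) stop("nRuns must be at least 1")
  if (is.null(seeds)) seeds <- systemSeed + seq_len(nRuns)
  seeds <- as.integer(seeds)
  stopifnot(length(seeds) == nRuns)
  system <- generateSystem(n, nSources, maxParents, seed = systemSeed)
  sols <- enumerateSolutions(system)
  expr <- perturbSolutions(sols, replicates = replicates,
                           halfWidth = halfWidth,
                           includeExact = includeExact, seed = systemSeed)
  gold <- goldStandard(system)
  rows <- lapply(seq_len(nRuns), function(r) {
    t0 <- proc.time()[["elapsed"]]
    if (mode == "completion") {
      mod <- modifyNetwork(gold, kAdd = k, hDel = h, seed = seeds[r])
      res <- completeNetwork(expr, mod$network, completionSpec(k, h, K, H),
                             allowSelfLoops = allowSelfLoops)
      acc <- if (res@feasible)
        completionAccuracy(gold, res, k = k, h = h) else NA_real_
      feas <- res@feasible
    } else {
      res <- inferNetwork(expr, k = k, K = K,
                          allowSelfLoops = allowSelfLoops)
      acc <- if (res@feasible)
        inferenceAccuracy(gold, res, mode = matchingMode) else NA_real_
      feas <- res@feasible
    }
    data.frame(seed = seeds[r], accuracy = acc, feasible = feas,
               seconds = proc.time()[["elapsed"]] - t0)
  })
  runs <- do.call(rbind, rows)
  new("AccuracyReport", mode = mode, matchingMode = matchingMode,
      runs = runs, meanAccuracy = mean(runs$accuracy, na.rm = TRUE),
      config = list(n = n, nSources = nSources, maxParents = maxParents,
                    systemSeed = systemSeed, k = k, h = h, K = K, H = H,
                    nRuns = nRuns, seeds = seeds, replicates = replicates,
                    halfWidth = halfWidth, includeExact = includeExact,
                    allowSelfLoops = allowSelfLoops))
}

setMethod("show", "AccuracyReport", function(object) {
  cat(sprintf("AccuracyReport (%s, %s matching): mean accuracy %.4f over %d runs\n",
              object@mode, object@matchingMode, object@meanAccuracy,
              nrow(object@runs)))
  print(object@runs, row.names = FALSE)
})
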