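# internal helpers shared across modules

# run expr with a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# column index of the product x_j * x_k (j <= k, 1-based) in the dictionary
# [1, x_1..x_n, x_1x_1, x_1x_2, .., x_1x_n, x_2x_2, .., x_nx_n]
pairColumn <- function(j, k, n) {
  stopifnot(all(j <= k))
  1L + n + (j - 1L) * n - ((j - 1L) * (j - 2L)) %/% 2L + (k - j + 1L)
}

# all (j, k) index pairs with j <= k over 1..h, in design-row order
upperPairs <- function(h) {
  if (h == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, lapply(seq_len(h), function(j) cbind(j, j:h)))
}

# combn that returns a list of integer vectors, including the empty choice
chooseSets <- function(x, m) {
  if (m == 0) return(list(integer(0)))
  if (length(x) < m) return(list())
  cm <- utils::combn(x, m)
  lapply(seq_len(ncol(cm)), function(i) cm[, i])
}

edgeKey <- function(from, to) paste(from, to, sep = "\r")
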