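#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions are deterministic per seed without
#' clobbering the session RNG.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Edge index map for an N-node connectome
#'
#' Enumerates the N(N-1)/2 unordered node pairs of the upper triangle in
#' row-major order (all pairs (1,j), then (2,j), ...). Every module in the
#' package vectorizes symmetric matrices in this order, so edge-level outputs
#' are comparable across runs.
#'
#' @param nNodes number of nodes (>= 2).
#' @return data.frame with integer columns `node_i`, `node_j` (`node_i <
#'   node_j`) and one row per edge.
#' @examples
#' edgePairs(4)
#' @export
edgePairs <- function(nNodes) {
  nNodes <- as.integer(nNodes)
  stopifnot(nNodes >= 2L)
  i <- rep.int(seq_len(nNodes - 1L), times = (nNodes - 1L):1L)
  j <- sequence((nNodes - 1L):1L, from = 2:nNodes)
  data.frame(node_i = i, node_j = as.integer(j))
}

#' Vectorize a symmetric matrix over its upper triangle
#'
#' @param m symmetric numeric matrix.
#' @param pairs optional edge map from [edgePairs()]; recomputed if missing.
#' @return numeric vector of length N(N-1)/2 in row-major upper-triangle order.
#' @export
matrixToEdges <- function(m, pairs = NULL) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(pairs)) pairs <- edgePairs(nrow(m))
  m[cbind(pairs$node_i, pairs$node_j)]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' Inverse of [matrixToEdges()].
#'
#' @param edges numeric edge vector in row-major upper-triangle order.
#' @param nNodes node count.
#' @return symmetric `nNodes` x `nNodes` matrix with zero diagonal.
#' @export
edgesToMatrix <- function(edges, nNodes) {
  pairs <- edgePairs(nNodes)
  stopifnot(length(edges) == nrow(pairs))
  m <- matrix(0, nNodes, nNodes)
  m[cbind(pairs$node_i, pairs$node_j)] <- edges
  m[cbind(pairs$node_j, pairs$node_i)] <- edges
  m
}

## map (i, j) pairs (i < j) to their positions in the row-major upper-triangle
## ordering: offset(i) = (i-1)*N - i*(i-1)/2, position = offset(i) + (j - i)
edgeIndexOf <- function(i, j, nNodes) {
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
  stopifnot(all(i >= 1L), all(j <= nNodes), all(i < j))
  as.integer((i - 1) * nNodes - i * (i - 1) / 2 + (j - i))
}

## largest-remainder allocation of n units over length(weights) cells
allocateExact <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## truncated-normal draw by rejection (bounds wide relative to sd in all uses)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}
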