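#' Network Based Statistic configuration
#'
#' @param componentFormingP edge-level p threshold that binarizes the t map
#'   before component search (default 0.001, applied per the configured
#'   tail).
#' @param nPermutations Monte-Carlo permutations of group labels (default
#'   1000).
#' @param alpha component-wise corrected significance level.
#' @param tail `"greater"` tests group A > group B at each edge, `"less"`
#'   the reverse, `"two_sided"` both.
#' @param sizeMetric `"extent"` (edge count) or `"intensity"` (sum of
#'   suprathreshold |t| - t_threshold).
#' @param pMethod `"add-one"` uses (1 + b) / (1 + K) for the corrected
#'   p-value (always valid); `"raw"` uses b / K, the plain proportion of null
#'   maxima at or above the observed size.
#' @param exhaustive enumerate every group assignment instead of sampling
#'   (small designs only; errors above 200000 assignments).
#' @param seed RNG seed for the permutations.
#' @return list of class `NBSConfig`.
#' @export
nbsConfig <- function(componentFormingP = 0.001, nPermutations = 1000L,
                      alpha = 0.05,
                      tail = c("greater", "less", "two_sided"),
                      sizeMetric = c("extent", "intensity"),
                      pMethod = c("add-one", "raw"),
                      exhaustive = FALSE, seed = 1L) {
  stopifnot(componentFormingP > 0, componentFormingP < 1,
            nPermutations >= 1, alpha > 0, alpha < 1)
  structure(list(componentFormingP = componentFormingP,
                 nPermutations = as.integer(nPermutations), alpha = alpha,
                 tail = match.arg(tail), sizeMetric = match.arg(sizeMetric),
                 pMethod = match.arg(pMethod), exhaustive = exhaustive,
                 seed = as.integer(seed)),
            class = "NBSConfig")
}

## fast pooled-variance two-sample t per column of X (subjects x edges).
## gA: 0/1 numeric group-A indicator. Precomputed X2 = X^2, S = colSums(X),
## SS = colSums(X2) let the permutation loop touch only two mat-vec products.
.fastT <- function(X, X2, gA, S, SS, dfExtra = 0L) {
  nA <- sum(gA); nB <- length(gA) - nA
  sA <- crossprod(gA, X)[1L, ]
  ssA <- crossprod(gA, X2)[1L, ]
  mA <- sA / nA
  mB <- (S - sA) / nB
  sp2 <- (ssA - nA * mA^2 + (SS - ssA) - nB * mB^2) /
    (nA + nB - 2 - dfExtra)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  (mA - mB) / se   # zero pooled variance yields NaN; callers map to t = 0
}

#' Edge-wise two-sample t-test
#'
#' Pooled-variance two-sample t at every edge independently, group A minus
#' group B. When covariates are supplied they are regressed out of each edge
#' across all subjects first (intercept included) and the degrees of freedom
#' reduced accordingly. Edges with zero pooled variance get t = 0, p = 1.
#'
#' @param zA,zB subjects x edges matrices for the two groups.
#' @param covariates optional (nA + nB) x k numeric matrix, rows ordered as
#'   `rbind(zA, zB)`.
#' @param tail `"greater"`, `"less"`, or `"two_sided"`.
#' @return list of class `EdgeStatMap`: `t`, `p`, `df`, `nA`, `nB`, `tail`.
#' @export
edgeTTest <- function(zA, zB, covariates = NULL,
                      tail = c("greater", "less", "two_sided")) {
  tail <- match.arg(tail)
  zA <- as.matrix(zA); zB <- as.matrix(zB)
  if (nrow(zA) < 2 || nrow(zB) < 2) stop("need >= 2 subjects per group")
  if (ncol(zA) != ncol(zB)) stop("edge counts differ between groups")
  if (anyNA(zA) || anyNA(zB)) stop("NA values in edge data")
  X <- rbind(zA, zB)
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(X))
    X <- stats::lm.fit(cbind(1, covariates), X)$residuals
    k <- ncol(covariates)
  }
  gA <- c(rep(1, nrow(zA)), rep(0, nrow(zB)))
  t <- .fastT(X, X^2, gA, colSums(X), colSums(X^2), dfExtra = k)
  zeroVar <- !is.finite(t)
  t[zeroVar] <- 0
  df <- nrow(zA) + nrow(zB) - 2L - k
  p <- switch(tail,
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df),
              two_sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  p[zeroVar] <- 1   # degenerate edges never enter a component
  structure(list(t = t, p = p, df = df, nA = nrow(zA), nB = nrow(zB),
                 tail = tail),
            class = "EdgeStatMap")
}

#' Suprathreshold edges of an edge statistic map
#'
#' @param stats an `EdgeStatMap` from [edgeTTest()].
#' @param pThresh component-forming p threshold.
#' @return integer vector of edge indices with p < `pThresh`.
#' @export
thresholdEdges <- function(stats, pThresh = 0.001) {
  stopifnot(inherits(stats, "EdgeStatMap"))
  which(stats$p < pThresh)
}

## component membership of a set of edges given as a 2-column pair matrix;
## returns a list of row-index vectors, one per connected component, ordered
## by decreasing edge count then smallest node id
.componentEdgeSets <- function(pairs) {
  if (nrow(pairs) == 0) return(list())
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  memb <- igraph::components(g)$membership
  compOf <- memb[pairs[, 1]]
  sets <- split(seq_len(nrow(pairs)), compOf)
  minNode <- vapply(sets, function(ix) min(pairs[ix, ]), numeric(1))
  sizes <- lengths(sets)
  unname(sets[order(-sizes, minNode)])
}

#' Connected components of a suprathreshold edge set
#'
#' Partitions an edge set into the connected components of its union graph.
#' Extent is the number of edges per component; components come back in
#' deterministic order (decreasing extent, ties broken by smallest incident
#' node id).
#'
#' @param edges 2-column matrix of node pairs (one edge per row).
#' @param nNodes number of nodes in the connectome (validates the pairs).
#' @return list of components, each with `edges` (pair matrix), `nodes`
#'   (sorted incident vertices), `size` (extent).
#' @examples
#' edgeComponents(rbind(c(1, 2), c(2, 3), c(5, 6)), 6)
#' @export
edgeComponents <- function(edges, nNodes) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) && (min(edges) < 1 || max(edges) > nNodes))
    stop("edge endpoints outside 1..", nNodes)
  lapply(.componentEdgeSets(edges), function(ix) {
    e <- edges[ix, , drop = FALSE]
    list(edges = e, nodes = sort(unique(as.vector(e))), size = nrow(e))
  })
}

## component sizes under the configured metric for one thresholded map;
## returns max statistic only (permutation path)
.maxComponentStat <- function(supra, t, pairs, tcrit, metric) {
  if (length(supra) == 0) return(0)
  sets <- .componentEdgeSets(pairs[supra, , drop = FALSE])
  if (metric == "extent") return(max(lengths(sets)))
  max(vapply(sets, function(ix) sum(abs(t[supra[ix]]) - tcrit), numeric(1)))
}

#' Network Based Statistic
#'
#' Identifies connected subnetworks whose edges differ between two groups,
#' with family-wise error control over components. Procedure: a two-sample t
#' at every edge; edges with p below the component-forming threshold are kept;
#' the connected components of the kept edges are measured (extent = edge
#' count, or intensity); the same statistic is computed under random
#' permutations of the group labels, storing the maximal component size per
#' permutation; each observed component's corrected p-value is the proportion
#' of null maxima at least as large (with add-one smoothing by default, see
#' [nbsConfig()]). Permutations with no suprathreshold edge contribute a
#' maximal size of 0.
#'
#' When covariates are supplied they stay bound to subjects: edges are
#' residualized on the covariates once and group labels are permuted over the
#' residuals (a Freedman-Lane-style scheme).
#'
#' @param z subjects x edges matrix of Fisher-z values, edge order per
#'   [edgePairs()].
#' @param labels two-level factor (first level is group A, tested A > B under
#'   `tail = "greater"`).
#' @param nNodes node count of the connectome.
#' @param config an [nbsConfig()].
#' @param covariates optional subjects x k matrix.
#' @return an [NBSResult-class].
#' @export
nbs <- function(z, labels, nNodes, config = nbsConfig(), covariates = NULL) {
  stopifnot(inherits(config, "NBSConfig"))
  z <- as.matrix(z)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("labels must have exactly two levels, got: ",
         paste(levels(labels), collapse = ", "))
  if (any(table(labels) < 2)) stop("each group needs >= 2 subjects")
  if (nrow(z) != length(labels)) stop("rows of z must match labels")
  pairs <- as.matrix(edgePairs(nNodes))
  if (ncol(z) != nrow(pairs))
    stop("z has ", ncol(z), " columns but ", nNodes, " nodes imply ",
         nrow(pairs), " edges")

  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    z <- stats::lm.fit(cbind(1, covariates), z)$residuals
    k <- ncol(covariates)
  }
  n <- nrow(z)
  gA <- as.numeric(labels == levels(labels)[1])
  nA <- sum(gA)
  df <- n - 2L - k
  X2 <- z^2
  S <- colSums(z)
  SS <- colSums(X2)
  tcrit <- if (config$tail == "two_sided")
    stats::qt(1 - config$componentFormingP / 2, df)
  else stats::qt(1 - config$componentFormingP, df)
  supraOf <- function(t) switch(config$tail,
                                greater = which(t > tcrit),
                                less = which(t < -tcrit),
                                two_sided = which(abs(t) > tcrit))

  tObs <- .fastT(z, X2, gA, S, SS, dfExtra = k)
  zeroVar <- !is.finite(tObs)
  tObs[zeroVar] <- 0
  pObs <- switch(config$tail,
                 greater = stats::pt(tObs, df, lower.tail = FALSE),
                 less = stats::pt(tObs, df),
                 two_sided = 2 * stats::pt(abs(tObs), df, lower.tail = FALSE))
  pObs[zeroVar] <- 1
  supra <- supraOf(tObs)
  obsSets <- .componentEdgeSets(pairs[supra, , drop = FALSE])
  obsSize <- vapply(obsSets, function(ix) {
    if (config$sizeMetric == "extent") length(ix)
    else sum(abs(tObs[supra[ix]]) - tcrit)
  }, numeric(1))

  nullMax <- if (isTRUE(config$exhaustive)) {
    if (choose(n, nA) > 2e5)
      stop("exhaustive enumeration infeasible: ", choose(n, nA),
           " assignments")
    apply(utils::combn(n, nA), 2, function(ix) {
      g <- numeric(n); g[ix] <- 1
      t <- .fastT(z, X2, g, S, SS, dfExtra = k)
      .maxComponentStat(supraOf(t), t, pairs, tcrit, config$sizeMetric)
    })
  } else withSeed(config$seed, {
    vapply(seq_len(config$nPermutations), function(b) {
      g <- gA[sample.int(n)]
      t <- .fastT(z, X2, g, S, SS, dfExtra = k)
      .maxComponentStat(supraOf(t), t, pairs, tcrit, config$sizeMetric)
    }, numeric(1))
  })

  fweP <- vapply(obsSize, function(s) {
    b <- sum(nullMax >= s)
    if (isTRUE(config$exhaustive)) b / length(nullMax)
    else if (config$pMethod == "raw") b / length(nullMax)
    else (1 + b) / (1 + length(nullMax))
  }, numeric(1))

  comps <- Map(function(ix, s, p) {
    e <- pairs[supra[ix], , drop = FALSE]
    list(edges = e, edge_index = supra[ix],
         nodes = sort(unique(as.vector(e))), size = s, fwe_p = max(p, 1e-300))
  }, obsSets, obsSize, fweP)

  new("NBSResult", components = unname(comps), nullMaxSize = nullMax,
      edgeStats = data.frame(node_i = pairs[, 1], node_j = pairs[, 2],
                             t = tObs, p = pObs),
      config = unclass(config), nNodes = as.integer(nNodes),
      seed = config$seed)
}

#' Run the NBS on a cohort slice
#'
#' Convenience wrapper: extracts one timepoint and two outcome groups from a
#' [ConnectomeCohort-class] and calls [nbs()].
#'
#' @param cohort a `ConnectomeCohort`.
#' @param outcomes two `outcome` levels; the first is group A.
#' @param timepoint scan label.
#' @param config an [nbsConfig()].
#' @param covariates optional data.frame/matrix aligned to the selected
#'   subjects.
#' @return an [NBSResult-class].
#' @export
runNBS <- function(cohort, outcomes = c("remitter", "nonremitter"),
                   timepoint = "baseline", config = nbsConfig(),
                   covariates = NULL) {
  sl <- cohortSlice(cohort, timepoint = timepoint, outcomes = outcomes)
  nbs(sl$z, sl$labels, nNodes(cohort), config = config,
      covariates = covariates)
}
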