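#' Mean connectivity over a signature edge set
#'
#' The single per-subject estimate used by the downstream group statistics:
#' the arithmetic mean of Fisher-z connectivity over the edges of an
#' identified subnetwork.
#'
#' @param conn a [Connectome-class].
#' @param edges 2-column matrix of node pairs.
#' @return scalar mean z.
#' @export
meanSignature <- function(conn, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0) stop("empty signature edge set")
  if (max(edges) > nNodes(conn)) stop("edge endpoints outside the connectome")
  mean(zMatrix(conn)[edges])
}

#' Per-network-pair signature means for one connectome
#'
#' Maps every signature edge to the unordered pair of its endpoints'
#' intrinsic-network labels (after reporting aliases) and averages z within
#' each pair.
#'
#' @param conn a [Connectome-class].
#' @param edges 2-column node-pair matrix.
#' @param parc parcellation (defaults to the connectome's own).
#' @param aliases label alias map applied before pairing; `NULL` disables.
#' @return a [SignatureSummary-class].
#' @export
networkPairMeans <- function(conn, edges, parc = parcellation(conn),
                             aliases = networkAliases()) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0) stop("empty signature edge set")
  labs <- networkLabels(parc)
  if (!is.null(aliases)) labs <- aliasNetworkLabels(labs, aliases)
  if (max(edges) > length(labs))
    stop("node ", max(edges), " has no parcellation label")
  key <- pairKey(labs[edges[, 1]], labs[edges[, 2]])
  zv <- zMatrix(conn)[edges]
  agg <- tapply(zv, key, mean)
  cnt <- tapply(zv, key, length)
  pairs <- data.frame(pair = names(agg), n_edges = as.integer(cnt),
                      mean_z = as.numeric(agg), row.names = NULL)
  pairs <- pairs[order(-pairs$n_edges, pairs$pair), , drop = FALSE]
  rownames(pairs) <- NULL
  new("SignatureSummary", subjectId = conn@subjectId,
      timepoint = conn@timepoint, overallMeanZ = mean(zv), pairs = pairs)
}

#' Long-format signature summaries for a whole cohort
#'
#' Computes the overall and per-network-pair signature means for every scan
#' in a cohort, in the long layout the group-statistics stage consumes.
#'
#' @param cohort a [ConnectomeCohort-class].
#' @param edges 2-column node-pair matrix (the signature).
#' @param aliases label alias map; `NULL` disables.
#' @return data.frame with columns `subject_id`, `group`, `outcome`,
#'   `timepoint`, `measure` ("overall" or a pair key), `n_edges`, `value`.
#' @export
summarizeSignature <- function(cohort, edges, aliases = networkAliases()) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0) stop("empty signature edge set")
  n <- nNodes(cohort)
  labs <- networkLabels(parcellation(cohort))
  if (!is.null(aliases)) labs <- aliasNetworkLabels(labs, aliases)
  key <- pairKey(labs[edges[, 1]], labs[edges[, 2]])
  idx <- edgeIndexOf(edges[, 1], edges[, 2], n)
  z <- SummarizedExperiment::assay(cohort, "z")[idx, , drop = FALSE]
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  groups <- c(list(overall = seq_along(key)), split(seq_along(key), key))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    rows <- groups[[g]]
    data.frame(subject_id = cd$subject_id, group = cd$group,
               outcome = cd$outcome, timepoint = cd$timepoint,
               measure = g, n_edges = length(rows),
               value = colMeans(z[rows, , drop = FALSE]),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Report-style table of labeled signature edges
#'
#' Renders a signature edge set in the layout of published connectivity
#' tables: rows grouped by unordered network pair (with per-pair connection
#' counts), endpoint hemisphere/region labels and centroid coordinates, and
#' per-group mean +/- SD of the edge connectivity. Row order is
#' deterministic: pairs by decreasing count then name, edges by node ids.
#'
#' @param edges 2-column node-pair matrix.
#' @param parc a [Parcellation-class].
#' @param groupStats optional list of subjects x edges matrices named by
#'   group (e.g. `list(remitter = ..., nonremitter = ...)`, columns aligned
#'   to `edges` rows) used for the mean/SD columns.
#' @param aliases label alias map; `NULL` disables.
#' @return data.frame, one row per edge, with columns `network_pair`,
#'   `n_in_pair`, endpoint descriptors, and `<group>_mean` / `<group>_sd`
#'   per supplied group.
#' @export
labelEdges <- function(edges, parc, groupStats = NULL,
                       aliases = networkAliases()) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0) {
    return(data.frame(network_pair = character(0), n_in_pair = integer(0)))
  }
  nd <- as.data.frame(parc)
  labs <- nd$network_label
  if (!is.null(aliases)) labs <- aliasNetworkLabels(labs, aliases)
  key <- pairKey(labs[edges[, 1]], labs[edges[, 2]])
  cnt <- table(key)
  out <- data.frame(
    network_pair = key, n_in_pair = as.integer(cnt[key]),
    node_i = edges[, 1], node_j = edges[, 2],
    seed_hemisphere = nd$hemisphere[edges[, 1]],
    seed_x = nd$x[edges[, 1]], seed_y = nd$y[edges[, 1]],
    seed_z = nd$z[edges[, 1]],
    target_hemisphere = nd$hemisphere[edges[, 2]],
    target_x = nd$x[edges[, 2]], target_y = nd$y[edges[, 2]],
    target_z = nd$z[edges[, 2]])
  if (!is.null(groupStats)) {
    for (g in names(groupStats)) {
      m <- as.matrix(groupStats[[g]])
      stopifnot(ncol(m) == nrow(edges))
      out[[paste0(g, "_mean")]] <- colMeans(m)
      out[[paste0(g, "_sd")]] <- apply(m, 2, stats::sd)
    }
  }
  out <- out[order(-out$n_in_pair, out$network_pair, out$node_i, out$node_j),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count distinct network pairs in a signature report
#'
#' @param report data.frame with a `network_pair` column (from
#'   [labelEdges()] or [loadSignatureTable()]).
#' @return number of distinct unordered network-pair groups.
#' @export
countNetworkPairs <- function(report) {
  length(unique(report$network_pair))
}

#' Total connection count of a signature report
#'
#' Sums the per-pair header counts (`n_in_pair`, one value per pair), which
#' are authoritative even when a table prints only a subset of its rows.
#'
#' @param report data.frame with `network_pair` and `n_in_pair` columns.
#' @return total connection count.
#' @export
countConnections <- function(report) {
  perPair <- tapply(report$n_in_pair, report$network_pair,
                    function(v) unique(v)[1])
  as.integer(sum(perPair))
}

#' Load the packaged remitter-vs-non-remitter signature table
#'
#' A machine-readable transcription of the published pre-treatment
#' connectivity table of the antidepressant-remission connectome signature:
#' 15 unique network pairs totalling 86 connections across 59 nodes, with
#' endpoint region labels, MNI coordinates and per-group mean +/- SD. Some
#' pairs print fewer rows than their header count; the `n_in_pair` column
#' carries the authoritative per-pair totals.
#'
#' @param path alternative file path; default is the packaged fixture.
#' @return data.frame with one row per printed connection.
#' @export
loadSignatureTable <- function(path = system.file("extdata",
                                                  "remission_signature_table.tsv",
                                                  package = "connbs")) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
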