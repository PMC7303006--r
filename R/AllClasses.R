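#' @include AllGenerics.R
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# Parcellation
# ---------------------------------------------------------------------------

#' Labeled cortical parcellation
#'
#' Binds node ids to intrinsic-network labels, hemisphere, and (metadata-only)
#' centroid coordinates in MNI mm. The default template mirrors a 333-region
#' cortical parcellation with 13 intrinsic-network categories; see
#' [makeParcellation()].
#'
#' @slot nodes data.frame with columns `node_id` (1-based, contiguous),
#'   `network_label`, `hemisphere` ("L"/"R"), `x`, `y`, `z`.
#' @export
setClass("Parcellation", representation(nodes = "data.frame"))

setValidity("Parcellation", function(object) {
  nd <- object@nodes
  need <- c("node_id", "network_label", "hemisphere", "x", "y", "z")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (nrow(nd) < 1) return("parcellation has no nodes")
  if (!identical(as.integer(nd$node_id), seq_len(nrow(nd))))
    return("node_id must be contiguous 1..N")
  if (anyNA(nd$network_label) || any(!nzchar(nd$network_label)))
    return("every node needs a non-empty network_label")
  TRUE
})

#' @describeIn Parcellation number of nodes.
#' @param x a `Parcellation`.
#' @export
setMethod("nNodes", "Parcellation", function(x) nrow(x@nodes))

#' @describeIn Parcellation character vector of per-node network labels.
#' @export
setMethod("networkLabels", "Parcellation", function(x)
  as.character(x@nodes$network_label))

#' @describeIn Parcellation the node table as a data.frame.
#' @param row.names,optional,... ignored (base-generic signature).
#' @export
setMethod("as.data.frame", "Parcellation", function(x, ...) x@nodes)

setMethod("show", "Parcellation", function(object) {
  tab <- sort(table(networkLabels(object)), decreasing = TRUE)
  cat("Parcellation with", nNodes(object), "nodes,",
      length(tab), "network labels\n")
  cat("  ", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# RegionTimeSeries
# ---------------------------------------------------------------------------

#' Region-level BOLD time series for one run
#'
#' @slot values T x N numeric matrix (frames x regions), BOLD-like units.
#' @slot trSeconds repetition time in seconds.
#' @slot runId run label.
#' @slot censorMask logical length-T vector, `TRUE` = frame retained.
#' @export
setClass("RegionTimeSeries",
         representation(values = "matrix", trSeconds = "numeric",
                        runId = "character", censorMask = "logical"))

setValidity("RegionTimeSeries", function(object) {
  if (nrow(object@values) < 2) return("need at least 2 frames")
  if (length(object@censorMask) != nrow(object@values))
    return("censorMask length must equal the number of frames")
  if (length(object@trSeconds) != 1 || object@trSeconds <= 0)
    return("trSeconds must be a single positive number")
  if (!is.numeric(object@values)) return("values must be numeric")
  TRUE
})

#' Construct a RegionTimeSeries
#'
#' @param values T x N numeric matrix (frames in rows).
#' @param trSeconds repetition time (s).
#' @param runId run label.
#' @param censorMask logical retained-frame mask; default all retained.
#' @return a [RegionTimeSeries-class] object.
#' @export
RegionTimeSeries <- function(values, trSeconds, runId = "run1",
                             censorMask = rep(TRUE, nrow(values))) {
  new("RegionTimeSeries", values = as.matrix(values),
      trSeconds = as.numeric(trSeconds), runId = as.character(runId),
      censorMask = as.logical(censorMask))
}

#' @describeIn RegionTimeSeries the frames x regions matrix.
#' @param x a `RegionTimeSeries`.
#' @export
setMethod("tsValues", "RegionTimeSeries", function(x) x@values)

#' @describeIn RegionTimeSeries logical retained-frame mask.
#' @export
setMethod("censorMask", "RegionTimeSeries", function(x) x@censorMask)

#' @describeIn RegionTimeSeries replace the retained-frame mask.
#' @param value logical mask.
#' @export
setMethod("censorMask<-", "RegionTimeSeries", function(x, value) {
  x@censorMask <- as.logical(value)
  validObject(x)
  x
})

#' @describeIn RegionTimeSeries repetition time in seconds.
#' @export
setMethod("trSeconds", "RegionTimeSeries", function(x) x@trSeconds)

setMethod("show", "RegionTimeSeries", function(object) {
  cat(sprintf("RegionTimeSeries '%s': %d frames x %d regions, TR %.3g s, %d censored\n",
              object@runId, nrow(object@values), ncol(object@values),
              object@trSeconds, sum(!object@censorMask)))
})

# ---------------------------------------------------------------------------
# Connectome
# ---------------------------------------------------------------------------

#' Subject-level Fisher-z connectome
#'
#' Symmetric matrix of Fisher-z transformed inter-regional correlations with a
#' zero diagonal, bound to a [Parcellation-class].
#'
#' @slot z N x N numeric matrix in Fisher-z units.
#' @slot parcellation the node parcellation.
#' @slot subjectId subject identifier.
#' @slot timepoint session label (e.g. "baseline", "week8").
#' @export
setClass("Connectome",
         representation(z = "matrix", parcellation = "Parcellation",
                        subjectId = "character", timepoint = "character"))

setValidity("Connectome", function(object) {
  z <- object@z
  if (nrow(z) != ncol(z)) return("z must be square")
  if (nrow(z) != nNodes(object@parcellation))
    return("z dimension must match the parcellation")
  if (any(!is.finite(z))) return("z must be finite everywhere")
  if (any(abs(diag(z)) > 1e-12)) return("diagonal must be zero")
  if (max(abs(z - t(z))) > 1e-8) return("z must be symmetric")
  TRUE
})

#' Construct a Connectome
#'
#' @param z symmetric N x N Fisher-z matrix, zero diagonal.
#' @param parcellation matching [Parcellation-class].
#' @param subjectId,timepoint identifiers.
#' @return a [Connectome-class].
#' @export
Connectome <- function(z, parcellation, subjectId = "subject",
                       timepoint = "baseline") {
  new("Connectome", z = as.matrix(z), parcellation = parcellation,
      subjectId = as.character(subjectId), timepoint = as.character(timepoint))
}

#' @describeIn Connectome the Fisher-z matrix.
#' @param x a `Connectome`.
#' @export
setMethod("zMatrix", "Connectome", function(x) x@z)

#' @describeIn Connectome the bound parcellation.
#' @export
setMethod("parcellation", "Connectome", function(x) x@parcellation)

#' @describeIn Connectome node count.
#' @export
setMethod("nNodes", "Connectome", function(x) nrow(x@z))

setMethod("show", "Connectome", function(object) {
  ut <- matrixToEdges(object@z)
  cat(sprintf("Connectome %s/%s: %d nodes, edge z mean %.3f (sd %.3f)\n",
              object@subjectId, object@timepoint, nrow(object@z),
              mean(ut), stats::sd(ut)))
})

# ---------------------------------------------------------------------------
# ConnectomeCohort
# ---------------------------------------------------------------------------

#' Cohort of edge-vectorized connectomes
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay `"z"` holds Fisher-z edges (rows, row-major upper
#' triangle per [edgePairs()]) by scan (columns, one per subject-timepoint).
#' `colData` carries the subject records (subject_id, group, outcome,
#' timepoint, ...); `metadata()` carries the `parcellation` and, for synthetic
#' cohorts, the generator `groundTruth`.
#'
#' @export
setClass("ConnectomeCohort", contains = "SummarizedExperiment")

#' @describeIn ConnectomeCohort the cohort parcellation.
#' @param x a `ConnectomeCohort`.
#' @export
setMethod("parcellation", "ConnectomeCohort", function(x)
  metadata(x)$parcellation)

#' @describeIn ConnectomeCohort node count.
#' @export
setMethod("nNodes", "ConnectomeCohort", function(x)
  nNodes(metadata(x)$parcellation))

#' @describeIn ConnectomeCohort generator ground truth (synthetic cohorts;
#'   `NULL` otherwise).
#' @export
setMethod("groundTruth", "ConnectomeCohort", function(x)
  metadata(x)$groundTruth)

setMethod("show", "ConnectomeCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("ConnectomeCohort: %d edges x %d scans (%d nodes)\n",
              nrow(object), ncol(object), nNodes(object)))
  if (all(c("group", "timepoint") %in% names(cd)))
    print(table(group = cd$group, timepoint = cd$timepoint))
})

# ---------------------------------------------------------------------------
# NBSResult
# ---------------------------------------------------------------------------

#' Result of a Network Based Statistic analysis
#'
#' @slot components list of components, each a list with `edges` (two-column
#'   matrix of node pairs), `edge_index`, `nodes`, `size`, `fwe_p`; sorted by
#'   decreasing size.
#' @slot nullMaxSize numeric permutation null of the maximal component size.
#' @slot edgeStats data.frame of per-edge `t` and `p` aligned to
#'   [edgePairs()].
#' @slot config list echo of the [nbsConfig()] used.
#' @slot nNodes node count of the analysed connectome.
#' @slot seed RNG seed used for the permutations.
#' @export
setClass("NBSResult",
         representation(components = "list", nullMaxSize = "numeric",
                        edgeStats = "data.frame", config = "list",
                        nNodes = "integer", seed = "integer"))

setValidity("NBSResult", function(object) {
  for (cmp in object@components) {
    if (cmp$size <= 0) return("component size must be positive")
    if (cmp$fwe_p <= 0 || cmp$fwe_p > 1) return("fwe_p must be in (0, 1]")
  }
  TRUE
})

#' @describeIn NBSResult list of all observed components.
#' @param x an `NBSResult`.
#' @export
setMethod("nbsComponents", "NBSResult", function(x) x@components)

#' @describeIn NBSResult permutation null distribution of the max component
#'   size.
#' @export
setMethod("nullDistribution", "NBSResult", function(x) x@nullMaxSize)

#' @describeIn NBSResult components with family-wise-corrected p below
#'   `alpha` (default: the alpha in the result's config).
#' @param alpha significance level; `NULL` uses the config value.
#' @export
setMethod("significantComponents", "NBSResult", function(x, alpha = NULL) {
  if (is.null(alpha)) alpha <- x@config$alpha
  Filter(function(cmp) cmp$fwe_p < alpha, x@components)
})

setMethod("show", "NBSResult", function(object) {
  cat(sprintf("NBSResult: %d component(s), %d permutations, tail '%s'\n",
              length(object@components), length(object@nullMaxSize),
              object@config$tail))
  for (cmp in utils::head(object@components, 5))
    cat(sprintf("  component: %d edges / %d nodes, FWE p = %.4g%s\n",
                cmp$size, length(cmp$nodes), cmp$fwe_p,
                if (cmp$fwe_p < object@config$alpha) " *" else ""))
})

# ---------------------------------------------------------------------------
# SignatureSummary
# ---------------------------------------------------------------------------

#' Per-subject summary of a connectomic signature
#'
#' Mean Fisher-z connectivity over a signature edge set, overall and per
#' unordered network-label pair. The overall mean always equals the
#' edge-count-weighted mean of the per-pair means.
#'
#' @slot subjectId,timepoint identifiers.
#' @slot overallMeanZ mean z over all signature edges.
#' @slot pairs data.frame with `pair` (canonical "A-B" key, labels sorted),
#'   `n_edges`, `mean_z`.
#' @export
setClass("SignatureSummary",
         representation(subjectId = "character", timepoint = "character",
                        overallMeanZ = "numeric", pairs = "data.frame"))

setValidity("SignatureSummary", function(object) {
  p <- object@pairs
  if (!all(c("pair", "n_edges", "mean_z") %in% names(p)))
    return("pairs needs columns pair, n_edges, mean_z")
  w <- sum(p$n_edges * p$mean_z) / sum(p$n_edges)
  if (abs(w - object@overallMeanZ) > 1e-10)
    return("overallMeanZ must equal the edge-count-weighted mean of pair means")
  TRUE
})

#' @describeIn SignatureSummary overall signature mean z.
#' @param x a `SignatureSummary`.
#' @export
setMethod("overallMeanZ", "SignatureSummary", function(x) x@overallMeanZ)

#' @describeIn SignatureSummary per-network-pair means (data.frame).
#' @export
setMethod("pairMeans", "SignatureSummary", function(x) x@pairs)

setMethod("show", "SignatureSummary", function(object) {
  cat(sprintf("SignatureSummary %s/%s: overall mean z = %.3f over %d edges in %d network pairs\n",
              object@subjectId, object@timepoint, object@overallMeanZ,
              sum(object@pairs$n_edges), nrow(object@pairs)))
})
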