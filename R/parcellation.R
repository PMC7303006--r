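## Intrinsic-network vocabulary of the 333-region cortical template and the
## merged names used in clinical reports. Node counts per network follow the
## published template; centroid coordinates in the synthetic default template
## are random placeholders (metadata only, no spatial computation happens).

.gordonNetworkSizes <- c(
  Default = 41, SMhand = 38, SMmouth = 8, Visual = 39, FrontoParietal = 24,
  Auditory = 24, CinguloOperc = 40, RetrosplenialTemporal = 8,
  CinguloParietal = 5, DorsalAttn = 32, VentralAttn = 23, Salience = 4,
  None = 47)

#' Reporting aliases for intrinsic-network labels
#'
#' Maps template network labels onto the merged vocabulary used in summary
#' tables: the two somatomotor subdivisions collapse to "Somatomotor",
#' unassigned parcels become "Unspecified", and the default-mode and attention
#' networks take their common short names. Labels without an alias pass
#' through unchanged.
#'
#' @return named character vector (template label -> reporting label).
#' @examples
#' networkAliases()[["SMhand"]]
#' @export
networkAliases <- function() {
  c(Default = "DMN", SMhand = "Somatomotor", SMmouth = "Somatomotor",
    CinguloOperc = "CinguloOpercular", DorsalAttn = "DorsalAttention",
    VentralAttn = "VentralAttention", None = "Unspecified")
}

#' Apply reporting aliases to network labels
#'
#' @param labels character vector of template labels.
#' @param aliases named alias map, default [networkAliases()].
#' @return character vector of reporting labels.
#' @export
aliasNetworkLabels <- function(labels, aliases = networkAliases()) {
  hit <- labels %in% names(aliases)
  labels[hit] <- aliases[labels[hit]]
  labels
}

#' Synthetic default parcellation template
#'
#' Builds a labeled parcellation with the node-per-network composition of the
#' 333-region cortical template (13 intrinsic-network categories including
#' unassigned parcels). Hemisphere assignment alternates within each network
#' and centroid coordinates are synthetic draws inside a brain-sized bounding
#' box -- they are carried as metadata only and never used in computation.
#'
#' For reduced problem sizes (`nNodes < 333`) the network composition is
#' scaled proportionally with largest-remainder rounding, so small test
#' parcellations keep the full label vocabulary mix.
#'
#' @param nNodes number of nodes (default 333).
#' @param seed RNG seed for the synthetic coordinates.
#' @return a [Parcellation-class].
#' @examples
#' p <- makeParcellation(50)
#' table(networkLabels(p))
#' @export
makeParcellation <- function(nNodes = 333L, seed = 42L) {
  nNodes <- as.integer(nNodes)
  stopifnot(nNodes >= 4L)
  sizes <- allocateExact(nNodes, .gordonNetworkSizes)
  names(sizes) <- names(.gordonNetworkSizes)
  labels <- rep(names(sizes), times = sizes)
  hemi <- unlist(lapply(sizes, function(k) rep_len(c("L", "R"), k)),
                 use.names = FALSE)
  withSeed(seed, {
    xyz <- cbind(x = round(stats::runif(nNodes, -70, 70), 1),
                 y = round(stats::runif(nNodes, -100, 70), 1),
                 z = round(stats::runif(nNodes, -45, 75), 1))
    xyz[, 1] <- ifelse(hemi == "L", -abs(xyz[, 1]), abs(xyz[, 1]))
    new("Parcellation", nodes = data.frame(
      node_id = seq_len(nNodes), network_label = labels, hemisphere = hemi,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  })
}

#' Read a parcellation table from delimited text
#'
#' Expects a header with columns `node_id`, `network_label`, `hemisphere`,
#' `x`, `y`, `z`. Node ids must be contiguous from 1 with no duplicates.
#' Labels outside the known template vocabulary (plus their reporting
#' aliases) are accepted with a warning, so alternative parcellations load.
#'
#' @param path file path (tab- or whitespace-delimited, `sep = ""` default of
#'   [utils::read.table()] with `header = TRUE`).
#' @param sep field separator, default tab.
#' @return a [Parcellation-class].
#' @export
loadParcellation <- function(path, sep = "\t") {
  nd <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (anyDuplicated(nd$node_id))
    stop("duplicate node_id in parcellation file: ",
         paste(unique(nd$node_id[duplicated(nd$node_id)]), collapse = ", "))
  nd <- nd[order(nd$node_id), , drop = FALSE]
  known <- c(names(.gordonNetworkSizes), unname(networkAliases()))
  unknown <- setdiff(unique(nd$network_label), known)
  if (length(unknown))
    warning("unknown network label(s) accepted as-is: ",
            paste(unknown, collapse = ", "))
  rownames(nd) <- NULL
  new("Parcellation", nodes = nd)
}

#' Write a parcellation table
#'
#' @param parc a [Parcellation-class].
#' @param path output path (tab-delimited with header).
#' @return `path`, invisibly.
#' @export
writeParcellation <- function(parc, path) {
  utils::write.table(as.data.frame(parc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## canonical unordered network-pair key: labels sorted, joined by "-"
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "-")
}
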