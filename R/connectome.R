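#' Fisher z transformation
#'
#' Variance-stabilizing `atanh` mapping of correlation coefficients.
#'
#' @param r correlations, strictly inside (-1, 1).
#' @return Fisher-z values.
#' @examples
#' fisherZ(tanh(1))  # 1
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1))
    stop("fisherZ requires |r| < 1; clip degenerate correlations first")
  atanh(r)
}

#' Correlate regions across denoised runs
#'
#' Pearson correlation over the concatenation of the retained (non-censored)
#' frames of all runs, with each run mean-centered per region before
#' concatenation so run-specific offsets do not masquerade as coupling.
#'
#' @param runs a [RegionTimeSeries-class] or list of them (same regions).
#' @param minFrames minimum total retained frames; below this the subject is
#'   rejected with an informative error so callers can flag and exclude.
#' @return N x N correlation matrix (diagonal 1).
#' @export
correlateRegions <- function(runs, minFrames = 30L) {
  if (is(runs, "RegionTimeSeries")) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  N <- ncol(tsValues(runs[[1]]))
  blocks <- lapply(runs, function(r) {
    stopifnot(ncol(tsValues(r)) == N)
    v <- tsValues(r)[censorMask(r), , drop = FALSE]
    sweep(v, 2, colMeans(v))
  })
  dat <- do.call(rbind, blocks)
  if (nrow(dat) < minFrames)
    stop("subject excluded: only ", nrow(dat), " retained frames (< ",
         minFrames, ")")
  stats::cor(dat)
}

#' Assemble a Fisher-z connectome from denoised runs
#'
#' Correlation -> clip to +/- `clip` -> Fisher z -> zero diagonal, bound to
#' the parcellation. Clipping keeps degenerate (|r| = 1) edges finite.
#'
#' @param runs denoised run(s) (see [correlateRegions()]).
#' @param parcellation matching [Parcellation-class].
#' @param clip correlation magnitude ceiling before `atanh`.
#' @param subjectId,timepoint identifiers.
#' @param minFrames forwarded to [correlateRegions()].
#' @return a [Connectome-class].
#' @export
assembleConnectome <- function(runs, parcellation, clip = 0.999999,
                               subjectId = "subject", timepoint = "baseline",
                               minFrames = 30L) {
  r <- correlateRegions(runs, minFrames = minFrames)
  r <- pmin(pmax(r, -clip), clip)
  z <- fisherZ(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  Connectome(z, parcellation, subjectId, timepoint)
}

#' Read a connectome matrix from delimited text
#'
#' @param path N x N tab-delimited matrix file (no header).
#' @param parcellation matching [Parcellation-class].
#' @param subjectId,timepoint identifiers.
#' @return a [Connectome-class].
#' @export
readConnectome <- function(path, parcellation, subjectId = "subject",
                           timepoint = "baseline") {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    stop("non-finite entries in ", path, " at (",
         paste(apply(utils::head(bad, 5), 1, paste, collapse = ","),
               collapse = "), ("), ")")
  }
  asym <- abs(m - t(m)) > 1e-8
  if (any(asym)) {
    bad <- which(asym, arr.ind = TRUE)
    stop("asymmetric matrix in ", path, " at (",
         paste(apply(utils::head(bad, 5), 1, paste, collapse = ","),
               collapse = "), ("), ")")
  }
  diag(m) <- 0
  Connectome(m, parcellation, subjectId, timepoint)
}

#' Write a connectome matrix to delimited text
#'
#' Full-precision round trip: [readConnectome()] on the written file
#' reproduces the matrix exactly to printed precision (~1e-15 relative).
#'
#' @param conn a [Connectome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConnectome <- function(conn, path) {
  m <- format(zMatrix(conn), digits = 17, trim = TRUE, scientific = TRUE)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
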