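#' Denoising configuration
#'
#' Thresholds and band edges for the censoring / regression / filtering
#' chain. Framewise displacement is in mm (rotations converted at
#' `headRadiusMm`); the DVARS threshold applies to percent-signal-change
#' units; the band 0.009-0.08 Hz is the conventional intrinsic-connectivity
#' passband (Nyquist is 0.2 Hz at a 2.5 s repetition time).
#'
#' @param fdThresholdMm censor frames with framewise displacement above this.
#' @param dvarsThreshold censor frames with percent-signal-change DVARS above
#'   this.
#' @param extendFrames also censor this many neighbours on each side of a
#'   flagged frame.
#' @param bandLowHz,bandHighHz band-pass edges (Hz).
#' @param headRadiusMm radius for rotation-to-mm conversion.
#' @param minRetainedFrames floor on usable frames per subject for
#'   correlation.
#' @return list of class `DenoiseConfig`.
#' @export
denoiseConfig <- function(fdThresholdMm = 0.3, dvarsThreshold = 1.5,
                          extendFrames = 1L, bandLowHz = 0.009,
                          bandHighHz = 0.08, headRadiusMm = 50,
                          minRetainedFrames = 30L) {
  if (bandLowHz <= 0 || bandLowHz >= bandHighHz)
    stop("need 0 < bandLowHz < bandHighHz")
  structure(list(fdThresholdMm = fdThresholdMm,
                 dvarsThreshold = dvarsThreshold,
                 extendFrames = as.integer(extendFrames),
                 bandLowHz = bandLowHz, bandHighHz = bandHighHz,
                 headRadiusMm = headRadiusMm,
                 minRetainedFrames = as.integer(minRetainedFrames)),
            class = "DenoiseConfig")
}

#' Framewise displacement from realignment parameters
#'
#' Per-frame head-motion index: the sum of absolute frame-to-frame changes of
#' the three translations (mm) plus the three rotations (rad) converted to mm
#' of arc at an assumed head radius. The first frame is 0 by convention.
#'
#' @param motion T x 6 matrix: columns 1-3 translations (mm), 4-6 rotations
#'   (rad).
#' @param headRadiusMm rotation-to-mm radius (default 50).
#' @return nonnegative numeric vector of length T.
#' @examples
#' m <- matrix(0, 10, 6); m[5, 1] <- 0.1
#' framewiseDisplacement(m)
#' @export
framewiseDisplacement <- function(motion, headRadiusMm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop("motion must have 6 columns (3 translations, 3 rotations)")
  if (nrow(motion) < 2) stop("need at least 2 frames")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      headRadiusMm * rowSums(d[, 4:6, drop = FALSE]))
}

#' DVARS: RMS frame-to-frame signal change
#'
#' Element t is the root-mean-square over regions of the signal difference
#' between frames t and t-1; element 1 is 0.
#'
#' @param values T x N signal matrix (frames in rows).
#' @return nonnegative numeric vector of length T.
#' @export
dvars <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 frames")
  c(0, sqrt(rowMeans(diff(values)^2)))
}

## convert to percent signal change about the per-region temporal mean
percentSignalChange <- function(values) {
  mu <- colMeans(values)
  if (any(abs(mu) < 1e-8))
    stop("cannot compute percent signal change: region mean ~ 0")
  sweep(sweep(values, 2, mu, "-"), 2, mu, "/") * 100
}

#' Retained-frame mask from motion metrics
#'
#' Flags frames whose framewise displacement or DVARS exceeds its threshold,
#' extends the flag to `extendFrames` neighbours on each side, and returns
#' the mask of retained frames.
#'
#' @param fd framewise displacement vector.
#' @param dvars DVARS vector (same length, percent-signal-change units when
#'   used with the default threshold).
#' @param config a [denoiseConfig()].
#' @return logical vector, `TRUE` = frame retained.
#' @export
motionCensorMask <- function(fd, dvars, config = denoiseConfig()) {
  stopifnot(length(fd) == length(dvars))
  bad <- fd > config$fdThresholdMm | dvars > config$dvarsThreshold
  if (config$extendFrames > 0 && any(bad)) {
    idx <- which(bad)
    ext <- unique(as.vector(outer(idx,
                                  -config$extendFrames:config$extendFrames,
                                  "+")))
    bad[ext[ext >= 1 & ext <= length(bad)]] <- TRUE
  }
  !bad
}

#' Volterra (24-parameter) expansion of realignment parameters
#'
#' Expands the 6 realignment parameters R into the 24-column motion design
#' `[R, R^2, R lagged one frame, lagged R^2]`; the first row of each lagged
#' block is zero-padded.
#'
#' @param motion T x 6 realignment-parameter matrix.
#' @return T x 24 matrix.
#' @export
volterraExpand <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 frames")
  lag <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, lag, lag^2)
  colnames(out) <- c(paste0("R", 1:6), paste0("R", 1:6, "_sq"),
                     paste0("R", 1:6, "_lag"), paste0("R", 1:6, "_lag_sq"))
  out
}

#' Assemble a nuisance design matrix
#'
#' Stacks an intercept, task-condition regressors, the Volterra motion
#' expansion, optional extra regressors (e.g. tissue signals), and one-hot
#' spike regressors for censored frames. Columns that are constant zero are
#' dropped with a warning.
#'
#' @param nFrames run length.
#' @param motion optional T x 6 realignment parameters (expanded to 24
#'   columns).
#' @param task optional T x K task-regressor matrix.
#' @param extra optional additional T x K regressors.
#' @param retained optional logical retained-frame mask; censored frames get
#'   one spike regressor each.
#' @return numeric matrix with named columns.
#' @export
nuisanceDesign <- function(nFrames, motion = NULL, task = NULL, extra = NULL,
                           retained = NULL) {
  X <- matrix(1, nFrames, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(task)) {
    task <- as.matrix(task)
    colnames(task) <- paste0("task", seq_len(ncol(task)))
    X <- cbind(X, task)
  }
  if (!is.null(motion)) X <- cbind(X, volterraExpand(motion))
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (is.null(colnames(extra)))
      colnames(extra) <- paste0("extra", seq_len(ncol(extra)))
    X <- cbind(X, extra)
  }
  if (!is.null(retained) && any(!retained)) {
    idx <- which(!retained)
    S <- matrix(0, nFrames, length(idx),
                dimnames = list(NULL, paste0("spike", idx)))
    S[cbind(idx, seq_along(idx))] <- 1
    X <- cbind(X, S)
  }
  zero <- apply(X == 0, 2, all)
  if (any(zero)) {
    warning("dropping constant-zero design column(s): ",
            paste(colnames(X)[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  X
}

#' Regress nuisance signals out of a run
#'
#' Ordinary least squares of every region on the design, fit over retained
#' frames only; residuals are returned for all frames (so the censor mask
#' propagates unchanged) and are orthogonal to every design column over the
#' retained frames.
#'
#' @param ts a [RegionTimeSeries-class].
#' @param design T x K numeric design matrix (include an intercept if
#'   mean-removal is wanted).
#' @return a `RegionTimeSeries` of residuals.
#' @export
residualize <- function(ts, design) {
  design <- as.matrix(design)
  Y <- tsValues(ts)
  if (nrow(design) != nrow(Y))
    stop("design rows must equal the number of frames")
  keep <- censorMask(ts)
  Xr <- design[keep, , drop = FALSE]
  ## spike regressors for censored frames are all-zero on retained rows
  active <- colSums(Xr != 0) > 0
  qrX <- qr(Xr[, active, drop = FALSE])
  if (qrX$rank < sum(active)) {
    bad <- colnames(Xr[, active, drop = FALSE])[qrX$pivot[-seq_len(qrX$rank)]]
    if (is.null(bad)) bad <- qrX$pivot[-seq_len(qrX$rank)]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y[keep, , drop = FALSE])
  res <- Y
  res[keep, ] <- Y[keep, , drop = FALSE] - Xr[, active, drop = FALSE] %*% beta
  res[!keep, ] <- 0   # censored frames carry no information downstream
  RegionTimeSeries(res, trSeconds(ts), runId = ts@runId, censorMask = keep)
}

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (zero phase, no group delay). Censored frames are linearly interpolated
#' before filtering so they do not leak artifacts through the filter, and are
#' re-flagged afterwards.
#'
#' @param ts a [RegionTimeSeries-class].
#' @param config a [denoiseConfig()] supplying the band edges.
#' @return a filtered `RegionTimeSeries` (same censor mask).
#' @export
bandpassFilter <- function(ts, config = denoiseConfig()) {
  nyq <- 1 / (2 * trSeconds(ts))
  if (config$bandHighHz >= nyq)
    stop("band edge ", config$bandHighHz, " Hz is at or above Nyquist (",
         nyq, " Hz)")
  Y <- tsValues(ts)
  keep <- censorMask(ts)
  tIdx <- seq_len(nrow(Y))
  if (any(!keep)) {
    if (sum(keep) < 2) stop("too few retained frames to interpolate")
    for (j in seq_len(ncol(Y)))
      Y[!keep, j] <- stats::approx(tIdx[keep], Y[keep, j], xout = tIdx[!keep],
                                   rule = 2)$y
  }
  bf <- signal::butter(2, c(config$bandLowHz, config$bandHighHz) / nyq,
                       type = "pass")
  ## filtfilt on mean-removed series; DC is outside the band anyway
  mu <- colMeans(Y)
  out <- apply(sweep(Y, 2, mu), 2, function(col)
    signal::filtfilt(bf, col))
  RegionTimeSeries(out, trSeconds(ts), runId = ts@runId, censorMask = keep)
}

#' Full denoising chain for one run
#'
#' Order of operations: censor-mask computation (framewise displacement +
#' percent-signal-change DVARS) -> nuisance regression (task regressors,
#' Volterra motion expansion, spike regressors for censored frames) ->
#' zero-phase band-pass with interpolation over censored frames. Censored
#' frames remain flagged and are excluded from any later correlation.
#'
#' @param ts raw [RegionTimeSeries-class].
#' @param motion optional T x 6 realignment parameters.
#' @param task optional task-regressor matrix.
#' @param extra optional extra nuisance regressors.
#' @param config a [denoiseConfig()].
#' @param censor apply volume censoring (`FALSE` retains every frame, e.g.
#'   for ablation comparisons).
#' @param bandpass apply the band-pass stage.
#' @return list with `ts` (denoised run), `fd`, `dvars`, and `info` (frames
#'   censored, design rank, thresholds used).
#' @export
denoiseRun <- function(ts, motion = NULL, task = NULL, extra = NULL,
                       config = denoiseConfig(), censor = TRUE,
                       bandpass = TRUE) {
  Y <- tsValues(ts)
  fd <- if (is.null(motion)) rep(0, nrow(Y))
        else framewiseDisplacement(motion, config$headRadiusMm)
  dv <- dvars(percentSignalChange(Y))
  keep <- if (censor) motionCensorMask(fd, dv, config) & censorMask(ts)
          else censorMask(ts)
  censorMask(ts) <- keep
  X <- nuisanceDesign(nrow(Y), motion = motion, task = task, extra = extra,
                      retained = keep)
  out <- residualize(ts, X)
  if (bandpass) out <- bandpassFilter(out, config)
  list(ts = out, fd = fd, dvars = dv,
       info = list(n_frames = nrow(Y), n_censored = sum(!keep),
                   design_columns = ncol(X),
                   fd_threshold_mm = config$fdThresholdMm,
                   dvars_threshold = config$dvarsThreshold))
}
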