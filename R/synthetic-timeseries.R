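#' Nuisance structure for the time-series simulator
#'
#' Amplitudes of the non-neural components mixed into simulated region
#' signals. Signals are generated on a BOLD-like scale: unit-SD latent
#' fluctuations on a constant baseline, with task-evoked effects, a
#' motion-coupled artifact proportional to framewise displacement (large at
#' motion spikes, which is what volume censoring removes), slow polynomial
#' drift, and white noise.
#'
#' @param taskAmp SD of per-region task-regressor effects (signal units).
#' @param motionArtifactAmp artifact amplitude per mm of framewise
#'   displacement.
#' @param driftAmp peak-to-peak scale of the slow drift.
#' @param noiseSD white-noise SD.
#' @param motionStepSD per-frame SD of the translation random walk (mm).
#' @param rotationStepSD per-frame SD of the rotation random walk (rad);
#'   kept small so baseline framewise displacement sits well under typical
#'   censoring thresholds.
#' @param nSpikes number of head-motion spike frames per run.
#' @param spikeAmp translation jump at a spike frame (mm).
#' @param baseline constant signal offset (BOLD-like units).
#' @return list of class `NuisanceSimConfig`.
#' @export
nuisanceSimConfig <- function(taskAmp = 1, motionArtifactAmp = 5,
                              driftAmp = 2, noiseSD = 0.2,
                              motionStepSD = 0.005, rotationStepSD = 1e-4,
                              nSpikes = 8, spikeAmp = 1, baseline = 1000) {
  structure(list(taskAmp = taskAmp, motionArtifactAmp = motionArtifactAmp,
                 driftAmp = driftAmp, noiseSD = noiseSD,
                 motionStepSD = motionStepSD, rotationStepSD = rotationStepSD,
                 nSpikes = as.integer(nSpikes),
                 spikeAmp = spikeAmp, baseline = baseline),
            class = "NuisanceSimConfig")
}

#' Simulate region time series with known latent correlation
#'
#' Draws region signals as correlated latent Gaussian series (temporally
#' white, so the target correlation is the ground truth at every frequency)
#' plus the nuisance components of [nuisanceSimConfig()], and returns
#' everything a denoising chain needs: the raw run, the motion-parameter
#' table, the task design, and the true correlation matrix.
#'
#' @param latentCor N x N symmetric positive semi-definite correlation
#'   matrix of the latent neural signal.
#' @param nFrames frames per run (>= 50).
#' @param trSeconds repetition time (s).
#' @param nRuns number of independent runs sharing `latentCor`.
#' @param nTask number of boxcar task regressors per run.
#' @param nuisance a [nuisanceSimConfig()].
#' @param seed RNG seed.
#' @return list with `runs` (list of [RegionTimeSeries-class]), `motion`
#'   (list of T x 6 matrices), `task` (list of T x nTask matrices),
#'   `trueCor`, `trueZ` (Fisher-z edge vector of `trueCor`).
#' @export
simulateSubjectTimeSeries <- function(latentCor, nFrames = 120L,
                                      trSeconds = 2.5, nRuns = 1L,
                                      nTask = 2L,
                                      nuisance = nuisanceSimConfig(),
                                      seed = 1L) {
  stopifnot(is.matrix(latentCor), nrow(latentCor) == ncol(latentCor))
  if (max(abs(latentCor - t(latentCor))) > 1e-8)
    stop("latentCor must be symmetric")
  ev <- eigen(latentCor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("latentCor must be positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  nFrames <- as.integer(nFrames)
  if (nFrames < 50L) stop("nFrames must be >= 50")
  N <- nrow(latentCor)
  L <- chol(latentCor + diag(1e-10, N))
  withSeed(seed, {
    runs <- vector("list", nRuns)
    motion <- vector("list", nRuns)
    task <- vector("list", nRuns)
    for (r in seq_len(nRuns)) {
      latent <- matrix(stats::rnorm(nFrames * N), nFrames, N) %*% L
      ## boxcar task regressors: shifted 15-frame on/off blocks
      X <- sapply(seq_len(max(nTask, 1L)), function(k)
        as.numeric(((seq_len(nFrames) + 7L * k) %/% 15L) %% 2L == 0L))
      X <- X[, seq_len(nTask), drop = FALSE]
      beta <- matrix(stats::rnorm(nTask * N, 0, nuisance$taskAmp), nTask, N)
      ## motion: slow random walk + isolated spikes on the translations
      steps <- cbind(matrix(stats::rnorm(nFrames * 3, 0,
                                         nuisance$motionStepSD), nFrames, 3),
                     matrix(stats::rnorm(nFrames * 3, 0,
                                         nuisance$rotationStepSD), nFrames, 3))
      mp <- apply(steps, 2, cumsum)
      at <- integer(0)
      if (nuisance$nSpikes > 0) {
        at <- sample(5:(nFrames - 4L), nuisance$nSpikes)
        mp[at, 1] <- mp[at, 1] + nuisance$spikeAmp *
          sample(c(-1, 1), nuisance$nSpikes, replace = TRUE)
      }
      fd <- framewiseDisplacement(mp)
      ## motion-coupled artifact: smooth motion couples through fixed region
      ## loadings (linearly recoverable by the motion regressors), while
      ## spike frames get frame-specific loadings -- like spin-history
      ## effects, not a linear function of the realignment parameters, so
      ## only censoring can remove them
      W <- matrix(stats::rnorm(N, 1, 0.5), nFrames, N, byrow = TRUE)
      if (length(at)) {
        aff <- unique(pmin(c(at, at + 1L), nFrames))
        W[aff, ] <- stats::rnorm(length(aff) * N, 0, 1.5)
      }
      artifact <- (W * fd) * nuisance$motionArtifactAmp
      tt <- seq_len(nFrames) / nFrames
      drift <- outer(tt, stats::rnorm(N, 0, nuisance$driftAmp)) +
        outer(tt^2, stats::rnorm(N, 0, nuisance$driftAmp))
      noise <- matrix(stats::rnorm(nFrames * N, 0, nuisance$noiseSD),
                      nFrames, N)
      vals <- nuisance$baseline + latent + X %*% beta + artifact + drift +
        noise
      runs[[r]] <- RegionTimeSeries(vals, trSeconds,
                                    runId = sprintf("run%d", r))
      motion[[r]] <- mp
      task[[r]] <- X
    }
    list(runs = runs, motion = motion, task = task, trueCor = latentCor,
         trueZ = fisherZ(pmin(pmax(matrixToEdges(latentCor), -0.999999),
                              0.999999)))
  })
}
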