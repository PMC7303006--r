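test_that("framewise displacement matches hand computation", {
  m <- matrix(0, 12, 6)
  expect_equal(framewiseDisplacement(m), rep(0, 12))
  # persistent 0.1 mm x-translation step at frame 5
  m[5:12, 1] <- 0.1
  fd <- framewiseDisplacement(m)
  expect_equal(fd[5], 0.1)
  expect_equal(fd[-5], rep(0, 11))
  # 0.002 rad rotation step at 50 mm radius -> 0.1 mm
  r <- matrix(0, 12, 6); r[5:12, 4] <- 0.002
  expect_equal(framewiseDisplacement(r, headRadiusMm = 50)[5], 0.1)
  expect_error(framewiseDisplacement(matrix(0, 12, 5)), "6 columns")
})

test_that("dvars matches closed forms and is homogeneous", {
  v <- matrix(5, 10, 4)
  expect_equal(dvars(v), rep(0, 10))
  v[6:10, ] <- v[6:10, ] + 3   # uniform +3 step across regions at frame 6
  expect_equal(dvars(v)[6], 3)
  set.seed(1)
  x <- matrix(rnorm(80), 20, 4)
  expect_equal(dvars(3 * x), 3 * dvars(x))
})

test_that("censoring flags spikes, extends to neighbours, and is monotone", {
  cfg <- denoiseConfig(fdThresholdMm = 0.3, dvarsThreshold = 1.5,
                       extendFrames = 1)
  fd <- rep(0.1, 20); dv <- rep(0.5, 20)
  expect_true(all(motionCensorMask(fd, dv, cfg)))
  fd[10] <- 1
  expect_equal(which(!motionCensorMask(fd, dv, cfg)), 9:11)
  inf <- denoiseConfig(fdThresholdMm = Inf, dvarsThreshold = Inf)
  expect_true(all(motionCensorMask(fd, dv, inf)))
  # lowering the FD threshold never retains more frames
  set.seed(2)
  fdr <- runif(50, 0, 1); dvr <- runif(50, 0, 2)
  prev <- rep(TRUE, 50)
  for (thr in c(0.8, 0.5, 0.3, 0.1)) {
    cur <- motionCensorMask(fdr, dvr, denoiseConfig(fdThresholdMm = thr,
                                                    dvarsThreshold = 1.5))
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("Volterra expansion follows the 24-parameter convention", {
  m <- matrix(0, 8, 6)
  expect_equal(unname(volterraExpand(m)), matrix(0, 8, 24))
  m[3, 2] <- 1
  v <- volterraExpand(m)
  expect_equal(dim(v), c(8L, 24L))
  expect_equal(unname(v[4, 14]), 1)  # lagged block: column 12 + 2, row 3 + 1
  expect_equal(unname(v[3, 8]), 1)   # squared block
  expect_equal(unname(v[4, 20]), 1)  # lagged squared block
})

test_that("residualization is exact least squares with mask propagation", {
  set.seed(3)
  ts <- RegionTimeSeries(matrix(rnorm(200, mean = 7), 50, 4), 2.5)
  # intercept only -> mean-centering
  out <- residualize(ts, matrix(1, 50, 1))
  expect_equal(tsValues(out), scale(tsValues(ts), scale = FALSE),
               ignore_attr = TRUE)
  # input equal to a design column -> ~0 residuals
  x <- rnorm(50)
  ts2 <- RegionTimeSeries(cbind(x, 2 * x), 2.5)
  out2 <- residualize(ts2, cbind(1, x))
  expect_lt(max(abs(tsValues(out2))), 1e-12)
  # orthogonality to every design column over retained frames
  mask <- rep(TRUE, 50); mask[c(4, 20)] <- FALSE
  ts3 <- RegionTimeSeries(matrix(rnorm(200), 50, 4), 2.5, censorMask = mask)
  X <- cbind(1, rnorm(50), rnorm(50))
  res <- tsValues(residualize(ts3, X))[mask, ]
  expect_lt(max(abs(crossprod(X[mask, ], res))), 1e-8)
  # rank-deficient design errors and names the collinear column
  Xbad <- cbind(intercept = 1, a = X[, 2], b = 2 * X[, 2])
  expect_error(residualize(ts3, Xbad), "collinear")
})

test_that("planted regressor effects are removed down to the noise floor", {
  set.seed(4)
  n <- 300
  reg <- rnorm(n)
  noise <- matrix(rnorm(3 * n, 0, 1), n, 3)
  y <- noise + 2 * reg   # beta = 2 on every region
  out <- residualize(RegionTimeSeries(y, 2.5), cbind(1, reg))
  expect_lt(abs(sd(tsValues(out)) - 1), 0.1)
})

test_that("band-pass preserves the passband and kills stopband and DC", {
  tr <- 2.5; n <- 600
  t <- seq_len(n) * tr
  amp <- function(x, f) {
    sp <- Mod(fft(x))[seq_len(n / 2)]
    fr <- (seq_len(n / 2) - 1) / (n * tr)
    sp[which.min(abs(fr - f))]
  }
  for (f in c(0.02, 0.04)) {
    x <- sin(2 * pi * f * t)
    y <- tsValues(bandpassFilter(RegionTimeSeries(cbind(x, x), tr)))[, 1]
    expect_gt(amp(y, f) / amp(x, f), 0.9)
  }
  for (f in c(0.15, 0.19)) {
    x <- sin(2 * pi * f * t)
    y <- tsValues(bandpassFilter(RegionTimeSeries(cbind(x, x), tr)))[, 1]
    expect_lt(amp(y, f) / amp(x, f), 0.1)
  }
  const <- tsValues(bandpassFilter(RegionTimeSeries(matrix(3, n, 2), tr)))
  expect_lt(max(abs(const)), 1e-6)
  expect_error(bandpassFilter(RegionTimeSeries(matrix(0, n, 2), 2.5),
                              denoiseConfig(bandHighHz = 0.3)),
               "Nyquist")
})

test_that("band-pass is linear", {
  set.seed(5)
  x <- matrix(rnorm(400), 200, 2)
  y <- matrix(rnorm(400), 200, 2)
  f <- function(m) tsValues(bandpassFilter(RegionTimeSeries(m, 2.5)))
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-8)
})

test_that("denoising recovers latent correlations better than no denoising", {
  blk <- matrix(0.6, 4, 4); diag(blk) <- 1
  R <- diag(8); R[1:4, 1:4] <- blk
  sim <- simulateSubjectTimeSeries(R, nFrames = 400, trSeconds = 2.5,
                                   seed = 31)
  den <- denoiseRun(sim$runs[[1]], motion = sim$motion[[1]],
                    task = sim$task[[1]])
  p <- makeParcellation(8)
  zOn <- matrixToEdges(zMatrix(assembleConnectome(den$ts, p)))
  zRaw <- matrixToEdges(zMatrix(assembleConnectome(sim$runs[[1]], p)))
  expect_lt(mean(abs(zOn - sim$trueZ)), mean(abs(zRaw - sim$trueZ)))
  # block structure recovered near atanh(0.6)
  blockE <- sim$trueZ > 0.1
  expect_lt(mean(abs(zOn[blockE] - atanh(0.6))), 0.15)
})
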