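test_that("dF/F normalizes against the baseline window", {
  expect_equal(dff(c(2, 2, 2, 2), baselineWindow = 1:4), rep(0, 4))
  tr <- c(3, 3, 3, 6, 6, 6)
  expect_equal(dff(tr, baselineWindow = 1:3), c(0, 0, 0, 1, 1, 1))
  # hand-computed 6-sample example against an inline oracle
  x <- c(1.0, 1.2, 0.8, 2.0, 1.5, 0.5)
  fb <- mean(x[1:3])
  expect_equal(dff(x, baselineWindow = 1:3), (x - fb) / fb)
  # matrix input, rowwise
  m <- rbind(a = c(2, 2, 4), b = c(1, 1, 3))
  expect_equal(dff(m, baselineWindow = 1:2),
               rbind(a = c(0, 0, 1), b = c(0, 0, 2)))
  expect_error(dff(c(0, 0, 1), baselineWindow = 1:2), "zero baseline")
})

test_that("Welch PSD satisfies Parseval and finds planted tones", {
  set.seed(8)
  x <- matrix(rnorm(4096 * 10), 4096, 10)
  w <- welchPsd(x, fs = 2, nperseg = 256)
  totals <- colSums(w$power) * diff(w$frequency)[1]
  expect_lt(abs(mean(totals) - mean(apply(x, 2, var))) /
              mean(apply(x, 2, var)), 0.05)
  # pure tone on an exact bin
  t <- (0:719) / 2
  tone <- sin(2 * pi * t / 6)
  sp <- welchPsd(tone, 2, nperseg = 360)
  expect_equal(sp$frequency[which.max(sp$power)], 1 / 6)
  expect_true(all(w$frequency >= 0 & w$frequency <= 1))
})

test_that("pixel-wise mean PSD peaks at the stimulus frequency", {
  sim <- simulateCalciumMovie(20, 20, 20, snr = 2, frameShape = c(32, 32),
                              duration = 360, seed = 1)
  psd <- pixelwiseMeanPsd(sim$movie)
  expect_s4_class(psd, "PsdResult")
  expect_equal(peakFrequency(psd), 1 / 6, tolerance = 1e-9)
  expect_equal(psd@n, 1024L)
  expect_true(all(psd@meanPower >= 0))
  # a constant movie has an all-zero spectrum
  const <- calciumMovie(array(5, c(8, 8, 64)))
  expect_equal(max(pixelwiseMeanPsd(const)@meanPower), 0)
  expect_error(pixelwiseMeanPsd(calciumMovie(array(1, c(4, 4, 1)))),
               "2 frames")
})

test_that("stimulus correlations behave at the exact and null limits", {
  reg <- buildRegressor(stimulusLog(6, 360))
  m <- rbind(same = reg@trace, neg = -reg@trace + 2)
  r <- stimCorrelation(m, reg)
  expect_equal(as.numeric(r), c(1, -1))
  expect_warning(
    rz <- stimCorrelation(rbind(flat = rep(1, 720)), reg), "zero-variance")
  expect_true(is.na(rz[1]))
  # null distribution: independent noise stays below |r| = 0.3
  set.seed(20)
  fracHigh <- vapply(1:20, function(i) {
    noise <- matrix(rnorm(50 * 720), 50)
    mean(abs(stimCorrelation(noise, reg)) >= 0.3)
  }, numeric(1))
  expect_lt(mean(fracHigh), 0.01)
})

test_that("tuned fraction thresholds absolute correlations", {
  expect_equal(tunedFraction(c(0.5, -0.4, 0.1)), 2 / 3)
  expect_equal(tunedFraction(rep(0, 10)), 0)
  expect_equal(tunedFraction(c(0.31, NA, -0.29)), 0.5)
  expect_error(tunedFraction(numeric(0)), "no correlation")
})

test_that("the variance comparison matches a textbook Levene oracle", {
  a <- c(0.12, -0.33, 0.41, 0.05, -0.2)
  b <- c(0.55, -0.61, 0.72, -0.48, 0.1)
  res <- correlationVarianceTest(a, b)
  o <- oracleLevene(a, b)
  expect_equal(res$statistic, o$F, tolerance = 1e-6)
  expect_equal(res$p, o$p, tolerance = 1e-6)
  # identical samples: statistic 0, p 1
  same <- correlationVarianceTest(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # power: wide vs narrow distributions detected in >= 95% of seeds
  set.seed(2)
  ps <- vapply(1:20, function(i)
    correlationVarianceTest(rnorm(200, 0, 0.3), rnorm(200, 0, 0.05))$p,
    numeric(1))
  expect_gte(mean(ps < 0.01), 0.95)
})

test_that("cross-correlation matrices carry the on/off block structure", {
  sim <- simulateCalciumMovie(40, 40, 40, snr = 0.5, frameShape = c(64, 128),
                              duration = 360, seed = 1)
  reg <- buildRegressor(stimulusLog(6, 360))
  r <- stimCorrelation(sim$rois, reg)
  cc <- crossCorrMatrix(sim$rois, r)
  expect_equal(nrow(cc@mat), ceiling(0.2 * 120))
  expect_equal(diag(cc@mat), rep(1, nrow(cc@mat)))
  expect_equal(cc@mat, t(cc@mat))
  expect_true(all(diff(cc@r) <= 0))  # sorted positive to negative
  on <- cc@r > 0
  expect_gt(mean(cc@mat[on, on][upper.tri(cc@mat[on, on])]), 0.5)
  expect_gt(mean(cc@mat[!on, !on][upper.tri(cc@mat[!on, !on])]), 0.5)
  expect_lt(mean(cc@mat[on, !on]), -0.5)
  # a duplicated single trace correlates perfectly everywhere
  dup <- matrix(rep(sin(1:100), 5), 5, byrow = TRUE) +
    matrix(rnorm(500, 0, 1e-8), 5)
  ccd <- crossCorrMatrix(dup, rep(0.5, 5), topFraction = 1)
  expect_true(all(ccd@mat > 0.999))
  expect_error(crossCorrMatrix(dup[1:4, ], rep(0.5, 4)), "at least 5")
  expect_error(crossCorrMatrix(dup, rep(0.5, 5), topFraction = 0.2),
               "fewer than 2")
})

test_that("cross-fish averaging interpolates and weights by ROI count", {
  m1 <- new("CrossCorrMatrix", mat = matrix(c(1, 0.2, 0.2, 1), 2),
            r = c(0.9, 0.5), weight = 1)
  m2 <- new("CrossCorrMatrix", mat = matrix(c(1, -0.4, -0.4, 1), 2),
            r = c(0.8, -0.6), weight = 3)
  avg <- averageMatrices(list(m1, m2))
  # hand-checked 1:3 weighted mean of the off-diagonal
  expect_equal(avg@mat[1, 2], (0.2 * 1 + (-0.4) * 3) / 4)
  expect_equal(avg@weight, 4)
  # identical matrices average to themselves
  same <- averageMatrices(list(m1, m1))
  expect_equal(same@mat, m1@mat)
  # mean side length: 10 and 20 -> 15
  b1 <- new("CrossCorrMatrix", mat = diag(10), r = numeric(10), weight = 5)
  b2 <- new("CrossCorrMatrix", mat = diag(20), r = numeric(20), weight = 5)
  expect_equal(nrow(averageMatrices(list(b1, b2))@mat), 15)
  expect_error(averageMatrices(list()), "empty")
})

test_that("ACFs are periodic for stimulus-locked traces, unit at lag zero", {
  sim <- simulateCalciumMovie(20, 20, 0, snr = 3, frameShape = c(32, 32),
                              duration = 360, seed = 2)
  reg <- buildRegressor(stimulusLog(6, 360))
  a <- roiAcf(sim$rois, reg, maxLag = 30)
  expect_equal(a@meanAcf[1], 1)
  expect_true(all(abs(a@meanAcf) <= 1 + 1e-8))
  peaks <- a@lags[which(diff(sign(diff(a@meanAcf))) == -2) + 1]
  expect_true(all(c(6, 12, 18) %in% round(peaks)))
  expect_length(a@regressorAcf, length(a@lags))
  # a linear ramp decays strictly over positive lags
  ramp <- matrix(seq(0, 1, length.out = 200), 1)
  ar <- roiAcf(ramp, maxLag = 20, frameRate = 2)
  expect_true(all(diff(ar@meanAcf) < 0))
  expect_error(roiAcf(ramp, maxLag = 200, frameRate = 2), "below")
  expect_warning(roiAcf(rbind(ramp, rep(1, 200)), maxLag = 10,
                        frameRate = 2), "zero-variance")
})

test_that("per-bin repeated-measures comparison flags the stimulus bin", {
  set.seed(1)
  mkpsd <- function(peak) {
    m <- simulateCalciumMovie(nOn = if (peak) 30 else 0,
                              nOff = if (peak) 30 else 0,
                              nUntuned = if (peak) 20 else 80, snr = 2,
                              frameShape = c(40, 40), duration = 120,
                              seed = sample.int(1e6, 1))
    pixelwiseMeanPsd(m$movie, nperseg = 120)
  }
  psds <- lapply(1:4, function(f)
    list(baseline = mkpsd(TRUE), shock = mkpsd(FALSE),
         recovery = mkpsd(FALSE)))
  names(psds) <- paste0("fish", 1:4)
  res <- comparePsdAcrossRecordings(psds)
  stim <- res[abs(res$frequency - 1 / 6) < 1e-9 &
                grepl("baseline", res$contrast), ]
  expect_true(all(stim$significant))
  # null: statistically identical recordings yield no significant bins
  psds0 <- lapply(1:4, function(f)
    list(baseline = mkpsd(FALSE), shock = mkpsd(FALSE),
         recovery = mkpsd(FALSE)))
  names(psds0) <- paste0("fish", 1:4)
  expect_lt(mean(comparePsdAcrossRecordings(psds0)$significant), 0.1)
  # degenerate duplicated fish: NA p-values, no crash
  p1 <- mkpsd(TRUE)
  dup <- list(f1 = list(baseline = p1, shock = p1),
              f2 = list(baseline = p1, shock = p1))
  expect_true(all(is.na(comparePsdAcrossRecordings(dup)$p)))
  expect_error(comparePsdAcrossRecordings(psds[1]), "insufficient")
})
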