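test_that("generators are bit-reproducible under a fixed seed", {
  a <- simulateCalciumMovie(5, 5, 5, snr = 2, frameShape = c(24, 24),
                            duration = 30, seed = 42)
  b <- simulateCalciumMovie(5, 5, 5, snr = 2, frameShape = c(24, 24),
                            duration = 30, seed = 42)
  expect_identical(frames(a$movie), frames(b$movie))
  expect_identical(traces(a$rois), traces(b$rois))
  p1 <- simulatePostStunMovie(c(24, 24), 60, 30, seed = 7)
  p2 <- simulatePostStunMovie(c(24, 24), 60, 30, seed = 7)
  expect_identical(frames(p1$movie), frames(p2$movie))
  v1 <- simulateTailVideo("driven", 60, duration = 0.01, seed = 3)
  v2 <- simulateTailVideo("driven", 60, duration = 0.01, seed = 3)
  expect_identical(frames(v1$stack), frames(v2$stack))
})

test_that("ROI footprints are disjoint, non-empty and inside the frame", {
  for (seed in 1:5) {
    sim <- simulateCalciumMovie(10, 10, 10, snr = 1, frameShape = c(32, 40),
                                duration = 10, seed = seed)
    fps <- sim$truth$footprints
    expect_length(fps, 30)
    all_px <- do.call(rbind, fps)
    expect_true(all(all_px[, 1] >= 1 & all_px[, 1] <= 32 &
                      all_px[, 2] >= 1 & all_px[, 2] <= 40))
    keys <- all_px[, 1] + (all_px[, 2] - 1) * 32
    expect_false(anyDuplicated(keys) > 0)  # pairwise disjoint
  }
  expect_error(simulateCalciumMovie(100, 100, 100, 1,
                                    frameShape = c(16, 16), duration = 6),
               "capacity")
})

test_that("noise-free tuned ROIs recover their planted labels exactly", {
  sim <- simulateCalciumMovie(6, 6, 6, snr = 30, snrJitter = 0,
                              frameShape = c(32, 32), duration = 60,
                              seed = 1)
  reg <- buildRegressor(stimulusLog(6, 60))
  r <- stimCorrelation(sim$rois, reg)
  lab <- sim$truth$tuningLabels
  expect_true(all(r[lab == "on"] > 0.999))
  expect_true(all(r[lab == "off"] < -0.9))
  expect_true(all(abs(r[lab == "untuned"]) < 0.5))
})

test_that("tuned ROIs out-correlate untuned ones at moderate SNR", {
  diffs <- vapply(1:20, function(seed) {
    sim <- simulateCalciumMovie(50, 50, 50, snr = 2, frameShape = c(64, 64),
                                duration = 60, seed = seed)
    r <- stimCorrelation(sim$rois, buildRegressor(stimulusLog(6, 60)))
    lab <- sim$truth$tuningLabels
    mean(abs(r[lab != "untuned"])) - mean(abs(r[lab == "untuned"]))
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("post-stun movies decay, propagate waves and never lock to the stimulus", {
  # no waves, no drift, no noise: every pixel is a pure exponential decay
  # above the intensity floor
  ps <- simulatePostStunMovie(c(16, 16), 120, decayTau = 40, noiseSd = 0,
                              floorF = 20, initialF = 80, seed = 1)
  tr <- frames(ps$movie)[4, 9, ] - 20
  t <- (seq_along(tr) - 1) / 2
  expect_equal(tr, 80 * exp(-t / 40), tolerance = 1e-9)
  # one wave event: per-pixel peak time increases along the direction
  pw <- simulatePostStunMovie(c(16, 48), 120, decayTau = 1e6, noiseSd = 0,
                              waveEvents = list(list(onset = 10, speed = 1,
                                                     direction = "col")),
                              seed = 1)
  peak <- apply(frames(pw$movie)[8, , ], 1, which.max)
  expect_true(all(diff(peak) >= 0))
  expect_gt(tail(peak, 1), peak[1])
  expect_error(simulatePostStunMovie(c(16, 16), 60, 30,
                                     waveEvents = list(list(onset = 90,
                                                            speed = 1,
                                                            direction = "col"))),
               "onset")
})

test_that("no recovery ROI crosses the 0.3 tuning threshold", {
  reg <- buildRegressor(stimulusLog(6, 240))
  for (seed in 1:10) {
    ps <- simulatePostStunMovie(c(32, 32), 240, decayTau = 80,
                                waveEvents = list(list(onset = 60, speed = 0.5,
                                                       direction = "row")),
                                seed = seed)
    tr <- patchTraces(ps$movie)
    r <- suppressWarnings(stimCorrelation(tr, reg))
    expect_true(all(abs(r) < 0.3, na.rm = TRUE))
  }
})

test_that("drift translates frames linearly with edge padding", {
  sim <- simulateCalciumMovie(4, 4, 4, 1, frameShape = c(16, 130),
                              duration = 20, seed = 2)
  m <- sim$movie
  expect_identical(frames(applyDrift(m, 0)), frames(m))
  dr <- applyDrift(m, 100, nFrames = 40)
  expect_equal(dim(frames(dr)), dim(frames(m)))
  # frame k shifts by round(total * k / (n - 1)): the last frame by 100 px
  expect_equal(frames(dr)[, 101:130, 40], frames(m)[, 1:30, 40])
  # vacated pixels are edge-padded
  expect_true(all(frames(dr)[, 1:100, 40] ==
                    frames(m)[, rep(1, 100), 40]))
  # a constant movie is invariant under drift
  const <- calciumMovie(array(3, c(8, 120, 10)))
  expect_identical(frames(applyDrift(const, 50)), frames(const))
  expect_error(applyDrift(m, 200), "extent")
  expect_error(applyDrift(m, 10, nFrames = 100), "length")
})

test_that("tail videos encode the planted kinematics", {
  # driven mode: ground-truth angle is the pure drive sinusoid
  v <- simulateTailVideo("driven", 60, amplitude = 25, duration = 0.05,
                         seed = 1)
  t <- (0:24) / 500
  expect_equal(v$truth$angleDeg, 25 * sin(2 * pi * 60 * t), tolerance = 1e-6)
  expect_equal(v$truth$lengthMm, rep(3.9, 25), tolerance = 1e-9)
  # amplitude 0: straight larva, identical frames up to noise, zero angle
  v0 <- simulateTailVideo("driven", 60, amplitude = 0, duration = 0.01,
                          seed = 1, noiseSd = 0)
  expect_equal(v0$truth$angleDeg, rep(0, 5))
  expect_identical(v0$stack@frames[, , 1], v0$stack@frames[, , 5])
  # swim mode: truth angle is sinusoidal at the drive frequency
  vs <- simulateTailVideo("swim", 20, duration = 0.1, seed = 2)
  sp <- welchPsd(vs$truth$angleDeg, 500, nperseg = 50)
  expect_equal(sp$frequency[-1][which.max(sp$power[-1])], 20)
  expect_error(simulateTailVideo("driven", 300, duration = 0.01), "aliasing")
})

test_that("swim-mode bending travels rostrocaudally, driven bending does not", {
  # lateral displacement profiles of the rendered skeletons: in swim mode
  # the bending wave reaches caudal positions later (growing phase lag down
  # the tail, as in a displacement kymograph); in driven mode the whole
  # tail moves in phase
  skelDisp <- function(masks, n) {
    vapply(seq_len(dim(masks)[3]), function(k) {
      xy <- extractSkeleton(masks[, , k])@coords
      approx(seq(0, 1, length.out = nrow(xy)), xy[, 1] - dim(masks)[1] / 2,
             xout = seq(0, 1, length.out = n))$y
    }, numeric(n))
  }
  vs <- simulateTailVideo("swim", 20, duration = 0.1, seed = 4,
                          returnMasks = TRUE)
  lagsS <- kymographLags(skelDisp(vs$truth$masks, 100))
  expect_true(all(diff(lagsS) >= 0))
  expect_gt(tail(lagsS, 1), 0)
  vd <- simulateTailVideo("driven", 20, duration = 0.1, seed = 4,
                          returnMasks = TRUE)
  lagsD <- kymographLags(skelDisp(vd$truth$masks, 100))
  expect_true(all(lagsD == 0))
})
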