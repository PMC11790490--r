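test_that("preprocessing isolates the larva and drops speckles", {
  v <- simulateTailVideo("driven", 60, duration = 0.01, seed = 1,
                         returnMasks = TRUE)
  frame <- v$stack@frames[, , 2]
  # add twelve sub-600 px dark speckles
  set.seed(3)
  for (i in 1:12) {
    r <- sample(10:260, 1); c <- sample(10:340, 1)
    frame[r:(r + 14), c:(c + 14)] <- 0.1
  }
  mask <- preprocessFrame(frame)
  lab <- EBImage::bwlabel(mask)
  expect_equal(max(lab), 1)  # exactly the larva component survives
  truth <- v$truth$masks[, , 2]
  expect_gt(sum(mask & truth) / sum(truth), 0.9)
  # area within 5% of the noise-free ground truth silhouette
  expect_lt(abs(sum(mask) - sum(truth)) / sum(truth), 0.05)
  # blank frame: no silhouette
  expect_error(preprocessFrame(matrix(0.85, 100, 100)), "empty silhouette")
  expect_error(preprocessFrame(array(0, c(4, 4, 4))), "2-D")
})

test_that("skeletons are ordered head-first paths of the right length", {
  # a straight rectangle thins to a straight line along its long axis
  rect <- matrix(FALSE, 60, 120)
  rect[26:34, 11:110] <- TRUE
  sk <- extractSkeleton(rect)
  expect_lte(diff(range(sk@coords[, 1])), 1)
  expect_gt(diff(range(sk@coords[, 2])), 80)
  # consecutive points are 8-neighbors and unique (class validity)
  expect_s4_class(sk, "SkeletonPath")
  # synthetic curved larva: arc length within 3% of the planted midline
  v <- simulateTailVideo("driven", 60, amplitude = 25, duration = 0.01,
                         seed = 5, returnMasks = TRUE)
  for (k in c(1, 3, 5)) {
    sk <- extractSkeleton(v$truth$masks[, , k], v$truth$mmPerPx)
    expect_lt(abs(standardLength(sk, mmPerPx = 1) - 240) / 240, 0.03)
    # head-first: the first point sits in the wide head blob (left side)
    expect_lt(sk@coords[1, 2], sk@coords[nrow(sk@coords), 2])
  }
  # a disk has no elongated skeleton
  disk <- matrix(FALSE, 50, 50)
  disk[as.matrix(expand.grid(1:50, 1:50))[
    (rep(1:50, 50) - 25)^2 + (rep(1:50, each = 50) - 25)^2 <= 300, ]] <- TRUE
  expect_error(extractSkeleton(disk), "degenerate")
  expect_error(extractSkeleton(matrix(FALSE, 5, 5)), "empty")
})

test_that("total tail angle matches analytic turning angles", {
  # collinear path
  line <- cbind(10:60, rep(5L, 51))
  expect_equal(totalTailAngle(line), 0, tolerance = 1e-8)
  # right-angle L
  L <- rbind(cbind(10:40, 10L), cbind(40L, 11:40))
  expect_equal(abs(totalTailAngle(L)), 90, tolerance = 1e-6)
  # discretized quarter circles of several radii: 90 degrees within 2
  for (R in c(25, 40, 60))
    expect_equal(abs(totalTailAngle(arcMidline(R))), 90, tolerance = 2)
  # a half circle
  expect_equal(abs(totalTailAngle(arcMidline(40, pi))), 180, tolerance = 2)
  expect_error(totalTailAngle(cbind(1:2, 1:2)), "3 skeleton points")
})

test_that("standard length scales the skeleton arc length", {
  path <- cbind(rep(30L, 101), 10:110)
  colnames(path) <- c("row", "col")
  sk <- new("SkeletonPath", coords = path, mmPerPx = 0.039)
  expect_equal(standardLength(sk), 3.9)
  v <- simulateTailVideo("driven", 60, amplitude = 20, duration = 0.01,
                         seed = 2, returnMasks = TRUE)
  skc <- extractSkeleton(v$truth$masks[, , 3], v$truth$mmPerPx)
  expect_lt(abs(standardLength(skc) - 3.9) / 3.9, 0.03)
  expect_warning(res <- standardLength(sk, mmPerPx = 0), "suspicious")
  expect_equal(res, 0)
})

test_that("stack analysis recovers driven kinematics and flags bad frames", {
  v <- simulateTailVideo("driven", 60, duration = 0.1, seed = 1)
  res <- analyzeStack(v$stack)
  tr <- res$trace
  expect_s4_class(tr, "TailTrace")
  expect_gt(cor(tr@angle, v$truth$angleDeg[tr@frame]), 0.95)
  expect_equal(dominantFrequency(tr), 60)
  # a static straight larva gives a flat angle trace and near-zero kymograph
  v0 <- simulateTailVideo("driven", 5, amplitude = 0, duration = 0.01,
                          seed = 3, noiseSd = 0)
  r0 <- analyzeStack(v0$stack)
  expect_lt(max(abs(r0$trace@angle)), 2)
  expect_lt(diff(range(r0$kymograph@displacement)), 1e-6)
  # an unusable frame is excluded with a warning, not an error
  bad <- frames(v$stack)
  bad[, , 2] <- 0.85
  stackBad <- silhouetteStack(bad, 500, v$stack@mmPerPx)
  expect_warning(rb <- analyzeStack(stackBad), "excluded")
  expect_false(2L %in% rb$trace@frame)
})

test_that("swim stacks show a rostrocaudally traveling displacement wave", {
  v <- simulateTailVideo("swim", 20, duration = 0.25, seed = 2)
  res <- analyzeStack(v$stack)
  expect_equal(dominantFrequency(res$trace), 20)
  lags <- kymographLags(res$kymograph@displacement)
  # phase lag relative to a rostral row grows down the tail
  expect_true(all(diff(lags) >= 0))
  expect_gt(tail(lags, 1), 0)
  # the driven stack is bilaterally synchronous: no phase gradient
  vd <- simulateTailVideo("driven", 60, duration = 0.1, seed = 1)
  lagsD <- kymographLags(analyzeStack(vd$stack)$kymograph@displacement)
  expect_true(all(lagsD == 0))
})

test_that("angle magnitudes are invariant under 90-degree frame rotation", {
  v <- simulateTailVideo("driven", 60, amplitude = 25, duration = 0.02,
                         seed = 6)
  rot <- frames(v$stack)
  rot <- aperm(rot, c(2, 1, 3))[dim(rot)[2]:1, , , drop = FALSE]
  a1 <- analyzeStack(v$stack)$trace@angle
  a2 <- analyzeStack(silhouetteStack(rot, 500, v$stack@mmPerPx))$trace@angle
  expect_equal(abs(a1), abs(a2), tolerance = 2)
})

test_that("a 20% mid-stack length contraction is measured within 2 points", {
  prof <- rep(c(1, 0.8), each = 15)
  v <- simulateTailVideo("driven", 5, amplitude = 0, duration = 0.06,
                         seed = 7, lengthProfile = prof)
  # near-noise-free frames: the median step is unnecessary and its fixed
  # pixel window would truncate the two body lengths at different relative
  # positions
  res <- analyzeStack(v$stack, medianSize = 0)
  pre <- mean(res$trace@lengthMm[res$trace@frame <= 15])
  post <- mean(res$trace@lengthMm[res$trace@frame > 15])
  expect_equal(1 - post / pre, 0.2, tolerance = 0.02)
})

test_that("dominant frequency lands on the planted spectral bin", {
  t <- (0:499) / 500
  for (f in c(5, 20, 60)) {
    tr <- tailTrace(10 * sin(2 * pi * f * t), frameRate = 500)
    expect_equal(dominantFrequency(tr), f)
  }
  expect_error(dominantFrequency(tailTrace(rep(1, 100), 500)), "no peak")
})
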