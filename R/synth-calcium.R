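## Synthetic calcium movies with known ground truth. ROI footprints are
## square patches placed disjointly on a jittered grid; tuned ROI traces are
## the CIRF-convolved (inverted) stimulus scaled to the requested SNR; noise
## is additive Gaussian per pixel and frame with unit s.d., so
## snr = planted signal s.d. / noise s.d.

.placeFootprints <- function(nRois, frameShape, radius) {
  side <- 2L * radius + 1L
  pitch <- side + 1L
  centersR <- seq.int(radius + 1L, frameShape[1] - radius, by = pitch)
  centersC <- seq.int(radius + 1L, frameShape[2] - radius, by = pitch)
  grid <- expand.grid(r = centersR, c = centersC)
  if (nrow(grid) < nRois)
    stop("capacity error: cannot place ", nRois,
         " disjoint footprints in a ", frameShape[1], "x", frameShape[2],
         " frame")
  sel <- grid[sample.int(nrow(grid), nRois), , drop = FALSE]
  lapply(seq_len(nRois), function(i) {
    rows <- (sel$r[i] - radius):(sel$r[i] + radius)
    cols <- (sel$c[i] - radius):(sel$c[i] + radius)
    as.matrix(expand.grid(row = rows, col = cols))
  })
}

#' Generate a synthetic baseline calcium movie
#'
#' Emulates a 2 Hz optic-tectum recording under a full-field flash stimulus:
#' on-tuned ROIs follow the CIRF-convolved stimulus, off-tuned ROIs the
#' convolved inverted stimulus, untuned ROIs carry noise only. All pixels of
#' a footprint share the ROI trace; additive Gaussian noise (s.d. 1) is
#' applied per pixel and frame, with the planted signal scaled to
#' `snr` times the noise s.d.
#'
#' @param nOn,nOff,nUntuned ROI counts per tuning class (each >= 0).
#' @param snr planted signal s.d. / noise s.d. (dimensionless), the
#'   population-median response gain.
#' @param snrJitter s.d. of the per-ROI lognormal gain spread (default 0.5),
#'   emulating the natural variation of response strength across neurons.
#' @param frameShape integer c(rows, cols) of the frame (default 64 x 64).
#' @param duration recording duration in s (default 360).
#' @param stimulus a [StimulusLog] covering the recording; default: 6 s flash
#'   period over `duration`.
#' @param seed integer seed; identical seeds give bit-identical movies.
#' @param frameRate imaging rate in Hz (default 2).
#' @param roiRadius half-width of the square ROI footprints in px (default 1,
#'   i.e. 3 x 3 px).
#' @param baselineF resting fluorescence of ROI pixels (default 100).
#' @param background resting fluorescence of non-ROI pixels; defaults to
#'   `baselineF`, emulating the spatially homogeneous resting brightness of
#'   densely expressed nuclear GCaMP, where somata and neuropil are of
#'   comparable brightness and spatial drift translates almost no resting
#'   contrast.
#' @param label recording label for the movie (default `"baseline"`).
#' @return List with `movie` ([CalciumMovie]), `rois` ([RoiTraceSet], traces
#'   extracted as footprint means, tuning labels in `rowData`), and `truth`
#'   (list: `footprints`, `tuningLabels`, `plantedSnr`, `driftPath`,
#'   `waveEvents`).
#' @export
simulateCalciumMovie <- function(nOn, nOff, nUntuned, snr, snrJitter = 0.5,
                                 frameShape = c(64, 64), duration = 360,
                                 stimulus = NULL, seed = NULL,
                                 frameRate = 2, roiRadius = 1,
                                 baselineF = 100, background = baselineF,
                                 label = "baseline") {
  stopifnot(nOn >= 0, nOff >= 0, nUntuned >= 0, snr >= 0)
  if (is.null(stimulus)) stimulus <- stimulusLog(6, duration)
  nFrames <- round(duration * frameRate)
  nRois <- nOn + nOff + nUntuned
  noiseSd <- 1

  onReg <- buildRegressor(stimulus, frameRate)@trace[seq_len(nFrames)]
  offReg <- buildRegressor(stimulus, frameRate, invert = TRUE)@trace[
    seq_len(nFrames)]
  # planted modulation is zero-mean at the target s.d.: resting brightness
  # is set by expression level, activity modulates around it
  scaleTo <- function(x, s) if (sd(x) > 0) (x - mean(x)) / sd(x) * s else x * 0

  .withSeed(seed, {
    fps <- .placeFootprints(nRois, frameShape, roiRadius)
    labels <- rep(c("on", "off", "untuned"), c(nOn, nOff, nUntuned))
    gain <- snr * noiseSd * exp(rnorm(nRois, 0, snrJitter))
    gain[labels == "untuned"] <- 0
    sig <- matrix(0, nRois, nFrames)
    if (nOn > 0)
      sig[seq_len(nOn), ] <- outer(gain[seq_len(nOn)], scaleTo(onReg, 1))
    if (nOff > 0)
      sig[nOn + seq_len(nOff), ] <-
        outer(gain[nOn + seq_len(nOff)], scaleTo(offReg, 1))
    npx <- prod(frameShape)
    frameOffset <- (seq_len(nFrames) - 1L) * npx
    arr <- array(rnorm(npx * nFrames, mean = background, sd = noiseSd),
                 c(frameShape, nFrames))
    for (i in seq_len(nRois)) {
      fp <- fps[[i]]
      pix <- fp[, 1] + (fp[, 2] - 1L) * frameShape[1]
      idx <- rep(pix, nFrames) + rep(frameOffset, each = length(pix))
      arr[idx] <- arr[idx] + (baselineF - background) +
        rep(sig[i, ], each = length(pix))
    }
    arr <- pmax(arr, 0)
    movie <- calciumMovie(arr, frameRate, label)
    tr <- t(vapply(fps, function(fp) {
      pix <- fp[, 1] + (fp[, 2] - 1L) * frameShape[1]
      idx <- rep(pix, nFrames) + rep(frameOffset, each = length(pix))
      colMeans(matrix(arr[idx], nrow = length(pix)))
    }, numeric(nFrames)))
    rois <- roiTraceSet(tr, recording = label, frameRate = frameRate,
                        tuning = labels)
    list(movie = movie, rois = rois,
         truth = list(footprints = fps, tuningLabels = labels,
                      plantedSnr = snr, roiSnr = gain / noiseSd,
                      driftPath = NULL, waveEvents = NULL))
  })
}

#' Generate a synthetic post-stun (recovery) calcium movie
#'
#' Emulates the recording after electrical stunning: a global monotone
#' exponential decay of fluorescence, additive slowly traveling Gaussian
#' wavefronts, linear spatial drift, and no stimulus-locked component.
#'
#' @param frameShape integer c(rows, cols).
#' @param duration recording duration in s (default 720, the 12 min recovery).
#' @param decayTau decay constant of the global baseline in s (> 0).
#' @param waveEvents list of wave events, each a list with `onset` (s),
#'   `speed` (px/s) and `direction` (`"row"` or `"col"`); onsets must lie
#'   inside the recording.
#' @param driftTotalPx total linear drift in px over the movie (default 0).
#' @param seed integer seed.
#' @param frameRate imaging rate in Hz (default 2).
#' @param noiseSd additive Gaussian noise s.d. (default 1).
#' @param waveAmplitude peak added intensity of each wavefront (default 30).
#' @param waveWidthPx spatial s.d. of the Gaussian front in px (default 6).
#' @param initialF initial amplitude of the decaying global baseline
#'   (default 80).
#' @param floorF intensity floor the decay approaches (detector offset plus
#'   residual autofluorescence; default 20).
#' @return List with `movie` ([CalciumMovie], label `"recovery"`) and
#'   `truth` (footprints empty; `waveEvents` and `driftPath` as planted).
#' @export
simulatePostStunMovie <- function(frameShape = c(64, 64), duration = 720,
                                  decayTau = 120, waveEvents = list(),
                                  driftTotalPx = 0, seed = NULL,
                                  frameRate = 2, noiseSd = 1,
                                  waveAmplitude = 30, waveWidthPx = 6,
                                  initialF = 80, floorF = 20) {
  if (decayTau <= 0) stop("'decayTau' must be positive")
  nFrames <- round(duration * frameRate)
  t <- (seq_len(nFrames) - 1L) / frameRate
  for (w in waveEvents)
    if (w$onset < 0 || w$onset >= duration)
      stop("wave onset outside the recording")

  .withSeed(seed, {
    base <- initialF * exp(-t / decayTau)
    arr <- array(rnorm(prod(frameShape) * nFrames, floorF, noiseSd),
                 c(frameShape, nFrames))
    arr <- sweep(arr, 3L, base, "+")
    for (w in waveEvents) {
      s <- if (identical(w$direction, "row")) seq_len(frameShape[1])
           else seq_len(frameShape[2])
      for (k in which(t >= w$onset)) {
        front <- w$speed * (t[k] - w$onset)
        prof <- waveAmplitude * exp(-(s - front)^2 / (2 * waveWidthPx^2))
        if (identical(w$direction, "row")) arr[, , k] <- arr[, , k] + prof
        else arr[, , k] <- arr[, , k] + rep(prof, each = frameShape[1])
      }
    }
    movie <- calciumMovie(pmax(arr, 0), frameRate, "recovery")
    driftPath <- NULL
    if (driftTotalPx > 0) {
      movie <- applyDrift(movie, driftTotalPx, nFrames)
      driftPath <- round(driftTotalPx * (seq_len(nFrames) - 1L) /
                           (nFrames - 1L))
    }
    list(movie = movie,
         truth = list(footprints = list(), tuningLabels = character(),
                      plantedSnr = NA_real_, driftPath = driftPath,
                      waveEvents = waveEvents))
  })
}

#' Apply a simulated linear spatial drift to a movie
#'
#' Translates frame `k` (0-based) by `round(totalPx * k / (nFrames - 1))`
#' pixels along one axis, filling vacated pixels by edge padding; the frame
#' shape is unchanged. Emulates the published robustness check of a 100 px
#' drift over 720 frames (6 min).
#'
#' @param movie a [CalciumMovie].
#' @param totalPx total drift in px (>= 0; must be smaller than the frame
#'   extent along the drift axis).
#' @param nFrames number of frames over which the drift accumulates
#'   (default: all frames; must not exceed the movie length).
#' @param axis `"col"` (default) or `"row"`.
#' @return A [CalciumMovie] with drifted frames.
#' @export
applyDrift <- function(movie, totalPx, nFrames = NULL, axis = c("col", "row")) {
  stopifnot(is(movie, "CalciumMovie"))
  axis <- match.arg(axis)
  d <- dim(movie@frames)
  if (is.null(nFrames)) nFrames <- d[3]
  if (nFrames > d[3]) stop("'nFrames' exceeds the movie length")
  if (totalPx < 0) stop("'totalPx' must be >= 0")
  extent <- if (axis == "col") d[2] else d[1]
  if (totalPx >= extent) stop("'totalPx' exceeds the frame extent")
  if (totalPx == 0 || nFrames < 2) return(movie)
  arr <- movie@frames
  for (k in seq_len(nFrames)) {
    s <- round(totalPx * (k - 1) / (nFrames - 1))
    if (s == 0) next
    if (axis == "col") {
      src <- pmax(1L, seq_len(d[2]) - s)   # edge padding on the leading side
      arr[, , k] <- arr[, src, k]
    } else {
      src <- pmax(1L, seq_len(d[1]) - s)
      arr[, , k] <- arr[src, , k]
    }
  }
  calciumMovie(arr, movie@frameRate, movie@label)
}
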