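## Synthetic high-speed silhouette videos of an embedded larva with its tail
## cut free. The larva is rendered as a filled 2-D shape: disks of a tapering
## half-width profile stamped along a parametric midline (head blob wide,
## tail tapering to a point). Only silhouette topology matters downstream,
## so no photorealism is attempted.
##
## Driven mode bends the whole midline with one spatially uniform sinusoidal
## curvature (the passive response to an AC field); swim mode carries a
## curvature wave traveling head-to-tail each cycle (a spontaneous bout).

.diskOffsets <- function(maxR) {
  lapply(0:maxR, function(r) {
    g <- expand.grid(dr = -r:r, dc = -r:r)
    g[g$dr^2 + g$dc^2 <= r^2 + 0.25, , drop = FALSE]
  })
}

## half-width profile in px at relative arc positions u = s/L of a midline of
## current length L. The head/yolk blob is a half-ellipse rising from the
## snout (u = 0) so the anatomical midline starts at the snout tip; the tail
## tapers linearly to a point. Widths scale with the RESTING length L0, not
## the instantaneous L: muscle contraction shortens the body without
## thinning it.
.widthProfile <- function(s, L, L0 = L) {
  headLen <- L0 / 6  # head/yolk length is rigid: contraction is muscular
  w <- numeric(length(s))
  head <- s <= headLen
  # pointed snout (linear rise): the medial axis then spans the full
  # midline instead of retracting inside a blunt cap
  w[head] <- 0.09 * L0 * s[head] / headLen
  ut <- (s[!head] - headLen) / max(L - headLen, 1)
  w[!head] <- 0.085 * L0 * (1 - ut) + 0.015 * L0 * ut
  w
}

.renderMask <- function(midline, halfw, frameShape, offs) {
  mask <- matrix(FALSE, frameShape[1], frameShape[2])
  ri <- pmin(round(halfw), length(offs) - 1L)
  for (r in unique(ri)) {
    o <- offs[[r + 1L]]
    pts <- midline[ri == r, , drop = FALSE]
    rows <- rep(round(pts[, 1]), each = nrow(o)) + o$dr
    cols <- rep(round(pts[, 2]), each = nrow(o)) + o$dc
    ok <- rows >= 1 & rows <= frameShape[1] & cols >= 1 & cols <= frameShape[2]
    mask[cbind(rows[ok], cols[ok])] <- TRUE
  }
  mask
}

#' Render a synthetic larva silhouette video
#'
#' Generates a grayscale stack (dark larva on a bright background, Gaussian
#' pixel noise) together with its kinematic ground truth. In `"driven"` mode
#' the midline bends with a single spatially uniform sinusoid at `frequency`
#' (total tail angle `amplitude * sin(2 pi f t)`); in `"swim"` mode a
#' curvature wave of half a wavelength advances rostrocaudally along the
#' tail each cycle, as in a spontaneous swim bout.
#'
#' @param mode `"driven"` or `"swim"`.
#' @param frequency tail-beat frequency in Hz (must be below `frameRate/2`).
#' @param amplitude peak total tail angle in degrees (default 30; 0 renders
#'   a straight larva in every frame).
#' @param frameRate video rate in Hz (default 500).
#' @param duration video duration in s.
#' @param mmPerPx spatial scale (default 0.01625, giving a 3.9 mm standard
#'   length for the default 240 px midline).
#' @param seed integer seed for pixel noise.
#' @param frameShape integer c(rows, cols) (default 280 x 360).
#' @param bodyLengthPx midline length from head-blob center to tail tip, px.
#' @param noiseSd grayscale noise s.d. (default 0.02).
#' @param lengthProfile optional per-frame multiplier on the midline length
#'   (default 1 for all frames), e.g. to emulate the standard-length
#'   contraction during exposure.
#' @param returnMasks logical; also return the noise-free binary masks in
#'   the ground truth (memory-heavy, for validation).
#' @return List with `stack` ([SilhouetteStack]) and `truth`, a list with
#'   `mode`, `driveFrequency`, `angleDeg` (per-frame true total tail angle),
#'   `lengthMm` (per-frame true midline length), `mmPerPx` and optionally
#'   `masks`.
#' @export
simulateTailVideo <- function(mode = c("driven", "swim"), frequency,
                              amplitude = 30, frameRate = 500, duration = 1,
                              mmPerPx = 0.01625, seed = NULL,
                              frameShape = c(280, 360), bodyLengthPx = 240,
                              noiseSd = 0.02, lengthProfile = NULL,
                              returnMasks = FALSE) {
  mode <- match.arg(mode)
  if (frequency >= frameRate / 2)
    stop("aliasing: 'frequency' must be below frameRate/2")
  if (frequency <= 0) stop("'frequency' must be positive")
  nFrames <- round(duration * frameRate)
  if (is.null(lengthProfile)) lengthProfile <- rep(1, nFrames)
  stopifnot(length(lengthProfile) == nFrames)
  t <- (seq_len(nFrames) - 1L) / frameRate
  ds <- 0.5
  offs <- .diskOffsets(ceiling(0.09 * bodyLengthPx * max(lengthProfile)))
  anchor <- c(frameShape[1] / 2, 0.2 * frameShape[2])  # head center (row, col)
  ampRad <- amplitude * pi / 180

  arr <- array(0, c(frameShape, nFrames))
  masks <- if (returnMasks) array(FALSE, c(frameShape, nFrames)) else NULL
  angleDeg <- lengthMm <- numeric(nFrames)

  # the RNG scope covers the whole render loop; noise is drawn frame by
  # frame to avoid holding a second stack-sized array
  .withSeed(seed, for (k in seq_len(nFrames)) {
    L <- bodyLengthPx * lengthProfile[k]
    s <- seq(0, L, by = ds)
    kappa <- switch(mode,
      driven = rep(ampRad * sin(2 * pi * frequency * t[k]) / L, length(s)),
      swim = (ampRad * pi / (2 * L)) *
        sin(2 * pi * frequency * t[k] - pi * s / L))
    # integrate heading and position along the midline (base heading +col)
    phi <- cumsum(c(0, kappa[-1] * ds))
    row <- anchor[1] + cumsum(c(0, sin(phi[-1]) * ds))
    col <- anchor[2] + cumsum(c(0, cos(phi[-1]) * ds))
    mask <- .renderMask(cbind(row, col), .widthProfile(s, L, bodyLengthPx),
                        frameShape, offs)
    noise <- if (noiseSd > 0)
      matrix(rnorm(prod(frameShape), 0, noiseSd), frameShape[1]) else 0
    arr[, , k] <- pmin(pmax(0.85 - 0.73 * mask + noise, 0), 1)
    if (returnMasks) masks[, , k] <- mask
    angleDeg[k] <- (phi[length(phi)] - phi[1]) * 180 / pi
    lengthMm[k] <- L * mmPerPx
  })

  truth <- list(mode = mode, driveFrequency = frequency,
                angleDeg = angleDeg, lengthMm = lengthMm, mmPerPx = mmPerPx)
  if (returnMasks) truth$masks <- masks
  list(stack = silhouetteStack(arr, frameRate, mmPerPx), truth = truth)
}
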