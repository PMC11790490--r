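## Fig.-4-style analysis stack: dF/F, pixel-wise mean Welch PSD, stimulus
## regressor tuning, correlation-variance comparison, top-20%
## cross-correlation matrices with cross-fish averaging, and ACFs.

#' Fluorescence change relative to baseline (dF/F)
#'
#' `(F(t) - F_b) / F_b` with `F_b` the mean fluorescence over the baseline
#' window.
#'
#' @param trace numeric fluorescence trace, or a matrix with one ROI per row.
#' @param baselineWindow index range of the baseline window (default: the
#'   first 60 s at 2 Hz, i.e. samples 1-120, truncated to the trace length).
#' @return dF/F series of the same shape as `trace`.
#' @export
dff <- function(trace, baselineWindow = NULL) {
  m <- if (is.null(dim(trace))) matrix(trace, nrow = 1) else as.matrix(trace)
  if (is.null(baselineWindow))
    baselineWindow <- seq_len(min(120L, ncol(m)))
  if (!length(baselineWindow)) stop("empty baseline window")
  Fb <- rowMeans(m[, baselineWindow, drop = FALSE])
  if (any(Fb == 0)) stop("zero baseline fluorescence")
  out <- sweep(sweep(m, 1, Fb), 1, Fb, "/")
  if (is.null(dim(trace))) drop(out) else out
}

#' Pixel-wise mean Welch power spectral density of a movie
#'
#' Computes, for every pixel of the raw movie (no registration or
#' segmentation), the Welch PSD of its mean-detrended intensity trace, and
#' returns the per-bin mean and standard deviation across pixels. The
#' default segment length of 360 samples (180 s at 2 Hz) places the 1/6 Hz
#' stimulus main frequency exactly on a bin.
#'
#' @param movie a [CalciumMovie] with at least 2 frames.
#' @param nperseg Welch segment length in samples (default
#'   `min(nFrames, 360)`).
#' @return A [PsdResult].
#' @export
pixelwiseMeanPsd <- function(movie, nperseg = NULL) {
  stopifnot(is(movie, "CalciumMovie"))
  d <- dim(movie@frames)
  if (d[3] < 2) stop("movie must have at least 2 frames")
  if (is.null(nperseg)) nperseg <- min(d[3], 360L)
  x <- t(matrix(movie@frames, d[1] * d[2], d[3]))  # time x pixels
  w <- welchPsd(x, movie@frameRate, nperseg = nperseg, demean = TRUE)
  new("PsdResult", frequency = w$frequency,
      meanPower = rowMeans(w$power),
      sdPower = apply(w$power, 1, sd),
      n = as.integer(d[1] * d[2]))
}

#' Frequency of the maximum non-DC PSD bin
#'
#' @param psd a [PsdResult].
#' @return Frequency in Hz of the largest mean-power bin excluding DC.
#' @export
peakFrequency <- function(psd) {
  stopifnot(is(psd, "PsdResult"))
  psd@frequency[-1][which.max(psd@meanPower[-1])]
}

#' Correlation of ROI traces with a stimulus regressor
#'
#' Pearson correlation of each ROI trace with the regressor's predicted
#' calcium trace. Zero-variance traces yield NA with a warning.
#'
#' @param rois a [RoiTraceSet], or a matrix with one ROI trace per row.
#' @param reg a [Regressor] (trace length must match).
#' @return Named numeric vector of per-ROI Pearson r in `[-1, 1]`.
#' @export
stimCorrelation <- function(rois, reg) {
  stopifnot(is(reg, "Regressor"))
  m <- if (is(rois, "RoiTraceSet")) traces(rois) else as.matrix(rois)
  if (ncol(m) != length(reg@trace))
    stop("trace length does not match the regressor")
  sds <- apply(m, 1, sd)
  if (any(sds == 0))
    warning("undefined correlation for ", sum(sds == 0),
            " zero-variance trace(s)")
  r <- rep(NA_real_, nrow(m))
  if (sd(reg@trace) > 0)
    r[sds > 0] <- as.numeric(cor(t(m[sds > 0, , drop = FALSE]), reg@trace))
  names(r) <- rownames(m)
  r
}

#' Fraction of stimulus-tuned ROIs
#'
#' Fraction of ROIs whose absolute stimulus correlation exceeds the
#' threshold (0.3 in the published analysis; 3.5% of tectal neurons passed
#' it at baseline, none after stunning).
#'
#' @param rs per-ROI correlation coefficients (NAs are dropped).
#' @param threshold absolute-correlation threshold (default 0.3).
#' @return Fraction in `[0, 1]`.
#' @export
tunedFraction <- function(rs, threshold = 0.3) {
  rs <- rs[!is.na(rs)]
  if (!length(rs)) stop("no correlation coefficients supplied")
  mean(abs(rs) > threshold)
}

#' Compare the variance of two correlation distributions
#'
#' Classical Levene test (absolute deviations from the group means) for a
#' difference in variance between two samples of correlation coefficients,
#' e.g. baseline vs recovery. Delegates to [car::leveneTest()] with
#' `center = mean`.
#'
#' @param rsA,rsB numeric samples (each at least 2 values).
#' @return List with `statistic` (the Levene F), `p` (two-sided), and `df`.
#' @export
correlationVarianceTest <- function(rsA, rsB) {
  rsA <- rsA[!is.na(rsA)]; rsB <- rsB[!is.na(rsB)]
  if (length(rsA) < 2 || length(rsB) < 2)
    stop("both samples need at least 2 values")
  if (sd(rsA) == 0 && sd(rsB) == 0 && identical(sort(rsA), sort(rsB)))
    warning("degenerate comparison: both samples constant and equal")
  y <- c(rsA, rsB)
  g <- factor(rep(c("A", "B"), c(length(rsA), length(rsB))))
  lt <- car::leveneTest(y, g, center = mean)
  list(statistic = lt[1, "F value"], p = lt[1, "Pr(>F)"],
       df = c(lt[1, "Df"], lt[2, "Df"]))
}

#' Cross-correlation matrix of the best stimulus-correlated ROIs
#'
#' Selects the `ceiling(topFraction * N)` ROIs with the largest absolute
#' stimulus correlation, orders them by signed correlation (positive to
#' negative) and fills the matrix with pairwise Pearson correlations of
#' their traces. At baseline this exposes two anti-correlated populations
#' (on- and off-responding neurons).
#'
#' @param rois a [RoiTraceSet] (at least 5 ROIs).
#' @param rs per-ROI stimulus correlations, aligned with `rois` rows.
#' @param topFraction fraction of ROIs to keep (default 0.2).
#' @return A [CrossCorrMatrix] with weight = total ROI count of the fish.
#' @export
crossCorrMatrix <- function(rois, rs, topFraction = 0.2) {
  m <- if (is(rois, "RoiTraceSet")) traces(rois) else as.matrix(rois)
  if (nrow(m) < 5) stop("need at least 5 ROIs")
  stopifnot(length(rs) == nrow(m))
  k <- ceiling(topFraction * nrow(m))
  if (k < 2) stop("fewer than 2 ROIs selected")
  sel <- order(abs(rs), decreasing = TRUE)[seq_len(k)]
  sel <- sel[order(rs[sel], decreasing = TRUE)]
  cc <- cor(t(m[sel, , drop = FALSE]))
  new("CrossCorrMatrix", mat = unname(cc), r = unname(rs[sel]),
      weight = nrow(m))
}

## bilinear (separable linear) resampling of a square matrix to side n
.resampleMatrix <- function(m, n) {
  if (nrow(m) == n && ncol(m) == n) return(m)
  if (nrow(m) == 1) return(matrix(m[1, 1], n, n))
  src <- seq(0, 1, length.out = nrow(m))
  dst <- seq(0, 1, length.out = n)
  rowsOut <- apply(m, 2, function(col) approx(src, col, xout = dst)$y)
  t(apply(rowsOut, 1, function(row) approx(src, row, xout = dst)$y))
}

#' Weighted cross-fish average of cross-correlation matrices
#'
#' Resamples each matrix by linear interpolation to the rounded mean side
#' length and averages entries with weights proportional to each fish's
#' total ROI count.
#'
#' @param mats list of [CrossCorrMatrix] objects (at least 1).
#' @return A [CrossCorrMatrix] (the `r` slot is empty after averaging;
#'   weight = summed ROI counts).
#' @export
averageMatrices <- function(mats) {
  if (!length(mats)) stop("empty matrix list")
  stopifnot(all(vapply(mats, is, logical(1), "CrossCorrMatrix")))
  sides <- vapply(mats, function(m) nrow(m@mat), integer(1))
  target <- as.integer(round(mean(sides)))
  wts <- vapply(mats, function(m) m@weight, numeric(1))
  acc <- matrix(0, target, target)
  for (i in seq_along(mats))
    acc <- acc + wts[i] * .resampleMatrix(mats[[i]]@mat, target)
  avg <- acc / sum(wts)
  avg <- (avg + t(avg)) / 2
  avg[] <- pmin(1, pmax(-1, avg))
  diag(avg) <- 1
  new("CrossCorrMatrix", mat = avg, r = numeric(0), weight = sum(wts))
}

#' Mean autocorrelation function across ROIs
#'
#' Normalized (mean-removed, lag-0 = 1) autocorrelation per ROI, averaged
#' across ROIs with its standard deviation; the regressor's ACF, computed
#' identically, is attached as reference. Periodic stimulus-following
#' activity shows ACF peaks at multiples of the flash period; post-stun
#' activity decays monotonically.
#'
#' @param rois a [RoiTraceSet] or a matrix with one ROI trace per row.
#' @param reg optional [Regressor] for the reference ACF.
#' @param maxLag maximum lag in s (must be below the trace duration).
#' @param frameRate sampling rate in Hz, for matrix input (default 2).
#' @return An [AcfResult].
#' @export
roiAcf <- function(rois, reg = NULL, maxLag = 30, frameRate = 2) {
  m <- if (is(rois, "RoiTraceSet")) {
    frameRate <- frameRate(rois)
    traces(rois)
  } else as.matrix(rois)
  nlag <- round(maxLag * frameRate)
  if (nlag >= ncol(m)) stop("'maxLag' must be below the trace duration")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " zero-variance trace(s)")
    m <- m[sds > 0, , drop = FALSE]
  }
  if (!nrow(m)) stop("no admissible traces")
  a <- apply(m, 1, function(x)
    as.numeric(acf(x, lag.max = nlag, plot = FALSE, demean = TRUE)$acf))
  regAcf <- numeric(0)
  if (!is.null(reg)) {
    stopifnot(is(reg, "Regressor"))
    regAcf <- as.numeric(acf(reg@trace, lag.max = nlag, plot = FALSE,
                             demean = TRUE)$acf)
  }
  new("AcfResult", lags = (0:nlag) / frameRate,
      meanAcf = rowMeans(a), sdAcf = apply(a, 1, sd),
      regressorAcf = regAcf)
}

#' Per-bin repeated-measures comparison of PSDs across recordings
#'
#' For each frequency bin, compares the per-fish mean power across the
#' recordings (baseline, shock, recovery) with a repeated-measures ANOVA
#' (fish as the blocking factor) followed by Tukey-adjusted pairwise
#' contrasts via \pkg{emmeans}. Bins with degenerate variance yield NA
#' p-values rather than errors.
#'
#' @param psds named list (one element per fish), each a named list of
#'   [PsdResult] objects keyed by recording label. At least 2 fish; all
#'   PSDs must share one frequency grid.
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05).
#' @return data.frame with columns `frequency`, `contrast`, `estimate`,
#'   `p`, `significant`.
#' @export
comparePsdAcrossRecordings <- function(psds, alpha = 0.05) {
  if (length(psds) < 2)
    stop("insufficient replicates: need at least 2 fish")
  grids <- lapply(psds, function(f) lapply(f, function(p) p@frequency))
  freq <- grids[[1]][[1]]
  for (f in grids) for (g in f)
    if (length(g) != length(freq) || max(abs(g - freq)) > 1e-9)
      stop("PSDs must share one frequency grid")
  recs <- names(psds[[1]])
  long <- do.call(rbind, lapply(names(psds), function(fish)
    do.call(rbind, lapply(recs, function(rec)
      data.frame(fish = fish, recording = rec, bin = seq_along(freq),
                 power = psds[[fish]][[rec]]@meanPower)))))
  # sum-to-zero contrasts up front so emmeans does not re-fit the model
  # (its re-fit re-evaluates the aov call outside this scope)
  oldOpts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(oldOpts), add = TRUE)
  out <- lapply(seq_along(freq), function(b) {
    d <- long[long$bin == b, ]
    d$fish <- factor(d$fish); d$recording <- factor(d$recording)
    res <- tryCatch({
      fit <- aov(power ~ recording + Error(fish), data = d)
      em <- suppressMessages(emmeans::emmeans(fit, ~recording, data = d))
      as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
    }, error = function(e) NULL)
    if (is.null(res))
      return(data.frame(frequency = freq[b], contrast = NA_character_,
                        estimate = NA_real_, p = NA_real_))
    p <- res$p.value
    # zero residual variance (e.g. duplicated fish) gives meaningless
    # t-ratios: report NA rather than p = 0
    p[!is.finite(p) | res$SE < 1e-10] <- NA_real_
    data.frame(frequency = freq[b], contrast = as.character(res$contrast),
               estimate = res$estimate, p = p)
  })
  out <- do.call(rbind, out)
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}
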