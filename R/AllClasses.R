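#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## StimulusLog
## ---------------------------------------------------------------------------

#' On/off visual stimulus log
#'
#' Time-stamped binary record of a full-field flash stimulus, as logged by the
#' stimulation hardware (default sampling 100 Hz). Create with [stimulusLog()].
#'
#' @slot time numeric, sample times in seconds (strictly increasing).
#' @slot state integer, 0 (off) or 1 (on) per sample.
#' @slot sampleRate numeric, sampling rate in Hz.
#' @seealso [stimulusLog()], [buildRegressor()]
#' @exportClass StimulusLog
setClass("StimulusLog",
  slots = c(time = "numeric", state = "integer", sampleRate = "numeric"))

setValidity("StimulusLog", function(object) {
  msg <- character()
  if (length(object@time) != length(object@state))
    msg <- c(msg, "'time' and 'state' must have equal length")
  if (length(object@time) > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "'time' must be strictly increasing")
  if (!all(object@state %in% c(0L, 1L)))
    msg <- c(msg, "'state' must be binary (0/1)")
  if (length(object@sampleRate) != 1 || object@sampleRate <= 0)
    msg <- c(msg, "'sampleRate' must be a positive scalar")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StimulusLog", function(object) {
  cat("StimulusLog:", length(object@time), "samples at",
      object@sampleRate, "Hz;",
      round(sum(object@state) / max(1L, length(object@state)) * 100, 1),
      "% on\n")
})

## ---------------------------------------------------------------------------
## FieldExposureConfig
## ---------------------------------------------------------------------------

#' Electric field exposure configuration
#'
#' Waveform, field strength and chamber geometry of one stunning exposure;
#' the source of all dosimetry. Units follow field conventions: V/cm, S/cm,
#' cm, cm^2, cm^3. Create with [fieldExposureConfig()].
#'
#' @slot waveform character, one of `"DC"`, `"AC_sine"`, `"PDC"`.
#' @slot E numeric, applied voltage gradient (peak), V/cm.
#' @slot frequency numeric, waveform frequency in Hz (0 for DC).
#' @slot dutyCycle numeric in (0, 1], PDC duty cycle (1 otherwise).
#' @slot duration numeric, exposure duration in s.
#' @slot sigma numeric, medium conductivity in S/cm.
#' @slot electrodeDistance numeric, electrode gap d in cm; the applied
#'   voltage is `U = E * d`.
#' @slot wettedArea numeric, wetted electrode area A in cm^2.
#' @slot mediumVolume numeric, medium volume V in cm^3.
#' @seealso [effectiveField()], [powerDensity()], [simulateJouleHeating()]
#' @exportClass FieldExposureConfig
setClass("FieldExposureConfig",
  slots = c(waveform = "character", E = "numeric", frequency = "numeric",
            dutyCycle = "numeric", duration = "numeric", sigma = "numeric",
            electrodeDistance = "numeric", wettedArea = "numeric",
            mediumVolume = "numeric"))

setValidity("FieldExposureConfig", function(object) {
  msg <- character()
  if (!object@waveform %in% c("DC", "AC_sine", "PDC"))
    msg <- c(msg, "'waveform' must be one of 'DC', 'AC_sine', 'PDC'")
  if (object@E < 0) msg <- c(msg, "'E' must be >= 0")
  if (object@frequency < 0) msg <- c(msg, "'frequency' must be >= 0")
  if (object@dutyCycle <= 0 || object@dutyCycle > 1)
    msg <- c(msg, "'dutyCycle' must be in (0, 1]")
  if (object@duration <= 0) msg <- c(msg, "'duration' must be > 0")
  if (object@sigma <= 0) msg <- c(msg, "'sigma' must be > 0")
  if (object@electrodeDistance <= 0)
    msg <- c(msg, "'electrodeDistance' must be > 0")
  if (object@wettedArea <= 0) msg <- c(msg, "'wettedArea' must be > 0")
  if (object@mediumVolume <= 0) msg <- c(msg, "'mediumVolume' must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FieldExposureConfig", function(object) {
  cat(sprintf(
    "FieldExposureConfig: %s, %g V/cm%s, %g s\n  sigma = %g S/cm, d = %g cm (U = %g V), A = %g cm^2, V = %g cm^3\n",
    object@waveform, object@E,
    if (object@waveform == "DC") "" else paste0(" at ", object@frequency, " Hz"),
    object@duration, object@sigma, object@electrodeDistance,
    object@E * object@electrodeDistance, object@wettedArea,
    object@mediumVolume))
})

## ---------------------------------------------------------------------------
## DosimetryTrace
## ---------------------------------------------------------------------------

#' Time-resolved dosimetry of one exposure
#'
#' Current, power density, current density and medium temperature on a shared
#' time base. Produced by [densityFromCurrent()], [simulateJouleHeating()] and
#' [simulateCurrentTrace()].
#'
#' @slot time numeric, s.
#' @slot current numeric, A.
#' @slot powerDensity numeric, W/cm^3 (`U * I / V`).
#' @slot currentDensity numeric, A/cm^2 (`I / A`).
#' @slot temperature numeric, degrees C (NA when not modeled).
#' @exportClass DosimetryTrace
setClass("DosimetryTrace",
  slots = c(time = "numeric", current = "numeric", powerDensity = "numeric",
            currentDensity = "numeric", temperature = "numeric"))

setValidity("DosimetryTrace", function(object) {
  n <- length(object@time)
  msg <- character()
  if (any(lengths(list(object@current, object@powerDensity,
                       object@currentDensity, object@temperature)) != n))
    msg <- c(msg, "all series must share one time base")
  if (any(object@powerDensity < 0, na.rm = TRUE))
    msg <- c(msg, "power density must be non-negative")
  if (any(object@current < 0, na.rm = TRUE))
    msg <- c(msg, "current must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DosimetryTrace", function(object) {
  cat("DosimetryTrace:", length(object@time), "samples over",
      signif(diff(range(object@time)), 4), "s; power density",
      signif(object@powerDensity[1], 3), "->",
      signif(object@powerDensity[length(object@powerDensity)], 3), "W/cm^3\n")
})

#' Convert a DosimetryTrace to a data.frame
#'
#' @param x a [DosimetryTrace].
#' @param ... unused.
#' @return A data.frame with columns `time_s`, `current_A`, `power_Wcm3`,
#'   `currentdensity_Acm2`, `temp_C`.
#' @export
as.data.frame.DosimetryTrace <- function(x, ...) {
  data.frame(time_s = x@time, current_A = x@current,
             power_Wcm3 = x@powerDensity,
             currentdensity_Acm2 = x@currentDensity,
             temp_C = x@temperature)
}

## ---------------------------------------------------------------------------
## CalciumMovie / SilhouetteStack
## ---------------------------------------------------------------------------

#' Calcium imaging movie
#'
#' Pixel intensity time series on a 2-D grid, acquired at 2 Hz in the study
#' design (baseline 6 min, shock 6 min, recovery 12 min).
#'
#' @slot frames 3-D numeric array (row, column, frame), non-negative.
#' @slot frameRate numeric, Hz.
#' @slot label character, one of `"baseline"`, `"shock"`, `"recovery"`.
#' @seealso [simulateCalciumMovie()], [pixelwiseMeanPsd()], [applyDrift()]
#' @exportClass CalciumMovie
setClass("CalciumMovie",
  slots = c(frames = "array", frameRate = "numeric", label = "character"))

setValidity("CalciumMovie", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3)
    msg <- c(msg, "'frames' must be a 3-D array (row, col, frame)")
  if (any(object@frames < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@frameRate) != 1 || object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a positive scalar")
  if (!object@label %in% c("baseline", "shock", "recovery"))
    msg <- c(msg, "'label' must be 'baseline', 'shock' or 'recovery'")
  if (length(msg)) msg else TRUE
})

#' Construct a CalciumMovie
#'
#' @param frames 3-D numeric array (row, column, frame).
#' @param frameRate acquisition rate in Hz (default 2).
#' @param label recording label (default `"baseline"`).
#' @return A [CalciumMovie].
#' @export
calciumMovie <- function(frames, frameRate = 2, label = "baseline") {
  new("CalciumMovie", frames = frames, frameRate = frameRate, label = label)
}

#' High-speed silhouette video
#'
#' Grayscale frames of a backlit larva (dark silhouette on bright background),
#' sampled at 500 Hz in the study design.
#'
#' @slot frames 3-D numeric array (row, column, frame) in `[0, 1]`.
#' @slot frameRate numeric, Hz.
#' @slot mmPerPx numeric, spatial scale.
#' @seealso [simulateTailVideo()], [analyzeStack()]
#' @exportClass SilhouetteStack
setClass("SilhouetteStack",
  slots = c(frames = "array", frameRate = "numeric", mmPerPx = "numeric"))

setValidity("SilhouetteStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3)
    msg <- c(msg, "'frames' must be a 3-D array (row, col, frame)")
  if (length(object@frameRate) != 1 || object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a positive scalar")
  if (length(object@mmPerPx) != 1 || object@mmPerPx < 0)
    msg <- c(msg, "'mmPerPx' must be a non-negative scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a SilhouetteStack
#'
#' @param frames 3-D numeric array (row, column, frame).
#' @param frameRate acquisition rate in Hz (default 500).
#' @param mmPerPx spatial scale in mm per pixel.
#' @return A [SilhouetteStack].
#' @export
silhouetteStack <- function(frames, frameRate = 500, mmPerPx = NA_real_) {
  new("SilhouetteStack", frames = frames, frameRate = frameRate,
      mmPerPx = mmPerPx)
}

#' @rdname frames
setMethod("frames", "CalciumMovie", function(x) x@frames)
#' @rdname frames
setMethod("frames", "SilhouetteStack", function(x) x@frames)
#' @rdname frames
setMethod("frameRate", "CalciumMovie", function(x) x@frameRate)
#' @rdname frames
setMethod("frameRate", "SilhouetteStack", function(x) x@frameRate)
#' @rdname frames
setMethod("mmPerPx", "SilhouetteStack", function(x) x@mmPerPx)
#' @rdname frames
setMethod("nFrames", "CalciumMovie", function(x) dim(x@frames)[3])
#' @rdname frames
setMethod("nFrames", "SilhouetteStack", function(x) dim(x@frames)[3])
#' @rdname recordingLabel
setMethod("recordingLabel", "CalciumMovie", function(x) x@label)

setMethod("show", "CalciumMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("CalciumMovie (%s): %d x %d px, %d frames at %g Hz (%g s)\n",
              object@label, d[1], d[2], d[3], object@frameRate,
              d[3] / object@frameRate))
})

setMethod("show", "SilhouetteStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("SilhouetteStack: %d x %d px, %d frames at %g Hz, %g mm/px\n",
              d[1], d[2], d[3], object@frameRate, object@mmPerPx))
})

## ---------------------------------------------------------------------------
## RoiTraceSet
## ---------------------------------------------------------------------------

#' Set of ROI fluorescence traces
#'
#' One fluorescence trace per segmented ROI (putative neuron), stored as a
#' [SummarizedExperiment::SummarizedExperiment] with assay `"fluorescence"`
#' (rows = ROIs, columns = time points). Segmentation itself is an upstream
#' step; this class is its output contract.
#'
#' @seealso [roiTraceSet()], [stimCorrelation()], [crossCorrMatrix()]
#' @exportClass RoiTraceSet
setClass("RoiTraceSet", contains = "SummarizedExperiment")

setValidity("RoiTraceSet", function(object) {
  msg <- character()
  if (!"fluorescence" %in% names(assays(object)))
    msg <- c(msg, "assay 'fluorescence' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "ROI identifiers must be unique")
  md <- metadata(object)
  if (is.null(md$frameRate) || md$frameRate <= 0)
    msg <- c(msg, "metadata 'frameRate' must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a RoiTraceSet
#'
#' @param traces numeric matrix, ROIs in rows, time points in columns.
#'   Row names are used as ROI identifiers (generated when absent).
#' @param fishId character scalar identifying the fish.
#' @param recording recording label (`"baseline"`, `"shock"`, `"recovery"`).
#' @param frameRate sampling rate of the traces in Hz (default 2).
#' @param tuning optional per-ROI tuning label (`"on"`, `"off"`, `"untuned"`),
#'   stored in `rowData`; used for synthetic ground truth.
#' @return A [RoiTraceSet].
#' @export
roiTraceSet <- function(traces, fishId = "fish1", recording = "baseline",
                        frameRate = 2, tuning = NULL) {
  traces <- as.matrix(traces)
  if (is.null(rownames(traces)))
    rownames(traces) <- sprintf("roi%04d", seq_len(nrow(traces)))
  rd <- DataFrame(roi_id = rownames(traces))
  if (!is.null(tuning)) {
    stopifnot(length(tuning) == nrow(traces))
    rd$tuning <- tuning
  }
  se <- SummarizedExperiment(
    assays = SimpleList(fluorescence = traces), rowData = rd,
    metadata = list(fishId = fishId, recording = recording,
                    frameRate = frameRate))
  new("RoiTraceSet", se)
}

#' @rdname traces
setMethod("traces", "RoiTraceSet", function(x) assay(x, "fluorescence"))
#' @rdname traces
setMethod("fishId", "RoiTraceSet", function(x) metadata(x)$fishId)
#' @rdname recordingLabel
setMethod("recordingLabel", "RoiTraceSet", function(x) metadata(x)$recording)
#' @rdname frames
setMethod("frameRate", "RoiTraceSet", function(x) metadata(x)$frameRate)

setMethod("show", "RoiTraceSet", function(object) {
  cat(sprintf("RoiTraceSet (%s, %s): %d ROIs x %d time points at %g Hz\n",
              fishId(object), recordingLabel(object), nrow(object),
              ncol(object), frameRate(object)))
})

## ---------------------------------------------------------------------------
## Regressor
## ---------------------------------------------------------------------------

#' Stimulus regressor
#'
#' Predicted calcium trace for a stimulus-following neuron: the binary
#' stimulus resampled to the imaging rate and convolved with an exponential
#' calcium impulse response (tau = 1.61 s for nuclear GCaMP6f).
#'
#' @slot trace numeric, the predicted trace (non-negative, in `[0, 1]` for a
#'   unit-sum kernel and binary input).
#' @slot tau numeric, decay constant in s.
#' @slot sampleRate numeric, Hz.
#' @seealso [buildRegressor()], [stimCorrelation()]
#' @exportClass Regressor
setClass("Regressor",
  slots = c(trace = "numeric", tau = "numeric", sampleRate = "numeric"))

setValidity("Regressor", function(object) {
  msg <- character()
  if (any(object@trace < -1e-12))
    msg <- c(msg, "'trace' must be non-negative")
  if (object@tau <= 0) msg <- c(msg, "'tau' must be > 0")
  if (object@sampleRate <= 0) msg <- c(msg, "'sampleRate' must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Regressor", function(object) {
  cat(sprintf("Regressor: %d samples at %g Hz, CIRF tau = %g s\n",
              length(object@trace), object@sampleRate, object@tau))
})

## ---------------------------------------------------------------------------
## SkeletonPath / TailTrace / KymographMatrix
## ---------------------------------------------------------------------------

#' Ordered midline skeleton of a larva silhouette
#'
#' Pixel path from the head anchor to the tail tip, extracted by morphological
#' thinning followed by longest-geodesic-path retention.
#'
#' @slot coords integer matrix with columns `row`, `col`; consecutive points
#'   are 8-neighbors.
#' @slot mmPerPx numeric, spatial scale (NA when unknown).
#' @seealso [extractSkeleton()], [totalTailAngle()], [standardLength()]
#' @exportClass SkeletonPath
setClass("SkeletonPath",
  slots = c(coords = "matrix", mmPerPx = "numeric"))

setValidity("SkeletonPath", function(object) {
  msg <- character()
  xy <- object@coords
  if (ncol(xy) != 2 || nrow(xy) < 2)
    msg <- c(msg, "'coords' must be an n x 2 matrix with n >= 2")
  else {
    d <- abs(diff(xy))
    if (any(pmax(d[, 1], d[, 2]) != 1))
      msg <- c(msg, "consecutive points must be 8-neighbors")
    if (anyDuplicated(xy))
      msg <- c(msg, "repeated points are not allowed")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SkeletonPath", function(object) {
  cat(sprintf("SkeletonPath: %d points, arc length %.1f px\n",
              nrow(object@coords), .arcLengthPx(object@coords)))
})

#' Per-frame tail kinematics
#'
#' Total tail angle and standard length per analyzed video frame.
#'
#' @slot angle numeric, total tail angle in degrees per frame.
#' @slot lengthMm numeric, standard length in mm per frame.
#' @slot frame integer, indices of the frames retained by the pipeline.
#' @slot frameRate numeric, Hz.
#' @seealso [analyzeStack()], [dominantFrequency()]
#' @exportClass TailTrace
setClass("TailTrace",
  slots = c(angle = "numeric", lengthMm = "numeric", frame = "integer",
            frameRate = "numeric"))

setValidity("TailTrace", function(object) {
  msg <- character()
  if (length(object@angle) != length(object@lengthMm) ||
      length(object@angle) != length(object@frame))
    msg <- c(msg, "'angle', 'lengthMm' and 'frame' must have equal length")
  if (any(!is.finite(object@angle)))
    msg <- c(msg, "'angle' must be finite")
  if (object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TailTrace
#'
#' @param angle per-frame total tail angle in degrees.
#' @param frameRate sampling rate in Hz.
#' @param lengthMm per-frame standard length in mm (default NA).
#' @param frame frame indices (default sequential).
#' @return A [TailTrace].
#' @export
tailTrace <- function(angle, frameRate, lengthMm = rep(NA_real_,
                      length(angle)), frame = seq_along(angle)) {
  new("TailTrace", angle = angle, lengthMm = lengthMm,
      frame = as.integer(frame), frameRate = frameRate)
}

setMethod("show", "TailTrace", function(object) {
  cat(sprintf(
    "TailTrace: %d frames at %g Hz; angle range [%.1f, %.1f] deg; mean length %.2f mm\n",
    length(object@angle), object@frameRate, min(object@angle),
    max(object@angle), mean(object@lengthMm)))
})

#' Lateral tail displacement kymograph
#'
#' Normalized lateral displacement of the tail midline relative to the
#' rostrocaudal reference axis, indexed by (position along tail, frame).
#'
#' @slot displacement numeric matrix, rows = resampled positions along the
#'   tail (head at row 1), columns = frames.
#' @exportClass KymographMatrix
setClass("KymographMatrix", slots = c(displacement = "matrix"))

setValidity("KymographMatrix", function(object) {
  if (any(!is.finite(object@displacement)))
    "'displacement' must be finite" else TRUE
})

setMethod("show", "KymographMatrix", function(object) {
  d <- dim(object@displacement)
  cat(sprintf("KymographMatrix: %d positions x %d frames\n", d[1], d[2]))
})

## ---------------------------------------------------------------------------
## PsdResult / CrossCorrMatrix / AcfResult
## ---------------------------------------------------------------------------

#' Mean Welch power spectral density across traces
#'
#' @slot frequency numeric, bin frequencies in Hz (uniform spacing,
#'   `[0, rate/2]`).
#' @slot meanPower numeric, mean power density per bin across traces/pixels.
#' @slot sdPower numeric, standard deviation per bin.
#' @slot n integer, number of traces (pixels) averaged.
#' @seealso [pixelwiseMeanPsd()], [welchPsd()]
#' @exportClass PsdResult
setClass("PsdResult",
  slots = c(frequency = "numeric", meanPower = "numeric",
            sdPower = "numeric", n = "integer"))

setValidity("PsdResult", function(object) {
  msg <- character()
  if (length(object@frequency) != length(object@meanPower) ||
      length(object@frequency) != length(object@sdPower))
    msg <- c(msg, "'frequency', 'meanPower' and 'sdPower' must match")
  if (any(object@meanPower < 0)) msg <- c(msg, "power must be >= 0")
  if (length(object@frequency) > 2) {
    df <- diff(object@frequency)
    if (max(abs(df - df[1])) > 1e-9 * max(abs(df)))
      msg <- c(msg, "bin spacing must be uniform")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PsdResult", function(object) {
  cat(sprintf("PsdResult: %d bins, 0-%.3g Hz, averaged over %d traces\n",
              length(object@frequency), max(object@frequency), object@n))
})

#' Cross-correlation matrix of stimulus-sorted ROIs
#'
#' Pairwise Pearson correlations of the best stimulus-correlated ROIs, rows
#' and columns sorted by signed stimulus correlation (positive to negative).
#'
#' @slot mat numeric matrix, symmetric with unit diagonal, entries in
#'   `[-1, 1]`.
#' @slot r numeric, signed stimulus correlations of the selected ROIs in
#'   matrix order (empty after cross-fish averaging).
#' @slot weight numeric, averaging weight: total ROI count of the source fish.
#' @seealso [crossCorrMatrix()], [averageMatrices()]
#' @exportClass CrossCorrMatrix
setClass("CrossCorrMatrix",
  slots = c(mat = "matrix", r = "numeric", weight = "numeric"))

setValidity("CrossCorrMatrix", function(object) {
  m <- object@mat
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "'mat' must be square")
  else {
    if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "'mat' must be symmetric")
    if (max(abs(m)) > 1 + 1e-8) msg <- c(msg, "entries must be in [-1, 1]")
  }
  if (object@weight <= 0) msg <- c(msg, "'weight' must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CrossCorrMatrix", function(object) {
  cat(sprintf("CrossCorrMatrix: %d x %d ROIs, weight %g\n",
              nrow(object@mat), ncol(object@mat), object@weight))
})

#' Mean autocorrelation function across ROIs
#'
#' @slot lags numeric, lags in seconds (starting at 0).
#' @slot meanAcf numeric, mean normalized autocorrelation across ROIs.
#' @slot sdAcf numeric, standard deviation across ROIs.
#' @slot regressorAcf numeric, reference ACF of the stimulus regressor
#'   (length 0 when no regressor supplied).
#' @seealso [roiAcf()]
#' @exportClass AcfResult
setClass("AcfResult",
  slots = c(lags = "numeric", meanAcf = "numeric", sdAcf = "numeric",
            regressorAcf = "numeric"))

setValidity("AcfResult", function(object) {
  msg <- character()
  if (length(object@lags) != length(object@meanAcf))
    msg <- c(msg, "'lags' and 'meanAcf' must match")
  if (length(object@meanAcf) &&
      abs(object@meanAcf[1] - 1) > 1e-8)
    msg <- c(msg, "ACF must be 1 at lag 0")
  if (any(abs(object@meanAcf) > 1 + 1e-8))
    msg <- c(msg, "|ACF| must be <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AcfResult", function(object) {
  cat(sprintf("AcfResult: lags 0-%g s (%d), regressor ACF %s\n",
              max(object@lags), length(object@lags),
              if (length(object@regressorAcf)) "attached" else "absent"))
})

## ---------------------------------------------------------------------------
## MortalityGroup
## ---------------------------------------------------------------------------

#' Per-condition mortality counts
#'
#' @slot label character, condition label (waveform, field, duration).
#' @slot n integer, number of larvae.
#' @slot deaths integer, number classified dead.
#' @seealso [mortalityRate()], [compareProportions()]
#' @exportClass MortalityGroup
setClass("MortalityGroup",
  slots = c(label = "character", n = "integer", deaths = "integer"))

setValidity("MortalityGroup", function(object) {
  msg <- character()
  if (object@n <= 0) msg <- c(msg, "'n' must be > 0")
  if (object@deaths < 0 || object@deaths > object@n)
    msg <- c(msg, "'deaths' must be in [0, n]")
  if (length(msg)) msg else TRUE
})

#' Construct a MortalityGroup
#'
#' @param deaths number of larvae classified dead.
#' @param n number of larvae in the condition.
#' @param label condition label.
#' @return A [MortalityGroup].
#' @export
mortalityGroup <- function(deaths, n, label = "condition") {
  new("MortalityGroup", label = label, n = as.integer(n),
      deaths = as.integer(deaths))
}

setMethod("show", "MortalityGroup", function(object) {
  cat(sprintf("MortalityGroup '%s': %d/%d dead (%.0f%%)\n", object@label,
              object@deaths, object@n, 100 * object@deaths / object@n))
})
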