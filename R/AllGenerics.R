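#' @include zfstun-package.R
NULL

#' Frame data of an image stack
#'
#' Accessors for the pixel data, acquisition rate and spatial scale of
#' [CalciumMovie] and [SilhouetteStack] objects.
#'
#' @param x a `CalciumMovie` or `SilhouetteStack`.
#' @return `frames()` returns the 3-D pixel array (row, column, frame);
#'   `frameRate()` the acquisition rate in Hz; `mmPerPx()` the spatial
#'   scale in mm per pixel; `nFrames()` the number of frames.
#' @aliases frames frameRate mmPerPx nFrames
#' @rdname frames
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname frames
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))

#' @rdname frames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Recording label of a calcium object
#'
#' @param x a `CalciumMovie` or `RoiTraceSet`.
#' @return A character scalar, one of `"baseline"`, `"shock"`, `"recovery"`.
#' @export
setGeneric("recordingLabel", function(x) standardGeneric("recordingLabel"))

#' ROI fluorescence traces
#'
#' @param x a [RoiTraceSet].
#' @return `traces()` returns the ROI-by-time fluorescence matrix;
#'   `fishId()` the fish identifier.
#' @aliases traces fishId
#' @rdname traces
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname traces
#' @export
setGeneric("fishId", function(x) standardGeneric("fishId"))
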