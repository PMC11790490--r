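## File interchange: multi-page TIFF for movies and silhouette stacks (with a
## JSON sidecar carrying rate/scale metadata), CSV for traces, logs and
## records, JSON for exposure configurations and synthetic ground truth.

.sidecarPath <- function(path) paste0(path, ".json")

#' Read and write movies as multi-page TIFF
#'
#' Frames are stored as 16-bit grayscale pages scaled to the data maximum;
#' a JSON sidecar (`<path>.json`) records the frame rate, label/scale and
#' the intensity scale factor so that `read*` round-trips the data.
#'
#' @param movie a [CalciumMovie]; `stack` a [SilhouetteStack].
#' @param stack a [SilhouetteStack].
#' @param path TIFF file path.
#' @return Writers return `path` invisibly; readers return the object.
#' @rdname movie-io
#' @export
writeCalciumMovie <- function(movie, path) {
  stopifnot(is(movie, "CalciumMovie"))
  mx <- max(movie@frames, 1e-12)
  pages <- lapply(seq_len(nFrames(movie)),
                  function(k) movie@frames[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(type = "CalciumMovie", frameRate = movie@frameRate,
         label = movie@label, intensityScale = mx),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname movie-io
#' @export
readCalciumMovie <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  calciumMovie(arr * meta$intensityScale, meta$frameRate, meta$label)
}

#' @rdname movie-io
#' @export
writeSilhouetteStack <- function(stack, path) {
  stopifnot(is(stack, "SilhouetteStack"))
  pages <- lapply(seq_len(nFrames(stack)),
                  function(k) pmin(pmax(stack@frames[, , k], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(type = "SilhouetteStack", frameRate = stack@frameRate,
         mmPerPx = stack@mmPerPx),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname movie-io
#' @export
readSilhouetteStack <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  silhouetteStack(arr, meta$frameRate, meta$mmPerPx)
}

#' Read and write stimulus logs as CSV
#'
#' Columns `time_s`, `state`.
#'
#' @param log a [StimulusLog].
#' @param path CSV file path.
#' @rdname stimlog-io
#' @export
writeStimulusLog <- function(log, path) {
  stopifnot(is(log, "StimulusLog"))
  write.csv(data.frame(time_s = log@time, state = log@state), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname stimlog-io
#' @export
readStimulusLog <- function(path) {
  d <- read.csv(path)
  sr <- 1 / stats::median(diff(d$time_s))
  new("StimulusLog", time = d$time_s, state = as.integer(d$state),
      sampleRate = sr)
}

#' Read and write ROI trace sets as CSV
#'
#' One row per ROI: `roi_id`, `fish_id`, `recording`, then `t0...tn`.
#'
#' @param rois a [RoiTraceSet].
#' @param path CSV file path.
#' @param frameRate sampling rate in Hz used when reading (default 2).
#' @rdname roi-io
#' @export
writeRoiTraces <- function(rois, path) {
  stopifnot(is(rois, "RoiTraceSet"))
  m <- traces(rois)
  d <- data.frame(roi_id = rownames(m), fish_id = fishId(rois),
                  recording = recordingLabel(rois))
  tr <- as.data.frame(m)
  colnames(tr) <- paste0("t", seq_len(ncol(m)) - 1L)
  write.csv(cbind(d, tr), path, row.names = FALSE)
  invisible(path)
}

#' @rdname roi-io
#' @export
readRoiTraces <- function(path, frameRate = 2) {
  d <- read.csv(path)
  m <- as.matrix(d[, grep("^t\\d+$", names(d)), drop = FALSE])
  dimnames(m) <- list(d$roi_id, NULL)
  roiTraceSet(m, fishId = d$fish_id[1], recording = d$recording[1],
              frameRate = frameRate)
}

#' Read and write assessment records as CSV
#'
#' One row per larva with `larva_id` and the eight criterion flag columns
#' of [assessmentColumns()].
#'
#' @param records assessment record data.frame.
#' @param path CSV file path.
#' @rdname records-io
#' @export
writeAssessmentRecords <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname records-io
#' @export
readAssessmentRecords <- function(path) {
  d <- read.csv(path)
  for (col in assessmentColumns()) d[[col]] <- as.logical(d[[col]])
  d
}

#' Read and write exposure configurations as JSON
#'
#' @param config a [FieldExposureConfig].
#' @param path JSON file path.
#' @rdname config-io
#' @export
writeFieldExposureConfig <- function(config, path) {
  stopifnot(is(config, "FieldExposureConfig"))
  jsonlite::write_json(
    list(waveform = config@waveform, E = config@E,
         frequency = config@frequency, dutyCycle = config@dutyCycle,
         duration = config@duration, sigma = config@sigma,
         electrodeDistance = config@electrodeDistance,
         wettedArea = config@wettedArea, mediumVolume = config@mediumVolume),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname config-io
#' @export
readFieldExposureConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fieldExposureConfig(j$waveform, E = j$E, frequency = j$frequency,
                      dutyCycle = j$dutyCycle, duration = j$duration,
                      sigma = j$sigma,
                      electrodeDistance = j$electrodeDistance,
                      wettedArea = j$wettedArea,
                      mediumVolume = j$mediumVolume)
}

#' Write a dosimetry trace as CSV
#'
#' Columns `time_s,current_A,power_Wcm3,currentdensity_Acm2,temp_C`.
#'
#' @param trace a [DosimetryTrace].
#' @param path CSV file path.
#' @rdname dosimetry-io
#' @export
writeDosimetryTrace <- function(trace, path) {
  stopifnot(is(trace, "DosimetryTrace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname dosimetry-io
#' @export
readDosimetryTrace <- function(path) {
  d <- read.csv(path)
  new("DosimetryTrace", time = d$time_s, current = d$current_A,
      powerDensity = d$power_Wcm3, currentDensity = d$currentdensity_Acm2,
      temperature = d$temp_C)
}
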