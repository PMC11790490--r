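#' Generate a square-wave flash stimulus log
#'
#' Emulates the logged on/off signal of a full-field flash stimulus: a square
#' wave with equal on and off half-periods, starting in the off state,
#' sampled at `sampleRate` (the hardware logged at 100 Hz). A 6 s period
#' gives the stimulus main frequency of 1/6 Hz (0.1667 Hz).
#'
#' @param period flash period in s (off half + on half).
#' @param duration total log duration in s (must be >= `period`).
#' @param sampleRate sampling rate in Hz (default 100).
#' @return A [StimulusLog] with `duration * sampleRate` samples.
#' @examples
#' log <- stimulusLog(6, 180)
#' length(log@time)  # 18000
#' @export
stimulusLog <- function(period, duration, sampleRate = 100) {
  if (period <= 0) stop("'period' must be positive")
  if (duration < period) stop("'duration' must be at least one period")
  if (sampleRate <= 0) stop("'sampleRate' must be positive")
  n <- round(duration * sampleRate)
  t <- (seq_len(n) - 1L) / sampleRate
  half <- period / 2
  state <- as.integer(floor(t / half) %% 2 == 1)  # starts off
  new("StimulusLog", time = t, state = state, sampleRate = sampleRate)
}

#' Build a calcium stimulus regressor
#'
#' Resamples a binary stimulus log to the imaging rate and convolves it
#' causally with an exponential calcium impulse response function
#' (`exp(-t/tau)`, unit-sum, truncated at `5 * tau`), yielding the predicted
#' calcium trace of a neuron that follows the stimulus. The default decay
#' constant of 1.61 s corresponds to GCaMP6f.
#'
#' Resampling takes the mean of the log states over each output sampling
#' interval and thresholds at 0.5, equivalent to sample-and-hold for square
#' waves whose transitions align with the output grid.
#'
#' @param log a [StimulusLog].
#' @param targetRate output sampling rate in Hz (default 2, the imaging rate).
#' @param tau exponential decay constant in s (default 1.61).
#' @param invert logical; if TRUE the stimulus is inverted before convolution,
#'   giving the "off" regressor.
#' @return A [Regressor] whose trace has `duration * targetRate` samples.
#' @examples
#' reg <- buildRegressor(stimulusLog(6, 60), targetRate = 2)
#' @export
buildRegressor <- function(log, targetRate = 2, tau = 1.61, invert = FALSE) {
  stopifnot(is(log, "StimulusLog"))
  if (tau <= 0) stop("'tau' must be positive")
  if (targetRate <= 0) stop("'targetRate' must be positive")
  duration <- length(log@time) / log@sampleRate
  m <- round(duration * targetRate)
  # interval means on the output grid, then threshold at 0.5
  idx <- pmin(floor(log@time * targetRate) + 1L, m)
  means <- vapply(split(as.numeric(log@state), idx), mean, numeric(1))
  binary <- numeric(m)
  binary[as.integer(names(means))] <- as.numeric(means >= 0.5)
  if (invert) binary <- 1 - binary
  trace <- .cirfConvolve(binary, targetRate, tau)
  new("Regressor", trace = trace, tau = tau, sampleRate = targetRate)
}

## causal convolution with a unit-sum exponential kernel truncated at 5*tau
.cirfConvolve <- function(x, rate, tau) {
  dt <- 1 / rate
  k <- exp(-(0:ceiling(5 * tau / dt)) * dt / tau)
  k <- k / sum(k)
  out <- stats::convolve(x, rev(k), type = "open")[seq_along(x)]
  pmax(out, 0)
}
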