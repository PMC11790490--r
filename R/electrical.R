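#' Construct a field exposure configuration
#'
#' Defaults describe the free-swimming exposure chamber: 5 cm electrode gap,
#' 3.6 x 1.5 cm wetted electrodes, 24 mL of E3 medium at 680 uS/cm.
#'
#' @param waveform `"DC"`, `"AC_sine"` or `"PDC"`.
#' @param E voltage gradient (peak) in V/cm.
#' @param frequency waveform frequency in Hz (0 for DC).
#' @param dutyCycle PDC duty cycle in (0, 1]; ignored for DC/AC.
#' @param duration exposure duration in s.
#' @param sigma medium conductivity in S/cm (680 uS/cm = `680e-6`).
#' @param electrodeDistance electrode gap in cm.
#' @param wettedArea wetted electrode area in cm^2.
#' @param mediumVolume medium volume in cm^3.
#' @return A [FieldExposureConfig].
#' @examples
#' cfg <- fieldExposureConfig("AC_sine", E = 50, frequency = 60)
#' powerDensity(cfg)  # 0.85 W/cm^3
#' @export
fieldExposureConfig <- function(waveform = c("AC_sine", "DC", "PDC"),
                                E = 50, frequency = 60, dutyCycle = 1,
                                duration = 32, sigma = 680e-6,
                                electrodeDistance = 5, wettedArea = 5.4,
                                mediumVolume = 24) {
  waveform <- match.arg(waveform)
  new("FieldExposureConfig", waveform = waveform, E = E,
      frequency = frequency, dutyCycle = dutyCycle, duration = duration,
      sigma = sigma, electrodeDistance = electrodeDistance,
      wettedArea = wettedArea, mediumVolume = mediumVolume)
}

#' Effective (heating-equivalent) field strength
#'
#' Converts the applied peak voltage gradient to the field value that enters
#' the dissipation formula `p = E_eff^2 * sigma`: DC uses the field directly,
#' sinusoidal AC its RMS value (`E / sqrt(2)`), and PDC the peak field with
#' no duty-cycle factor. These conventions jointly reproduce the published
#' dissipation levels for both the AC and the PDC euthanasia conditions.
#'
#' @param config a [FieldExposureConfig].
#' @return Effective field in V/cm.
#' @export
effectiveField <- function(config) {
  stopifnot(is(config, "FieldExposureConfig"))
  switch(config@waveform,
         DC = config@E,
         AC_sine = config@E / sqrt(2),
         PDC = config@E,
         stop("unknown waveform: ", config@waveform))
}

#' Expected volumetric power density
#'
#' `p = effectiveField(config)^2 * sigma`, the dissipation per unit medium
#' volume ignoring joule heating (the "expected" level before conductivity
#' rises). 50 V/cm sinusoidal AC in 680 uS/cm medium gives 0.85 W/cm^3.
#'
#' @param config a [FieldExposureConfig].
#' @return Power density in W/cm^3.
#' @export
powerDensity <- function(config) {
  effectiveField(config)^2 * config@sigma
}

#' Dosimetry from a measured current trace
#'
#' Converts a measured current time series to power and current densities:
#' `p(t) = U * I(t) / V` and `J(t) = I(t) / A`. For sinusoidal AC the
#' measured current and voltage are taken as RMS readings, so
#' `U = effectiveField(config) * d`; with consistent geometry (`V = A * d`)
#' and `I = sigma * E_eff * A` this reproduces [powerDensity()] exactly for
#' every waveform.
#'
#' @param current numeric, measured current in A (non-negative).
#' @param time numeric, sample times in s (same length as `current`).
#' @param config a [FieldExposureConfig] supplying `U`, `V` and `A`.
#' @return A [DosimetryTrace] (temperature NA).
#' @export
densityFromCurrent <- function(current, time, config) {
  stopifnot(is(config, "FieldExposureConfig"))
  if (length(current) != length(time))
    stop("'current' and 'time' must have equal length")
  if (any(current < 0)) stop("negative current sample in trace")
  U <- effectiveField(config) * config@electrodeDistance
  new("DosimetryTrace", time = time, current = current,
      powerDensity = U * current / config@mediumVolume,
      currentDensity = current / config@wettedArea,
      temperature = rep(NA_real_, length(time)))
}

#' Simulate joule heating with conductivity feedback
#'
#' Forward-Euler integration of adiabatic heating of the medium: dissipated
#' power raises the temperature, which raises conductivity linearly
#' (`sigma(T) = sigma0 * (1 + tempCoeff * (T - T0))`), which in turn raises
#' the dissipated power — the feedback loop behind the observed rise in
#' current and power density over an exposure.
#'
#' @param config a [FieldExposureConfig].
#' @param tempCoeff linear conductivity temperature coefficient per degree C
#'   (>= 0; about 0.02/degree C for dilute aqueous electrolytes).
#' @param heatCapacity volumetric heat capacity in J/(cm^3 degree C)
#'   (default 4.18, water).
#' @param dt integration step in s (default 0.01; must be < duration).
#' @param T0 starting temperature in degrees C (default 25).
#' @return A [DosimetryTrace] covering `[0, duration]`; with `tempCoeff = 0`
#'   all series are constant.
#' @export
simulateJouleHeating <- function(config, tempCoeff, heatCapacity = 4.18,
                                 dt = 0.01, T0 = 25) {
  stopifnot(is(config, "FieldExposureConfig"))
  if (tempCoeff < 0) stop("'tempCoeff' must be >= 0")
  if (dt <= 0) stop("'dt' must be positive")
  if (dt >= config@duration)
    stop("'dt' must be smaller than the exposure duration")
  Eeff <- effectiveField(config)
  n <- floor(config@duration / dt) + 1L
  time <- (seq_len(n) - 1L) * dt
  temp <- power <- sigmaSeries <- numeric(n)
  Tk <- T0
  for (k in seq_len(n)) {
    sigmaT <- config@sigma * (1 + tempCoeff * (Tk - T0))
    p <- Eeff^2 * sigmaT
    temp[k] <- Tk
    power[k] <- p
    sigmaSeries[k] <- sigmaT
    Tk <- Tk + dt * p / heatCapacity
  }
  current <- sigmaSeries * Eeff * config@wettedArea
  new("DosimetryTrace", time = time, current = current,
      powerDensity = power, currentDensity = current / config@wettedArea,
      temperature = temp)
}

#' Generate a synthetic measured current trace
#'
#' Produces the current trace a current probe would record during an
#' exposure, consistent with conductivity rising under adiabatic joule
#' heating ([simulateJouleHeating()]). With `tempCoeff = 0` the current is
#' constant at `sigma * effectiveField * A`. Optional Gaussian measurement
#' noise (clipped at zero) is seed-reproducible.
#'
#' @param config a [FieldExposureConfig].
#' @param tempCoeff conductivity temperature coefficient per degree C (>= 0).
#' @param dt sampling interval in s (default 0.01).
#' @param noiseSd measurement noise s.d. in A (default 0, noise-free).
#' @param seed integer seed for the measurement noise.
#' @return A [DosimetryTrace]; power and current densities are recomputed
#'   from the (possibly noisy) current via [densityFromCurrent()].
#' @export
simulateCurrentTrace <- function(config, tempCoeff, dt = 0.01, noiseSd = 0,
                                 seed = NULL) {
  sim <- simulateJouleHeating(config, tempCoeff, dt = dt)
  current <- sim@current
  if (noiseSd > 0)
    current <- .withSeed(seed,
      pmax(0, current + rnorm(length(current), 0, noiseSd)))
  out <- densityFromCurrent(current, sim@time, config)
  out@temperature <- sim@temperature
  out
}
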