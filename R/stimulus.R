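#' Sinusoidal voltage stimulus
#'
#' An ideal sinusoidal voltage source with optional DC offset,
#' \eqn{v(t) = A \sin(2\pi f t) + v_{DC}}.  The phase convention is a sine
#' starting at zero, so a positive-amplitude run begins with the positive
#' half-wave.  The amplitude may be negative (sign-flipped drive).  The
#' analytic time derivative is available for the capacitor branch.
#'
#' @param amplitude Amplitude A, in volt (may be negative).
#' @param frequency Frequency f, in Hz (> 0).
#' @param dcOffset DC offset, in volt.
#' @param nPeriods Number of full signal periods to simulate (>= 1).
#' @return An object of class `"Stimulus"`.
#' @export
#' @examples
#' s <- stimulus(amplitude = 4.5, frequency = 0.025)
#' voltageAt(s, 10)  # quarter period: 4.5 V
stimulus <- function(amplitude = 4.5, frequency = 0.025, dcOffset = 0,
                     nPeriods = 2L) {
  stopifnot(frequency > 0, nPeriods >= 1, nPeriods == round(nPeriods))
  structure(list(amplitude = amplitude, frequency = frequency,
                 dcOffset = dcOffset, nPeriods = as.integer(nPeriods)),
            class = "Stimulus")
}

#' @export
print.Stimulus <- function(x, ...) {
  cat(sprintf(
    "Sinusoidal stimulus: %g V at %g Hz, offset %g V, %d period(s) (t_period = %g s)\n",
    x$amplitude, x$frequency, x$dcOffset, x$nPeriods, stimulusPeriod(x)))
  invisible(x)
}

#' Period of a stimulus
#'
#' @param stim A [stimulus()] object.
#' @return The duration of one full period, 1/f, in seconds.
#' @export
stimulusPeriod <- function(stim) 1 / stim$frequency

#' Stimulus voltage at given times
#'
#' @param stim A [stimulus()] object.
#' @param t Times in seconds (vectorised).
#' @return Voltage(s) in volt.
#' @export
voltageAt <- function(stim, t) {
  stim$amplitude * sin(2 * pi * stim$frequency * t) + stim$dcOffset
}

#' Analytic voltage derivative at given times
#'
#' @param stim A [stimulus()] object.
#' @param t Times in seconds (vectorised).
#' @return dv/dt in V/s.
#' @export
dvdtAt <- function(stim, t) {
  2 * pi * stim$frequency * stim$amplitude * cos(2 * pi * stim$frequency * t)
}
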