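#' Parameters of the tangential (NTC-thermistor) memristor model
#'
#' A self-heating negative-temperature-coefficient thermistor behaves as a
#' memristor whose internal state is its temperature: current flow heats the
#' device, heat dissipates towards ambient, and the conductance increases
#' with temperature.  Under a sinusoidal voltage its V-I trace is a pinched
#' hysteresis loop whose branches touch the pinch point with equal slopes
#' (a *tangential* loop).  Defaults reproduce the reference device used
#' throughout this package.
#'
#' @param r0 Resistance at the reference (ambient) temperature, in ohm.
#' @param t0 Reference/ambient temperature, in kelvin.
#' @param beta Material-specific constant of the NTC characteristic, in kelvin.
#' @param delta Dissipation constant towards ambient, in W/K.
#' @param heatCapacity Heat capacitance of the device, in J/K.
#'
#' @return An object of class `"TangentialModelParams"` (a named list).
#' @seealso [tangentialConductance()], [tangentialStateDerivative()]
#' @export
#' @examples
#' p <- tangentialParams()
#' tangentialConductance(300, p) # 1/3890 S at ambient
tangentialParams <- function(r0 = 3890, t0 = 300, beta = 5e5,
                             delta = 0.1, heatCapacity = 0.14) {
  stopifnot(r0 > 0, t0 > 0, beta > 0, delta > 0, heatCapacity > 0)
  structure(list(r0 = r0, t0 = t0, beta = beta, delta = delta,
                 heatCapacity = heatCapacity),
            class = "TangentialModelParams")
}

#' Parameters of the transversal (modified HP linear-drift) memristor model
#'
#' The HP titanium-dioxide memristor is a two-layer device whose doped-region
#' extension, normalised to `x` in \[0, 1\], sets the memristance by linear
#' mixing of the extreme values `rOn` and `rOff`.  The state drifts in
#' proportion to the device current.  Its V-I loop crosses the pinch point
#' with different branch slopes (a *transversal* loop).  The `slowdown`
#' factor scales the state-change rate so that the state stays well inside
#' its bounds at the slow drive frequencies used here; without it the state
#' would saturate almost instantly.
#'
#' @param rOn Minimum memristance (fully doped, `x = 1`), in ohm.
#' @param rOff Maximum memristance (undoped, `x = 0`), in ohm.
#' @param thickness Total oxide layer extent D, in metres.
#' @param mobility Oxygen-vacancy mobility, in m^2/(s V).
#' @param slowdown Dimensionless state-rate factor.
#'
#' @return An object of class `"TransversalModelParams"` (a named list).
#' @seealso [transversalMemristance()], [transversalStateDerivative()]
#' @export
#' @examples
#' p <- transversalParams()
#' transversalMemristance(0.76, p) # 3916 ohm
transversalParams <- function(rOn = 100, rOff = 16000, thickness = 1e-8,
                              mobility = 1e-14, slowdown = 5e-4) {
  stopifnot(rOn > 0, rOff > rOn, thickness > 0, mobility >= 0, slowdown > 0)
  structure(list(rOn = rOn, rOff = rOff, thickness = thickness,
                 mobility = mobility, slowdown = slowdown),
            class = "TransversalModelParams")
}

#' Temperature-dependent conductance of the tangential memristor
#'
#' Evaluates the NTC characteristic
#' \deqn{G(T) = \left[R_0 \exp\!\big(\beta (1/T - 1/T_0)\big)\right]^{-1},}
#' which is strictly increasing in temperature.
#'
#' @param temperature Device temperature(s), in kelvin; must be positive.
#' @param params A [tangentialParams()] object.
#' @return Conductance in siemens (vectorised over `temperature`).
#' @export
tangentialConductance <- function(temperature, params = tangentialParams()) {
  if (any(temperature <= 0)) {
    stop("temperature must be strictly positive (kelvin)")
  }
  1 / (params$r0 * exp(params$beta * (1 / temperature - 1 / params$t0)))
}

#' Temperature rate of the tangential memristor
#'
#' Energy balance of the self-heating thermistor: Newtonian cooling towards
#' ambient plus Joule heating,
#' \deqn{dT/dt = \frac{\delta}{H_C}(T_0 - T) + \frac{G(T)}{H_C} v^2.}
#' The rate depends on the voltage only through \eqn{v^2}, so it is invariant
#' under a sign flip of the drive.
#'
#' @param temperature Device temperature, in kelvin; must be positive.
#' @param voltage Applied voltage, in volt.
#' @param params A [tangentialParams()] object.
#' @return Temperature rate in K/s (vectorised).
#' @export
tangentialStateDerivative <- function(temperature, voltage,
                                      params = tangentialParams()) {
  g <- tangentialConductance(temperature, params)
  params$delta / params$heatCapacity * (params$t0 - temperature) +
    g / params$heatCapacity * voltage^2
}

#' Memristance of the transversal memristor
#'
#' Linear mixing of the doped and undoped layer resistances,
#' \deqn{M(x) = R_{on} x + R_{off} (1 - x),}
#' strictly decreasing in `x`; `x = 1` gives `rOn`, `x = 0` gives `rOff`.
#'
#' @param x Normalised doped-region extension(s) in \[0, 1\].
#' @param params A [transversalParams()] object.
#' @return Memristance in ohm (vectorised over `x`).
#' @export
transversalMemristance <- function(x, params = transversalParams()) {
  if (any(x < 0 | x > 1)) {
    stop("state x must lie in [0, 1]")
  }
  params$rOn * x + params$rOff * (1 - x)
}

#' State-dependent conductance of the transversal memristor
#'
#' Convenience inverse of [transversalMemristance()]; the natural description
#' of a memristor inside a parallel circuit.
#'
#' @inheritParams transversalMemristance
#' @return Memductance in siemens.
#' @export
transversalConductance <- function(x, params = transversalParams()) {
  1 / transversalMemristance(x, params)
}

#' State rate of the transversal memristor
#'
#' Linear dopant drift driven by the device current,
#' \deqn{dx/dt = \frac{\mu_v R_{on}}{D^2}\, \frac{v}{M(x)}\, s,}
#' with `s` the slowdown factor.  The state is confined to \[0, 1\] by a hard
#' clamp: at a boundary, a rate that would push `x` outside is replaced by 0;
#' inward-pointing rates are unaffected.  In the interior the sign of the
#' rate equals the sign of the voltage.
#'
#' @param x Normalised doped-region extension in \[0, 1\].
#' @param voltage Applied voltage, in volt.
#' @param params A [transversalParams()] object.
#' @return State rate in 1/s (vectorised over `x` and `voltage`).
#' @export
transversalStateDerivative <- function(x, voltage,
                                       params = transversalParams()) {
  m <- transversalMemristance(x, params)
  rate <- params$mobility * params$rOn / params$thickness^2 *
    (voltage / m) * params$slowdown
  # hard clamp: zero any outward-pushing rate at the boundaries
  rate * !((x >= 1 & rate > 0) | (x <= 0 & rate < 0))
}

#' Capacitor branch current
#'
#' \eqn{i_C = C\, dv/dt} for the constant parallel capacitance.
#'
#' @param dvdt Time derivative of the applied voltage, in V/s.
#' @param capacitance Capacitance in farad, non-negative.
#' @return Current in ampere (vectorised over `dvdt`).
#' @export
capacitorCurrent <- function(dvdt, capacitance) {
  stopifnot(capacitance >= 0)
  capacitance * dvdt
}

#' Circuit configuration for the parallel memristor-capacitor network
#'
#' Describes which branches are present in the parallel circuit (tangential
#' memristor, transversal memristor, capacitor), the device parameters, and
#' the initial internal states.  A capacitor-only circuit (both memristors
#' absent) is allowed; it is useful as a closed-form reference.
#'
#' @param includeTangential Logical; include the NTC-thermistor branch.
#' @param includeTransversal Logical; include the HP-memristor branch.
#' @param capacitance Parallel capacitance in farad (>= 0; 0 removes the
#'   branch).
#' @param tangentialParams,transversalParams Device parameter objects.
#' @param initialTemperature Initial thermistor temperature, in kelvin.
#' @param initialX Initial normalised doped-region extension, in \[0, 1\].
#'
#' @return An object of class `"CircuitConfig"`.
#' @export
#' @examples
#' circuitConfig(includeTangential = TRUE, capacitance = 60e-6)
circuitConfig <- function(includeTangential = FALSE,
                          includeTransversal = FALSE,
                          capacitance = 0,
                          tangentialParams = pinchloop::tangentialParams(),
                          transversalParams = pinchloop::transversalParams(),
                          initialTemperature = 300,
                          initialX = 0.76) {
  stopifnot(is.logical(includeTangential), is.logical(includeTransversal),
            capacitance >= 0,
            inherits(tangentialParams, "TangentialModelParams"),
            inherits(transversalParams, "TransversalModelParams"),
            initialTemperature > 0, initialX >= 0, initialX <= 1)
  if (!includeTangential && !includeTransversal && capacitance == 0) {
    stop("circuit must contain at least one branch")
  }
  structure(list(includeTangential = includeTangential,
                 includeTransversal = includeTransversal,
                 capacitance = capacitance,
                 tangentialParams = tangentialParams,
                 transversalParams = transversalParams,
                 initialTemperature = initialTemperature,
                 initialX = initialX),
            class = "CircuitConfig")
}

#' @export
print.CircuitConfig <- function(x, ...) {
  branches <- c(if (x$includeTangential) "tangential (NTC)",
                if (x$includeTransversal) "transversal (HP)",
                if (x$capacitance > 0)
                  sprintf("capacitor (%.4g uF)", x$capacitance * 1e6))
  cat("Parallel circuit configuration\n")
  cat("  branches:", paste(branches, collapse = " | "), "\n")
  if (x$includeTangential)
    cat(sprintf("  initial T: %g K\n", x$initialTemperature))
  if (x$includeTransversal)
    cat(sprintf("  initial x: %g\n", x$initialX))
  invisible(x)
}

#' Branch and total currents of the parallel circuit
#'
#' Evaluates the state-dependent Ohm law for each active memristor branch
#' and the capacitor current, and sums them:
#' \eqn{i = i_{tran} + i_{tang} + i_C}.  Inactive branches contribute
#' exactly 0.
#'
#' @param voltage Applied voltage, in volt.
#' @param dvdt Voltage time derivative, in V/s.
#' @param temperature Thermistor temperature, in kelvin (ignored when the
#'   branch is absent).
#' @param x Doped-region extension (ignored when the branch is absent).
#' @param config A [circuitConfig()] object.
#' @return A list with components `iTang`, `iTran`, `iC`, `iTotal`, in
#'   ampere; all vectorised over the inputs.
#' @export
totalCurrent <- function(voltage, dvdt, temperature = NULL, x = NULL,
                         config) {
  stopifnot(inherits(config, "CircuitConfig"))
  zero <- numeric(length(voltage))
  iTang <- if (config$includeTangential) {
    voltage * tangentialConductance(temperature, config$tangentialParams)
  } else zero
  iTran <- if (config$includeTransversal) {
    voltage * transversalConductance(x, config$transversalParams)
  } else zero
  iC <- capacitorCurrent(dvdt, config$capacitance) + zero
  list(iTang = iTang, iTran = iTran, iC = iC,
       iTotal = iTang + iTran + iC)
}

#' Small-signal admittance of the circuit around a state
#'
#' Around an operating state the parallel network has admittance
#' \eqn{Y = G(x, T) + jB} with real conductance equal to the sum of the
#' active memristor branch conductances and susceptance
#' \eqn{B = 2\pi f C = \omega C}.
#'
#' @param x Doped-region extension (used when the transversal branch is
#'   active).
#' @param temperature Thermistor temperature in kelvin (used when the
#'   tangential branch is active).
#' @param frequency Signal frequency in Hz (>= 0).
#' @param config A [circuitConfig()] object.
#' @return An object of class `"AdmittancePoint"`: a list with
#'   `conductanceReal` (S), `susceptance` (S) and `angularFrequency` (rad/s).
#' @export
circuitAdmittance <- function(x = NULL, temperature = NULL, frequency,
                              config) {
  stopifnot(inherits(config, "CircuitConfig"), frequency >= 0)
  g <- 0
  if (config$includeTangential) {
    g <- g + tangentialConductance(temperature, config$tangentialParams)
  }
  if (config$includeTransversal) {
    g <- g + transversalConductance(x, config$transversalParams)
  }
  omega <- 2 * pi * frequency
  structure(list(conductanceReal = g,
                 susceptance = omega * config$capacitance,
                 angularFrequency = omega),
            class = "AdmittancePoint")
}

#' @export
print.AdmittancePoint <- function(x, ...) {
  cat(sprintf("Admittance point: G = %.6g S, B = %.6g S (omega = %.6g rad/s)\n",
              x$conductanceReal, x$susceptance, x$angularFrequency))
  invisible(x)
}
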