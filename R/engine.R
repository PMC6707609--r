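#' Solver options for the simulation engine
#'
#' @param relTol Relative tolerance of the adaptive integrator.
#' @param absTol Absolute tolerance (applied per state; the states are O(1)
#'   to O(300), so the defaults are conservative).
#' @param samplesPerPeriod Number of uniform output samples per signal
#'   period (>= 1000).  Loop-feature extraction always operates on this
#'   sampled grid, never on internal solver steps.
#' @return An object of class `"SolverOptions"`.
#' @export
solverOptions <- function(relTol = 1e-8, absTol = 1e-10,
                          samplesPerPeriod = 4000L) {
  stopifnot(relTol > 0, absTol > 0, samplesPerPeriod >= 1000)
  structure(list(relTol = relTol, absTol = absTol,
                 samplesPerPeriod = as.integer(samplesPerPeriod)),
            class = "SolverOptions")
}

# State derivatives with the boundary clamp, shared by both integrators.
# `tempr`/`x` may be NA for inactive branches; only active derivatives are
# returned, in the order (temperature, x).
.stateDerivs <- function(tempr, x, v, config) {
  d <- numeric(0)
  if (config$includeTangential) {
    d <- c(d, tangentialStateDerivative(tempr, v, config$tangentialParams))
  }
  if (config$includeTransversal) {
    # tolerate tiny integrator excursions beyond [0, 1]
    xc <- min(max(x, 0), 1)
    d <- c(d, transversalStateDerivative(xc, v, config$transversalParams))
  }
  d
}

.initialState <- function(config) {
  y <- numeric(0)
  if (config$includeTangential) y <- c(y, temperature = config$initialTemperature)
  if (config$includeTransversal) y <- c(y, x = config$initialX)
  y
}

# Assemble a SimulationTrace data frame from sampled times and states.
.makeTrace <- function(t, tempr, x, config, stim, options) {
  v <- voltageAt(stim, t)
  dvdt <- dvdtAt(stim, t)
  gTang <- if (config$includeTangential) {
    tangentialConductance(tempr, config$tangentialParams)
  } else rep(NA_real_, length(t))
  gTran <- if (config$includeTransversal) {
    transversalConductance(x, config$transversalParams)
  } else rep(NA_real_, length(t))
  iTang <- if (config$includeTangential) v * gTang else numeric(length(t))
  iTran <- if (config$includeTransversal) v * gTran else numeric(length(t))
  iC <- capacitorCurrent(dvdt, config$capacitance) + numeric(length(t))
  trace <- data.frame(
    t = t, v = v,
    i_tang = iTang, i_tran = iTran, i_c = iC,
    i_total = iTang + iTran + iC,
    temperature = if (config$includeTangential) tempr else NA_real_,
    x = if (config$includeTransversal) x else NA_real_,
    g_tang = gTang, g_tran = gTran
  )
  structure(trace,
            class = c("SimulationTrace", "data.frame"),
            config = config, stimulus = stim, options = options,
            samplesPerPeriod = options$samplesPerPeriod,
            nPeriods = stim$nPeriods)
}

#' Simulate the parallel circuit over full signal periods
#'
#' Integrates the internal-state ODEs of the active memristor branches
#' (thermistor temperature and/or doped-region extension; they decouple
#' because the voltage is imposed by an ideal source) from `t = 0` over
#' `nPeriods` full periods with an adaptive embedded Runge-Kutta-Fehlberg
#' 4(5) scheme, then evaluates all branch currents on a uniform sample grid.
#' The transversal state is confined to \[0, 1\] by zeroing outward-pointing
#' rates at the boundaries (with the default device parameters and drive the
#' boundaries are never reached).
#'
#' @param config A [circuitConfig()] object.
#' @param stim A [stimulus()] object.
#' @param options A [solverOptions()] object.
#' @return A `"SimulationTrace"`: a data frame with columns `t` (s), `v`
#'   (V), `i_tang`, `i_tran`, `i_c`, `i_total` (A), `temperature` (K), `x`,
#'   `g_tang`, `g_tran` (S), uniformly sampled with
#'   `samplesPerPeriod` points per period (plus the final endpoint), and
#'   metadata attributes `config`, `stimulus`, `options`.  Inactive-branch
#'   state and memductance columns are `NA`; their currents are exactly 0.
#' @export
#' @examples
#' cfg <- circuitConfig(includeTangential = TRUE)
#' tr <- simulateCircuit(cfg, stimulus(), solverOptions(samplesPerPeriod = 1000))
#' range(tr$g_tang) * 1e6 # memductance swing in microsiemens
simulateCircuit <- function(config, stim = stimulus(),
                            options = solverOptions()) {
  stopifnot(inherits(config, "CircuitConfig"), inherits(stim, "Stimulus"),
            inherits(options, "SolverOptions"))
  tp <- stimulusPeriod(stim)
  n <- stim$nPeriods * options$samplesPerPeriod
  times <- seq(0, stim$nPeriods * tp, length.out = n + 1)
  y0 <- .initialState(config)
  if (length(y0) == 0) {
    # capacitor-only circuit: purely algebraic
    return(.makeTrace(times, NULL, NULL, config, stim, options))
  }
  rhs <- function(t, y, p) {
    v <- voltageAt(stim, t)
    list(.stateDerivs(if (config$includeTangential) y[["temperature"]] else NA,
                      if (config$includeTransversal) y[["x"]] else NA,
                      v, config))
  }
  out <- deSolve::ode(y0, times, rhs, parms = NULL,
                      method = deSolve::rkMethod("rk45f"),
                      rtol = options$relTol, atol = options$absTol)
  if (nrow(out) < length(times) || any(!is.finite(out))) {
    lastGood <- if (nrow(out) > 0) max(out[stats::complete.cases(out), "time"]) else 0
    stop(sprintf("integration failed; last accepted time %.6g s", lastGood))
  }
  tempr <- if (config$includeTangential) out[, "temperature"] else NULL
  x <- if (config$includeTransversal) pmin(pmax(out[, "x"], 0), 1) else NULL
  .makeTrace(times, tempr, x, config, stim, options)
}

#' Fixed-step classical Runge-Kutta reference integration
#'
#' Integrates the same circuit ODEs with a hand-written classical
#' fixed-step 4th-order Runge-Kutta scheme, independent of the adaptive
#' engine.  Intended as a verification reference in tests, not for
#' production runs.
#'
#' @param config A [circuitConfig()] object.
#' @param stim A [stimulus()] object.
#' @param nStepsPerPeriod Number of fixed steps per signal period
#'   (>= 1e4); must be a multiple of `samplesPerPeriod`.
#' @param samplesPerPeriod Output grid density (default 4000, matching
#'   [solverOptions()]).
#' @return A `"SimulationTrace"` on the same uniform grid as
#'   [simulateCircuit()] with matching `samplesPerPeriod`.
#' @export
oracleFixedStep <- function(config, stim = stimulus(),
                            nStepsPerPeriod = 2e4,
                            samplesPerPeriod = 4000L) {
  stopifnot(inherits(config, "CircuitConfig"), inherits(stim, "Stimulus"),
            nStepsPerPeriod >= 1e4,
            nStepsPerPeriod %% samplesPerPeriod == 0)
  tp <- stimulusPeriod(stim)
  h <- tp / nStepsPerPeriod
  thin <- nStepsPerPeriod / samplesPerPeriod
  nSteps <- stim$nPeriods * nStepsPerPeriod
  nOut <- stim$nPeriods * samplesPerPeriod + 1

  hasT <- config$includeTangential
  hasX <- config$includeTransversal
  y <- .initialState(config)
  times <- seq(0, stim$nPeriods * tp, length.out = nOut)
  if (length(y) == 0) {
    return(.makeTrace(times, NULL, NULL, config, stim,
                      solverOptions(samplesPerPeriod = samplesPerPeriod)))
  }
  Tout <- if (hasT) numeric(nOut) else NULL
  Xout <- if (hasX) numeric(nOut) else NULL
  Tcur <- if (hasT) config$initialTemperature else NA
  Xcur <- if (hasX) config$initialX else NA
  if (hasT) Tout[1] <- Tcur
  if (hasX) Xout[1] <- Xcur

  f <- function(t, Tt, xx) {
    v <- voltageAt(stim, t)
    dT <- if (hasT) tangentialStateDerivative(Tt, v, config$tangentialParams) else 0
    dx <- if (hasX) {
      transversalStateDerivative(min(max(xx, 0), 1), v, config$transversalParams)
    } else 0
    c(dT, dx)
  }
  outIdx <- 1L
  t <- 0
  for (s in seq_len(nSteps)) {
    k1 <- f(t, Tcur, Xcur)
    k2 <- f(t + h / 2, Tcur + h / 2 * k1[1], Xcur + h / 2 * k1[2])
    k3 <- f(t + h / 2, Tcur + h / 2 * k2[1], Xcur + h / 2 * k2[2])
    k4 <- f(t + h, Tcur + h * k3[1], Xcur + h * k3[2])
    incr <- h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    Tcur <- Tcur + incr[1]
    Xcur <- Xcur + incr[2]
    t <- t + h
    if (s %% thin == 0) {
      outIdx <- outIdx + 1L
      if (hasT) Tout[outIdx] <- Tcur
      if (hasX) Xout[outIdx] <- min(max(Xcur, 0), 1)
    }
  }
  .makeTrace(times, Tout, Xout, config, stim,
             solverOptions(samplesPerPeriod = samplesPerPeriod))
}

#' @export
print.SimulationTrace <- function(x, ...) {
  cfg <- attr(x, "config")
  stim <- attr(x, "stimulus")
  cat(sprintf("SimulationTrace: %d samples, %d period(s) of %g s\n",
              nrow(x), attr(x, "nPeriods"), stimulusPeriod(stim)))
  print(cfg)
  cat(sprintf("  total current range: [%.4g, %.4g] A\n",
              min(x$i_total), max(x$i_total)))
  invisible(x)
}

#' Plot a voltage-current hysteresis loop
#'
#' @param x A `"SimulationTrace"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.SimulationTrace <- function(x, ...) {
  graphics::plot(x$v, x$i_total * 1e3, type = "l",
                 xlab = "voltage (V)", ylab = "current (mA)", ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}

# indices of samples belonging to one full period (both boundary samples)
.periodIndices <- function(trace, periodIndex) {
  spp <- attr(trace, "samplesPerPeriod")
  np <- attr(trace, "nPeriods")
  if (is.null(spp) || is.null(np)) {
    stop("trace is missing sampling metadata")
  }
  if (periodIndex < 1 || periodIndex > np) {
    stop(sprintf("period %d not present in trace (%d periods)",
                 periodIndex, np))
  }
  ((periodIndex - 1L) * spp + 1L):(periodIndex * spp + 1L)
}

# number-preserving text formatting: %.17g round-trips doubles exactly
.fmtNum <- function(v) {
  out <- sprintf("%.17g", v)
  out[is.na(v)] <- "NA"
  out
}

#' Write a simulation trace to delimited text
#'
#' Writes the trace as a CSV with columns `t_s, v_V, i_tang_A, i_tran_A,
#' i_c_A, i_total_A, T_K, x, g_tang_S, g_tran_S` at full double precision,
#' plus a JSON metadata sidecar (`<path>.meta.json`) carrying the circuit
#' configuration, stimulus and solver options.
#'
#' @param trace A `"SimulationTrace"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  cols <- data.frame(
    t_s = .fmtNum(trace$t), v_V = .fmtNum(trace$v),
    i_tang_A = .fmtNum(trace$i_tang), i_tran_A = .fmtNum(trace$i_tran),
    i_c_A = .fmtNum(trace$i_c), i_total_A = .fmtNum(trace$i_total),
    T_K = .fmtNum(trace$temperature), x = .fmtNum(trace$x),
    g_tang_S = .fmtNum(trace$g_tang), g_tran_S = .fmtNum(trace$g_tran))
  utils::write.csv(cols, path, row.names = FALSE, quote = FALSE)
  cfg <- attr(trace, "config")
  stim <- attr(trace, "stimulus")
  opt <- attr(trace, "options")
  meta <- list(
    config = list(
      include_tangential = cfg$includeTangential,
      include_transversal = cfg$includeTransversal,
      capacitance_F = cfg$capacitance,
      tangential_params = unclass(cfg$tangentialParams),
      transversal_params = unclass(cfg$transversalParams),
      initial_temperature_K = cfg$initialTemperature,
      initial_x = cfg$initialX),
    stimulus = list(amplitude_V = stim$amplitude, frequency_Hz = stim$frequency,
                    dc_offset_V = stim$dcOffset, n_periods = stim$nPeriods),
    solver = list(rel_tol = opt$relTol, abs_tol = opt$absTol,
                  samples_per_period = opt$samplesPerPeriod))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a simulation trace written by [writeTrace()]
#'
#' @param path CSV path; the `<path>.meta.json` sidecar is read when
#'   present so that period-based feature extraction works on the result.
#' @return A `"SimulationTrace"`.
#' @export
readTrace <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_s", "v_V", "i_tang_A", "i_tran_A", "i_c_A", "i_total_A",
            "T_K", "x", "g_tang_S", "g_tran_S")
  if (!all(need %in% names(d))) {
    stop("trace file is missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  trace <- data.frame(t = d$t_s, v = d$v_V, i_tang = d$i_tang_A,
                      i_tran = d$i_tran_A, i_c = d$i_c_A,
                      i_total = d$i_total_A, temperature = d$T_K, x = d$x,
                      g_tang = d$g_tang_S, g_tran = d$g_tran_S)
  class(trace) <- c("SimulationTrace", "data.frame")
  metaPath <- paste0(path, ".meta.json")
  if (file.exists(metaPath)) {
    m <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    cfg <- circuitConfig(
      includeTangential = m$config$include_tangential,
      includeTransversal = m$config$include_transversal,
      capacitance = m$config$capacitance_F,
      tangentialParams = do.call(tangentialParams, m$config$tangential_params),
      transversalParams = do.call(transversalParams, m$config$transversal_params),
      initialTemperature = m$config$initial_temperature_K,
      initialX = m$config$initial_x)
    stim <- stimulus(amplitude = m$stimulus$amplitude_V,
                     frequency = m$stimulus$frequency_Hz,
                     dcOffset = m$stimulus$dc_offset_V,
                     nPeriods = m$stimulus$n_periods)
    opt <- solverOptions(relTol = m$solver$rel_tol, absTol = m$solver$abs_tol,
                         samplesPerPeriod = m$solver$samples_per_period)
    attr(trace, "config") <- cfg
    attr(trace, "stimulus") <- stim
    attr(trace, "options") <- opt
    attr(trace, "samplesPerPeriod") <- opt$samplesPerPeriod
    attr(trace, "nPeriods") <- stim$nPeriods
  } else {
    # fall back to sampling metadata inferred from the time grid
    spp <- .inferSampling(trace$t)
    attr(trace, "samplesPerPeriod") <- spp$samplesPerPeriod
    attr(trace, "nPeriods") <- spp$nPeriods
  }
  trace
}

# infer samples-per-period and period count from a uniform grid spanning an
# integer number of periods of the voltage column (used for ingested data)
.inferSampling <- function(t) {
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("time grid must be uniform and strictly increasing")
  }
  list(samplesPerPeriod = length(t) - 1L, nPeriods = 1L)
}
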