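# Shared fixtures: standard circuits and lazily cached simulation traces.
# All traces use the default study drive (4.5 V at 0.025 Hz, two periods)
# unless a helper says otherwise.

ntcConfig <- function(C = 0) circuitConfig(includeTangential = TRUE, capacitance = C)
hpConfig <- function(C = 0) circuitConfig(includeTransversal = TRUE, capacitance = C)
bothConfig <- function(C = 0) {
  circuitConfig(includeTangential = TRUE, includeTransversal = TRUE, capacitance = C)
}

.traceCache <- new.env(parent = emptyenv())

# canonical traces at the default sampling density, built once per session
cachedTrace <- function(key) {
  if (!is.null(.traceCache[[key]])) return(.traceCache[[key]])
  tr <- switch(key,
    ntc = simulateCircuit(ntcConfig(), stimulus(), solverOptions()),
    hp = simulateCircuit(hpConfig(), stimulus(), solverOptions()),
    ntc_c60 = simulateCircuit(ntcConfig(60e-6), stimulus(), solverOptions()),
    ntc_c120 = simulateCircuit(ntcConfig(120e-6), stimulus(), solverOptions()),
    ntc_c240 = simulateCircuit(ntcConfig(240e-6), stimulus(), solverOptions()),
    hp_c60 = simulateCircuit(hpConfig(60e-6), stimulus(), solverOptions()),
    hp_c120 = simulateCircuit(hpConfig(120e-6), stimulus(), solverOptions()),
    hp_c240 = simulateCircuit(hpConfig(240e-6), stimulus(), solverOptions()),
    both = simulateCircuit(bothConfig(), stimulus(), solverOptions()),
    both_c60 = simulateCircuit(bothConfig(60e-6), stimulus(), solverOptions()),
    ntc_neg = simulateCircuit(ntcConfig(), stimulus(amplitude = -4.5), solverOptions()),
    hp_neg = simulateCircuit(hpConfig(), stimulus(amplitude = -4.5), solverOptions()),
    ntc_offset = simulateCircuit(ntcConfig(), stimulus(dcOffset = -0.25), solverOptions()),
    hp_offset = simulateCircuit(hpConfig(), stimulus(dcOffset = -0.25), solverOptions()),
    stop("unknown cached trace: ", key))
  .traceCache[[key]] <- tr
  tr
}

# a frozen-state transversal device: zero vacancy mobility, so the circuit
# reduces to a plain resistor of 3916 ohm
frozenHpConfig <- function() {
  circuitConfig(includeTransversal = TRUE,
                transversalParams = transversalParams(mobility = 0))
}

# wrap bare (t, v, i) arrays as a single-period trace for the geometry code
asLoopTrace <- function(t, v, i) {
  tr <- data.frame(t = t, v = v, i_tang = NA_real_, i_tran = NA_real_,
                   i_c = NA_real_, i_total = i, temperature = NA_real_,
                   x = NA_real_, g_tang = NA_real_, g_tran = NA_real_)
  class(tr) <- c("SimulationTrace", "data.frame")
  attr(tr, "samplesPerPeriod") <- length(t) - 1L
  attr(tr, "nPeriods") <- 1L
  tr
}

# independent brute-force oracle: all-pairs segment intersection of the
# closed polygon, O(n^2), used only on small downsampled loops
bruteForceIntersections <- function(xn, yn, closed = TRUE) {
  n <- length(xn)
  px <- if (closed) c(xn, xn[1]) else xn
  py <- if (closed) c(yn, yn[1]) else yn
  ns <- length(px) - 1L
  out <- NULL
  for (a in seq_len(ns - 1L)) {
    for (b in (a + 1L):ns) {
      sep <- min(b - a, if (closed) ns - (b - a) else Inf)
      if (sep < if (closed) 4L else 2L) next
      d1x <- px[a + 1] - px[a]; d1y <- py[a + 1] - py[a]
      d2x <- px[b + 1] - px[b]; d2y <- py[b + 1] - py[b]
      den <- d1x * d2y - d1y * d2x
      if (abs(den) < 1e-300) next
      ex <- px[b] - px[a]; ey <- py[b] - py[a]
      s <- (ex * d2y - ey * d2x) / den
      u <- (ex * d1y - ey * d1x) / den
      if (s >= -1e-9 && s <= 1 + 1e-9 && u >= -1e-9 && u <= 1 + 1e-9) {
        out <- rbind(out, c(a, b, px[a] + s * d1x, py[a] + s * d1y))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(segA = integer(0), segB = integer(0),
                      x = numeric(0), y = numeric(0)))
  }
  data.frame(segA = out[, 1], segB = out[, 2], x = out[, 3], y = out[, 4])
}
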