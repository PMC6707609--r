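#' @name recordings
#' @title Synthetic noisy voltage-current recordings
#' @description
#' Stand-ins for measured recordings of nonlinear tissue impedance: the
#' generator simulates one of three known parallel-circuit compositions
#' (transversal memristor + capacitor, tangential memristor + capacitor, or
#' both memristors + capacitor) and adds zero-mean Gaussian noise to the
#' current channel, so the loop-feature classifier can be exercised against
#' a known ground truth.  The voltage channel stays noise-free (ideal
#' source).
NULL

.recordingLabels <- c("transversal_dominated", "tangential_dominated",
                      "mixed", "unknown")

# memoised forward simulations: the trace underlying a recording depends
# only on (scenario, stimulus, capacitance, solver options), never the seed
.simCache <- new.env(parent = emptyenv())

.scenarioTrace <- function(label, stim, capacitance, options) {
  key <- paste(label, stim$amplitude, stim$frequency, stim$dcOffset,
               stim$nPeriods, capacitance, options$relTol, options$absTol,
               options$samplesPerPeriod, sep = "|")
  if (!is.null(.simCache[[key]])) return(.simCache[[key]])
  cfg <- switch(label,
    transversal_dominated = circuitConfig(includeTransversal = TRUE,
                                          capacitance = capacitance),
    tangential_dominated = circuitConfig(includeTangential = TRUE,
                                         capacitance = capacitance),
    mixed = circuitConfig(includeTangential = TRUE,
                          includeTransversal = TRUE,
                          capacitance = capacitance))
  tr <- simulateCircuit(cfg, stim, options)
  .simCache[[key]] <- tr
  tr
}

# run code with a locally seeded RNG, leaving the caller's RNG untouched
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic noisy recording with known ground truth
#'
#' Simulates the circuit matching the scenario label
#' (`"transversal_dominated"`: transversal memristor + capacitance;
#' `"tangential_dominated"`: tangential memristor + capacitance;
#' `"mixed"`: both memristors + capacitance; all with default device
#' parameters) and adds independent zero-mean Gaussian noise with standard
#' deviation `noiseLevel` times the peak current magnitude to the current
#' channel only.  Deterministic for a fixed
#' (scenario, stimulus, noise level, seed).
#'
#' @param label Scenario label, one of `"transversal_dominated"`,
#'   `"tangential_dominated"`, `"mixed"`.
#' @param stim A [stimulus()] object.
#' @param noiseLevel Noise standard deviation as a fraction of the peak
#'   current, in \[0, 0.2\].
#' @param seed Integer seed for the noise.
#' @param capacitance Parallel capacitance in farad.
#' @param options A [solverOptions()] object.
#' @return An object of class `"Recording"`: a data frame with columns `t`
#'   (s), `v` (V), `i` (A) and attributes `label`, `seed`, `noiseLevel`,
#'   `samplesPerPeriod`, `nPeriods`.
#' @export
#' @examples
#' rec <- generateRecording("tangential_dominated", noiseLevel = 0.01, seed = 1)
#' classifyRecording(rec)
generateRecording <- function(label, stim = stimulus(), noiseLevel = 0.01,
                              seed = 1L, capacitance = 60e-6,
                              options = solverOptions()) {
  if (!label %in% setdiff(.recordingLabels, "unknown")) {
    stop("unknown recording scenario: ", label)
  }
  stopifnot(noiseLevel >= 0, noiseLevel <= 0.2)
  tr <- .scenarioTrace(label, stim, capacitance, options)
  i <- tr$i_total
  if (noiseLevel > 0) {
    sdI <- noiseLevel * max(abs(i))
    i <- i + .withSeed(seed, stats::rnorm(length(i), 0, sdI))
  }
  structure(data.frame(t = tr$t, v = tr$v, i = i),
            class = c("Recording", "data.frame"),
            label = label, seed = as.integer(seed),
            noiseLevel = noiseLevel,
            samplesPerPeriod = attr(tr, "samplesPerPeriod"),
            nPeriods = attr(tr, "nPeriods"))
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("Recording: %d samples, label '%s', noise level %g, seed %s\n",
              nrow(x), attr(x, "label") %||% "unknown",
              attr(x, "noiseLevel") %||% NA, attr(x, "seed") %||% "-"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# estimate the signal period (in samples) from upward zero crossings of the
# clean voltage channel
.estimateSamplesPerPeriod <- function(t, v) {
  vc <- v - mean(v)
  up <- which(vc[-length(vc)] < 0 & vc[-1] >= 0)
  dn <- which(vc[-length(vc)] > 0 & vc[-1] <= 0)
  cross <- sort(c(up, dn))   # half-period spacing
  if (length(cross) < 2) stop("cannot estimate signal period from voltage")
  as.integer(round(2 * mean(diff(cross))))
}

# final full period of a recording as a 1-period pseudo-trace, with the
# current channel denoised by truncating its Fourier series
.recordingToTrace <- function(recording, nHarmonics = 25L) {
  spp <- attr(recording, "samplesPerPeriod")
  if (is.null(spp)) {
    spp <- .estimateSamplesPerPeriod(recording$t, recording$v)
  }
  n <- nrow(recording)
  if (n < spp + 1) stop("recording does not contain one full signal period")
  idx <- (n - spp):n
  t <- recording$t[idx]
  v <- recording$v[idx]
  i <- recording$i[idx]
  # harmonic truncation over the period (drop the duplicated endpoint)
  ip <- i[seq_len(spp)]
  co <- stats::fft(ip)
  keep <- c(seq_len(nHarmonics + 1L), (spp - nHarmonics + 1L):spp)
  co[setdiff(seq_len(spp), keep)] <- 0
  ism <- Re(stats::fft(co, inverse = TRUE)) / spp
  ism <- c(ism, ism[1])
  dt <- t[2] - t[1]
  dvdt <- c((v[2] - v[1]) / dt,
            (v[-(1:2)] - v[seq_len(spp + 1 - 2)]) / (2 * dt),
            (v[spp + 1] - v[spp]) / dt)
  trace <- data.frame(t = t, v = v, i_tang = NA_real_, i_tran = NA_real_,
                      i_c = NA_real_, i_total = ism,
                      temperature = NA_real_, x = NA_real_,
                      g_tang = NA_real_, g_tran = NA_real_, dvdt = dvdt)
  structure(trace, class = c("SimulationTrace", "data.frame"),
            samplesPerPeriod = spp, nPeriods = 1L)
}

#' Classify a recording by its pinched-hysteresis-loop morphology
#'
#' Extracts loop features from the final full period of the recording
#' (the current channel is first denoised by Fourier-series truncation;
#' dv/dt is recovered by central differences) and applies the decision
#' rule distilled from the circuit simulations: two pinch points mean the
#' tangential branch shapes the loop, with strong origin asymmetry
#' indicating that the transversal branch contributes as well (mixed); a
#' single pinch displaced from the origin indicates a dominating
#' transversal memristor in parallel with a capacitance; a single origin
#' pinch is resolved by lobe asymmetry and branch-slope classification.
#'
#' @param recording A `"Recording"` (from [generateRecording()] or
#'   [readRecording()]).
#' @param tol A [loopTolerances()] object.
#' @return One of `"transversal_dominated"`, `"tangential_dominated"`,
#'   `"mixed"`, `"unknown"`.
#' @export
classifyRecording <- function(recording, tol = loopTolerances()) {
  ptrace <- .recordingToTrace(recording)
  pp <- detectPinchPoints(ptrace, 1L, tol)
  if (length(pp) == 0) return("unknown")
  if (length(pp) >= 2) {
    # a tangential memristor + capacitance yields a pinch pair mapped onto
    # itself by (v, i) -> (-v, -i); a contribution from the transversal
    # branch breaks that point symmetry of the pinch set
    loop <- .loopPolyline(ptrace, 1L)
    px <- vapply(pp, `[[`, numeric(1), "v") / loop$sv
    py <- vapply(pp, `[[`, numeric(1), "i") / loop$si
    scale <- max(sqrt(px^2 + py^2), 0.05)
    mismatch <- max(vapply(seq_along(px), function(k) {
      min(sqrt((px[k] + px)^2 + (py[k] + py)^2))
    }, numeric(1))) / scale
    if (mismatch >= 0.3) return("mixed")
    score <- originSymmetryScore(ptrace, 1L)
    return(if (score < tol$asymmetryTol) "tangential_dominated" else "mixed")
  }
  p <- pp[[1]]
  if (p$distance > tol$pinchClusterRadius) return("transversal_dominated")
  la <- lobeAreas(ptrace, 1L)
  if (la["q3"] > 0 && la["q1"] / la["q3"] > 3) return("mixed")
  cls <- tryCatch(classifyPinch(p, tol), error = function(e) NA_character_)
  if (is.na(cls)) return("unknown")
  if (cls == "tangential") "tangential_dominated" else "transversal_dominated"
}

#' Write a recording to delimited text
#'
#' CSV with columns `t_s, v_V, i_A` at full double precision and a JSON
#' sidecar (`<path>.meta.json`) carrying the label, seed and noise level.
#'
#' @param recording A `"Recording"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path) {
  d <- data.frame(t_s = .fmtNum(recording$t), v_V = .fmtNum(recording$v),
                  i_A = .fmtNum(recording$i))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  meta <- list(label = attr(recording, "label") %||% "unknown",
               seed = attr(recording, "seed"),
               noise_level = attr(recording, "noiseLevel"),
               samples_per_period = attr(recording, "samplesPerPeriod"),
               n_periods = attr(recording, "nPeriods"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording written by [writeRecording()] or from external data
#'
#' @param path CSV path with columns `t_s, v_V, i_A`; a `<path>.meta.json`
#'   sidecar is honoured when present.  The time grid must be uniform and
#'   strictly increasing.  Without a sidecar the label defaults to
#'   `"unknown"`.
#' @return A `"Recording"`.
#' @export
readRecording <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_s", "v_V", "i_A")
  if (!all(need %in% names(d))) {
    stop("recording file is missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  dt <- diff(d$t_s)
  if (length(dt) == 0 || any(dt <= 0) ||
      diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("recording time grid must be uniform and strictly increasing")
  }
  rec <- structure(data.frame(t = d$t_s, v = d$v_V, i = d$i_A),
                   class = c("Recording", "data.frame"),
                   label = "unknown")
  metaPath <- paste0(path, ".meta.json")
  if (file.exists(metaPath)) {
    m <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    attr(rec, "label") <- m$label %||% "unknown"
    attr(rec, "seed") <- m$seed
    attr(rec, "noiseLevel") <- m$noise_level
    attr(rec, "samplesPerPeriod") <- m$samples_per_period
    attr(rec, "nPeriods") <- m$n_periods
  }
  rec
}
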