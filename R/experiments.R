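#' Define a named simulation scenario
#'
#' A scenario bundles one or more sub-runs (circuit configuration plus
#' stimulus) under a unique name, together with the solver options and
#' feature tolerances used when it is run.
#'
#' @param name Unique scenario name.
#' @param description One-line description.
#' @param subRuns Named list; each element is a list with components
#'   `config` (a [circuitConfig()]) and `stim` (a [stimulus()]).
#' @param options A [solverOptions()] object.
#' @param tol A [loopTolerances()] object.
#' @return An object of class `"Scenario"`.
#' @export
scenario <- function(name, description = "", subRuns,
                     options = solverOptions(), tol = loopTolerances()) {
  stopifnot(is.character(name), length(name) == 1, length(subRuns) >= 1,
            !is.null(names(subRuns)), all(nzchar(names(subRuns))))
  structure(list(name = name, description = description, subRuns = subRuns,
                 options = options, tol = tol), class = "Scenario")
}

.singleRun <- function(tangential, transversal, capacitance = 0,
                       amplitude = 4.5, frequency = 0.025, dcOffset = 0) {
  list(config = circuitConfig(includeTangential = tangential,
                              includeTransversal = transversal,
                              capacitance = capacitance),
       stim = stimulus(amplitude = amplitude, frequency = frequency,
                       dcOffset = dcOffset, nPeriods = 2L))
}

#' Default scenario registry
#'
#' The registry of named, reproducible simulation scenarios covering the
#' reference study conditions: each single memristor model alone, the
#' sign-flipped and DC-offset drives, the capacitance and frequency sweeps
#' of the single models with a parallel capacitor, and the two-memristor
#' combinations with and without a capacitor.  All scenarios use a 4.5 V
#' amplitude (unless overridden), two signal periods, and initial states
#' x = 0.76 and T = 300 K.
#'
#' @return A named list of `"Scenario"` objects.
#' @export
#' @examples
#' names(scenarioRegistry())
scenarioRegistry <- function() {
  reg <- list(
    scenario("fig2_tangential",
             "tangential (NTC) memristor alone, 4.5 V at 0.025 Hz",
             list(tangential = .singleRun(TRUE, FALSE))),
    scenario("fig2_transversal",
             "transversal (HP) memristor alone, 4.5 V at 0.025 Hz",
             list(transversal = .singleRun(FALSE, TRUE))),
    scenario("s1_negative_amplitude",
             "both single models driven with amplitude -4.5 V",
             list(tangential = .singleRun(TRUE, FALSE, amplitude = -4.5),
                  transversal = .singleRun(FALSE, TRUE, amplitude = -4.5))),
    scenario("s2_dc_offset",
             "both single models driven with a -0.25 V DC offset",
             list(tangential = .singleRun(TRUE, FALSE, dcOffset = -0.25),
                  transversal = .singleRun(FALSE, TRUE, dcOffset = -0.25))),
    scenario("fig3a_capacitance_sweep",
             "each single model + C in {60, 120, 240} uF at 0.025 Hz",
             {
               runs <- list()
               for (C in c(60e-6, 120e-6, 240e-6)) {
                 lab <- sprintf("C%guF", C * 1e6)
                 runs[[paste0("tangential_", lab)]] <-
                   .singleRun(TRUE, FALSE, capacitance = C)
                 runs[[paste0("transversal_", lab)]] <-
                   .singleRun(FALSE, TRUE, capacitance = C)
               }
               runs
             }),
    scenario("fig3b_frequency_sweep",
             "each single model + 60 uF at f in {0.025, 0.05, 0.1} Hz",
             {
               runs <- list()
               for (f in c(0.025, 0.05, 0.1)) {
                 lab <- sprintf("f%gHz", f)
                 runs[[paste0("tangential_", lab)]] <-
                   .singleRun(TRUE, FALSE, capacitance = 60e-6, frequency = f)
                 runs[[paste0("transversal_", lab)]] <-
                   .singleRun(FALSE, TRUE, capacitance = 60e-6, frequency = f)
               }
               runs
             }),
    scenario("fig4a_both_memristors",
             "both memristors in parallel, f in {0.025, 0.05, 0.1} Hz",
             {
               runs <- list()
               for (f in c(0.025, 0.05, 0.1)) {
                 runs[[sprintf("f%gHz", f)]] <-
                   .singleRun(TRUE, TRUE, frequency = f)
               }
               runs
             }),
    scenario("fig4b_both_plus_capacitance",
             "both memristors + 60 uF, f in {0.025, 0.05, 0.1} Hz",
             {
               runs <- list()
               for (f in c(0.025, 0.05, 0.1)) {
                 runs[[sprintf("f%gHz", f)]] <-
                   .singleRun(TRUE, TRUE, capacitance = 60e-6, frequency = f)
               }
               runs
             }))
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  reg
}

#' Add a scenario to a registry
#'
#' @param registry A registry list (see [scenarioRegistry()]).
#' @param scen A `"Scenario"`; its name must not already be registered.
#' @return The extended registry.
#' @export
registerScenario <- function(registry, scen) {
  stopifnot(inherits(scen, "Scenario"))
  if (scen$name %in% names(registry)) {
    stop("scenario name already registered: ", scen$name)
  }
  registry[[scen$name]] <- scen
  registry
}

#' List available scenarios
#'
#' @param registry A registry list.
#' @param filter Optional substring; only matching names are listed (an
#'   empty string lists everything).
#' @return Invisibly, the matching scenario names; prints a table of names,
#'   descriptions and sub-run counts.
#' @export
listScenarios <- function(registry = scenarioRegistry(), filter = "") {
  nm <- names(registry)
  if (nzchar(filter)) nm <- nm[grepl(filter, nm, fixed = TRUE)]
  for (n in nm) {
    cat(sprintf("%-28s %2d run(s)  %s\n", n, length(registry[[n]]$subRuns),
                registry[[n]]$description))
  }
  invisible(nm)
}

#' Run a named scenario and write its outputs
#'
#' Simulates every sub-run of the scenario and writes, per sub-run, a
#' trace CSV (`<scenario>_<run>.csv`, with JSON metadata sidecar) and a
#' loop-feature summary (`<scenario>_<run>_features.json`) computed on the
#' final simulated period.  The forward simulations contain no stochastic
#' elements, so re-running a scenario reproduces its outputs exactly.
#'
#' @param name Scenario name (must be in the registry).
#' @param outputDir Directory for the output files (created if missing).
#' @param registry A registry list.
#' @param options Optional [solverOptions()] override.
#' @param quiet Suppress the per-run progress lines.
#' @return Invisibly, a named list of `"LoopFeatures"`, one per sub-run.
#' @export
runScenario <- function(name, outputDir = ".",
                        registry = scenarioRegistry(),
                        options = NULL, quiet = FALSE) {
  if (!name %in% names(registry)) {
    stop("unknown scenario: ", name, " (see listScenarios())")
  }
  scen <- registry[[name]]
  opts <- options %||% scen$options
  if (!dir.exists(outputDir)) {
    ok <- dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outputDir)
  }
  out <- list()
  for (runName in names(scen$subRuns)) {
    run <- scen$subRuns[[runName]]
    tr <- simulateCircuit(run$config, run$stim, opts)
    base <- file.path(outputDir, paste0(name, "_", runName))
    writeTrace(tr, paste0(base, ".csv"))
    feats <- loopFeatures(tr, tol = scen$tol)
    writeFeatures(feats, paste0(base, "_features.json"))
    if (!quiet) {
      message(sprintf("%s/%s: %d pinch point(s) [%s], symmetry %.3g",
                      name, runName, feats$pinchCount, feats$pinchClass,
                      feats$originSymmetryScore))
    }
    out[[runName]] <- feats
  }
  invisible(out)
}
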