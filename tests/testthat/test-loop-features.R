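# Loop geometry: pinch detection and classification, orientation, lobe
# areas, symmetry, extrema, lags, drift, phase angles.

test_that("pinch detection agrees with a brute-force intersection oracle", {
  for (key in c("ntc_c60", "hp_c60", "both")) {
    tr <- cachedTrace(key)
    loop <- pinchloop:::.loopPolyline(tr, 2)
    # downsample the period polyline to <= 200 points
    pick <- unique(c(seq(1, length(loop$v), by = 25), length(loop$v)))
    xn <- loop$v[pick] / loop$sv
    yn <- loop$i[pick] / loop$si
    fast <- pinchloop:::.segIntersections(xn, yn, closed = TRUE)
    slow <- bruteForceIntersections(xn, yn, closed = TRUE)
    ordF <- order(fast$segA, fast$segB)
    ordS <- order(slow$segA, slow$segB)
    expect_equal(fast$segA[ordF], slow$segA[ordS])
    expect_equal(fast$segB[ordF], slow$segB[ordS])
    expect_equal(fast$x[ordF], slow$x[ordS], tolerance = 1e-12)
    expect_equal(fast$y[ordF], slow$y[ordS], tolerance = 1e-12)
  }
})

test_that("single memristor models pinch once at the origin with their class", {
  ppN <- detectPinchPoints(cachedTrace("ntc"))
  expect_length(ppN, 1)
  expect_lt(ppN[[1]]$distance, 0.01)
  expect_equal(classifyPinch(ppN[[1]]), "tangential")
  ppH <- detectPinchPoints(cachedTrace("hp"))
  expect_length(ppH, 1)
  expect_lt(ppH[[1]]$distance, 0.01)
  expect_equal(classifyPinch(ppH[[1]]), "transversal")
})

test_that("a parallel capacitance splits or shifts the pinch as expected", {
  # tangential + C: two pinch points, mapped onto each other by the double
  # flip (v, i) -> (-v, -i)
  pp <- detectPinchPoints(cachedTrace("ntc_c60"))
  expect_length(pp, 2)
  loop <- pinchloop:::.loopPolyline(cachedTrace("ntc_c60"), 2)
  mirrored <- sqrt(((pp[[1]]$v + pp[[2]]$v) / loop$sv)^2 +
                     ((pp[[1]]$i + pp[[2]]$i) / loop$si)^2)
  expect_lt(mirrored, 0.01)
  # transversal + C: one pinch, displaced from the origin
  ppH <- detectPinchPoints(cachedTrace("hp_c60"))
  expect_length(ppH, 1)
  expect_gt(ppH[[1]]$distance, 0.01)
})

test_that("degenerate loops yield no pinch points", {
  tr <- simulateCircuit(frozenHpConfig(), stimulus(),
                        solverOptions(samplesPerPeriod = 1000))
  expect_length(detectPinchPoints(tr), 0)
})

test_that("pinch classification uses relative slope equality", {
  mk <- function(s1, s2) structure(list(v = 0, i = 0, slopeBranch1 = s1,
                                        slopeBranch2 = s2, distance = 0),
                                   class = "PinchPoint")
  expect_equal(classifyPinch(mk(1e-3, 1e-3)), "tangential")
  expect_equal(classifyPinch(mk(1e-3, 1.05e-3)), "tangential")
  expect_equal(classifyPinch(mk(1e-3, 2e-3)), "transversal")
  expect_error(classifyPinch(mk(0, 0)), "undefined")
  expect_error(classifyPinch(mk(NaN, 1)), "finite")
})

test_that("quadrant orientations match the loop fingerprints", {
  trH <- cachedTrace("hp")
  expect_equal(quadrantOrientation(trH, quadrant = 1), "ccw")
  expect_equal(quadrantOrientation(trH, quadrant = 3), "cw")
  trN <- cachedTrace("ntc")
  expect_equal(quadrantOrientation(trN, quadrant = 1), "ccw")
  expect_equal(quadrantOrientation(trN, quadrant = 3), "ccw")
})

test_that("orientation flips when the traversal direction is reversed", {
  for (key in c("ntc", "hp")) {
    tr <- cachedTrace(key)
    idx <- pinchloop:::.periodIndices(tr, 2)
    rev_tr <- asLoopTrace(tr$t[idx], rev(tr$v[idx]), rev(tr$i_total[idx]))
    for (q in c(1, 3)) {
      fwd <- quadrantOrientation(tr, 2, q)
      bwd <- quadrantOrientation(rev_tr, 1, q)
      expect_equal(bwd, setNames(c(cw = "ccw", ccw = "cw")[fwd], NULL))
    }
  }
})

test_that("lobe areas partition the loop area at the axis crossings", {
  for (key in c("ntc", "hp", "both")) {
    tr <- cachedTrace(key)
    la <- lobeAreas(tr)
    expect_true(all(la >= 0))
    # independent oracle: walk the axis-refined polygon, accumulate the
    # shoelace area of every maximal run with constant quadrant membership
    loop <- pinchloop:::.loopPolyline(tr, 2)
    ref <- pinchloop:::.axisRefine(loop$v, loop$i, closed = TRUE)
    m <- pinchloop:::.quadrantOf(ref$x, ref$y)
    shoe <- function(xs, ys) {
      sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys) / 2
    }
    total <- 0
    start <- which(m != m[1])[1]
    ord <- c(start:length(m), seq_len(start - 1L))
    xs <- ref$x[ord]; ys <- ref$y[ord]; ms <- m[ord]
    r <- rle(ms)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0) next
      a <- max(1L, starts[k] - 1L); b <- min(length(ms), ends[k] + 1L)
      total <- total + abs(shoe(xs[a:b], ys[a:b]))
    }
    expect_equal(sum(la), total, tolerance = 1e-6)
  }
})

test_that("tangential lobes are balanced; the combination is lopsided", {
  laN <- lobeAreas(cachedTrace("ntc"))
  expect_equal(unname(laN["q1"] / laN["q3"]), 1, tolerance = 0.05)
  laB <- lobeAreas(cachedTrace("both"))
  expect_gt(laB["q1"], laB["q3"])
  laF <- lobeAreas(simulateCircuit(frozenHpConfig(), stimulus(),
                                   solverOptions(samplesPerPeriod = 1000)))
  expect_lt(max(laF), 1e-12)
})

test_that("origin-symmetry score is exact on closed-form shapes", {
  th <- seq(0, 2 * pi, length.out = 2001)
  sym <- asLoopTrace(th, sin(th), cos(th))
  expect_lt(originSymmetryScore(sym, 1), 1e-9)
  # ellipse shifted upward by a fraction d of its current scale: the worst
  # flipped point sits 2d from the loop, normalised by (1 + d)
  d <- 0.1
  shifted <- asLoopTrace(th, sin(th), cos(th) + d)
  expect_equal(originSymmetryScore(shifted, 1), 2 * d / (1 + d),
               tolerance = 1e-6)
  # simulated loops: tangential + C is symmetric, the combination is not
  expect_lt(originSymmetryScore(cachedTrace("ntc_c60")), 0.02)
  expect_gt(originSymmetryScore(cachedTrace("both")), 0.05)
})

test_that("memductance extrema land where the state dynamics put them", {
  trN <- cachedTrace("ntc")
  ex <- memductanceExtrema(trN, 2, "tangential")
  expect_equal(nrow(ex), 2)
  tp <- 40
  t0 <- trN$t[pinchloop:::.periodIndices(trN, 2)[1]]
  expect_lt(abs((ex$time[1] - t0) - 0.25 * tp), 0.1 * tp)
  expect_lt(abs((ex$time[2] - t0) - 0.75 * tp), 0.1 * tp)
  trH <- cachedTrace("hp")
  exH <- memductanceExtrema(trH, 2, "transversal")
  expect_equal(nrow(exH), 1)
  # the single maximum comes after the positive half of the period starts,
  # at or just past its end
  expect_gt(exH$time[1] - 40, 0)
  expect_lt(abs(exH$time[1] - 60), 0.05 * tp)
  # constant memductance: one degenerate maximum at the period start
  trF <- simulateCircuit(frozenHpConfig(), stimulus(),
                         solverOptions(samplesPerPeriod = 1000))
  exF <- memductanceExtrema(trF, 2, "transversal")
  expect_equal(nrow(exF), 1)
  expect_equal(exF$time, trF$t[pinchloop:::.periodIndices(trF, 2)[1]])
  expect_error(memductanceExtrema(trF, 2, "tangential"), "not active")
})

test_that("current peaks lag or lead the voltage peaks by model type", {
  lagN <- currentPeakLag(cachedTrace("ntc"))
  expect_gt(lagN$lagMax, 0)
  expect_gt(lagN$lagMin, 0)
  lagH <- currentPeakLag(cachedTrace("hp"))
  expect_gt(lagH$lagMax, 0)
  expect_lt(lagH$lagMin, 0)
  trF <- simulateCircuit(frozenHpConfig(), stimulus(),
                         solverOptions(samplesPerPeriod = 1000))
  lagF <- currentPeakLag(trF)
  dt <- trF$t[2] - trF$t[1]
  expect_lte(abs(lagF$lagMax), dt)
  expect_lte(abs(lagF$lagMin), dt)
})

test_that("per-period drift flags the DC-offset asymmetry between models", {
  dH <- perPeriodDrift(cachedTrace("hp_offset"))
  expect_true(all(abs(dH$x) > 1e-3))
  dN <- perPeriodDrift(cachedTrace("ntc_offset"))
  trN <- cachedTrace("ntc_offset")
  swing <- diff(range(trN$temperature[pinchloop:::.periodIndices(trN, 2)]))
  expect_lt(abs(dN$temperature[2]) / swing, 1e-3)
  dH0 <- perPeriodDrift(cachedTrace("hp"))
  expect_true(all(abs(dH0$x) < 1e-4))
  expect_error(perPeriodDrift(simulateCircuit(ntcConfig(),
                                              stimulus(nPeriods = 1L),
                                              solverOptions(samplesPerPeriod = 1000))),
               "at least 2")
})

test_that("phase-angle range follows the conductance extrema", {
  # no capacitance: no phase shift at all
  ph0 <- phaseAngleRange(cachedTrace("ntc"))
  expect_equal(ph0$alphaMin, 0)
  expect_equal(ph0$alphaMax, 0)
  # constant conductance: both extremes collapse to the closed form
  trF <- simulateCircuit(circuitConfig(includeTransversal = TRUE,
                                       capacitance = 60e-6,
                                       transversalParams = transversalParams(mobility = 0)),
                         stimulus(), solverOptions(samplesPerPeriod = 1000))
  phF <- phaseAngleRange(trF)
  aExp <- atan(2 * pi * 0.025 * 60e-6 * 3916) * 180 / pi
  expect_equal(phF$alphaMin, aExp, tolerance = 1e-9)
  expect_equal(phF$alphaMax, aExp, tolerance = 1e-9)
  # closed-form reference at the starting conductance of the NTC model
  aN <- atan(2 * pi * 0.025 * 60e-6 / (1 / 3890)) * 180 / pi
  expect_equal(aN, 2.0997, tolerance = 1e-4)
  # halving G at fixed f and C strictly increases alpha
  expect_gt(atan(9.4248e-6 / (2.5707e-4 / 2)), atan(9.4248e-6 / 2.5707e-4))
  ph <- phaseAngleRange(cachedTrace("ntc_c60"))
  expect_lte(ph$alphaMin, ph$alphaMax)
  expect_error(phaseAngleRange(cachedTrace("both_c60")), "single-memristor")
})

test_that("equal susceptance at different frequencies is not equal physics", {
  # 0.05 Hz with 60 uF has the same B = 2 pi f C as 0.025 Hz with 120 uF,
  # but the faster drive allows less state change, so the conductance
  # extrema and hence the phase ranges differ
  trA <- simulateCircuit(ntcConfig(60e-6), stimulus(frequency = 0.05),
                         solverOptions(samplesPerPeriod = 1000))
  trB <- simulateCircuit(ntcConfig(120e-6), stimulus(frequency = 0.025),
                         solverOptions(samplesPerPeriod = 1000))
  bA <- 2 * pi * 0.05 * 60e-6
  bB <- 2 * pi * 0.025 * 120e-6
  expect_equal(bA, bB, tolerance = 1e-12)
  phA <- phaseAngleRange(trA)
  phB <- phaseAngleRange(trB)
  expect_gt(abs(phA$alphaMax - phB$alphaMax), 1e-3)
  gA <- range(trA$g_tang[pinchloop:::.periodIndices(trA, 2)])
  gB <- range(trB$g_tang[pinchloop:::.periodIndices(trB, 2)])
  expect_lt(diff(gA), diff(gB))  # less state change at higher frequency
})

test_that("pinch detection on a loop plus its flipped copy is symmetric", {
  tr <- cachedTrace("hp_c60")
  idx <- pinchloop:::.periodIndices(tr, 2)
  flipped <- asLoopTrace(tr$t[idx], -tr$v[idx], -tr$i_total[idx])
  pp <- detectPinchPoints(tr, 2)
  ppF <- detectPinchPoints(flipped, 1)
  expect_length(ppF, length(pp))
  expect_equal(ppF[[1]]$v, -pp[[1]]$v, tolerance = 1e-6)
  expect_equal(ppF[[1]]$i, -pp[[1]]$i, tolerance = 1e-6)
})
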