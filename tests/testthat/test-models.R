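# Constitutive relations of the two memristor models, the capacitor branch,
# and the composite parallel circuit.

test_that("tangential conductance follows the NTC characteristic", {
  p <- tangentialParams()
  # at the reference temperature the exponent vanishes: G = 1/r0
  expect_identical(tangentialConductance(300, p), 1 / 3890)
  # printed headline value: ~260 uS at simulation start (2 significant figures)
  expect_equal(signif(tangentialConductance(300, p) * 1e6, 2), 260)
  # closed-form evaluation one kelvin above ambient
  expect_equal(tangentialConductance(301, p),
               1 / (3890 * exp(5e5 * (1 / 301 - 1 / 300))),
               tolerance = 1e-12)
  expect_equal(tangentialConductance(301, p), 6.529e-2, tolerance = 1e-3)
  # strictly increasing in temperature
  grid <- seq(250, 350, by = 0.5)
  expect_true(all(diff(tangentialConductance(grid, p)) > 0))
  expect_error(tangentialConductance(-1, p), "positive")
})

test_that("tangential temperature rate balances dissipation and Joule heating", {
  p <- tangentialParams()
  expect_identical(tangentialStateDerivative(300, 0, p), 0)
  expect_equal(tangentialStateDerivative(300, 4.5, p),
               (1 / 3890) * 4.5^2 / 0.14, tolerance = 1e-12)
  expect_equal(tangentialStateDerivative(310, 0, p), (0.1 / 0.14) * (300 - 310),
               tolerance = 1e-12)
  # invariant under a voltage sign flip (depends on v only through v^2)
  for (Tk in c(295, 300, 305, 320)) {
    for (v in c(0.1, 1, 4.5, 10)) {
      expect_identical(tangentialStateDerivative(Tk, v, p),
                       tangentialStateDerivative(Tk, -v, p))
    }
  }
})

test_that("transversal memristance mixes the layer resistances linearly", {
  p <- transversalParams()
  expect_identical(transversalMemristance(1, p), 100)
  expect_identical(transversalMemristance(0, p), 16000)
  expect_equal(transversalMemristance(0.76, p), 3916)
  # affine in x: second differences vanish on any grid
  xs <- seq(0, 1, by = 0.05)
  expect_equal(max(abs(diff(diff(transversalMemristance(xs, p))))), 0)
  expect_true(all(diff(transversalMemristance(xs, p)) < 0))
  expect_error(transversalMemristance(1.2, p), "\\[0, 1\\]")
  expect_error(transversalMemristance(-0.1, p), "\\[0, 1\\]")
})

test_that("transversal state rate is current-driven and clamped at the bounds", {
  p <- transversalParams()
  expect_identical(transversalStateDerivative(0.5, 0, p), 0)
  expect_equal(transversalStateDerivative(0.76, 4.5, p),
               (1e-14 * 100 / 1e-16) * 5e-4 * (4.5 / 3916), tolerance = 1e-12)
  expect_equal(transversalStateDerivative(0.76, 4.5, p), 5.7456e-3,
               tolerance = 1e-4)
  # hard clamp: outward-pushing rates at the boundaries are exactly zero,
  # inward ones are not
  expect_identical(transversalStateDerivative(1, 4.5, p), 0)
  expect_identical(transversalStateDerivative(0, -4.5, p), 0)
  expect_lt(transversalStateDerivative(1, -4.5, p), 0)
  expect_gt(transversalStateDerivative(0, 4.5, p), 0)
  # interior sign follows the voltage sign
  for (x in c(0.1, 0.5, 0.9)) {
    expect_gt(transversalStateDerivative(x, 2, p), 0)
    expect_lt(transversalStateDerivative(x, -2, p), 0)
  }
})

test_that("capacitor current is C dv/dt", {
  expect_identical(capacitorCurrent(123, 0), 0)
  expect_identical(capacitorCurrent(0, 60e-6), 0)
  expect_equal(capacitorCurrent(2 * pi * 0.025 * 4.5, 60e-6), 4.2412e-5,
               tolerance = 1e-4)
  expect_error(capacitorCurrent(1, -1e-6))
})

test_that("total current sums the active branch currents exactly", {
  cfg <- bothConfig()
  z <- totalCurrent(0, 0, temperature = 300, x = 0.76, config = cfg)
  expect_identical(unlist(z), c(iTang = 0, iTran = 0, iC = 0, iTotal = 0))
  r <- totalCurrent(4.5, 0, temperature = 300, x = 0.76, config = cfg)
  expect_equal(r$iTotal, 4.5 / 3890 + 4.5 / 3916, tolerance = 1e-12)
  # single-branch identity: capacitor only
  cc <- circuitConfig(capacitance = 60e-6)
  expect_identical(totalCurrent(3, 1, config = cc)$iTotal, 6e-5)
  # component-sum invariant over randomised operating points
  set.seed(42)
  for (k in 1:25) {
    v <- runif(1, -5, 5); dv <- runif(1, -1, 1)
    Tk <- runif(1, 295, 310); x <- runif(1)
    cfgk <- circuitConfig(includeTangential = TRUE, includeTransversal = TRUE,
                          capacitance = runif(1, 0, 3e-4))
    r <- totalCurrent(v, dv, Tk, x, cfgk)
    expect_identical(r$iTotal, r$iTang + r$iTran + r$iC)
    # inactive branches contribute exactly zero
    rt <- totalCurrent(v, dv, Tk, x, ntcConfig())
    expect_identical(rt$iTran, 0)
  }
})

test_that("small-signal admittance combines branch conductances and susceptance", {
  cfg <- circuitConfig(includeTangential = TRUE, includeTransversal = TRUE,
                       capacitance = 60e-6)
  y <- circuitAdmittance(x = 0.76, temperature = 300, frequency = 0.025,
                         config = cfg)
  expect_equal(y$conductanceReal, 1 / 3890 + 1 / 3916, tolerance = 1e-12)
  expect_equal(y$susceptance, 2 * pi * 0.025 * 60e-6, tolerance = 1e-12)
  expect_identical(y$susceptance, y$angularFrequency * cfg$capacitance)
  # C = 0 removes the susceptance; a single branch reduces to its conductance
  y0 <- circuitAdmittance(x = 0.5, temperature = 300, frequency = 1,
                          config = bothConfig())
  expect_identical(y0$susceptance, 0)
  yt <- circuitAdmittance(temperature = 300, frequency = 0.025,
                          config = ntcConfig())
  expect_identical(yt$conductanceReal, 1 / 3890)
})

test_that("parameter and configuration invariants are enforced", {
  expect_error(tangentialParams(r0 = -1))
  expect_error(transversalParams(rOn = 200, rOff = 100))
  expect_error(circuitConfig(), "at least one branch")
  expect_error(circuitConfig(includeTangential = TRUE, initialX = 1.5))
  expect_s3_class(circuitConfig(capacitance = 1e-6), "CircuitConfig")
})
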