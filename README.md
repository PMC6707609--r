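# pinchloop

Simulation and quantitative feature extraction for the pinched hysteresis
loops of parallel memristor–capacitor circuits.

## What this is for

Nonlinear bioimpedance measurements — human skin is the motivating case —
produce voltage–current loops that are *pinched*: the two branches of the
closed V–I trajectory meet at a point.  Skin combines two memristive
conduction pathways (electro-osmotic sweat-duct conduction, behaving like a
**transversal** memristor whose branches cross the pinch with different
slopes, and the temperature-dependent stratum corneum, behaving like a
**tangential** memristor whose branches touch with equal slopes) with a
parallel capacitance that distorts the recorded loops.  `pinchloop` lets you
simulate that three-branch circuit and *quantify* the resulting loop
morphology, so qualitative statements ("the pinch splits in two", "the loop
is asymmetric") become reproducible numbers.

## The models

Tangential branch — a self-heating NTC thermistor with temperature state
*T*:

    G(T)  = [ R0 · exp(β (1/T − 1/T0)) ]^(−1)
    dT/dt = δ/Hc · (T0 − T) + G(T)/Hc · v²

with R0 = 3.89 kΩ, T0 = 300 K, β = 5·10⁵ K, δ = 0.1 W/K, Hc = 0.14 J/K.

Transversal branch — the HP linear-drift memristor with normalised
doped-layer extension *x* ∈ [0, 1]:

    M(x)  = Ron·x + Roff·(1 − x)
    dx/dt = μv·Ron/D² · i_tran · s

with Ron = 0.1 kΩ, Roff = 16 kΩ, D = 10 nm, μv = 10⁻¹⁴ m²/(sV) and the
slowdown factor s = 5·10⁻⁴.  All branches share an ideal sinusoidal source
(canonically 4.5 V at 0.025 Hz, two periods; initial states T = 300 K,
x = 0.76) and the total current is

    i = v·G_tang(T) + v·G_tran(x) + C·dv/dt.

The ODEs are integrated with an adaptive Runge–Kutta–Fehlberg 4(5) scheme;
loop features (pinch detection/classification, quadrant orientation, lobe
areas, origin symmetry, memductance extrema, peak lags, per-period drift,
phase-angle ranges α = arctan(2πfC/G)) are computed from the uniformly
sampled traces.

## Worked example

```r
library(pinchloop)

# tangential memristor with a 60 uF capacitance in parallel
cfg <- circuitConfig(includeTangential = TRUE, capacitance = 60e-6)
tr  <- simulateCircuit(cfg, stimulus(amplitude = 4.5, frequency = 0.025))
loopFeatures(tr)
#> LoopFeatures (period 2)
#>   pinch points: 2 (transversal)
#>    PinchPoint at (-2.115 V, -0.0006 A), branch slopes 0.0002816 / 0.0003676 A/V (norm. dist 0.5902)
#>    PinchPoint at (2.115 V, 0.0006 A), branch slopes 0.0002816 / 0.0003676 A/V (norm. dist 0.5902)
#>   orientation: Q1 ccw, Q3 ccw
#>   lobe areas (V*A): q1=0.000168 q2=6.52e-09 q3=0.000168 q4=6.52e-09
#>   origin symmetry score: 3.362e-13
#>   phase range: 1.41 to 2.07 deg
#>   current peak lag: max +0.8 s, min +0.8 s
```

Read: the parallel capacitance has split the single tangential pinch into
**two** pinch points at ±(2.115 V, 0.6 mA), mapped onto each other by the
double flip (v, i) → (−v, −i) — the loop is origin-symmetric to 3·10⁻¹³.
The state-dependent phase shift ranges from 1.41° (at the period's maximum
conductance) to 2.07° (at its minimum).

Every simulation of the study is packaged as a named scenario:

```r
listScenarios()            # 8 scenarios: single models, sign flip, DC offset,
                           # C sweep, f sweep, two-model combinations
runScenario("fig3a_capacitance_sweep", "out/")  # trace CSVs + feature JSONs
```

Synthetic noisy recordings with known ground truth exercise the classifier:

```r
rec <- generateRecording("mixed", noiseLevel = 0.05, seed = 1)
classifyRecording(rec)
#> [1] "mixed"
```

A thin command-line front end over these functions ships in
`inst/scripts/pinchloop.R` (`run`, `list`, `simulate`, `features`, `synth`,
`classify`).

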