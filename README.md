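# poolage

Physics-based dating of human blood pools from photographs of the
drying front.

## The problem

After a bloodshed event a pool of blood dries on the floor. A dark,
desiccated rim forms at the edge and a *drying front* — the visible
boundary between wet (red) and dried (black) blood — recedes towards the
centre. When no body is present at a scene, classical methods for
placing events in time (body temperature, rigor mortis, entomology) do
not apply, and the time at which the pool was formed becomes the missing
piece of the timeline. `poolage` implements a quantitative estimator of
that time-since-deposition, aimed at bloodstain-pattern analysts and at
researchers studying the drying physics of biofluid pools: the only
required field measurement is a calibrated photograph.

## The model

A blood pool is intermediate between a sessile drop and an open liquid
surface: gravity flattens it into a pancake of mean height *h*, but
evaporation at the triple line still depends on its outline. The package
composes the following stages (all units SI):

- geometry: `V = m_i / ρ`, `h = V / A`, shape factor `L* = A / (h P)`,
  contact angle `θ = arccos(1 − g m_i² / (2 γ ρ A_i²))`;
- evaporation: Knudsen layer `L_k = k T / (π d² P_a)`, saturation
  vapour pressure `P_w(T)` (Buck correlation), and the
  diffusion-weighted flux
  `J* = D_blood · M P_w / (L_k R T √L*)`
  with the calibrated plateau diffusion coefficient
  `D_blood = 1·10⁻⁹ m² s⁻¹` (established at 23 ± 1 °C, 20 % RH, on
  tile);
- the empirical mass–wet-area relation
  `m/m_i = 1 − α [1 − (A/A_i)]^β`, with calibrated `α = 0.78`,
  `β = 0.16`, which converts a measured wet area `A_x` into the current
  mass `m_x`;
- the elapsed time `δt = (m_i − m_x) / (J* A_i)`, or equivalently the
  closed form

  ```
  t_x = α R k_B T² A_i^{1/2} h^{1/2} ρ [1 − (A_x/A_i)]^β
        ───────────────────────────────────────────────
        M d² π P^{1/2} D_blood P_w P_a
  ```

Uncertainty is propagated by seeded Monte Carlo over the surface height
prior (on tile: `h = 1.44 ± 0.19 mm`) and the area measurement noise;
the point estimate is the median of the draws, the interval the central
90 %.

The package also ships the surrounding toolchain: drying-curve analysis
of mass/area time series (evaporation-rate series, normalised curves,
the diffusion-plateau estimate that collapses pools of different sizes
and shapes onto a common `D`, and the two empirical fits), calibrated
image segmentation of the pool and its wet region (adaptive colour
thresholds, Crofton perimeter), and a fully seeded forward simulator and
photograph renderer so that every stage is testable without laboratory
data.

## Worked example

Dating a pool on tile at 22.5 °C from one calibrated photograph in
which the total area, wet area and perimeter have been measured:

```r
library(poolage)

snap <- data.frame(Ai = 3.1e-3,   # total pool area, m^2
                   Ax = 2.4e-3,   # wet area inside the front, m^2
                   P  = 0.215)    # outline perimeter, m
est <- estimateAgeWithUncertainty(snap,
                                  surface = tileSurfacePrior(),
                                  env = ambientConditions(22.5, 20),
                                  nDraws = 2000, seed = 42)
est
#> AgeEstimate (closed_form): 6h 58m 52s  [6h 06m 26s, 7h 46m 08s] at 90% coverage
```

The pool was formed an estimated 6 h 59 min before the photograph; the
90 % interval (±≈50 min) is dominated by the ±0.19 mm spread of the
tile height prior. `reportJson(est)` serialises the estimate together
with every constant, input and flag that produced it — a forensic report
must be reproducible from its own provenance.

The same pipeline runs end-to-end on synthetic data:

```r
sc  <- poolScenario(5.24e-3, shapeIrregularity = 0.2, seed = 7)
sim <- simulateDrying(sc, dt = 120)
sim
#> SimulatedPool: J* = 4.39e-05 kg/m^2/s, 297 time points
#> PoolScenario: m_i = 5.24 g, irregularity = 0.20, h = 1.87 mm, flux basis = total, seed = 7

tr  <- truthRecord(sim)
min(masses(tr)) / 5.24e-3          # residual deposit: 0.23 of m_i
sel <- round(seq(1, length(obsTimes(tr)), length.out = 50))
fitMassArea(wetAreas(tr)[sel] / totalAreas(tr)[1],
            masses(tr)[sel] / 5.24e-3)
#> MassAreaFit: m/m_i = 1 - 0.78 * (1 - A/A_i)^0.16  (rms resid 6.85e-11)
```

A thin command-line launcher is installed under
`inst/scripts/poolage` with subcommands `simulate`, `segment`,
`analyze`, `estimate-age` and `fit`; see `?runPoolageCli`.

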