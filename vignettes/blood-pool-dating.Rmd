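---
title: "Dating blood pools from the drying front: model and methods"
author: "poolage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating blood pools from the drying front: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolage)
```

# The physical picture

A pool of blood deposited on a non-porous floor flattens under gravity
into a pancake of millimetre height bounded by a contact line. Blood
behaves as a colloidal suspension: red cells disperse in plasma, the
pool coagulates into a gel, and drying then proceeds like gel drying —
a near-constant evaporation period followed by falling-rate periods as
the liquid retreats into the porous deposit. Morphologically, a dark
desiccated rim appears at the edge and a drying front (the wet/dried
colour boundary) recedes towards the centre, and about 23 % of the
initial mass survives as the dry biological deposit. The front is the
one feature of this process that a camera can measure at a scene
without touching the evidence, and the whole package is organised
around it.

The estimator composes five stages, each exposed as a tested function:

1. **Geometry.** `volumeFromMass()` (V = m/ρ), `heightFromVolumeArea()`
   (h = V/A), `shapeFactor()` (L* = A/(hP)) and `contactAngle()`.
   L* measures how much evaporating edge a pool has per unit area:
   thin, stretched pools (small L*) evaporate faster than compact ones.
2. **Vapour physics.** `saturationVapourPressure()` (Buck correlation),
   `knudsenLayer()` (L_k = kT/(πd²P_a)), the characteristic thickness
   of the vapour layer through which evaporative transfer occurs.
3. **Flux.** `evaporationRateFromDiffusion()`:
   J* = D·M·P_w/(L_k·R·T·√L*), with the calibrated plateau diffusion
   coefficient D_blood. Its exact inverse,
   `diffusionFromEvaporationRate()`, is what collapses measured rate
   curves of dissimilar pools onto a common plateau
   (`weightedRateSeries()`, `estimatePlateau()`).
4. **Mass from the front.** The empirical relation
   m/mᵢ = 1 − α(1 − A/Aᵢ)^β (`massFromWetArea()`, fitted by
   `fitMassArea()`).
5. **Elapsed time.** δt = (mᵢ − m_x)/(J*·Aᵢ), available both as the
   chained composition (`elapsedTimeChained()`) and as the algebraically
   identical closed form (`elapsedTimeClosedForm()`); the test suite
   proves their equivalence numerically to 1e-10 over random parameter
   sweeps.

# Parameters, units, defaults

All internal units are strictly SI; gram/millimetre/Celsius conversions
happen only at the CSV, YAML and CLI boundaries.

| parameter | default | unit | role / why this value |
|---|---|---|---|
| `density` (ρ) | 1060 | kg m⁻³ | whole-blood literature value; the calibration experiments did not report theirs |
| `surfaceTension` (γ) | 0.058 | N m⁻¹ | whole-blood literature value; only enters the contact angle |
| `molarMass` (M) | 0.018015 | kg mol⁻¹ | evaporating species is water |
| `molecularDiameter` (d) | 2.75e-10 | m | water, for the Knudsen layer; ambient L_k then falls in 1–3·10⁻⁷ m |
| `residualMassFraction` | 0.23 | – | dry deposit left after complete drying |
| `dBlood` | 1e-9 | m² s⁻¹ | plateau diffusion coefficient at 23 ± 1 °C / 20 % RH on tile |
| `massAreaAlpha`, `massAreaBeta` | 0.78, 0.16 | – | calibrated mass–wet-area relation |
| tile height prior | 1.44 ± 0.19 | mm | mean ± sd of pool height on tile (30 pools); replaces a height measurement |
| `areaRelSd` | 0.02 | – | relative sd assumed for photographic area measurements |
| MC draws / coverage | 2000 / 0.90 | – | median point estimate, central 90 % interval |

Every default is overridable programmatically or through the YAML run
configuration (`readRunConfig()` / `configToObjects()`), which rejects
unknown keys so that a misspelled override cannot pass silently.

# Design decisions

**Contact-angle sign.** The flattened-puddle relation
1 − cos θ = ρgh²/2γ with h = mᵢ/(ρAᵢ) gives
θ = arccos(1 − g·mᵢ²/(2γρAᵢ²)). A frequently reprinted variant carries
a "+1" inside the arccos, whose argument exceeds 1 for any positive
mass; the package implements the physically consistent sign and raises
an explicit "out of range" error (never a silent clamp) when a pool is
too heaped for the puddle approximation.

**Saturation vapour pressure.** No specific correlation is prescribed
by the source calibration; the Buck correlation is used (0–100 °C,
error a few hundredths of a percent — negligible against every other
model term) and can be swapped via the `formula` argument.

**Humidity.** The flux formula is implemented as printed, independent
of relative humidity. A vapour-pressure-deficit extension multiplying
P_w by (1 − RH) is available behind `humidityCorrection = TRUE`
(default off) for sensitivity studies; it is an extension, not part of
the calibrated estimator.

**Flux-bearing area.** The published elapsed-time estimator divides the
mass deficit by J*·Aᵢ (total area) even though the constant-rate
plateau is established on the wet-area basis; the package keeps the
printed form as the default and provides `fluxArea = "wet"` — which
integrates dm/(J*·A_wet(m)) exactly via a series solution — as a
research variant. The forward simulator mirrors the same choice
(`fluxBasis`), so the default simulator/estimator round trip is exact
by construction, and the wet-basis mode reproduces the plateau
collapse.

**Plateau window.** `estimatePlateau()` uses the samples with
35–85 % of evaporable water left: the early pre-coagulation dip and
the late-stage tail (where the wet area cannot be segmented reliably)
are excluded. Median/MAD is used rather than mean/sd because the
excursions outside the plateau are one-sided.

**Rate differencing.** `evaporationRate()` takes centred finite
differences on the raw, possibly irregular weighing grid — matching
interval-based weighing protocols and avoiding resampling artefacts —
with the basis area interpolated at each window midpoint. An optional
running-mean `smoothWindow` exists but defaults to off.

**Shape-linear fit.** Each pool contributes its average J* computed
from samples taken after 50 % of the initial mass has evaporated, so
the very slow final stage does not bias the per-pool average.

**Uncertainty.** The Monte-Carlo point estimate is the median of the
draws: under the √h nonlinearity the mean is biased and unstable.
Multiple snapshots are combined per draw by converting each snapshot to
a formation-time estimate (captureTime − δt), taking the per-draw
median, and reporting the age at the last capture time.

**Calibration domain.** D_blood, α and β were established at
23 ± 1 °C and 20 % RH on tile. `estimateAgeWithUncertainty()` refuses
to report outside 22–24 °C or 15–25 % RH unless `force = TRUE`; a
plateau coefficient is condition-specific and extrapolating it silently
would be forensically indefensible. Only a tile height prior ships with
the package; other substrates need a user-supplied `surfacePrior()`.

**Water-fraction convention.** "Fraction of evaporable water left" is
(m − m_res)/(mᵢ − m_res) with m_res = 0.23·mᵢ, clipped to [0, 1]: the
residual deposit is subtracted so the curve reaches 0 exactly at
complete dryness. The residual fraction (0.23) and the fit limit
(1 − α = 0.22) disagree by 0.01 in the calibration data; the simulator
stops mass at the residual fraction, where the inverted fit still
leaves a wet fraction of ≈ 0.078 — consistent with the method's
requirement that a front remain visible to the end.

# The synthetic generator

`poolScenario()` + `simulateDrying()` emulate the calibration
experiments: pools of 0.1–50 g (presets cover 0.30–31.37 g) on
non-porous surfaces at 23 °C / 20 % RH, constant flux, linear mass
decline to the 23 % residual, wet area following the inverted
mass–area relation, constant total area, two-minute sampling, Gaussian
observation noise (0.01 g-scale balance, 2 % relative area error) and
full determinism under the scenario seed. `generateShape()` builds
star-shaped outlines (a circle perturbed by Fourier modes 2–6 with
amplitude set by `shapeIrregularity`) with exact polygon area and
perimeter; `renderSequence()` rasterises them into photograph-like
frames — red wet core, dark dried annulus obtained as a
distance-transform level set (a uniform inward offset of the boundary),
optional substrate-coloured cracks, reference scale bar, pixel noise —
together with ground-truth masks.

What the generator deliberately does **not** emulate: the early
pre-coagulation rate dip, temperature transients inside the pool,
Marangoni flows, crack mechanics, humidity feedback, porous substrates,
or any irregularity of the real front (the rendered front is a uniform
offset of the outline). Passing round-trip tests therefore demonstrate
the *internal consistency* of estimator and model — they do not
validate the calibration constants against new laboratory data, and the
segmentation accuracy figures hold for renderer-like images, not for
arbitrary crime-scene photography.

# Numerical choices

- **Wet-basis drying ODE.** dm/dt = −J*·A_wet(m) is separable; the
  package evaluates t(f) = mᵢW(f)/(J*Aᵢ), with
  W(f) = αβ Σₖ u^(β+k)/(β+k), u = (f/α)^(1/β), summed to machine
  precision, and inverts it by vectorised Newton iteration. No
  numerical integrator error enters the simulator.
- **Problem sizes.** Plateau-collapse checks sample each simulated pool
  at ~25 000 points (the centred-difference rate estimator has O(dt²)
  truncation error, so the <1e-9 relative flatness of the weighted
  plateau is resolution-dependent); the accuracy cohort uses 50 pools
  with 2000 Monte-Carlo draws each; segmentation budgets are asserted
  over 20 rendered frames of random shapes.
- **Perimeter.** The Crofton multi-direction estimator
  (`croftonPerimeter()`): boundary crossings counted along rows,
  columns and both diagonals, combined as
  (π/8)(C_h + C_v + (C_d1 + C_d2)/√2). Boundary-pixel counting was
  rejected (up to ~27 % overestimation on rasters). On masks only a few
  pixels across Crofton legitimately undershoots the isoperimetric
  bound 2√(πA), so that bound is a quality flag, not a validity error.
- **Segmentation.** Pool vs background: Otsu split on brightness with a
  minimum-contrast guard (a blank image raises "no pool found" rather
  than thresholding noise). Wet vs dried inside the pool: Otsu split on
  a redness channel R − (G+B)/2, falling back to an absolute redness
  cutoff when the pool is homogeneous (fully wet or fully dry); a small
  morphological opening removes substrate-coloured cracks. Fixed RGB
  thresholds were rejected as lighting-fragile.
- **Mass–area fit.** Bounded Levenberg–Marquardt (α ∈ (0,1),
  β ∈ (0,2], start (0.8, 0.2)); the fit requires ≥ 5 pairs spanning an
  area range of at least 0.3 to be identifiable.
- **Degenerate inputs.** A fully wet pool (A_x = A_i) and a fully dry
  pool (A_x = 0) raise advisory errors — the method needs a visible
  front. Ties and clamps: noisy wet areas are clipped to the total
  area; Monte-Carlo draws clamp A_x below A_i rather than erroring.

# Known limitations

- The calibration constants are condition-specific (23 °C, 20 % RH,
  tile, healthy-donor blood); the package guards but cannot extend
  them. A temperature/humidity reference table is future work.
- At early drying stages the front has receded only a few percent of
  the pool area: because δt ∝ (1 − A_x/A_i)^0.16, area measurement
  noise is then strongly amplified. Snapshots taken after about half
  the mass has evaporated date the pool much more reliably, and
  repeated snapshots (supported via `captureTime`) reduce the
  uncertainty further.
- Elapsed-time accuracy degrades linearly with pool age (the interval
  scales with the estimate); the 90 % interval width is dominated by
  the height prior's ±0.19 mm.
- The image module assumes overhead, evenly lit photographs with a
  neutral background and a single pool; no illumination correction
  beyond per-image adaptive thresholds is attempted.
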