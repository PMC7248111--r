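## Single-valued formulas of the pool drying model: geometry, contact
## angle, vapour pressure, Knudsen layer, and the diffusion-weighted
## evaporation rate.

#' Pool volume from mass
#'
#' V = m / rho: the deposited volume follows from the initial mass and
#' the blood density.
#'
#' @param mass pool mass, kg (> 0).
#' @param fluid a [FluidProperties-class].
#' @return volume, m^3.
#' @examples
#' volumeFromMass(5.24e-3, bloodProperties())  # ~4.94e-6 m^3
#' @export
volumeFromMass <- function(mass, fluid = bloodProperties()) {
  if (any(mass <= 0)) stop("mass must be strictly positive")
  mass / fluid@density
}

#' Mean pool height from volume and area
#'
#' h = V / A: the pancake approximation of a gravity-flattened pool.
#'
#' @param volume pool volume, m^3 (>= 0).
#' @param area pool area, m^2 (> 0).
#' @return mean height, m.
#' @examples
#' heightFromVolumeArea(4.94e-6, 3.43e-3)  # ~1.44e-3 m
#' @export
heightFromVolumeArea <- function(volume, area) {
  if (any(area <= 0)) stop("area must be strictly positive")
  if (any(volume < 0)) stop("volume must be non-negative")
  volume / area
}

#' Shape factor L*
#'
#' L* = A / (h P), the dimensionless factor relating a pool's area to
#' its evaporating edge. Large L* means a compact pool with relatively
#' little perimeter per unit area; thin, stretched pools have small L*
#' and evaporate faster.
#'
#' @param geometry a [PoolGeometry-class], or the area A (m^2) if
#'   `height` and `perimeter` are given.
#' @param height mean height h, m (when `geometry` is numeric).
#' @param perimeter perimeter P, m (when `geometry` is numeric).
#' @return the shape factor, dimensionless, > 0.
#' @examples
#' shapeFactor(2.5e-3, height = 1.44e-3, perimeter = 0.20)  # ~8.68
#' @export
shapeFactor <- function(geometry, height = NULL, perimeter = NULL) {
  if (is(geometry, "PoolGeometry")) {
    a <- geometry@totalArea; h <- geometry@height; p <- geometry@perimeter
  } else {
    a <- geometry; h <- height; p <- perimeter
  }
  if (is.null(h) || is.null(p) || any(h <= 0) || any(p <= 0) || any(a <= 0))
    stop("degenerate geometry: A, h and P must all be > 0")
  a / (h * p)
}

#' Contact angle of a gravity-flattened pool
#'
#' Puddle approximation: theta = arccos(1 - g m_i^2 / (2 gamma rho
#' A_i^2)), which follows from the flattened-puddle relation
#' 1 - cos(theta) = rho g h^2 / (2 gamma) with h = m_i / (rho A_i).
#' (A frequently reprinted variant with "+1" in the arccos argument is
#' undefined for any positive mass; this implementation uses the
#' physically consistent sign.) When the argument falls below -1 the
#' pool is too heaped for the puddle approximation and an error is
#' raised rather than clamping.
#'
#' @param geometry a [PoolGeometry-class] (its `initialMass` and
#'   `totalArea` are used).
#' @param fluid a [FluidProperties-class].
#' @param constants a [PhysicalConstants-class].
#' @return contact angle theta, radians in [0, pi].
#' @examples
#' g <- poolGeometry(totalArea = 2.5e-3, perimeter = 0.2,
#'                   height = 1.44e-3, initialMass = 5.24e-3)
#' contactAngle(g)  # ~0.863 rad
#' @export
contactAngle <- function(geometry, fluid = bloodProperties(),
                         constants = physicalConstants()) {
  m <- geometry@initialMass
  a <- geometry@totalArea
  arg <- 1 - constants@gravity * m^2 /
    (2 * fluid@surfaceTension * fluid@density * a^2)
  if (any(arg < -1))
    stop("contact-angle approximation out of range: ",
         "pool too heaped for the flattened-puddle model")
  acos(pmin(arg, 1))
}

#' Saturation vapour pressure of water
#'
#' Buck correlation over liquid water, valid 0-100 degC:
#' P_w = 611.21 exp((18.678 - t/234.5) t / (257.14 + t)) with t in
#' degrees Celsius. Accuracy is a few hundredths of a percent over the
#' range, far below the other model uncertainties. Monotonically
#' increasing in temperature. An alternative correlation can be supplied
#' via `formula`.
#'
#' @param temperature temperature, K, in [273.15, 373.15].
#' @param formula optional function(temperatureK) -> Pa replacing the
#'   Buck correlation.
#' @return saturation vapour pressure, Pa.
#' @examples
#' saturationVapourPressure(293.15)  # ~2339 Pa
#' @export
saturationVapourPressure <- function(temperature, formula = NULL) {
  if (any(temperature < 273.15 | temperature > 373.15))
    stop("temperature outside the 273.15-373.15 K validity range")
  if (!is.null(formula)) return(formula(temperature))
  tc <- temperature - 273.15
  611.21 * exp((18.678 - tc / 234.5) * tc / (257.14 + tc))
}

#' Knudsen layer thickness
#'
#' L_k = k T / (pi d^2 P_a): the thin vapour layer adjacent to the
#' liquid surface across which evaporative mass transfer occurs; it is
#' the characteristic length converting the transfer coefficient
#' (m s^-1) into a diffusion coefficient (m^2 s^-1). About 1.7e-7 m at
#' ambient conditions.
#'
#' @param env an [EnvironmentConditions-class].
#' @param fluid a [FluidProperties-class] (its `molecularDiameter`).
#' @param constants a [PhysicalConstants-class].
#' @return Knudsen layer thickness, m.
#' @examples
#' knudsenLayer(ambientConditions(23, 20))  # ~1.70e-7 m
#' @export
knudsenLayer <- function(env, fluid = bloodProperties(),
                         constants = physicalConstants()) {
  constants@boltzmann * env@temperature /
    (pi * fluid@molecularDiameter^2 * env@pressure)
}

## Effective driving vapour pressure: saturation pressure, optionally
## reduced by (1 - RH) when the humidity-deficit extension is enabled.
effectiveVapourPressure <- function(env, humidityCorrection = FALSE,
                                    pwFormula = NULL) {
  pw <- saturationVapourPressure(env@temperature, formula = pwFormula)
  if (humidityCorrection) pw * (1 - env@relativeHumidity) else pw
}

#' Evaporation rate from the diffusion coefficient
#'
#' J* = D M P_w / (L_k R T sqrt(L*)): the mass flux of water leaving a
#' pool of shape factor L*, given the plateau diffusion coefficient D.
#' As printed the relation is independent of relative humidity; setting
#' `humidityCorrection = TRUE` multiplies P_w by (1 - RH) as a
#' vapour-pressure-deficit extension (off by default).
#'
#' @param D diffusion coefficient, m^2 s^-1 (> 0).
#' @param Lstar shape factor, dimensionless (> 0).
#' @param env an [EnvironmentConditions-class].
#' @param fluid a [FluidProperties-class].
#' @param constants a [PhysicalConstants-class].
#' @param humidityCorrection logical; apply the (1 - RH) factor.
#' @param pwFormula optional replacement vapour-pressure correlation.
#' @return evaporation rate J*, kg m^-2 s^-1.
#' @examples
#' evaporationRateFromDiffusion(1e-9, Lstar = 9, ambientConditions(20, 20))
#' @export
evaporationRateFromDiffusion <- function(D, Lstar,
                                         env = environmentConditions(),
                                         fluid = bloodProperties(),
                                         constants = physicalConstants(),
                                         humidityCorrection = FALSE,
                                         pwFormula = NULL) {
  if (any(D <= 0)) stop("D must be > 0")
  if (any(Lstar <= 0)) stop("Lstar must be > 0")
  pw <- effectiveVapourPressure(env, humidityCorrection, pwFormula)
  lk <- knudsenLayer(env, fluid, constants)
  D * fluid@molarMass * pw /
    (lk * constants@gasConstant * env@temperature * sqrt(Lstar))
}

#' Diffusion coefficient from the evaporation rate
#'
#' D = J* R T L_k sqrt(L*) / (M P_w): the exact algebraic inverse of
#' [evaporationRateFromDiffusion()]. Applied to measured wet-area-basis
#' evaporation rates it collapses pools of different sizes and shapes
#' onto a common diffusion-coefficient plateau.
#'
#' @inheritParams evaporationRateFromDiffusion
#' @param Jstar evaporation rate, kg m^-2 s^-1 (>= 0).
#' @return diffusion coefficient, m^2 s^-1.
#' @export
diffusionFromEvaporationRate <- function(Jstar, Lstar,
                                         env = environmentConditions(),
                                         fluid = bloodProperties(),
                                         constants = physicalConstants(),
                                         humidityCorrection = FALSE,
                                         pwFormula = NULL) {
  if (any(Jstar < 0)) stop("Jstar must be >= 0")
  if (any(Lstar <= 0)) stop("Lstar must be > 0")
  pw <- effectiveVapourPressure(env, humidityCorrection, pwFormula)
  lk <- knudsenLayer(env, fluid, constants)
  Jstar * constants@gasConstant * env@temperature * lk * sqrt(Lstar) /
    (fluid@molarMass * pw)
}

#' Initial mass from geometry
#'
#' m_i = h A_i rho: reconstructs the initial mass of a pool from its
#' photographed area and the surface height prior.
#'
#' @param geometry a [PoolGeometry-class], or the area A (m^2) if
#'   `height` is given.
#' @param fluid a [FluidProperties-class].
#' @param height mean height h, m (when `geometry` is numeric).
#' @return mass, kg.
#' @examples
#' massFromGeometry(2.5e-3, height = 1.44e-3)  # ~3.82e-3 kg
#' @export
massFromGeometry <- function(geometry, fluid = bloodProperties(),
                             height = NULL) {
  if (is(geometry, "PoolGeometry")) {
    a <- geometry@totalArea; h <- geometry@height
  } else {
    a <- geometry; h <- height
  }
  if (is.null(h) || any(h < 0) || any(a < 0))
    stop("height and area must be non-negative")
  h * a * fluid@density
}
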