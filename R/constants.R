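## Default constants, fluid properties and constructors.

#' CODATA physical constants
#'
#' @param boltzmann Boltzmann constant k, J K^-1.
#' @param gasConstant universal gas constant R, J mol^-1 K^-1.
#' @param gravity standard gravity g, m s^-2.
#' @return a [PhysicalConstants-class] object.
#' @examples
#' physicalConstants()
#' @export
physicalConstants <- function(boltzmann = 1.380649e-23,
                              gasConstant = 8.314462618,
                              gravity = 9.80665) {
  new("PhysicalConstants", boltzmann = boltzmann, gasConstant = gasConstant,
      gravity = gravity)
}

#' Ambient conditions
#'
#' Constructor in SI units. See [ambientConditions()] for the
#' degrees-Celsius / percent convenience form. Defaults are the reference
#' laboratory conditions of the calibration experiments: 23 degC, 20%
#' relative humidity, 1 atm.
#'
#' @param temperature air temperature, K.
#' @param relativeHumidity relative humidity, fraction in [0, 1].
#' @param pressure atmospheric pressure, Pa.
#' @return an [EnvironmentConditions-class] object.
#' @export
environmentConditions <- function(temperature = 296.15,
                                  relativeHumidity = 0.20,
                                  pressure = 101325) {
  new("EnvironmentConditions", temperature = temperature,
      relativeHumidity = relativeHumidity, pressure = pressure)
}

#' Ambient conditions from field units
#'
#' @param temperatureC air temperature, degrees Celsius.
#' @param rhPercent relative humidity, percent.
#' @param pressurePa atmospheric pressure, Pa.
#' @return an [EnvironmentConditions-class] object.
#' @examples
#' ambientConditions(23, 20)
#' @export
ambientConditions <- function(temperatureC = 23, rhPercent = 20,
                              pressurePa = 101325) {
  environmentConditions(temperature = temperatureC + 273.15,
                        relativeHumidity = rhPercent / 100,
                        pressure = pressurePa)
}

#' Whole-blood fluid properties
#'
#' Literature values for whole human blood at ambient temperature:
#' density 1060 kg m^-3, surface tension 0.058 N m^-1. The evaporating
#' species is water (molar mass 0.018015 kg mol^-1, effective molecular
#' diameter 2.75e-10 m). The residual mass fraction of 0.23 is the dry
#' biological deposit left after complete drying of a pool. All values
#' are overridable; the density and surface tension used in the original
#' calibration experiments were not reported, so these defaults are
#' standard literature values.
#'
#' @param density blood density rho, kg m^-3.
#' @param surfaceTension blood surface tension gamma, N m^-1.
#' @param molarMass molar mass of water M, kg mol^-1.
#' @param molecularDiameter molecular diameter of water d, m.
#' @param haematocrit red-cell volume fraction, in [0, 1].
#' @param residualMassFraction dry-deposit mass fraction, in (0, 1).
#' @return a [FluidProperties-class] object.
#' @examples
#' bloodProperties()
#' bloodProperties(haematocrit = 0.47)
#' @export
bloodProperties <- function(density = 1060, surfaceTension = 0.058,
                            molarMass = 0.018015,
                            molecularDiameter = 2.75e-10,
                            haematocrit = 0.42,
                            residualMassFraction = 0.23) {
  new("FluidProperties", density = density, surfaceTension = surfaceTension,
      molarMass = molarMass, molecularDiameter = molecularDiameter,
      haematocrit = haematocrit,
      residualMassFraction = residualMassFraction)
}

#' Pool geometry
#'
#' @param totalArea total pool area A, m^2.
#' @param perimeter outline perimeter P, m.
#' @param height mean pool height h, m.
#' @param initialMass initial mass m_i, kg.
#' @return a [PoolGeometry-class] object.
#' @examples
#' poolGeometry(totalArea = 2.5e-3, perimeter = 0.20, height = 1.44e-3,
#'              initialMass = 5.24e-3)
#' @export
poolGeometry <- function(totalArea, perimeter, height, initialMass) {
  new("PoolGeometry", totalArea = totalArea, perimeter = perimeter,
      height = height, initialMass = initialMass)
}

#' Surface height prior
#'
#' @param surfaceLabel substrate name.
#' @param heightMean mean equilibrium pool height on this surface, m.
#' @param heightSd standard deviation of the height, m.
#' @return a [SurfacePrior-class] object.
#' @export
surfacePrior <- function(surfaceLabel, heightMean, heightSd) {
  new("SurfacePrior", surfaceLabel = surfaceLabel, heightMean = heightMean,
      heightSd = heightSd)
}

#' Shipped height prior for tile
#'
#' The only substrate with a shipped prior: pools on white tile reach a
#' mean height of 1.44 mm with a standard deviation of 0.19 mm
#' (30 pools). Other substrates require a user-supplied
#' [surfacePrior()].
#'
#' @return a [SurfacePrior-class] object.
#' @examples
#' tileSurfacePrior()
#' @export
tileSurfacePrior <- function() {
  surfacePrior("tile", heightMean = 1.44e-3, heightSd = 0.19e-3)
}

#' Calibrated drying model
#'
#' Defaults are the calibration constants established at 23 +/- 1 degC,
#' 20% relative humidity, on tile: plateau diffusion coefficient
#' D_blood = 1e-9 m^2 s^-1 and mass-area relation parameters
#' alpha = 0.78, beta = 0.16.
#'
#' @param dBlood plateau diffusion coefficient, m^2 s^-1.
#' @param massAreaAlpha alpha of m/m_i = 1 - alpha (1 - A/A_i)^beta.
#' @param massAreaBeta beta of the same relation.
#' @return a [CalibratedModel-class] object.
#' @examples
#' calibratedModel()
#' @export
calibratedModel <- function(dBlood = 1e-9, massAreaAlpha = 0.78,
                            massAreaBeta = 0.16) {
  new("CalibratedModel", dBlood = dBlood, massAreaAlpha = massAreaAlpha,
      massAreaBeta = massAreaBeta)
}

#' Drying record constructor
#'
#' @param times observation times, s; strictly increasing.
#' @param masses optional pool masses, kg.
#' @param totalAreas optional total areas, m^2.
#' @param wetAreas optional wet areas, m^2.
#' @param environment an [EnvironmentConditions-class].
#' @param geometry optional [PoolGeometry-class].
#' @param initialMass optional known initial mass, kg.
#' @param surfaceLabel substrate name.
#' @param qualityFlags character vector of data-quality annotations.
#' @return a [DryingRecord-class] object.
#' @export
dryingRecord <- function(times, masses = numeric(), totalAreas = numeric(),
                         wetAreas = numeric(),
                         environment = environmentConditions(),
                         geometry = NULL, initialMass = numeric(),
                         surfaceLabel = "unknown",
                         qualityFlags = character()) {
  new("DryingRecord", times = as.numeric(times),
      masses = as.numeric(masses), totalAreas = as.numeric(totalAreas),
      wetAreas = as.numeric(wetAreas), environment = environment,
      geometry = geometry, initialMass = as.numeric(initialMass),
      surfaceLabel = surfaceLabel, qualityFlags = qualityFlags)
}

## Initial mass of a record: explicit slot, geometry, or first mass sample.
recordInitialMass <- function(record) {
  if (length(record@initialMass)) return(record@initialMass)
  if (!is.null(record@geometry)) return(record@geometry@initialMass)
  if (length(record@masses)) return(record@masses[1])
  stop("record has no initial mass (no initialMass, geometry or masses)")
}
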