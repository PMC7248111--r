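#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Physical constants
#'
#' Container for the universal constants entering the drying model:
#' Boltzmann's constant (Knudsen layer), the universal gas constant
#' (diffusion weighting) and standard gravity (contact-angle
#' approximation). Defaults are CODATA values; all fields are strictly
#' positive.
#'
#' @slot boltzmann Boltzmann constant k, J K^-1.
#' @slot gasConstant universal gas constant R, J mol^-1 K^-1.
#' @slot gravity standard gravity g, m s^-2.
#' @seealso [physicalConstants()]
#' @exportClass PhysicalConstants
setClass("PhysicalConstants",
  slots = c(boltzmann = "numeric", gasConstant = "numeric",
            gravity = "numeric"))

setValidity("PhysicalConstants", function(object) {
  v <- c(object@boltzmann, object@gasConstant, object@gravity)
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    return("all constants must be finite, strictly positive scalars")
  TRUE
})

#' Ambient conditions during drying
#'
#' Temperature, relative humidity and atmospheric pressure of the air
#' surrounding the pool. All internal units are SI (kelvin, fraction,
#' pascal); use [ambientConditions()] to construct from degrees Celsius
#' and percent.
#'
#' @slot temperature air temperature, K (> 200 K).
#' @slot relativeHumidity relative humidity as a fraction in [0, 1].
#' @slot pressure atmospheric pressure, Pa (> 0).
#' @exportClass EnvironmentConditions
setClass("EnvironmentConditions",
  slots = c(temperature = "numeric", relativeHumidity = "numeric",
            pressure = "numeric"))

setValidity("EnvironmentConditions", function(object) {
  msg <- NULL
  if (length(object@temperature) != 1L || !is.finite(object@temperature) ||
      object@temperature <= 200)
    msg <- c(msg, "temperature must be a finite scalar > 200 K")
  if (length(object@relativeHumidity) != 1L ||
      !is.finite(object@relativeHumidity) ||
      object@relativeHumidity < 0 || object@relativeHumidity > 1)
    msg <- c(msg, "relativeHumidity must lie in [0, 1]")
  if (length(object@pressure) != 1L || !is.finite(object@pressure) ||
      object@pressure <= 0)
    msg <- c(msg, "pressure must be a finite scalar > 0 Pa")
  if (is.null(msg)) TRUE else msg
})

#' Fluid properties of the pooled blood
#'
#' Material properties used throughout the drying model. Density and
#' surface tension shape the pool (volume, contact angle); the molar mass
#' and molecular diameter of water enter the evaporation flux and the
#' Knudsen layer; the residual mass fraction is the dry biological
#' deposit left when all evaporable water has gone (about 23% of the
#' initial mass for whole blood). Haematocrit is carried as metadata.
#'
#' @slot density mass density rho, kg m^-3.
#' @slot surfaceTension surface tension gamma, N m^-1.
#' @slot molarMass molar mass of water M, kg mol^-1.
#' @slot molecularDiameter effective molecular diameter of water d, m.
#' @slot haematocrit red-cell volume fraction, in [0, 1].
#' @slot residualMassFraction dry-deposit mass fraction, in (0, 1).
#' @seealso [bloodProperties()]
#' @exportClass FluidProperties
setClass("FluidProperties",
  slots = c(density = "numeric", surfaceTension = "numeric",
            molarMass = "numeric", molecularDiameter = "numeric",
            haematocrit = "numeric", residualMassFraction = "numeric"))

setValidity("FluidProperties", function(object) {
  msg <- NULL
  for (nm in c("density", "surfaceTension", "molarMass",
               "molecularDiameter")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, paste0(nm, " must be a finite scalar > 0"))
  }
  if (length(object@haematocrit) != 1L || !is.finite(object@haematocrit) ||
      object@haematocrit < 0 || object@haematocrit > 1)
    msg <- c(msg, "haematocrit must lie in [0, 1]")
  rf <- object@residualMassFraction
  if (length(rf) != 1L || !is.finite(rf) || rf <= 0 || rf >= 1)
    msg <- c(msg, "residualMassFraction must lie in (0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Macroscopic geometry of a blood pool
#'
#' The measurable dimensions of a pool: total (outline) area, outline
#' perimeter, mean height and initial mass. These are the inputs to the
#' shape factor L* = A/(hP) and the contact-angle approximation.
#'
#' @slot totalArea total pool area A, m^2.
#' @slot perimeter outline perimeter P, m.
#' @slot height mean pool height h, m.
#' @slot initialMass initial mass m_i, kg.
#' @exportClass PoolGeometry
setClass("PoolGeometry",
  slots = c(totalArea = "numeric", perimeter = "numeric",
            height = "numeric", initialMass = "numeric"))

setValidity("PoolGeometry", function(object) {
  msg <- NULL
  for (nm in c("totalArea", "perimeter", "height", "initialMass")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, paste0(nm, " must be a finite scalar > 0"))
  }
  ## isoperimetric inequality P^2 >= 4*pi*A, with slack for rasterised
  ## perimeter estimates on small masks
  if (is.null(msg) &&
      object@perimeter^2 < 4 * pi * object@totalArea * 0.90)
    msg <- c(msg, "perimeter violates the isoperimetric inequality P^2 >= 4*pi*A")
  if (is.null(msg)) TRUE else msg
})

setClassUnion("PoolGeometryOrNULL", c("PoolGeometry", "NULL"))

#' Surface-specific height prior
#'
#' Mean and standard deviation of the equilibrium pool height on a given
#' substrate, estimated from repeated pools. On tile the shipped prior is
#' 1.44 +/- 0.19 mm (30 pools). The prior replaces a direct height
#' measurement when only a photograph is available.
#'
#' @slot surfaceLabel substrate name, e.g. `"tile"`.
#' @slot heightMean mean pool height on this surface, m.
#' @slot heightSd standard deviation of the height, m (>= 0).
#' @seealso [tileSurfacePrior()]
#' @exportClass SurfacePrior
setClass("SurfacePrior",
  slots = c(surfaceLabel = "character", heightMean = "numeric",
            heightSd = "numeric"))

setValidity("SurfacePrior", function(object) {
  msg <- NULL
  if (length(object@heightMean) != 1L || !is.finite(object@heightMean) ||
      object@heightMean <= 0)
    msg <- c(msg, "heightMean must be > 0")
  if (length(object@heightSd) != 1L || !is.finite(object@heightSd) ||
      object@heightSd < 0)
    msg <- c(msg, "heightSd must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Calibrated drying model
#'
#' The three empirical calibration constants of the dating method: the
#' plateau diffusion coefficient of drying blood pools D_blood
#' (approximately 1e-9 m^2 s^-1 at 23 degC / 20% RH on tile) and the
#' (alpha, beta) parameters of the normalised mass versus wet-area
#' relation m/m_i = 1 - alpha * (1 - A/A_i)^beta.
#'
#' @slot dBlood plateau diffusion coefficient, m^2 s^-1.
#' @slot massAreaAlpha amplitude alpha of the mass-area relation, in (0, 1).
#' @slot massAreaBeta exponent beta of the mass-area relation, > 0.
#' @seealso [calibratedModel()]
#' @exportClass CalibratedModel
setClass("CalibratedModel",
  slots = c(dBlood = "numeric", massAreaAlpha = "numeric",
            massAreaBeta = "numeric"))

setValidity("CalibratedModel", function(object) {
  msg <- NULL
  if (length(object@dBlood) != 1L || !is.finite(object@dBlood) ||
      object@dBlood <= 0)
    msg <- c(msg, "dBlood must be > 0")
  a <- object@massAreaAlpha
  if (length(a) != 1L || !is.finite(a) || a <= 0 || a >= 1)
    msg <- c(msg, "massAreaAlpha must lie in (0, 1)")
  b <- object@massAreaBeta
  if (length(b) != 1L || !is.finite(b) || b <= 0)
    msg <- c(msg, "massAreaBeta must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Time-stamped drying observations of one pool
#'
#' A drying record holds the time series measured on a single pool:
#' mass (weighing) and/or total and wet areas (photography), together
#' with the ambient conditions. Times are strictly increasing seconds
#' since pool formation (or since the first observation when the
#' formation time is unknown). At least one of the mass / wet-area
#' channels must be present. Non-physical features tolerated as
#' measurement noise (e.g. small mass increases) are reported in
#' `qualityFlags` rather than rejected.
#'
#' @slot times observation times, s; strictly increasing.
#' @slot masses pool mass at each time, kg (length 0 if absent).
#' @slot totalAreas total pool area, m^2 (length 0 if absent).
#' @slot wetAreas wet (undried) area, m^2 (length 0 if absent).
#' @slot environment an [EnvironmentConditions-class] object.
#' @slot geometry optional [PoolGeometry-class] of the pool.
#' @slot initialMass optional known initial mass, kg (length 0 if absent).
#' @slot surfaceLabel substrate name.
#' @slot qualityFlags character vector of data-quality annotations.
#' @exportClass DryingRecord
setClass("DryingRecord",
  slots = c(times = "numeric", masses = "numeric", totalAreas = "numeric",
            wetAreas = "numeric", environment = "EnvironmentConditions",
            geometry = "PoolGeometryOrNULL", initialMass = "numeric",
            surfaceLabel = "character", qualityFlags = "character"))

setValidity("DryingRecord", function(object) {
  msg <- NULL
  n <- length(object@times)
  if (n < 1L || any(!is.finite(object@times)))
    msg <- c(msg, "times must be non-empty and finite")
  if (n > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  for (nm in c("masses", "totalAreas", "wetAreas")) {
    v <- slot(object, nm)
    if (length(v) && length(v) != n)
      msg <- c(msg, paste0(nm, " must match the length of times"))
    if (length(v) && any(!is.finite(v) | v < 0))
      msg <- c(msg, paste0(nm, " must be finite and non-negative"))
  }
  if (!length(object@masses) && !length(object@wetAreas))
    msg <- c(msg, "at least one of masses or wetAreas must be present")
  if (length(object@wetAreas) && length(object@totalAreas) &&
      any(object@wetAreas > object@totalAreas * (1 + 1e-9)))
    msg <- c(msg, "wetAreas must not exceed totalAreas")
  if (length(object@initialMass) > 1L)
    msg <- c(msg, "initialMass must have length 0 or 1")
  if (is.null(msg)) TRUE else msg
})

#' Evaporation-rate time series
#'
#' Per-interval evaporation rates J* (mass flux per unit area) derived
#' from a [DryingRecord-class], on either the total-area or the wet-area
#' basis, together with the fraction of evaporable water remaining at
#' each rate sample.
#'
#' @slot times times of the rate samples, s.
#' @slot rates evaporation rates J*, kg m^-2 s^-1.
#' @slot waterFractionLeft fraction of evaporable water left, in [0, 1].
#' @slot areaBasis `"total"` or `"wet"`.
#' @exportClass RateSeries
setClass("RateSeries",
  slots = c(times = "numeric", rates = "numeric",
            waterFractionLeft = "numeric", areaBasis = "character"))

setValidity("RateSeries", function(object) {
  msg <- NULL
  n <- length(object@times)
  if (length(object@rates) != n || length(object@waterFractionLeft) != n)
    msg <- c(msg, "times, rates and waterFractionLeft must have equal length")
  if (!object@areaBasis %in% c("total", "wet"))
    msg <- c(msg, "areaBasis must be 'total' or 'wet'")
  if (length(object@waterFractionLeft) &&
      any(object@waterFractionLeft < -1e-9 |
          object@waterFractionLeft > 1 + 1e-9))
    msg <- c(msg, "waterFractionLeft must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Fitted mass versus wet-area relation
#'
#' Result of the bounded nonlinear least-squares fit of
#' m/m_i = 1 - alpha * (1 - A/A_i)^beta to normalised (area, mass) pairs.
#'
#' @slot alpha fitted amplitude, in (0, 1).
#' @slot beta fitted exponent, in (0, 2].
#' @slot residualNorm root-mean-square residual of the fit.
#' @exportClass MassAreaFit
setClass("MassAreaFit",
  slots = c(alpha = "numeric", beta = "numeric", residualNorm = "numeric"))

#' Fitted shape-linear relation
#'
#' Ordinary least-squares fit of the shape-reduced evaporation rate
#' J*/L* against the contact angle theta: J*/L* = slope * theta +
#' intercept.
#'
#' @slot slope slope, kg m^-2 s^-1 rad^-1.
#' @slot intercept intercept, kg m^-2 s^-1.
#' @slot rSquared coefficient of determination of the fit.
#' @exportClass ShapeLinearFit
setClass("ShapeLinearFit",
  slots = c(slope = "numeric", intercept = "numeric", rSquared = "numeric"))

#' Pixel-to-metre calibration
#'
#' Image scale obtained from a reference length photographed next to the
#' pool.
#'
#' @slot metresPerPixel image scale, m per pixel (> 0).
#' @seealso [calibrateScale()]
#' @exportClass ScaleCalibration
setClass("ScaleCalibration", slots = c(metresPerPixel = "numeric"))

setValidity("ScaleCalibration", function(object) {
  v <- object@metresPerPixel
  if (length(v) != 1L || !is.finite(v) || v <= 0)
    return("metresPerPixel must be a finite scalar > 0")
  TRUE
})

#' Segmentation of one pool photograph
#'
#' Binary masks of the whole pool and of its wet (not yet dried) region,
#' with calibrated measurements. `wetMask` is always a subset of
#' `poolMask`; areas are pixel counts times the squared scale and the
#' perimeter comes from the multi-directional Crofton estimator.
#'
#' @slot poolMask logical matrix, TRUE on pool pixels.
#' @slot wetMask logical matrix, TRUE on wet pixels (subset of poolMask).
#' @slot totalArea calibrated pool area, m^2.
#' @slot wetArea calibrated wet area, m^2.
#' @slot perimeter calibrated pool perimeter, m.
#' @slot qualityFlags character vector of per-frame quality annotations.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  slots = c(poolMask = "matrix", wetMask = "matrix", totalArea = "numeric",
            wetArea = "numeric", perimeter = "numeric",
            qualityFlags = "character"))

setValidity("SegmentationResult", function(object) {
  msg <- NULL
  if (!identical(dim(object@poolMask), dim(object@wetMask)))
    msg <- c(msg, "poolMask and wetMask must have identical dimensions")
  else if (any(object@wetMask & !object@poolMask))
    msg <- c(msg, "wetMask must be a subset of poolMask")
  if (length(object@wetArea) == 1L && length(object@totalArea) == 1L &&
      object@wetArea > object@totalArea * (1 + 1e-9))
    msg <- c(msg, "wetArea must not exceed totalArea")
  if (is.null(msg)) TRUE else msg
})

#' Estimated time since pool formation
#'
#' The forensic product: the elapsed time between pool formation and the
#' (last) photograph, with a Monte-Carlo uncertainty interval and a full
#' snapshot of every input, constant and flag that entered the
#' calculation (provenance requirement for forensic reporting).
#'
#' @slot elapsedTime point estimate of the elapsed time, s.
#' @slot interval lower and upper bound of the uncertainty interval, s.
#' @slot coverage nominal coverage of the interval (e.g. 0.90).
#' @slot method `"closed_form"` or `"chained"`.
#' @slot inputsSnapshot named list of all inputs, constants and flags.
#' @exportClass AgeEstimate
setClass("AgeEstimate",
  slots = c(elapsedTime = "numeric", interval = "numeric",
            coverage = "numeric", method = "character",
            inputsSnapshot = "list"))

setValidity("AgeEstimate", function(object) {
  msg <- NULL
  if (length(object@elapsedTime) != 1L || !is.finite(object@elapsedTime) ||
      object@elapsedTime < 0)
    msg <- c(msg, "elapsedTime must be a finite scalar >= 0")
  if (length(object@interval) != 2L || any(!is.finite(object@interval)))
    msg <- c(msg, "interval must be two finite numbers")
  else if (object@interval[1] > object@elapsedTime + 1e-9 ||
           object@interval[2] < object@elapsedTime - 1e-9)
    msg <- c(msg, "interval must bracket the point estimate")
  if (is.null(msg)) TRUE else msg
})

#' Scenario for the forward drying simulator
#'
#' Everything needed to simulate one pool deterministically: initial
#' mass, shape irregularity, true height, ambient conditions, fluid
#' properties, calibrated model, surface prior, observation-noise levels
#' and the RNG seed. The same seed always yields the same shape, record
#' and rendered frames.
#'
#' @slot initialMass initial pool mass, kg; within [1e-4, 5e-2]
#'   (0.1-50 g, bracketing the 0.30-31.37 g experimental range).
#' @slot shapeIrregularity non-negative amplitude of the Fourier boundary
#'   perturbation (0 = circle).
#' @slot height true mean pool height, m.
#' @slot environment an [EnvironmentConditions-class].
#' @slot fluid a [FluidProperties-class].
#' @slot model a [CalibratedModel-class].
#' @slot surface a [SurfacePrior-class].
#' @slot noise named list with `areaRelSd` (relative sd of area
#'   observations) and `massSd` (absolute sd of mass observations, kg).
#' @slot fluxBasis `"total"` (flux through the total area, matching the
#'   elapsed-time estimator) or `"wet"` (constant flux through the wet
#'   area, the plateau experiment).
#' @slot seed integer RNG seed.
#' @seealso [poolScenario()], [simulateDrying()]
#' @exportClass PoolScenario
setClass("PoolScenario",
  slots = c(initialMass = "numeric", shapeIrregularity = "numeric",
            height = "numeric", environment = "EnvironmentConditions",
            fluid = "FluidProperties", model = "CalibratedModel",
            surface = "SurfacePrior", noise = "list",
            fluxBasis = "character", seed = "integer"))

setValidity("PoolScenario", function(object) {
  msg <- NULL
  m <- object@initialMass
  if (length(m) != 1L || !is.finite(m) || m < 1e-4 || m > 5e-2)
    msg <- c(msg, "initialMass must lie in [1e-4, 5e-2] kg")
  if (object@shapeIrregularity < 0)
    msg <- c(msg, "shapeIrregularity must be >= 0")
  if (length(object@height) != 1L || object@height <= 0)
    msg <- c(msg, "height must be a scalar > 0")
  if (!object@fluxBasis %in% c("total", "wet"))
    msg <- c(msg, "fluxBasis must be 'total' or 'wet'")
  if (!all(c("areaRelSd", "massSd") %in% names(object@noise)))
    msg <- c(msg, "noise must contain areaRelSd and massSd")
  if (is.null(msg)) TRUE else msg
})

#' Simulated pool: ground truth plus noisy observations
#'
#' Output of [simulateDrying()]: the generating scenario and shape, the
#' constant evaporation rate J* used, the noiseless ground-truth
#' [DryingRecord-class] and the noisy observed record.
#'
#' @slot scenario the generating [PoolScenario-class].
#' @slot shape list describing the pool boundary (see [generateShape()]).
#' @slot jStar evaporation rate J* used by the simulator, kg m^-2 s^-1.
#' @slot truth noiseless ground-truth [DryingRecord-class].
#' @slot record observed (noisy) [DryingRecord-class].
#' @exportClass SimulatedPool
setClass("SimulatedPool",
  slots = c(scenario = "PoolScenario", shape = "list", jStar = "numeric",
            truth = "DryingRecord", record = "DryingRecord"))
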