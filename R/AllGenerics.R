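## Accessor generics, methods and show() for the S4 classes.

#' @importFrom stats coef predict
NULL

#' @rdname DryingRecord-class
#' @param object,x a package object.
#' @export
setGeneric("obsTimes", function(x) standardGeneric("obsTimes"))
#' @rdname DryingRecord-class
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))
#' @rdname DryingRecord-class
#' @export
setGeneric("totalAreas", function(x) standardGeneric("totalAreas"))
#' @rdname DryingRecord-class
#' @export
setGeneric("wetAreas", function(x) standardGeneric("wetAreas"))
#' @rdname DryingRecord-class
#' @export
setGeneric("qualityFlags", function(x) standardGeneric("qualityFlags"))
#' @rdname AgeEstimate-class
#' @export
setGeneric("elapsedTime", function(x) standardGeneric("elapsedTime"))
#' @rdname AgeEstimate-class
#' @export
setGeneric("ageInterval", function(x) standardGeneric("ageInterval"))
#' @rdname AgeEstimate-class
#' @export
setGeneric("inputsSnapshot", function(x) standardGeneric("inputsSnapshot"))
#' @rdname SimulatedPool-class
#' @export
setGeneric("observedRecord", function(x) standardGeneric("observedRecord"))
#' @rdname SimulatedPool-class
#' @export
setGeneric("truthRecord", function(x) standardGeneric("truthRecord"))

#' @rdname DryingRecord-class
setMethod("obsTimes", "DryingRecord", function(x) x@times)
#' @rdname DryingRecord-class
setMethod("masses", "DryingRecord", function(x) x@masses)
#' @rdname DryingRecord-class
setMethod("totalAreas", "DryingRecord", function(x) x@totalAreas)
#' @rdname DryingRecord-class
setMethod("wetAreas", "DryingRecord", function(x) x@wetAreas)
#' @rdname DryingRecord-class
setMethod("qualityFlags", "DryingRecord", function(x) x@qualityFlags)
#' @rdname DryingRecord-class
setMethod("length", "DryingRecord", function(x) length(x@times))

#' @rdname RateSeries-class
setMethod("obsTimes", "RateSeries", function(x) x@times)
#' @rdname RateSeries-class
#' @param x a `RateSeries`.
#' @export
rates <- function(x) x@rates
#' @rdname RateSeries-class
#' @export
waterFraction <- function(x) x@waterFractionLeft
#' @rdname RateSeries-class
#' @export
areaBasis <- function(x) x@areaBasis

#' @rdname SegmentationResult-class
setMethod("qualityFlags", "SegmentationResult", function(x) x@qualityFlags)

#' @rdname AgeEstimate-class
setMethod("elapsedTime", "AgeEstimate", function(x) x@elapsedTime)
#' @rdname AgeEstimate-class
setMethod("ageInterval", "AgeEstimate", function(x) x@interval)
#' @rdname AgeEstimate-class
setMethod("inputsSnapshot", "AgeEstimate", function(x) x@inputsSnapshot)

#' @rdname SimulatedPool-class
setMethod("observedRecord", "SimulatedPool", function(x) x@record)
#' @rdname SimulatedPool-class
setMethod("truthRecord", "SimulatedPool", function(x) x@truth)

#' @describeIn MassAreaFit-class fitted parameters as
#'   `c(alpha = ..., beta = ...)`.
#' @param object a fit object.
#' @param ... ignored.
#' @export
setMethod("coef", "MassAreaFit", function(object, ...)
  c(alpha = object@alpha, beta = object@beta))

#' @describeIn MassAreaFit-class predicted m/m_i at normalised wet area
#'   `newdata` (a numeric vector of A/A_i values).
#' @param newdata numeric vector of A/A_i values in [0, 1].
#' @export
setMethod("predict", "MassAreaFit", function(object, newdata, ...) {
  stopifnot(is.numeric(newdata))
  1 - object@alpha * (1 - newdata)^object@beta
})

#' @describeIn ShapeLinearFit-class fitted coefficients as
#'   `c(intercept = ..., slope = ...)`.
#' @param object a fit object.
#' @param ... ignored.
#' @export
setMethod("coef", "ShapeLinearFit", function(object, ...)
  c(intercept = object@intercept, slope = object@slope))

setMethod("show", "EnvironmentConditions", function(object) {
  cat(sprintf(
    "EnvironmentConditions: T = %.2f K (%.1f degC), RH = %.0f%%, P_a = %.0f Pa\n",
    object@temperature, object@temperature - 273.15,
    100 * object@relativeHumidity, object@pressure))
})

setMethod("show", "FluidProperties", function(object) {
  cat(sprintf(
    paste0("FluidProperties: rho = %.0f kg/m^3, gamma = %.3f N/m, ",
           "M = %.5f kg/mol,\n  d = %.3g m, HCT = %.0f%%, residual = %.0f%%\n"),
    object@density, object@surfaceTension, object@molarMass,
    object@molecularDiameter, 100 * object@haematocrit,
    100 * object@residualMassFraction))
})

setMethod("show", "PoolGeometry", function(object) {
  cat(sprintf(
    paste0("PoolGeometry: A = %.3g m^2, P = %.3g m, h = %.3g m, ",
           "m_i = %.3g kg\n  (L* = %.3g)\n"),
    object@totalArea, object@perimeter, object@height, object@initialMass,
    object@totalArea / (object@height * object@perimeter)))
})

setMethod("show", "DryingRecord", function(object) {
  ch <- c(if (length(object@masses)) "mass",
          if (length(object@totalAreas)) "totalArea",
          if (length(object@wetAreas)) "wetArea")
  cat(sprintf(
    "DryingRecord: %d observations over %.2f h [%s] on '%s'\n",
    length(object@times), diff(range(object@times)) / 3600,
    paste(ch, collapse = ", "), object@surfaceLabel))
  if (length(object@qualityFlags))
    cat("  flags:", paste(object@qualityFlags, collapse = "; "), "\n")
})

setMethod("show", "RateSeries", function(object) {
  cat(sprintf(
    "RateSeries (%s-area basis): %d samples, median J* = %.3g kg/m^2/s\n",
    object@areaBasis, length(object@rates),
    stats::median(object@rates)))
})

setMethod("show", "MassAreaFit", function(object) {
  cat(sprintf(
    "MassAreaFit: m/m_i = 1 - %.4g * (1 - A/A_i)^%.4g  (rms resid %.3g)\n",
    object@alpha, object@beta, object@residualNorm))
})

setMethod("show", "ShapeLinearFit", function(object) {
  cat(sprintf(
    "ShapeLinearFit: J*/L* = %.4g * theta + %.4g  (R^2 = %.4f)\n",
    object@slope, object@intercept, object@rSquared))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    paste0("SegmentationResult: total %.3g m^2, wet %.3g m^2 (%.1f%%), ",
           "perimeter %.3g m\n"),
    object@totalArea, object@wetArea,
    100 * object@wetArea / max(object@totalArea, .Machine$double.xmin),
    object@perimeter))
  if (length(object@qualityFlags))
    cat("  flags:", paste(object@qualityFlags, collapse = "; "), "\n")
})

setMethod("show", "AgeEstimate", function(object) {
  cat(sprintf(
    "AgeEstimate (%s): %s  [%s, %s] at %.0f%% coverage\n",
    object@method, formatHMS(object@elapsedTime),
    formatHMS(object@interval[1]), formatHMS(object@interval[2]),
    100 * object@coverage))
})

setMethod("show", "PoolScenario", function(object) {
  cat(sprintf(
    paste0("PoolScenario: m_i = %.3g g, irregularity = %.2f, h = %.2f mm, ",
           "flux basis = %s, seed = %d\n"),
    1e3 * object@initialMass, object@shapeIrregularity,
    1e3 * object@height, object@fluxBasis, object@seed))
})

setMethod("show", "SimulatedPool", function(object) {
  cat(sprintf(
    "SimulatedPool: J* = %.3g kg/m^2/s, %d time points\n",
    object@jStar, length(object@truth@times)))
  show(object@scenario)
})

#' Format seconds as hours-minutes-seconds
#'
#' @param seconds elapsed time in seconds.
#' @return character like `"8h 18m 05s"`.
#' @export
formatHMS <- function(seconds) {
  vapply(seconds, function(s) {
    h <- floor(s / 3600); m <- floor((s - 3600 * h) / 60)
    sprintf("%dh %02dm %02ds", h, m, round(s - 3600 * h - 60 * m))
  }, character(1))
}
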