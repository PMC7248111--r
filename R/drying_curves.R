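## Turning time-stamped mass/area observations into evaporation-rate
## series, normalised curves, the weighted diffusion plateau, and the two
## empirical fits.

#' Fraction of evaporable water left
#'
#' (m(t) - m_res) / (m_i - m_res), clipped to [0, 1], where m_res is the
#' residual dry deposit residualMassFraction * m_i. By this convention
#' the curve reaches 0 exactly when the pool is fully dry (mass at 23%
#' of the initial mass with the default residual fraction); the residual
#' deposit is subtracted so that the fraction tracks evaporable water
#' only.
#'
#' @param record a [DryingRecord-class] with a mass channel.
#' @param fluid a [FluidProperties-class] (its residual mass fraction).
#' @return numeric vector in [0, 1], one value per observation.
#' @export
waterFractionLeft <- function(record, fluid = bloodProperties()) {
  if (!length(record@masses)) stop("record has no mass channel")
  mi <- recordInitialMass(record)
  mres <- fluid@residualMassFraction * mi
  if (mi <= mres)
    stop("initial mass does not exceed the residual mass; ",
         "check residualMassFraction")
  pmin(pmax((record@masses - mres) / (mi - mres), 0), 1)
}

## Interpolate an area channel at arbitrary times (constant outside the
## observed range).
.interpArea <- function(times, areas, at) {
  if (length(areas) == 1L) return(rep(areas, length(at)))
  stats::approx(times, areas, xout = at, rule = 2)$y
}

#' Evaporation-rate series from a drying record
#'
#' Centred finite differences of the mass channel over the (possibly
#' irregular) weighing grid, divided by the chosen basis area
#' interpolated at the midpoint of each differencing window:
#' J*(t_j) = -(m_{j+1} - m_{j-1}) / (t_{j+1} - t_{j-1}) / A(t_j).
#' On the `"total"` basis the constant initial area may be used (the
#' geometry area, or the first/constant total-area observation); on the
#' `"wet"` basis the wet-area channel is required. A two-point record
#' yields the single forward-difference rate. An optional running-mean
#' smoothing window (in samples, odd, default off) can be applied to the
#' mass channel before differencing.
#'
#' @param record a [DryingRecord-class] with >= 2 mass observations.
#' @param basis `"total"` or `"wet"`.
#' @param fluid a [FluidProperties-class], used to attach the water
#'   fraction left to each rate sample.
#' @param smoothWindow odd integer >= 3 to enable running-mean smoothing
#'   of the mass channel; `NULL` (default) leaves the data untouched.
#' @return a [RateSeries-class].
#' @export
evaporationRate <- function(record, basis = c("total", "wet"),
                            fluid = bloodProperties(),
                            smoothWindow = NULL) {
  basis <- match.arg(basis)
  t <- record@times
  m <- record@masses
  if (length(m) < 2L) stop("need at least two mass observations")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (!is.null(smoothWindow)) {
    k <- as.integer(smoothWindow)
    if (k < 3L || k %% 2L == 0L) stop("smoothWindow must be odd and >= 3")
    m <- stats::filter(m, rep(1 / k, k), sides = 2)
    keep <- !is.na(m)
    m <- as.numeric(m[keep]); t <- t[keep]
  }
  n <- length(t)
  if (basis == "wet") {
    if (!length(record@wetAreas)) stop("wet basis requires a wetAreas channel")
    areaT <- record@times; areaV <- record@wetAreas
  } else {
    if (length(record@totalAreas)) {
      areaT <- record@times; areaV <- record@totalAreas
    } else if (!is.null(record@geometry)) {
      areaT <- record@times
      areaV <- rep(record@geometry@totalArea, length(record@times))
    } else stop("total basis requires totalAreas or a geometry")
  }
  if (n == 2L) {
    tm <- mean(t)
    rate <- -(m[2] - m[1]) / (t[2] - t[1]) / .interpArea(areaT, areaV, tm)
    tout <- tm
  } else {
    j <- 2:(n - 1)
    tm <- (t[j + 1] + t[j - 1]) / 2
    rate <- -(m[j + 1] - m[j - 1]) / (t[j + 1] - t[j - 1]) /
      .interpArea(areaT, areaV, tm)
    tout <- t[j]
  }
  wfl <- waterFractionLeft(record, fluid)
  wfl <- stats::approx(record@times, wfl, xout = tout, rule = 2)$y
  new("RateSeries", times = tout, rates = pmax(rate, 0),
      waterFractionLeft = pmin(pmax(wfl, 0), 1), areaBasis = basis)
}

#' Normalised drying curves
#'
#' Normalises a record for cross-pool comparison: times by the last
#' observation time t_f, masses by the initial mass, areas by the
#' initial total area. The resulting curves are invariant under unit
#' rescaling of the inputs.
#'
#' @param record a [DryingRecord-class].
#' @return a data.frame with columns `tNorm` and, as available,
#'   `massNorm`, `totalAreaNorm`, `wetAreaNorm`.
#' @export
normalizeRecord <- function(record) {
  tf <- record@times[length(record@times)]
  if (tf <= 0) stop("last observation time must be > 0")
  out <- data.frame(tNorm = record@times / tf)
  if (length(record@masses))
    out$massNorm <- record@masses / recordInitialMass(record)
  ai <- if (length(record@totalAreas)) record@totalAreas[1]
        else if (!is.null(record@geometry)) record@geometry@totalArea
        else NA_real_
  if (length(record@totalAreas)) out$totalAreaNorm <- record@totalAreas / ai
  if (length(record@wetAreas) && is.finite(ai))
    out$wetAreaNorm <- record@wetAreas / ai
  out
}

#' Diffusion-weighted rate series
#'
#' Applies [diffusionFromEvaporationRate()] pointwise to a wet-basis
#' rate series: D(t) = J*(t) R T L_k sqrt(L*) / (M P_w). On pools drying
#' at a constant wet-area flux the result is flat at the generating
#' diffusion coefficient, collapsing pools of different shapes and sizes
#' onto a common plateau.
#'
#' @param rate a wet-basis [RateSeries-class].
#' @param geometry the pool's [PoolGeometry-class] (for L*).
#' @param env an [EnvironmentConditions-class].
#' @param fluid a [FluidProperties-class].
#' @param constants a [PhysicalConstants-class].
#' @param humidityCorrection logical, see
#'   [evaporationRateFromDiffusion()].
#' @return a list with `times`, `D` (m^2 s^-1) and `waterFractionLeft`.
#' @export
weightedRateSeries <- function(rate, geometry,
                               env = environmentConditions(),
                               fluid = bloodProperties(),
                               constants = physicalConstants(),
                               humidityCorrection = FALSE) {
  if (rate@areaBasis != "wet")
    stop("weighted rate series requires a wet-area-basis RateSeries")
  ls <- shapeFactor(geometry)
  D <- diffusionFromEvaporationRate(rate@rates, ls, env, fluid, constants,
                                    humidityCorrection)
  list(times = rate@times, D = D,
       waterFractionLeft = rate@waterFractionLeft)
}

#' Robust plateau estimate of a weighted rate series
#'
#' Median and median-absolute-deviation of the series values whose water
#' fraction left falls inside the plateau window (default [0.35, 0.85]).
#' The window excludes the pre-coagulation dip at the start of drying
#' and the biased tail where the wet area can no longer be measured
#' reliably; median/MAD is used because the excursions outside the
#' plateau are asymmetric.
#'
#' @param series a list as returned by [weightedRateSeries()] (fields
#'   `D` and `waterFractionLeft`), or a [RateSeries-class] (its rates
#'   are then used).
#' @param waterWindow length-2 numeric, window on the water fraction
#'   left.
#' @param minPoints minimum number of samples required in the window.
#' @return a list with `value` (median), `spread` (MAD) and `n`.
#' @export
estimatePlateau <- function(series, waterWindow = c(0.35, 0.85),
                            minPoints = 5L) {
  if (is(series, "RateSeries")) {
    v <- series@rates; w <- series@waterFractionLeft
  } else {
    v <- series$D; w <- series$waterFractionLeft
  }
  inWin <- w >= waterWindow[1] & w <= waterWindow[2]
  if (sum(inWin) < minPoints)
    stop("fewer than ", minPoints, " samples inside the plateau window")
  list(value = stats::median(v[inWin]),
       spread = stats::mad(v[inWin]), n = sum(inWin))
}

#' Fit the mass versus wet-area relation
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of
#' m/m_i = 1 - alpha * (1 - A/A_i)^beta to normalised pairs, with
#' alpha in (0, 1), beta in (0, 2] and start (0.8, 0.2). The relation is
#' anchored at (1, 1): a fully wet pool has lost no mass.
#'
#' @param areaNorm normalised wet areas A/A_i, in [0, 1].
#' @param massNorm normalised masses m/m_i, in [0, 1].
#' @param start named start values for `alpha` and `beta`.
#' @return a [MassAreaFit-class].
#' @examples
#' a <- seq(0.05, 1, length.out = 40)
#' m <- 1 - 0.78 * (1 - a)^0.16
#' coef(fitMassArea(a, m))
#' @export
fitMassArea <- function(areaNorm, massNorm,
                        start = c(alpha = 0.8, beta = 0.2)) {
  if (length(areaNorm) != length(massNorm))
    stop("areaNorm and massNorm must have equal length")
  if (length(areaNorm) < 5L)
    stop("need at least 5 (area, mass) pairs")
  if (diff(range(areaNorm)) < 0.3)
    stop("area range too narrow to constrain the fit (need >= 0.3)")
  df <- data.frame(a = areaNorm, m = massNorm)
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ 1 - alpha * (1 - a)^beta, data = df,
                      start = as.list(start),
                      lower = c(alpha = 1e-6, beta = 1e-6),
                      upper = c(alpha = 1 - 1e-9, beta = 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("mass-area fit failed to converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  new("MassAreaFit", alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
      residualNorm = sqrt(mean(stats::resid(fit)^2)))
}

#' Fit the shape-linear relation
#'
#' Ordinary least squares of the shape-reduced evaporation rate J*/L*
#' on the contact angle theta, across pools of similar mass drying in
#' the same conditions. Each pool contributes its average J* estimated
#' after 50% of the initial mass has evaporated (so the slow final stage
#' does not bias the average).
#'
#' @param theta contact angles, radians.
#' @param Jstar average evaporation rates, kg m^-2 s^-1.
#' @param Lstar shape factors (dimensionless).
#' @return a [ShapeLinearFit-class].
#' @export
fitShapeLinear <- function(theta, Jstar, Lstar) {
  if (length(theta) < 3L) stop("need at least 3 pools")
  if (stats::sd(theta) < 1e-12)
    stop("degenerate design: contact angles do not vary")
  y <- Jstar / Lstar
  fit <- stats::lm(y ~ theta)
  ssRes <- sum(stats::resid(fit)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  new("ShapeLinearFit", slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]), rSquared = r2)
}

#' Average evaporation rate after 50% mass loss
#'
#' The per-pool summary entering the shape-linear fit: the mean of the
#' evaporation-rate samples taken after the stated fraction of the
#' initial mass has evaporated.
#'
#' @param record a [DryingRecord-class] with a mass channel.
#' @param basis `"total"` or `"wet"` (see [evaporationRate()]).
#' @param massLossMin fraction of initial mass that must have evaporated
#'   before samples count (default 0.5).
#' @param fluid a [FluidProperties-class].
#' @return mean evaporation rate, kg m^-2 s^-1.
#' @export
averageEvaporationRate <- function(record, basis = "total",
                                   massLossMin = 0.5,
                                   fluid = bloodProperties()) {
  rs <- evaporationRate(record, basis = basis, fluid = fluid)
  mi <- recordInitialMass(record)
  mAt <- stats::approx(record@times, record@masses, xout = rs@times,
                       rule = 2)$y
  sel <- (mi - mAt) / mi >= massLossMin
  if (!any(sel)) stop("no rate samples after the requested mass loss")
  mean(rs@rates[sel])
}
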