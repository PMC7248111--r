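## Elapsed-time estimation from a photograph of the drying front:
## chained and closed-form routes, plus Monte-Carlo uncertainty
## propagation over the height prior and the area measurement noise.

#' Pool mass from the wet area
#'
#' Inverts the calibrated mass versus wet-area relation at a measured
#' wet area: m_x = m_i (1 - alpha (1 - A_x/A_i)^beta). At A_x = A_i the
#' pool has lost no mass; at A_x = 0 the mass is (1 - alpha) m_i.
#'
#' @param Ax measured wet area, m^2, with 0 <= Ax <= Ai.
#' @param Ai total pool area, m^2.
#' @param mi initial pool mass, kg.
#' @param model a [CalibratedModel-class].
#' @return current pool mass m_x, kg.
#' @examples
#' massFromWetArea(0.5, 1, mi = 1)  # ~0.302 with the default fit
#' @export
massFromWetArea <- function(Ax, Ai, mi, model = calibratedModel()) {
  if (any(Ax > Ai * (1 + 1e-12))) stop("Ax must not exceed Ai")
  if (any(Ax < 0)) stop("Ax must be >= 0")
  mi * (1 - model@massAreaAlpha * (1 - pmin(Ax / Ai, 1))^model@massAreaBeta)
}

## Guard the estimator's calibration validity domain (the plateau
## diffusion coefficient was established at 23 +/- 1 degC, 20% RH).
.checkCalibrationDomain <- function(env, force) {
  tC <- env@temperature - 273.15
  rh <- env@relativeHumidity
  if (!force && (tC < 22 || tC > 24 || rh < 0.15 || rh > 0.25))
    stop("conditions outside the calibration domain (T 22-24 degC, ",
         "RH 15-25%); the calibrated diffusion coefficient may not ",
         "apply. Use force = TRUE to override.")
  invisible(TRUE)
}

.checkFrontPresent <- function(Ax, Ai) {
  if (any(Ax >= Ai * (1 - 1e-12)))
    stop("pool still fully wet: no drying front yet, wait for the front ",
         "to appear")
  if (any(Ax <= 0))
    stop("pool fully dry: the drying front has vanished and the method ",
         "is no longer applicable")
  invisible(TRUE)
}

## Vectorised closed-form elapsed time:
## t_x = alpha R k T^2 sqrt(A_i) sqrt(h) rho (1 - A_x/A_i)^beta /
##       (M d^2 pi sqrt(P) D P_w P_a)
.ageClosedForm <- function(Ax, Ai, P, h, env, fluid, model, constants,
                           humidityCorrection = FALSE) {
  pw <- effectiveVapourPressure(env, humidityCorrection)
  u <- 1 - Ax / Ai
  model@massAreaAlpha * constants@gasConstant * constants@boltzmann *
    env@temperature^2 * sqrt(Ai) * sqrt(h) * fluid@density *
    u^model@massAreaBeta /
    (fluid@molarMass * fluid@molecularDiameter^2 * pi * sqrt(P) *
       model@dBlood * pw * env@pressure)
}

## Normalised time factor for the wet-area-flux variant:
## W(fx) = integral_0^fx df / (1 - (f/alpha)^(1/beta)); elapsed time is
## then m_i W(fx) / (J* A_i) with fx the mass-loss fraction. With
## u = (f/alpha)^(1/beta) the integral has the exact series
## alpha * beta * sum_k u^(beta+k) / (beta+k), summed to machine
## precision (requires fx < alpha).
.wetFluxTimeFactor <- function(fx, alpha, beta) {
  if (any(fx < 0) || any(fx >= alpha))
    stop("mass-loss fraction must lie in [0, alpha) for the wet-flux route")
  u <- (fx / alpha)^(1 / beta)
  res <- numeric(length(u))
  term <- u^beta
  k <- 0
  while (max(term) > 1e-18 && k < 2e5) {
    res <- res + term / (beta + k)
    term <- term * u
    k <- k + 1
  }
  alpha * beta * res
}

#' Elapsed time, chained route
#'
#' Composes the model stage by stage: the height prior gives h, the
#' photographed geometry gives m_i = h A_i rho and L* = A_i/(h P), the
#' calibrated diffusion coefficient gives J*, the mass-area relation
#' converts the wet area A_x into m_x, and the elapsed time is
#' delta_t = (m_i - m_x) / (J* A_i). By default the flux-bearing area is
#' the total area A_i, exactly as in the published estimator;
#' `fluxArea = "wet"` instead integrates dm / (J* A_wet(m)) — a research
#' variant consistent with the wet-area-constant evaporation-rate
#' observation.
#'
#' @param Ax measured wet area, m^2 (0 < Ax < Ai: the front must exist).
#' @param Ai total pool area, m^2.
#' @param P pool perimeter, m.
#' @param surface a [SurfacePrior-class] (its mean height is used).
#' @param env an [EnvironmentConditions-class].
#' @param fluid a [FluidProperties-class].
#' @param model a [CalibratedModel-class].
#' @param constants a [PhysicalConstants-class].
#' @param fluxArea `"total"` (published form) or `"wet"`.
#' @param humidityCorrection logical, see
#'   [evaporationRateFromDiffusion()].
#' @return elapsed time since pool formation, s.
#' @export
elapsedTimeChained <- function(Ax, Ai, P, surface = tileSurfacePrior(),
                               env = environmentConditions(),
                               fluid = bloodProperties(),
                               model = calibratedModel(),
                               constants = physicalConstants(),
                               fluxArea = c("total", "wet"),
                               humidityCorrection = FALSE) {
  fluxArea <- match.arg(fluxArea)
  .checkFrontPresent(Ax, Ai)
  h <- surface@heightMean
  mi <- massFromGeometry(Ai, fluid, height = h)
  ls <- shapeFactor(Ai, height = h, perimeter = P)
  jstar <- evaporationRateFromDiffusion(model@dBlood, ls, env, fluid,
                                        constants, humidityCorrection)
  mx <- massFromWetArea(Ax, Ai, mi, model)
  if (fluxArea == "total") {
    (mi - mx) / (jstar * Ai)
  } else {
    fx <- (mi - mx) / mi
    mi * .wetFluxTimeFactor(fx, model@massAreaAlpha,
                            model@massAreaBeta) / (jstar * Ai)
  }
}

#' Elapsed time, closed form
#'
#' Direct evaluation of the closed-form elapsed-time expression
#' t_x = alpha R k_B T^2 A_i^(1/2) h^(1/2) rho (1 - A_x/A_i)^beta /
#' (M d^2 pi P^(1/2) D_blood P_w P_a), which is the algebraic
#' composition of the chained route with the total-area flux; the two
#' agree to floating-point accuracy.
#'
#' @inheritParams elapsedTimeChained
#' @return elapsed time since pool formation, s.
#' @examples
#' elapsedTimeClosedForm(Ax = 1.5e-3, Ai = 3e-3, P = 0.21,
#'                       env = ambientConditions(22.5, 20))
#' @export
elapsedTimeClosedForm <- function(Ax, Ai, P, surface = tileSurfacePrior(),
                                  env = environmentConditions(),
                                  fluid = bloodProperties(),
                                  model = calibratedModel(),
                                  constants = physicalConstants(),
                                  humidityCorrection = FALSE) {
  .checkFrontPresent(Ax, Ai)
  .ageClosedForm(Ax, Ai, P, surface@heightMean, env, fluid, model,
                 constants, humidityCorrection)
}

#' Estimate pool age with Monte-Carlo uncertainty
#'
#' Propagates the two dominant uncertainties of the photographic method
#' through the closed-form estimator: the surface height prior (h drawn
#' from a positive-truncated normal) and the area / perimeter
#' measurement noise (multiplicative Gaussian at `areaRelSd`). Each
#' snapshot is a measured (A_i, A_x, P) triple with a capture time on a
#' common clock; per draw, every snapshot dates the formation time as
#' captureTime - delta_t, the per-draw formation estimate is the median
#' over snapshots, and the reported elapsed time refers to the last
#' capture time. The point estimate is the median of the draws (the
#' mean is unstable under the sqrt(h) nonlinearity) and the interval is
#' the central `coverage` quantile range.
#'
#' The calibrated diffusion coefficient only applies near its
#' calibration conditions; estimation refuses to run outside
#' 22-24 degC / 15-25% RH unless `force = TRUE`.
#'
#' @param snapshots data.frame with columns `Ai`, `Ax`, `P` (SI units)
#'   and optionally `captureTime` (s, common clock; defaults to 0 for a
#'   single snapshot).
#' @param surface a [SurfacePrior-class].
#' @param env an [EnvironmentConditions-class].
#' @param fluid a [FluidProperties-class].
#' @param model a [CalibratedModel-class].
#' @param constants a [PhysicalConstants-class].
#' @param nDraws number of Monte-Carlo draws (>= 100).
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param areaRelSd relative standard deviation of the area and
#'   perimeter measurements (default 0.02).
#' @param coverage nominal coverage of the interval (default 0.90).
#' @param fluxArea `"total"` (published estimator) or `"wet"`.
#' @param humidityCorrection logical, see
#'   [evaporationRateFromDiffusion()].
#' @param force logical; override the calibration-domain guard.
#' @return an [AgeEstimate-class] with a complete `inputsSnapshot`.
#' @export
estimateAgeWithUncertainty <- function(snapshots,
                                       surface = tileSurfacePrior(),
                                       env = environmentConditions(),
                                       fluid = bloodProperties(),
                                       model = calibratedModel(),
                                       constants = physicalConstants(),
                                       nDraws = 2000L, seed = NULL,
                                       areaRelSd = 0.02, coverage = 0.90,
                                       fluxArea = c("total", "wet"),
                                       humidityCorrection = FALSE,
                                       force = FALSE) {
  fluxArea <- match.arg(fluxArea)
  if (!is.data.frame(snapshots) || nrow(snapshots) < 1L)
    stop("snapshots must be a data.frame with at least one row")
  if (!all(c("Ai", "Ax", "P") %in% names(snapshots)))
    stop("snapshots needs columns Ai, Ax, P")
  if (is.null(snapshots$captureTime)) {
    if (nrow(snapshots) > 1L)
      stop("multiple snapshots require a captureTime column")
    snapshots$captureTime <- 0
  }
  nDraws <- as.integer(nDraws)
  if (nDraws < 100L) stop("nDraws must be at least 100")
  .checkCalibrationDomain(env, force)
  .checkFrontPresent(snapshots$Ax, snapshots$Ai)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  nSnap <- nrow(snapshots)
  ## pool height: one draw per MC iteration, shared across snapshots
  h <- if (surface@heightSd > 0) {
    hh <- stats::rnorm(nDraws, surface@heightMean, surface@heightSd)
    while (any(hh <= 0))
      hh[hh <= 0] <- stats::rnorm(sum(hh <= 0), surface@heightMean,
                                  surface@heightSd)
    hh
  } else rep(surface@heightMean, nDraws)

  ageFun <- function(Ax, Ai, P, h) {
    if (fluxArea == "total") {
      .ageClosedForm(Ax, Ai, P, h, env, fluid, model, constants,
                     humidityCorrection)
    } else {
      ls <- Ai / (h * P)
      js <- evaporationRateFromDiffusion(model@dBlood, ls, env, fluid,
                                         constants, humidityCorrection)
      mi <- h * Ai * fluid@density
      fx <- model@massAreaAlpha * (1 - Ax / Ai)^model@massAreaBeta
      mi * .wetFluxTimeFactor(fx, model@massAreaAlpha,
                              model@massAreaBeta) / (js * Ai)
    }
  }

  formation <- matrix(NA_real_, nDraws, nSnap)
  for (i in seq_len(nSnap)) {
    noise <- function() {
      if (areaRelSd > 0) 1 + stats::rnorm(nDraws, 0, areaRelSd)
      else rep(1, nDraws)
    }
    Ai <- snapshots$Ai[i] * noise()
    Ax <- snapshots$Ax[i] * noise()
    P <- snapshots$P[i] * noise()
    Ax <- pmin(pmax(Ax, 1e-12), Ai * (1 - 1e-9))
    formation[, i] <- snapshots$captureTime[i] - ageFun(Ax, Ai, P, h)
  }
  tRef <- max(snapshots$captureTime)
  ages <- tRef - apply(formation, 1L, stats::median)
  qq <- stats::quantile(ages, c((1 - coverage) / 2, (1 + coverage) / 2),
                        names = FALSE)
  pt <- stats::median(ages)

  snapInputs <- list(
    snapshots = snapshots,
    surface = list(label = surface@surfaceLabel,
                   heightMean = surface@heightMean,
                   heightSd = surface@heightSd),
    environment = list(temperature = env@temperature,
                       relativeHumidity = env@relativeHumidity,
                       pressure = env@pressure),
    fluid = list(density = fluid@density,
                 surfaceTension = fluid@surfaceTension,
                 molarMass = fluid@molarMass,
                 molecularDiameter = fluid@molecularDiameter,
                 haematocrit = fluid@haematocrit,
                 residualMassFraction = fluid@residualMassFraction),
    model = list(dBlood = model@dBlood,
                 massAreaAlpha = model@massAreaAlpha,
                 massAreaBeta = model@massAreaBeta),
    constants = list(boltzmann = constants@boltzmann,
                     gasConstant = constants@gasConstant,
                     gravity = constants@gravity),
    flags = list(fluxArea = fluxArea,
                 humidityCorrection = humidityCorrection,
                 areaRelSd = areaRelSd, nDraws = nDraws,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 coverage = coverage, force = force))

  new("AgeEstimate", elapsedTime = pt,
      interval = c(min(qq[1], pt), max(qq[2], pt)), coverage = coverage,
      method = if (fluxArea == "total") "closed_form" else "chained",
      inputsSnapshot = snapInputs)
}
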