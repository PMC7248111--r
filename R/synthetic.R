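## Forward drying simulator and photograph renderer. The simulator
## composes the drying model forwards (constant flux, residual deposit,
## wet area from the inverted mass-area relation) so that every analysis
## stage can be tested against known ground truth; the renderer turns a
## simulated record into RGB frames with ground-truth masks.

## Run expr with a private, seeded RNG stream; the caller's RNG state is
## untouched.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Construct a simulation scenario
#'
#' Defaults mirror the calibration experiments: pools on tile at 23 degC
#' and 20% relative humidity, observation noise matching a 0.01 g
#' balance and 2% relative area error, two-minute sampling. When
#' `height` is omitted the true height is drawn from the surface prior
#' (deterministically under `seed`).
#'
#' @param initialMass initial pool mass, kg (1e-4 to 5e-2).
#' @param shapeIrregularity boundary perturbation amplitude (0 =
#'   circular pool; ~0.35 = strongly lobed).
#' @param height true mean pool height, m; `NULL` draws from `surface`.
#' @param environment an [EnvironmentConditions-class].
#' @param fluid a [FluidProperties-class].
#' @param model a [CalibratedModel-class].
#' @param surface a [SurfacePrior-class].
#' @param noise list with `areaRelSd` (relative sd of area readings)
#'   and `massSd` (absolute sd of mass readings, kg).
#' @param fluxBasis `"total"` (flux through the total area; matches the
#'   elapsed-time estimator, making the simulator/estimator round trip
#'   exact) or `"wet"` (constant flux through the wet area; the plateau
#'   experiment).
#' @param seed integer seed; fully determines the scenario and all
#'   simulated output.
#' @return a [PoolScenario-class].
#' @examples
#' sc <- poolScenario(5.24e-3, seed = 7)
#' sc
#' @export
poolScenario <- function(initialMass, shapeIrregularity = 0.15,
                         height = NULL,
                         environment = environmentConditions(),
                         fluid = bloodProperties(),
                         model = calibratedModel(),
                         surface = tileSurfacePrior(),
                         noise = list(areaRelSd = 0.02, massSd = 5e-6),
                         fluxBasis = c("total", "wet"),
                         seed = 1L) {
  fluxBasis <- match.arg(fluxBasis)
  seed <- as.integer(seed)
  if (is.null(height)) {
    height <- .withSeed(seed, {
      h <- stats::rnorm(1, surface@heightMean, surface@heightSd)
      while (h <= 0)
        h <- stats::rnorm(1, surface@heightMean, surface@heightSd)
      h
    })
  }
  new("PoolScenario", initialMass = initialMass,
      shapeIrregularity = shapeIrregularity, height = height,
      environment = environment, fluid = fluid, model = model,
      surface = surface, noise = noise, fluxBasis = fluxBasis,
      seed = seed)
}

#' Generate a pool outline
#'
#' Closed boundary built as a circle of area m_i / (rho h), perturbed by
#' low-order Fourier modes (wavenumbers 2-6) with amplitudes
#' proportional to the scenario's `shapeIrregularity`. The boundary is
#' star-shaped (radius strictly positive in every direction), hence
#' never self-intersecting; amplitudes that would pinch the boundary are
#' rescaled. The polygon is rescaled so its shoelace area equals the
#' target area exactly; the perimeter is the exact polygon perimeter.
#'
#' @param scenario a [PoolScenario-class].
#' @param nVertices number of boundary vertices.
#' @return list with `angles`, `radii` (m), `x`, `y` (m), `area` (m^2),
#'   `perimeter` (m).
#' @export
generateShape <- function(scenario, nVertices = 720L) {
  fluid <- scenario@fluid
  targetArea <- scenario@initialMass / (fluid@density * scenario@height)
  r0 <- sqrt(targetArea / pi)
  irr <- scenario@shapeIrregularity
  modes <- 2:6
  pert <- .withSeed(scenario@seed + 1L, list(
    amp = irr * stats::runif(length(modes), 0.2, 1) / modes,
    phase = stats::runif(length(modes), 0, 2 * pi)))
  ## keep the boundary star-shaped: total relative perturbation < 0.8
  tot <- sum(pert$amp)
  if (tot > 0.8) pert$amp <- pert$amp * 0.8 / tot
  phi <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  rel <- rep(1, nVertices)
  for (i in seq_along(modes))
    rel <- rel + pert$amp[i] * cos(modes[i] * phi + pert$phase[i])
  if (any(rel <= 0)) stop("degenerate boundary: irregularity too large")
  r <- r0 * rel
  x <- r * cos(phi); y <- r * sin(phi)
  shoelace <- function(x, y) {
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    abs(sum(x * yn - xn * y)) / 2
  }
  s <- sqrt(targetArea / shoelace(x, y))
  r <- r * s; x <- x * s; y <- y * s
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  list(angles = phi, radii = r, x = x, y = y,
       area = shoelace(x, y),
       perimeter = sum(sqrt((xn - x)^2 + (yn - y)^2)))
}

## Constant evaporation rate and geometry of a scenario.
.scenarioPhysics <- function(scenario, shape = NULL) {
  if (is.null(shape)) shape <- generateShape(scenario)
  h <- scenario@height
  mi <- scenario@initialMass
  geom <- poolGeometry(totalArea = shape$area, perimeter = shape$perimeter,
                       height = h, initialMass = mi)
  js <- evaporationRateFromDiffusion(
    scenario@model@dBlood, shapeFactor(geom), scenario@environment,
    scenario@fluid, physicalConstants())
  list(shape = shape, geometry = geom, jStar = js, mi = mi,
       residMass = scenario@fluid@residualMassFraction * mi)
}

## Wet-area fraction at normalised mass loss f (inverted mass-area fit).
.wetFractionAtLoss <- function(f, model) {
  pmin(pmax(1 - (pmax(f, 0) / model@massAreaAlpha)^(1 / model@massAreaBeta),
            0), 1)
}

#' Simulate the drying of a pool
#'
#' Forward composition of the drying model. With the default
#' `fluxBasis = "total"` the mass declines linearly, m(t) = m_i - J*
#' A_i t, until the residual deposit (residualMassFraction * m_i) is
#' reached, then stays constant; with `fluxBasis = "wet"` the flux runs
#' through the shrinking wet area, dm/dt = -J* A_wet(t), integrated
#' exactly (series solution of the separable ODE). In both cases the
#' wet area follows the inverted mass-area relation A_wet/A_i = 1 -
#' ((1 - m/m_i)/alpha)^(1/beta) and the total area stays constant.
#' Observation channels add seeded Gaussian noise on top of the
#' noiseless ground truth.
#'
#' @param scenario a [PoolScenario-class].
#' @param dt sampling interval, s (default 120 s, the two-minute
#'   photography cadence).
#' @param tMax optional stop time, s; default runs slightly past
#'   complete drying.
#' @return a [SimulatedPool-class] holding the noiseless truth and the
#'   noisy observed record.
#' @examples
#' sim <- simulateDrying(poolScenario(5.24e-3, seed = 1), dt = 600)
#' sim
#' @export
simulateDrying <- function(scenario, dt = 120, tMax = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  ph <- .scenarioPhysics(scenario)
  mi <- ph$mi
  Ai <- ph$shape$area
  model <- scenario@model
  fmax <- 1 - scenario@fluid@residualMassFraction
  if (fmax >= model@massAreaAlpha && scenario@fluxBasis == "wet")
    stop("wet-basis simulation requires residualMassFraction > 1 - alpha")
  tau <- ph$jStar * Ai / mi            # fractional mass-loss rate, 1/s
  tEnd <- if (scenario@fluxBasis == "total") fmax / tau
          else .wetFluxTimeFactor(fmax, model@massAreaAlpha,
                                  model@massAreaBeta) / tau
  if (is.null(tMax)) tMax <- tEnd * 1.02
  times <- seq(0, tMax, by = dt)
  if (scenario@fluxBasis == "total") {
    f <- pmin(tau * times, fmax)
  } else {
    ## invert W(f) = tau * t by vectorised Newton iteration
    w <- pmin(tau * times, .wetFluxTimeFactor(
      fmax, model@massAreaAlpha, model@massAreaBeta))
    f <- pmin(w, fmax)                 # initial guess (W(f) >= f)
    for (it in 1:60) {
      g <- 1 - (f / model@massAreaAlpha)^(1 / model@massAreaBeta)
      step <- (.wetFluxTimeFactor(f, model@massAreaAlpha,
                                  model@massAreaBeta) - w) * g
      f <- pmin(pmax(f - step, 0), fmax)
      if (max(abs(step)) < 1e-15) break
    }
  }
  m <- mi * (1 - f)
  aw <- Ai * .wetFractionAtLoss(f, model)
  truth <- dryingRecord(
    times = times, masses = m, totalAreas = rep(Ai, length(times)),
    wetAreas = aw, environment = scenario@environment,
    geometry = ph$geometry, initialMass = mi,
    surfaceLabel = scenario@surface@surfaceLabel)
  obs <- .withSeed(scenario@seed + 2L, {
    n <- length(times)
    mObs <- m + stats::rnorm(n, 0, scenario@noise$massSd)
    aiObs <- Ai * (1 + stats::rnorm(n, 0, scenario@noise$areaRelSd))
    awObs <- aw * (1 + stats::rnorm(n, 0, scenario@noise$areaRelSd))
    list(m = mObs, ai = pmax(aiObs, 0),
         aw = pmin(pmax(awObs, 0), pmax(aiObs, 0)))
  })
  observed <- dryingRecord(
    times = times, masses = obs$m, totalAreas = obs$ai,
    wetAreas = obs$aw, environment = scenario@environment,
    geometry = ph$geometry, initialMass = mi,
    surfaceLabel = scenario@surface@surfaceLabel,
    qualityFlags = "synthetic-observation-noise")
  new("SimulatedPool", scenario = scenario, shape = ph$shape,
      jStar = ph$jStar, truth = truth, record = observed)
}

#' Ground-truth snapshot at a given mass loss
#'
#' Analytic state of a simulated pool at the instant a stated fraction
#' of the initial mass has evaporated: the elapsed time, the (exact)
#' total and wet areas and the perimeter. Used for round-trip tests of
#' the elapsed-time estimator.
#'
#' @param scenario a [PoolScenario-class].
#' @param massLossFraction fraction of the initial mass evaporated, in
#'   (0, 1 - residualMassFraction).
#' @return list with `time` (s), `Ai`, `Ax` (m^2), `P` (m), `mi`, `mx`
#'   (kg), `height` (m), `jStar` (kg m^-2 s^-1).
#' @export
snapshotAtMassLoss <- function(scenario, massLossFraction) {
  fmax <- 1 - scenario@fluid@residualMassFraction
  if (massLossFraction <= 0 || massLossFraction >= fmax)
    stop("massLossFraction must lie in (0, 1 - residualMassFraction)")
  ph <- .scenarioPhysics(scenario)
  tau <- ph$jStar * ph$shape$area / ph$mi
  model <- scenario@model
  t <- if (scenario@fluxBasis == "total") massLossFraction / tau
       else .wetFluxTimeFactor(massLossFraction, model@massAreaAlpha,
                               model@massAreaBeta) / tau
  list(time = t, Ai = ph$shape$area,
       Ax = ph$shape$area * .wetFractionAtLoss(massLossFraction, model),
       P = ph$shape$perimeter, mi = ph$mi,
       mx = ph$mi * (1 - massLossFraction), height = scenario@height,
       jStar = ph$jStar)
}

#' Image scale that fits a pool into a frame
#'
#' @param sim a [SimulatedPool-class].
#' @param imageSize frame size in pixels, c(nx, ny).
#' @param fill fraction of the smaller frame dimension spanned by the
#'   pool's largest diameter.
#' @return a [ScaleCalibration-class].
#' @export
fittingCalibration <- function(sim, imageSize = c(480L, 480L),
                               fill = 0.7) {
  rmax <- max(sim@shape$radii)
  new("ScaleCalibration",
      metresPerPixel = 2 * rmax / (fill * min(imageSize)))
}

## Rasterise a star-shaped boundary: TRUE where the pixel centre lies
## inside. cx, cy in pixel units; radii in metres.
.rasterizeShape <- function(shape, calibration, imageSize, cx, cy) {
  s <- calibration@metresPerPixel
  nx <- imageSize[1]; ny <- imageSize[2]
  px <- (seq_len(nx) - cx) * s
  py <- (seq_len(ny) - cy) * s
  X <- matrix(px, nx, ny)
  Y <- matrix(py, nx, ny, byrow = TRUE)
  ang <- atan2(Y, X)
  rad <- sqrt(X^2 + Y^2)
  ## periodic radius lookup
  a <- c(shape$angles - 2 * pi, shape$angles, shape$angles + 2 * pi)
  r <- rep(shape$radii, 3L)
  rAt <- matrix(stats::approx(a, r, xout = as.numeric(ang))$y, nx, ny)
  rad <= rAt
}

#' Render a simulated drying sequence
#'
#' Produces per-frame RGB rasters emulating overhead photographs:
#' neutral background, optional dark reference scale bar, the pool
#' silhouette from the scenario's generated shape, a dried annulus
#' (dark colour class) between the boundary and a wet core (red colour
#' class) obtained by uniform inward offset (distance-transform level
#' set) whose pixel area matches the record's wet area to the nearest
#' pixel, optional crack texture (thin lines exposing the substrate) in
#' the dried zone, and seeded Gaussian pixel noise. Ground-truth masks
#' are returned alongside each frame.
#'
#' @param sim a [SimulatedPool-class].
#' @param calibration a [ScaleCalibration-class]; default fits the pool
#'   into the frame.
#' @param imageSize frame size in pixels, c(nx, ny).
#' @param frames indices into the record's time points to render
#'   (default: 8 frames evenly spaced over drying).
#' @param pixelNoiseSd sd of the additive pixel noise (default 0.01).
#' @param scaleBar draw a 10 mm reference bar.
#' @param crackTexture draw substrate-coloured cracks in the dried zone.
#' @return list of frames; each has `image` (nx x ny x 3 array in
#'   [0, 1]), `poolMask`, `wetMask` (logical matrices), `time` and the
#'   ground-truth `wetArea` (m^2).
#' @export
renderSequence <- function(sim, calibration = NULL,
                           imageSize = c(480L, 480L), frames = NULL,
                           pixelNoiseSd = 0.01, scaleBar = TRUE,
                           crackTexture = FALSE) {
  truth <- sim@truth
  if (!length(truth@wetAreas)) stop("record has no wet-area channel")
  if (is.null(calibration)) calibration <- fittingCalibration(sim, imageSize)
  if (is.null(frames))
    frames <- unique(round(seq(1, length(truth@times), length.out = 8)))
  s <- calibration@metresPerPixel
  nx <- imageSize[1]; ny <- imageSize[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  pool <- .rasterizeShape(sim@shape, calibration, imageSize, cx, cy)
  if (!any(pool)) stop("pool does not intersect the frame")
  dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(pool * 1)))
  poolIdx <- which(pool)
  distOrder <- poolIdx[order(dist[poolIdx], decreasing = TRUE)]
  bg <- c(0.82, 0.82, 0.79)
  wetCol <- c(0.55, 0.06, 0.08)
  dryCol <- c(0.10, 0.04, 0.05)
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    i <- frames[k]
    awTarget <- truth@wetAreas[i]
    nWet <- min(round(awTarget / s^2), length(poolIdx))
    wet <- matrix(FALSE, nx, ny)
    if (nWet > 0) wet[distOrder[seq_len(nWet)]] <- TRUE
    if (nWet > 0 && nWet < length(poolIdx) &&
        abs(nWet * s^2 - awTarget) / max(awTarget, s^2) > 0.01)
      stop("internal error: rendered wet core misses the target area")
    img <- array(rep(bg, each = nx * ny), dim = c(nx, ny, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[pool] <- dryCol[ch]
      plane[wet] <- wetCol[ch]
      img[, , ch] <- plane
    }
    if (crackTexture && any(pool & !wet)) {
      img <- .withSeed(sim@scenario@seed + 40L + i, {
        .drawCracks(img, pool, wet, sim@shape, calibration, cx, cy, bg)
      })
    }
    if (scaleBar) {
      barLen <- max(2L, round(0.010 / s))
      xs <- 8:min(8 + barLen - 1, nx)
      ys <- 8:13
      for (ch in 1:3) img[xs, ys, ch] <- 0.05
    }
    if (pixelNoiseSd > 0) {
      img <- .withSeed(sim@scenario@seed + 100L + i, {
        pmin(pmax(img + stats::rnorm(length(img), 0, pixelNoiseSd), 0), 1)
      })
    }
    out[[k]] <- list(image = img, poolMask = pool, wetMask = wet,
                     time = truth@times[i], wetArea = awTarget)
  }
  out
}

## Thin substrate-coloured radial cracks across the dried annulus.
.drawCracks <- function(img, pool, wet, shape, calibration, cx, cy, bg) {
  s <- calibration@metresPerPixel
  nCracks <- 6L
  angles <- stats::runif(nCracks, 0, 2 * pi)
  rMaxPx <- max(shape$radii) / s
  for (a in angles) {
    wob <- stats::runif(1, -0.15, 0.15)
    rr <- seq(2, rMaxPx, by = 0.5)
    aa <- a + wob * rr / rMaxPx
    xi <- round(cx + rr * cos(aa)); yi <- round(cy + rr * sin(aa))
    ok <- xi >= 1 & xi <= nrow(pool) & yi >= 1 & yi <= ncol(pool)
    xi <- xi[ok]; yi <- yi[ok]
    idx <- cbind(xi, yi)
    inDried <- pool[idx] & !wet[idx]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx[inDried, , drop = FALSE]] <- bg[ch]
      img[, , ch] <- plane
    }
  }
  img
}

#' Cohorts of simulation scenarios
#'
#' Two presets mirroring the calibration experiments. `"size_study"`:
#' five pools spanning initial masses 0.30-31.37 g at fixed
#' irregularity. `"shape_study"`: twenty pools of the same initial mass
#' (5.24 +/- 0.47 g) with shape irregularity spanning [0, 0.35]. Both
#' are deterministic under `seed`; per-pool heights are drawn from the
#' surface prior.
#'
#' @param preset `"size_study"` or `"shape_study"`.
#' @param seed integer seed.
#' @param fluxBasis flux basis passed to every scenario.
#' @param noise observation-noise list passed to every scenario.
#' @return list of [PoolScenario-class] objects.
#' @export
cohort <- function(preset = c("size_study", "shape_study"), seed = 1L,
                   fluxBasis = "total",
                   noise = list(areaRelSd = 0.02, massSd = 5e-6)) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  if (preset == "size_study") {
    masses <- c(0.30, 1.74, 5.41, 8.75, 31.37) * 1e-3
    irr <- rep(0.15, length(masses))
  } else {
    masses <- .withSeed(seed,
      (5.24 + stats::runif(20, -0.47, 0.47)) * 1e-3)
    irr <- seq(0, 0.35, length.out = 20)
  }
  lapply(seq_along(masses), function(i)
    poolScenario(initialMass = masses[i], shapeIrregularity = irr[i],
                 fluxBasis = fluxBasis, noise = noise,
                 seed = seed + 1000L * i))
}
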