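test_that("volume, height and mass formulas are mutually consistent", {
  expect_equal(volumeFromMass(5.24e-3, blood), 4.943e-6, tolerance = 1e-3)
  expect_equal(volumeFromMass(blood@density * 1, blood), 1)
  expect_error(volumeFromMass(0), "positive")

  expect_equal(heightFromVolumeArea(4.94e-6, 3.43e-3), 1.44e-3,
               tolerance = 1e-2)
  expect_equal(heightFromVolumeArea(2.2, 2.2), 1)
  expect_equal(heightFromVolumeArea(0, 1e-3), 0)
  expect_error(heightFromVolumeArea(1e-6, 0), "area")

  expect_equal(massFromGeometry(2.5e-3, blood, height = 1.44e-3),
               3.816e-3, tolerance = 1e-6)
  expect_equal(massFromGeometry(0, blood, height = 1e-3), 0)
  ## identity chain: mass -> volume -> height recovers h
  m <- massFromGeometry(2.5e-3, blood, height = 1.44e-3)
  expect_equal(heightFromVolumeArea(volumeFromMass(m, blood), 2.5e-3),
               1.44e-3)
})

test_that("shape factor matches A/(hP) and its scaling law", {
  g <- poolGeometry(2.5e-3, 0.20, 1.44e-3, 5.24e-3)
  expect_equal(shapeFactor(g), 8.68, tolerance = 1e-3)
  expect_equal(shapeFactor(1.44e-3 * 0.2, height = 1.44e-3,
                           perimeter = 0.2), 1)
  ## isotropic rescale A -> s^2 A, P -> s P at fixed h: L* -> s L*
  s <- 3.7
  expect_equal(shapeFactor(s^2 * 2.5e-3, height = 1.44e-3,
                           perimeter = s * 0.20),
               s * shapeFactor(2.5e-3, height = 1.44e-3, perimeter = 0.20))
  expect_error(shapeFactor(1e-3, height = 0, perimeter = 0.1), "degenerate")
})

test_that("contact angle follows the flattened-puddle approximation", {
  g <- poolGeometry(2.5e-3, 0.20, 1.44e-3, 5.24e-3)
  expect_equal(contactAngle(g, blood, consts), 0.863, tolerance = 1e-3)
  ## flat-film limit: theta -> 0 as mass -> 0
  gSmall <- poolGeometry(2.5e-3, 0.20, 1.44e-3, 1e-9)
  expect_lt(contactAngle(gSmall, blood, consts), 1e-4)
  ## arccos(0) forced: g m^2 / (2 gamma rho A^2) = 1 gives pi/2
  mHalf <- sqrt(2 * blood@surfaceTension * blood@density * (2.5e-3)^2 /
                  consts@gravity)
  gHalf <- poolGeometry(2.5e-3, 0.20, 1.44e-3, mHalf)
  expect_equal(contactAngle(gHalf, blood, consts), pi / 2)
  ## out of range: explicit error, no clamping
  gHeap <- poolGeometry(1e-4, 0.04, 5e-3, 4e-2)
  expect_error(contactAngle(gHeap, blood, consts), "out of range")
  ## monotone in initial mass at fixed area
  ms <- seq(1e-3, 8e-3, length.out = 10)
  th <- vapply(ms, function(m)
    contactAngle(poolGeometry(2.5e-3, 0.2, 1.44e-3, m), blood, consts),
    numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("saturation vapour pressure matches steam-table anchors", {
  expect_equal(saturationVapourPressure(293.15), 2339, tolerance = 5e-3)
  expect_equal(saturationVapourPressure(373.15), 101325, tolerance = 1e-2)
  tt <- seq(274, 372, length.out = 40)
  expect_true(all(diff(saturationVapourPressure(tt)) > 0))
  expect_error(saturationVapourPressure(250), "range")
  expect_error(saturationVapourPressure(400), "range")
  ## swappable correlation
  expect_equal(saturationVapourPressure(300, formula = function(t) 42), 42)
})

test_that("Knudsen layer has the right value, range and proportionalities", {
  expect_equal(knudsenLayer(environmentConditions(296.15, 0.2, 101325),
                            blood, consts), 1.70e-7, tolerance = 3e-3)
  e1 <- environmentConditions(296.15, 0.2, 101325)
  e2 <- environmentConditions(296.15, 0.2, 2 * 101325)
  expect_equal(knudsenLayer(e1, blood, consts) / 2,
               knudsenLayer(e2, blood, consts))
  e3 <- environmentConditions(2 * 296.15, 0.2, 101325)
  expect_equal(2 * knudsenLayer(e1, blood, consts),
               knudsenLayer(e3, blood, consts))
  ## ambient-range invariant for plausible molecular diameters
  for (d in c(2.5e-10, 2.75e-10, 3.0e-10)) {
    fl <- bloodProperties(molecularDiameter = d)
    lk <- knudsenLayer(env23, fl, consts)
    expect_gt(lk, 1e-7); expect_lt(lk, 3e-7)
  }
})

test_that("evaporation rate and diffusion weighting invert each other", {
  e20 <- environmentConditions(293.15, 0.2)
  js <- evaporationRateFromDiffusion(1e-9, 9, e20, blood, consts)
  expect_equal(js, 3.4e-5, tolerance = 2e-2)
  ## L* quadrupled halves J*
  expect_equal(evaporationRateFromDiffusion(1e-9, 36, e20, blood, consts),
               js / 2)
  expect_equal(diffusionFromEvaporationRate(js, 9, e20, blood, consts),
               1e-9)
  expect_equal(diffusionFromEvaporationRate(0, 9, e20, blood, consts), 0)
  ## property sweep: forward-then-inverse is the identity to < 1e-12
  set.seed(42)
  for (i in 1:25) {
    D <- 10^runif(1, -10, -8)
    ls <- runif(1, 0.5, 40)
    env <- environmentConditions(runif(1, 285, 305), runif(1, 0, 0.8),
                                 runif(1, 9e4, 1.1e5))
    rt <- diffusionFromEvaporationRate(
      evaporationRateFromDiffusion(D, ls, env, blood, consts),
      ls, env, blood, consts)
    expect_equal(rt, D, tolerance = 1e-12)
  }
})

test_that("humidity correction multiplies the driving pressure by 1 - RH", {
  envH <- environmentConditions(296.15, 0.4)
  jOff <- evaporationRateFromDiffusion(1e-9, 9, envH, blood, consts)
  jOn <- evaporationRateFromDiffusion(1e-9, 9, envH, blood, consts,
                                      humidityCorrection = TRUE)
  expect_equal(jOn, jOff * 0.6)
  ## default (as-printed) form ignores RH entirely
  envDry <- environmentConditions(296.15, 0.0)
  expect_equal(evaporationRateFromDiffusion(1e-9, 9, envDry, blood, consts),
               jOff)
})

test_that("class validity rejects non-physical inputs", {
  expect_error(environmentConditions(150, 0.2), "temperature")
  expect_error(environmentConditions(296, 1.4), "relativeHumidity")
  expect_error(bloodProperties(residualMassFraction = 1.2),
               "residualMassFraction")
  expect_error(poolGeometry(1e-3, -0.1, 1e-3, 1e-3), "perimeter")
  ## isoperimetric violation: perimeter far below the disc bound
  expect_error(poolGeometry(1e-2, 0.01, 1e-3, 1e-3), "isoperimetric")
})
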