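test_that("mass from wet area honours the anchor points", {
  expect_equal(massFromWetArea(1, 1, mi = 1, model0), 1)
  expect_equal(massFromWetArea(0, 1, mi = 1, model0), 0.22)
  expect_equal(massFromWetArea(0.5, 1, mi = 1, model0), 0.302,
               tolerance = 1e-3)
  expect_error(massFromWetArea(1.1, 1, 1, model0), "exceed")
  expect_error(massFromWetArea(-0.1, 1, 1, model0), ">= 0")
})

test_that("closed form equals the chained route over a random sweep", {
  set.seed(11)
  for (i in 1:100) {
    Ai <- runif(1, 5e-4, 8e-3)
    Ax <- Ai * runif(1, 0.05, 0.98)
    P <- 2 * sqrt(pi * Ai) * runif(1, 1.0, 1.6)
    sp <- surfacePrior("x", runif(1, 0.8e-3, 2.2e-3), 0)
    env <- environmentConditions(runif(1, 288, 303), runif(1, 0.1, 0.6))
    a1 <- elapsedTimeChained(Ax, Ai, P, sp, env, blood, model0, consts)
    a2 <- elapsedTimeClosedForm(Ax, Ai, P, sp, env, blood, model0, consts)
    expect_lt(abs(a1 - a2) / a2, 1e-10)
  }
})

test_that("elapsed time behaves physically at the boundaries", {
  sp <- tilePrior
  ## front just appeared: elapsed time -> 0 (slowly, as (1 - Ax/Ai)^beta)
  tFull <- elapsedTimeClosedForm(3e-3 * 0.2, 3e-3, 0.21, sp, env23)
  eps <- c(1e-3, 1e-6, 1e-8, 1e-10)
  tEps <- vapply(eps, function(e)
    elapsedTimeClosedForm(3e-3 * (1 - e), 3e-3, 0.21, sp, env23),
    numeric(1))
  expect_true(all(diff(tEps) < 0))
  expect_lt(tEps[4] / tFull, 0.03)
  ## no front yet / fully dry: advisory errors
  expect_error(elapsedTimeChained(3e-3, 3e-3, 0.21, sp, env23),
               "fully wet")
  expect_error(elapsedTimeChained(0, 3e-3, 0.21, sp, env23), "fully dry")
  ## doubling D halves the elapsed time
  t1 <- elapsedTimeClosedForm(1.5e-3, 3e-3, 0.21, sp, env23,
                              model = calibratedModel(dBlood = 1e-9))
  t2 <- elapsedTimeClosedForm(1.5e-3, 3e-3, 0.21, sp, env23,
                              model = calibratedModel(dBlood = 2e-9))
  expect_equal(t1, 2 * t2)
  ## monotone decreasing in Ax; scales as sqrt(h)
  ax <- seq(0.2e-3, 2.8e-3, length.out = 12)
  tt <- elapsedTimeClosedForm(ax, 3e-3, 0.21, sp, env23)
  expect_true(all(diff(tt) < 0))
  spHalf <- surfacePrior("x", sp@heightMean / 4, 0)
  expect_equal(elapsedTimeClosedForm(1.5e-3, 3e-3, 0.21, spHalf, env23),
               elapsedTimeClosedForm(1.5e-3, 3e-3, 0.21, sp, env23) / 2)
})

test_that("noiseless simulator round trip recovers the snapshot age", {
  sc <- referenceScenario(seed = 31)
  sp0 <- surfacePrior("tile", sc@height, 0)
  for (w in c(0.15, 0.5, 0.85)) {
    f <- model0@massAreaAlpha * (1 - w)^model0@massAreaBeta
    sn <- snapshotAtMassLoss(sc, f)
    est <- elapsedTimeClosedForm(sn$Ax, sn$Ai, sn$P, sp0, sc@environment)
    expect_lt(abs(est - sn$time) / sn$time, 1e-3)
  }
  ## wet-flux research variant round-trips a wet-basis simulation
  scw <- referenceScenario(seed = 32, fluxBasis = "wet")
  snw <- snapshotAtMassLoss(scw, 0.5)
  estw <- elapsedTimeChained(snw$Ax, snw$Ai, snw$P,
                             surfacePrior("tile", scw@height, 0),
                             scw@environment, fluxArea = "wet")
  expect_lt(abs(estw - snw$time) / snw$time, 1e-6)
})

test_that("Monte-Carlo estimate degenerates to the closed form without noise", {
  sp0 <- surfacePrior("tile", 1.44e-3, 0)
  snap <- data.frame(Ai = 3e-3, Ax = 1.8e-3, P = 0.21)
  est <- estimateAgeWithUncertainty(snap, sp0, env23, nDraws = 200,
                                    seed = 1, areaRelSd = 0)
  cf <- elapsedTimeClosedForm(1.8e-3, 3e-3, 0.21, sp0, env23)
  expect_equal(elapsedTime(est), cf)
  expect_equal(ageInterval(est), c(cf, cf))
  expect_equal(est@method, "closed_form")
})

test_that("interval width matches the delta-method height propagation", {
  snap <- data.frame(Ai = 3e-3, Ax = 1.8e-3, P = 0.21)
  est <- estimateAgeWithUncertainty(snap, tilePrior, env23,
                                    nDraws = 20000, seed = 2,
                                    areaRelSd = 0)
  t0 <- elapsedTime(est)
  ## t ~ sqrt(h): relative sd ~ heightSd / (2 heightMean) = 6.6%; the
  ## central 90% half-width is 1.645 times that
  halfWidth <- diff(ageInterval(est)) / 2
  expected <- 1.645 * tilePrior@heightSd / (2 * tilePrior@heightMean) * t0
  expect_equal(halfWidth, expected, tolerance = 0.08)
})

test_that("multiple snapshots combine on a common formation time", {
  sc <- referenceScenario(seed = 33)
  sp0 <- surfacePrior("tile", sc@height, 0)
  f1 <- 0.35; f2 <- 0.55
  s1 <- snapshotAtMassLoss(sc, f1)
  s2 <- snapshotAtMassLoss(sc, f2)
  offset <- 1800  # first photo taken 30 min after some clock origin
  snaps <- data.frame(Ai = c(s1$Ai, s2$Ai), Ax = c(s1$Ax, s2$Ax),
                      P = c(s1$P, s2$P),
                      captureTime = offset + c(s1$time, s2$time))
  est <- estimateAgeWithUncertainty(snaps, sp0, sc@environment,
                                    nDraws = 200, seed = 3, areaRelSd = 0)
  ## age is reported at the last capture time
  expect_equal(elapsedTime(est), s2$time, tolerance = 1e-6)
  expect_error(estimateAgeWithUncertainty(
    data.frame(Ai = c(1, 1) * 3e-3, Ax = c(1, 1) * 2e-3,
               P = c(1, 1) * 0.21), sp0, env23), "captureTime")
})

test_that("estimation guards its inputs and calibration domain", {
  snap <- data.frame(Ai = 3e-3, Ax = 1.8e-3, P = 0.21)
  expect_error(estimateAgeWithUncertainty(snap, tilePrior,
    ambientConditions(30, 20), nDraws = 200), "calibration domain")
  expect_error(estimateAgeWithUncertainty(snap, tilePrior,
    ambientConditions(23, 60), nDraws = 200), "calibration domain")
  ## force overrides the guard
  est <- estimateAgeWithUncertainty(snap, tilePrior,
    ambientConditions(30, 20), nDraws = 200, seed = 1, force = TRUE)
  expect_s4_class(est, "AgeEstimate")
  expect_error(estimateAgeWithUncertainty(snap[0, ], tilePrior, env23),
               "at least one row")
  expect_error(estimateAgeWithUncertainty(snap, tilePrior, env23,
                                          nDraws = 50), "100")
  ## provenance: every constant and flag is echoed into the snapshot
  est2 <- estimateAgeWithUncertainty(snap, tilePrior, env23,
                                     nDraws = 200, seed = 4)
  snapList <- inputsSnapshot(est2)
  expect_setequal(names(snapList),
                  c("snapshots", "surface", "environment", "fluid",
                    "model", "constants", "flags"))
  expect_equal(snapList$model$dBlood, 1e-9)
  expect_equal(snapList$flags$seed, 4)
})

test_that("estimates are invariant under boundary unit conversion", {
  ## the same geometry entered in SI or via the mm-based CSV boundary
  sp0 <- surfacePrior("tile", 1.44e-3, 0)
  tSI <- elapsedTimeClosedForm(1.8e-3, 3e-3, 0.21, sp0, env23)
  AiMm2 <- 3e-3 * 1e6; AxMm2 <- 1.8e-3 * 1e6; Pmm <- 0.21 * 1e3
  tConv <- elapsedTimeClosedForm(AxMm2 * 1e-6, AiMm2 * 1e-6, Pmm * 1e-3,
                                 sp0, env23)
  expect_equal(tSI, tConv)
})
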