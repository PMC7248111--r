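test_that("water fraction left interpolates between full and residual", {
  t <- seq(0, 4000, by = 1000)
  mi <- 8e-3
  m <- mi * c(1, 0.8, 0.615, 0.4, 0.23)
  rec <- dryingRecord(t, masses = m, totalAreas = rep(3e-3, 5),
                      initialMass = mi)
  wfl <- waterFractionLeft(rec, blood)
  expect_equal(wfl[1], 1)
  expect_equal(wfl[5], 0)
  expect_equal(wfl[3], 0.5)
  ## below the residual: clipped at 0, never negative
  rec2 <- dryingRecord(t, masses = mi * c(1, 0.8, 0.5, 0.23, 0.20),
                       initialMass = mi)
  expect_equal(min(waterFractionLeft(rec2, blood)), 0)
  ## a residual fraction of 1 (residual >= initial mass) is rejected at
  ## construction, so the downstream configuration guard cannot be hit
  expect_error(bloodProperties(residualMassFraction = 1),
               "residualMassFraction")
})

test_that("evaporation rate is exact on linear mass loss and two points", {
  A <- 3.2e-3
  c0 <- 2e-8
  t <- seq(0, 9000, by = 600)
  rec <- dryingRecord(t, masses = 8e-3 - c0 * t,
                      totalAreas = rep(A, length(t)), initialMass = 8e-3)
  rs <- evaporationRate(rec, basis = "total")
  expect_equal(rates(rs), rep(c0 / A, length(t) - 2))
  expect_equal(obsTimes(rs), t[2:(length(t) - 1)])
  ## two-point record: single forward-difference rate
  rec2 <- dryingRecord(c(0, 600), masses = c(8e-3, 7.9e-3),
                       totalAreas = c(A, A), initialMass = 8e-3)
  rs2 <- evaporationRate(rec2, basis = "total")
  expect_equal(rates(rs2), 1e-4 / (600 * A))
  expect_error(evaporationRate(
    dryingRecord(c(0, 600), masses = c(8e-3, 7.9e-3), totalAreas = c(A, A)),
    basis = "wet"), "wet")
})

test_that("wet-basis rate recovers the generating constant flux", {
  sc <- referenceScenario(seed = 5, fluxBasis = "wet")
  sim <- simulateDrying(sc, dt = 2, tMax = 20000)
  rs <- evaporationRate(truthRecord(sim), basis = "wet")
  expect_true(all(abs(rates(rs) - sim@jStar) / sim@jStar < 1e-6))
})

test_that("normalised curves start at (0, 1) and are scale invariant", {
  sc <- referenceScenario(seed = 6)
  rec <- truthRecord(simulateDrying(sc, dt = 600))
  nc <- normalizeRecord(rec)
  expect_equal(nc$tNorm[1], 0)
  expect_equal(nc$massNorm[1], 1)
  expect_equal(nc$wetAreaNorm[1], 1)
  expect_equal(nc$tNorm[nrow(nc)], 1)
  ## rescaling every channel by constants leaves the curves unchanged
  rec2 <- dryingRecord(rec@times * 3, masses = rec@masses * 7,
                       totalAreas = rec@totalAreas * 2,
                       wetAreas = rec@wetAreas * 2,
                       initialMass = rec@initialMass * 7)
  expect_equal(normalizeRecord(rec2), nc)
})

test_that("weighted rate series is flat at the generating D", {
  sc1 <- referenceScenario(seed = 7, fluxBasis = "wet")
  sc2 <- poolScenario(2.1e-3, shapeIrregularity = 0.3, height = 1.2e-3,
                      fluxBasis = "wet", seed = 8)
  getD <- function(sc) {
    sim <- simulateDrying(sc, dt = 2, tMax = 15000)
    tr <- truthRecord(sim)
    w <- weightedRateSeries(evaporationRate(tr, basis = "wet"),
                            tr@geometry, sc@environment)
    estimatePlateau(w)$value
  }
  d1 <- getD(sc1); d2 <- getD(sc2)
  ## pools of different mass, shape and height collapse to the same D
  expect_equal(d1, 1e-9, tolerance = 1e-9)
  expect_equal(d2, d1, tolerance = 1e-9)
  ## zero rates map to zero D
  z <- new("RateSeries", times = 1:5, rates = rep(0, 5),
           waterFractionLeft = seq(1, 0.6, length.out = 5),
           areaBasis = "wet")
  g <- poolGeometry(3e-3, 0.21, 1.44e-3, 4.6e-3)
  expect_equal(weightedRateSeries(z, g, env23)$D, rep(0, 5))
  ## total-basis input is rejected
  zt <- new("RateSeries", times = 1:5, rates = rep(0, 5),
            waterFractionLeft = seq(1, 0.6, length.out = 5),
            areaBasis = "total")
  expect_error(weightedRateSeries(zt, g, env23), "wet")
})

test_that("plateau estimator is robust to excursions and noise", {
  wfl <- seq(0.99, 0.01, length.out = 120)
  flat <- list(D = rep(2.5e-9, 120), waterFractionLeft = wfl)
  pl <- estimatePlateau(flat)
  expect_equal(pl$value, 2.5e-9)
  expect_equal(pl$spread, 0)
  ## early/late excursions outside the window are ignored entirely
  exc <- flat
  exc$D[wfl > 0.85] <- 8e-9
  exc$D[wfl < 0.35] <- 0.2e-9
  expect_equal(estimatePlateau(exc)$value, 2.5e-9)
  ## Monte-Carlo: symmetric noise shrinks as 1/sqrt(n)
  set.seed(99)
  errs <- replicate(200, {
    noisy <- list(D = 2.5e-9 + rnorm(120, 0, 1e-10),
                  waterFractionLeft = wfl)
    estimatePlateau(noisy)$value - 2.5e-9
  })
  n <- sum(wfl >= 0.35 & wfl <= 0.85)
  expect_lt(abs(mean(errs)), 1e-10 / sqrt(n) * 3)
  expect_lt(stats::sd(errs), 1e-10 / sqrt(n) * 2)
  expect_error(estimatePlateau(list(D = 1:3,
    waterFractionLeft = c(0.9, 0.95, 0.99))), "window")
})

test_that("mass-area fit recovers generating parameters", {
  a <- seq(0, 1, length.out = 60)
  ## exact data on the model manifold (direct-evaluation oracle)
  m <- 1 - 0.78 * (1 - a)^0.16
  fit <- fitMassArea(a, m)
  expect_equal(unname(coef(fit)["alpha"]), 0.78, tolerance = 1e-4)
  expect_equal(unname(coef(fit)["beta"]), 0.16, tolerance = 1e-4)
  expect_lt(fit@residualNorm, 1e-8)
  ## anchor point: A/Ai = 1 maps to m/mi = 1 for any parameters
  expect_equal(predict(fit, 1), 1)
  ## noisy recovery, different truth
  set.seed(7)
  m2 <- 1 - 0.5 * (1 - a)^0.5 + rnorm(60, 0, 0.005)
  fit2 <- fitMassArea(a, m2)
  expect_equal(unname(coef(fit2)["alpha"]), 0.5, tolerance = 0.05)
  expect_equal(unname(coef(fit2)["beta"]), 0.5, tolerance = 0.12)
  ## preconditions
  expect_error(fitMassArea(a[1:3], m[1:3]), "5")
  expect_error(fitMassArea(seq(0.8, 1, length.out = 10),
                           rep(1, 10)), "range")
})

test_that("shape-linear fit recovers an exact line and flags degeneracy", {
  th <- seq(0.2, 1.0, length.out = 20)
  ls <- runif(20, 4, 12)
  js <- (1.72e-7 * th + 1.79e-6) * ls
  fit <- fitShapeLinear(th, js, ls)
  expect_equal(fit@slope, 1.72e-7, tolerance = 1e-10)
  expect_equal(fit@intercept, 1.79e-6, tolerance = 1e-10)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
  expect_error(fitShapeLinear(rep(0.5, 5), js[1:5], ls[1:5]), "degenerate")
  expect_error(fitShapeLinear(th[1:2], js[1:2], ls[1:2]), "3")
})

test_that("average rate after half mass loss matches the generating flux", {
  sc <- referenceScenario(seed = 9)
  tStop <- snapshotAtMassLoss(sc, 0.75)$time
  sim <- simulateDrying(sc, dt = 120, tMax = tStop)
  avg <- averageEvaporationRate(truthRecord(sim), basis = "total")
  ## constant-flux phase only: the average equals the generating flux
  expect_equal(avg, sim@jStar, tolerance = 1e-10)
})
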