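test_that("scale calibration converts lengths and areas", {
  cal <- calibrateScale(100, 0.01)
  expect_equal(cal@metresPerPixel, 1e-4)
  expect_equal(calibrateScale(100, 0.02)@metresPerPixel,
               2 * cal@metresPerPixel)
  ## areas scale with the square: 50x50 px at 1e-4 m/px
  sq <- matrix(TRUE, 50, 50)
  expect_equal(measureGeometry(sq, cal)$area, 2.5e-5)
  expect_error(calibrateScale(0, 0.01), "> 0")
  expect_error(calibrateScale(10, -1), "> 0")
})

test_that("disc area and Crofton perimeter match the analytic values", {
  cal <- calibrateScale(100, 0.01)
  d <- discMask(100)
  g <- measureGeometry(d, cal)
  expect_equal(g$area, pi * 0.01^2, tolerance = 1e-2)
  expect_equal(g$perimeter, 2 * pi * 0.01, tolerance = 2e-2)
  ## single pixel
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(measureGeometry(one, cal)$area, 1e-8)
  expect_error(measureGeometry(matrix(FALSE, 5, 5), cal), "empty")
  expect_error(measureGeometry(d, "not a calibration"), "ScaleCalibration")
})

test_that("isoperimetric inequality holds on realistic masks", {
  ## discs and simulator blobs of realistic size: P >= 2 sqrt(pi A)
  for (r in c(20, 55, 90)) {
    m <- discMask(r)
    expect_gte(croftonPerimeter(m), 0.99 * 2 * sqrt(pi * sum(m)))
  }
  set.seed(3)
  for (seed in 1:4) {
    sc <- poolScenario(4e-3, shapeIrregularity = runif(1, 0, 0.35),
                       height = 1.44e-3, seed = 30L + seed)
    sim <- simulateDrying(sc, dt = 6000)
    fr <- renderSequence(sim, frames = 1L, pixelNoiseSd = 0)
    m <- fr[[1]]$poolMask
    expect_gte(croftonPerimeter(m), 0.99 * 2 * sqrt(pi * sum(m)))
  }
})

test_that("pool segmentation matches the renderer ground truth", {
  sc <- poolScenario(5e-3, shapeIrregularity = 0.25, height = 1.44e-3,
                     seed = 21)
  sim <- simulateDrying(sc, dt = 3000)
  cal <- fittingCalibration(sim)
  fr <- renderSequence(sim, cal, frames = c(2L, 5L), crackTexture = TRUE)
  for (f in fr) {
    mask <- segmentPool(f$image)
    gt <- sum(f$poolMask)
    expect_lt(abs(sum(mask) - gt) / gt, 0.02)
    ## interior cracks are filled: one component, no holes
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    expect_equal(max(lab), 1)
    filled <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
    expect_equal(sum(filled), sum(mask))
  }
  ## blank background: no pool
  blank <- array(0.8, dim = c(120, 120, 3))
  expect_error(segmentPool(blank), "no pool")
})

test_that("wet-region segmentation tracks the drying front", {
  sc <- poolScenario(5e-3, shapeIrregularity = 0.2, height = 1.44e-3,
                     seed = 22)
  sim <- simulateDrying(sc, dt = 2500)
  cal <- fittingCalibration(sim)
  n <- length(truthRecord(sim)@times)
  ## mid-drying frame: wet/total ratio within 2% of ground truth
  mid <- which.min(abs(truthRecord(sim)@wetAreas / sim@shape$area - 0.5))
  fr <- renderSequence(sim, cal, frames = c(1L, mid, n))
  segMid <- segmentFrame(fr[[2]]$image, cal)
  gtRatio <- fr[[2]]$wetArea / sim@shape$area
  expect_lt(abs(segMid@wetArea / segMid@totalArea - gtRatio) / gtRatio,
            0.02)
  ## fully wet first frame: wet mask covers the pool
  pool1 <- segmentPool(fr[[1]]$image)
  wet1 <- segmentWetRegion(fr[[1]]$image, pool1)
  expect_gt(sum(wet1) / sum(pool1), 0.995)
  ## fully dried rendering: empty wet mask
  dryFrame <- renderSequence(sim, cal, frames = n)
  ## force a fully dark pool by zeroing the wet area channel
  img <- dryFrame[[1]]$image
  poolD <- segmentPool(img)
  ## repaint any wet pixels as dried colour
  wmask <- dryFrame[[1]]$wetMask
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[wmask] <- c(0.10, 0.04, 0.05)[ch]
    img[, , ch] <- plane
  }
  wetD <- segmentWetRegion(img, poolD)
  expect_equal(sum(wetD), 0)
  expect_error(segmentWetRegion(img, matrix(FALSE, 2, 2)), "empty")
})

test_that("sequence analysis reproduces the simulated area curves", {
  sc <- poolScenario(4.5e-3, shapeIrregularity = 0.15, height = 1.44e-3,
                     seed = 23)
  sim <- simulateDrying(sc, dt = 2000)
  cal <- fittingCalibration(sim)
  tr <- truthRecord(sim)
  idx <- unique(round(seq(1, length(tr@times), length.out = 6)))
  fr <- renderSequence(sim, cal, frames = idx)
  rec <- analyzeSequence(lapply(fr, `[[`, "image"), cal,
                         timestamps = tr@times[idx],
                         environment = sc@environment)
  expect_s4_class(rec, "DryingRecord")
  ## total area approximately constant and equal to truth
  expect_true(all(abs(rec@totalAreas - sim@shape$area) /
                    sim@shape$area < 0.02))
  ## wet curve matches ground truth within 3% pointwise except the
  ## flagged tail
  gtWet <- tr@wetAreas[idx]
  tail <- gtWet / sim@shape$area < 0.10
  relErr <- abs(rec@wetAreas - gtWet) / pmax(gtWet, 1e-12)
  expect_true(all(relErr[!tail] < 0.03))
  ## wet series non-increasing (up to segmentation noise)
  expect_true(all(diff(rec@wetAreas) <= 0.005 * sim@shape$area))
  ## error paths
  expect_error(analyzeSequence(lapply(fr, `[[`, "image"), cal,
                               timestamps = rev(tr@times[idx])),
               "increasing")
  expect_error(analyzeSequence(lapply(fr, `[[`, "image"), "nope",
                               timestamps = tr@times[idx]),
               "ScaleCalibration")
  expect_error(analyzeSequence(fr[1], cal, timestamps = 0), "2 images")
})
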