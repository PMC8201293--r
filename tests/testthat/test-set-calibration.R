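test_that("endpoint means average the calibration window", {
  flat <- amplificationCurve(rep(50, 40), state = "normalized")
  expect_equal(endpointMean(flat), 50)
  ramp <- amplificationCurve(as.numeric(1:40), state = "normalized")
  expect_equal(endpointMean(ramp), mean(35:40))
  expect_equal(endpointMean(ramp, window = c(11L, 20L)), mean(11:20))
  expect_error(endpointMean(ramp, window = c(35L, 45L)), "exceeds")
  expect_error(endpointMean(amplificationCurve(rep(1, 40))), "normalized")

  # grid: pooled mean across a set's curves, equal weight per value
  raw <- cbind(rep(c(0, 30), c(10, 30)), rep(c(0, 50), c(10, 30)))
  g <- baselineNormalize(PCRGrid(raw, data.frame(
    set_id = "A", experiment_id = 1:2, concentration = 1)))
  expect_equal(endpointMean(g, set = "A"), 40)
})

test_that("the calibration factor is the endpoint-mean ratio", {
  f1 <- calibrationFactor(74.2, 41.2, rounding = "1dp")
  expect_equal(calibrationRatio(f1), 1.8)
  f2 <- calibrationFactor(74.2, 41.2)
  expect_equal(calibrationRatio(f2), 1.8009708737864076, tolerance = 1e-12)
  expect_equal(calibrationRatio(calibrationFactor(50, 50)), 1)
  expect_error(calibrationFactor(74.2, 0), "> 0")

  rep1 <- calibrationReport(f1)
  expect_equal(rep1$ratio, 1.8)
  expect_equal(rep1$mean_reference, 74.2)
  expect_equal(c(rep1$window_start, rep1$window_end), c(35, 40))
})

test_that("applying a factor rescales the target set only", {
  fac <- calibrationFactor(74.2, 41.2, rounding = "1dp")
  cv <- amplificationCurve(c(10, 20), state = "normalized")
  expect_equal(intensities(applyCalibration(cv, fac)), c(18, 36))
  unit <- calibrationFactor(50, 50)
  expect_equal(intensities(applyCalibration(cv, unit)), c(10, 20))

  g <- baselineNormalize(cleanGrid())
  g <- logTransform(g)
  fac <- setCalibrationFactor(g)
  expect_equal(fac@referenceSet, "A")  # brighter set keeps its scale
  expect_equal(fac@targetSet, "B")
  cal <- applyCalibration(g, fac)
  expect_false("log" %in% assayNames(cal))  # stale log assay dropped
  isA <- colData(g)$set_id == "A"
  expect_identical(assay(cal, "normalized")[, isA],
                   assay(g, "normalized")[, isA])
  expect_equal(assay(cal, "normalized")[, !isA],
               assay(g, "normalized")[, !isA] * calibrationRatio(fac))
})

test_that("calibrating a set against itself is the identity", {
  g <- baselineNormalize(cleanGrid(setGains = c(1, 1)))
  mA <- endpointMean(g, set = "A")
  expect_equal(calibrationRatio(calibrationFactor(mA, mA)), 1)
  # equal-gain sets: ratio 1 and unchanged curves
  fac <- setCalibrationFactor(g)
  expect_equal(calibrationRatio(fac), 1, tolerance = 1e-12)
  cal <- applyCalibration(g, fac)
  expect_equal(assay(cal, "normalized"), assay(g, "normalized"),
               tolerance = 1e-12)
})

test_that("a pure gain gap closes exactly under full-precision calibration", {
  g <- baselineNormalize(cleanGrid(setGains = c(1, 1 / 1.8)))
  fac <- setCalibrationFactor(g)  # full precision
  expect_equal(calibrationRatio(fac), 1.8, tolerance = 1e-9)
  cal <- applyCalibration(g, fac)
  # endpoint means agree to many decimals after calibration
  expect_equal(endpointMean(cal, set = "B"), endpointMean(cal, set = "A"),
               tolerance = 1e-9)
  # and the two sets' curve matrices coincide to machine precision
  norm <- assay(cal, "normalized")
  cd <- colData(cal)
  expect_equal(unname(norm[, cd$set_id == "B"]),
               unname(norm[, cd$set_id == "A"]), tolerance = 1e-9)
})

test_that("rescaling all curves shifts t_opt by the log constant only", {
  k <- 2.7
  g <- cleanGrid()
  gk <- PCRGrid(assay(g, "raw") * k, colData(g))
  prep <- function(x) logTransform(baselineNormalize(x))
  ref <- referenceCt(experimentDesign())
  ts <- seq(0.5, 3, by = 0.05)
  r1 <- objectiveCurve(prep(g), ref, ts)
  r2 <- objectiveCurve(prep(gk), ref, ts + log(k))
  expect_equal(tOpt(r2), tOpt(r1) + log(k), tolerance = 1e-9)
  expect_equal(dOpt(r2), dOpt(r1), tolerance = 1e-9)
  expect_equal(objectiveTable(r2)$distance, objectiveTable(r1)$distance,
               tolerance = 1e-9)
})
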