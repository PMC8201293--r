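test_that("noiseless curves are logistic with the documented asymptote", {
  m <- amplificationModel(baselineIntensity = 20, plateauGain = 60,
                          trueCq = 15, slope = 1)
  cv <- simulateCurve(m, nCycles = 60, noiseSd = 0)
  v <- intensities(cv)
  expect_true(all(diff(v) >= 0))                # monotone; plateau saturates
  expect_true(all(diff(v[1:30]) > 0))           # strictly rising mid-curve
  expect_equal(v[60], 20 + 60, tolerance = 1e-6)     # plateau asymptote
  expect_gt(v[1], 20)                                # never below baseline
  # gain scales the rise, not the baseline
  cv2 <- simulateCurve(m, gain = 2, nCycles = 60, noiseSd = 0)
  expect_equal(intensities(cv2) - 20, 2 * (v - 20), tolerance = 1e-9)
})

test_that("curve simulation is deterministic given a seed", {
  m <- amplificationModel(trueCq = 24)
  a <- simulateCurve(m, noiseSd = 1, seed = 99L)
  b <- simulateCurve(m, noiseSd = 1, seed = 99L)
  c <- simulateCurve(m, noiseSd = 1, seed = 100L)
  expect_identical(intensities(a), intensities(b))
  expect_false(identical(intensities(a), intensities(c)))
})

test_that("sigmoidCenter pins the normalized crossing at the true Cq", {
  for (cq in c(14, 20, 27, 33)) {
    for (k in c(0.4, 0.6, 1)) {
      c0 <- sigmoidCenter(cq, k, ctFraction = 0.1)
      m <- mean(plogis(k * (1:10 - c0)))
      # defining equation: sigma(cq) - baseline mean = ctFraction
      expect_equal(plogis(k * (cq - c0)) - m, 0.1, tolerance = 1e-9)
    }
  }
})

test_that("Ct calling at the reference level recovers the true Cq", {
  for (cq in c(18, 22, 26, 30)) {
    for (gain in c(1, 1 / 1.8)) {
      m <- amplificationModel(trueCq = cq)
      lg <- logTransform(baselineNormalize(
        simulateCurve(m, gain = gain, nCycles = 40, noiseSd = 0)))
      ct <- computeCt(lg, ctReferenceLevel(m, gain))
      expect_equal(ct, cq, tolerance = 0.01)
      # and agrees with the continuous bisection oracle
      expect_equal(ct, oracleCq(m, gain), tolerance = 0.01)
    }
  }
})

test_that("dilution shifts Cq by log(dilution)/log(efficiency)", {
  expect_equal(shiftForDilution(20, 2, 2), 21)
  expect_equal(shiftForDilution(20, 10, 2), 20 + 3.3219280948873626)
  expect_equal(shiftForDilution(20, 1, 2), 20)
  expect_equal(shiftForDilution(20, 10, 1.9), 20 + log(10) / log(1.9))
  expect_error(shiftForDilution(20, 10, 1), "efficiency")
  expect_error(shiftForDilution(20, 0.5, 2), "dilutionFactor")
})

test_that("the experiment grid has the full design structure", {
  g <- generateExperimentGrid(experimentDesign(), seed = 3)
  expect_s4_class(g, "PCRGrid")
  expect_equal(dim(g), c(40L, 24L))  # 2 sets x 4 experiments x 3 conc
  cd <- colData(g)
  expect_setequal(unique(cd$set_id), c("A", "B"))
  expect_equal(sort(unique(cd$experiment_id)), 1:4)
  expect_setequal(unique(cd$concentration), c(1, 0.1, 0.01))
  tr <- groundTruth(g)
  expect_true(all(c("true_cq", "gain") %in% colnames(tr)))
  # determinism across calls
  g2 <- generateExperimentGrid(experimentDesign(), seed = 3)
  expect_identical(assay(g, "raw"), assay(g2, "raw"))
})

test_that("zero jitter and zero noise make replicates identical", {
  g <- cleanGrid()
  raw <- assay(g, "raw")
  cd <- colData(g)
  for (s in c("A", "B")) for (cc in c(1, 0.1, 0.01)) {
    cols <- which(cd$set_id == s & cd$concentration == cc)
    expect_identical(raw[, cols[1]], raw[, cols[2]])
  }
})

test_that("set gains reproduce the expected endpoint-intensity ratio", {
  g <- baselineNormalize(cleanGrid(setGains = c(1, 1 / 1.8)))
  ratio <- endpointMean(g, set = "A") / endpointMean(g, set = "B")
  expect_equal(ratio, 1.8, tolerance = 0.01)
})

test_that("dose-response is monotone: more dilute, later Ct", {
  g <- logTransform(baselineNormalize(cleanGrid(nExperiments = 1L)))
  tab <- ctTable(g, 1.5)
  for (s in c("A", "B")) {
    cts <- tab$ct[tab$set_id == s][order(-tab$concentration[tab$set_id == s])]
    expect_true(all(diff(cts) > 0))
  }
})

test_that("rendered stacks round-trip through quantification", {
  layout <- chipLayout()
  roi <- layout@roi
  m <- amplificationModel(trueCq = 18)
  cv <- simulateCurve(m, nCycles = 14, noiseSd = 0)
  st <- renderImageStack(cv, layout, cameraModel(noiseSd = 0))
  expect_identical(intensities(quantifyStack(st, roi)), intensities(cv))

  # constant curve: every ROI pixel holds the curve value in every frame
  flat <- amplificationCurve(rep(100, 3))
  stf <- renderImageStack(flat, layout, cameraModel(noiseSd = 0))
  mask <- roiMask(roi, layout@frameWidth, layout@frameHeight)
  for (f in stf@frames) {
    expect_true(all(f[mask] == 100))
    expect_true(all(f[!mask] == layout@backgroundLevel))
  }

  # seeded determinism of noisy rendering (background high enough that
  # the noise never clips at zero)
  cam <- cameraModel(noiseSd = 2, seed = 5)
  bright <- chipLayout(backgroundLevel = 20)
  s1 <- renderImageStack(cv, bright, cam)
  s2 <- renderImageStack(cv, bright, cam)
  expect_identical(s1@frames, s2@frames)
})

test_that("ROI averaging beats pixel noise by the CLT factor", {
  # sd 2 over a 100 x 100 ROI: standard error 0.02, so 0.1 is 5 sigma
  layout <- chipLayout(120L, 110L, roiSpec(10L, 5L, 100L, 100L),
                       backgroundLevel = 20)
  cv <- simulateCurve(amplificationModel(trueCq = 20), nCycles = 40,
                      noiseSd = 0)
  st <- renderImageStack(cv, layout, cameraModel(noiseSd = 2, seed = 11))
  q <- quantifyStack(st, layout@roi)
  expect_true(all(abs(intensities(q) - intensities(cv)) < 0.1))
})

test_that("out-of-range pixel intensities are clipped with a warning", {
  layout <- chipLayout()
  big <- amplificationCurve(c(100, 300))  # 300 > 255
  expect_warning(st <- renderImageStack(big, layout, cameraModel(noiseSd = 0)),
                 "clipped")
  expect_equal(max(st@frames[[2]]), 255)
})
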