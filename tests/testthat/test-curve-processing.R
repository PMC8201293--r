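test_that("baseline normalization zeroes the pre-amplification window", {
  cv <- amplificationCurve(c(rep(1, 10), 11))
  expect_equal(intensities(baselineNormalize(cv)), c(rep(0, 10), 10))

  flat <- amplificationCurve(rep(37.5, 15))
  expect_equal(intensities(baselineNormalize(flat)), rep(0, 15))

  set.seed(7)
  noisy <- amplificationCurve(runif(40, 10, 200))
  nv <- intensities(baselineNormalize(noisy))
  expect_equal(mean(nv[1:10]), 0, tolerance = 1e-12)

  # invariance to an additive offset of the raw curve
  shifted <- amplificationCurve(intensities(noisy) + 123.4)
  expect_equal(intensities(baselineNormalize(shifted)), nv,
               tolerance = 1e-10)

  expect_error(baselineNormalize(amplificationCurve(1:10)), "baseline")
  expect_error(baselineNormalize(baselineNormalize(noisy)), "state 'raw'")
})

test_that("log transform maps non-positive values to undefined", {
  cv <- amplificationCurve(c(0, -3, exp(2), 74.2, 1), state = "normalized")
  lv <- intensities(logTransform(cv))
  expect_true(is.na(lv[1]) && is.na(lv[2]))
  expect_equal(lv[3], 2)
  expect_equal(lv[4], 4.3067641501733345, tolerance = 1e-12)
  expect_equal(lv[5], 0)

  # configurable base
  l10 <- intensities(logTransform(cv, base = 10))
  expect_equal(l10[4], log10(74.2), tolerance = 1e-12)
  expect_error(logTransform(amplificationCurve(1:15)), "normalized")
})

test_that("Ct is the first threshold crossing, interpolated sub-cycle", {
  lc <- amplificationCurve(c(rep(NA, 19), 1, 3), state = "log")
  expect_equal(computeCt(lc, 2), 20.5)
  expect_equal(computeCt(lc, 1), 20)      # exact hit at a cycle
  expect_equal(computeCt(lc, 2.5), 20.75)

  # a flat all-undefined curve is undetermined at any threshold
  flat <- amplificationCurve(rep(NA_real_, 12), state = "log")
  expect_true(is.na(computeCt(flat, 0)))

  # first defined value already above the threshold: that cycle's index
  early <- amplificationCurve(c(5, 6, 7), state = "log")
  expect_equal(computeCt(early, 2), 1)

  # crossing preceded by an undefined cycle: no interpolation partner
  gap <- amplificationCurve(c(1, NA, 5), state = "log")
  expect_equal(computeCt(gap, 4), 3)

  # never reaches the threshold: undetermined
  expect_true(is.na(computeCt(early, 10)))
})

test_that("Ct is non-decreasing in the threshold", {
  set.seed(21)
  for (i in 1:20) {
    raw <- cumsum(abs(rnorm(40))) + rnorm(40, sd = 0.3) + 30
    lg <- logTransform(baselineNormalize(amplificationCurve(raw)))
    ts <- sort(runif(25, -2, max(intensities(lg), na.rm = TRUE)))
    cts <- computeCt(lg, ts)
    ok <- !is.na(cts)
    expect_true(all(diff(cts[ok]) >= -1e-12))
  }
})

test_that("delaying a curve by whole cycles delays Ct by the same amount", {
  # exactly flat before amplification, so the delayed curve keeps an
  # identical baseline window and the shift is exact
  base <- c(rep(30, 15), 30 + 2^seq(0.5, 12.5, by = 0.5))
  ct0 <- computeCt(logTransform(baselineNormalize(
    amplificationCurve(base))), 1.8)
  for (k in c(2L, 5L)) {
    delayed <- c(rep(30, k), base[seq_len(40 - k)])
    ctk <- computeCt(logTransform(baselineNormalize(
      amplificationCurve(delayed))), 1.8)
    expect_equal(ctk, ct0 + k, tolerance = 1e-9)
  }
})

test_that("grid-level processing matches the per-curve operations", {
  g <- cleanGrid(nExperiments = 1L)
  gn <- baselineNormalize(g)
  gl <- logTransform(gn)
  j <- 4L
  cv <- amplificationCurve(assay(g, "raw")[, j])
  expect_equal(unname(assay(gn, "normalized")[, j]),
               intensities(baselineNormalize(cv)), tolerance = 1e-12)
  expect_equal(unname(assay(gl, "log")[, j]),
               intensities(logTransform(baselineNormalize(cv))),
               tolerance = 1e-12)
  cts <- computeCt(gl, 1.5)
  expect_equal(unname(cts[j]),
               computeCt(logTransform(baselineNormalize(cv)), 1.5),
               tolerance = 1e-12)

  tab <- ctTable(gl, 1.5)
  expect_equal(nrow(tab), ncol(g))
  vecs <- ctVectors(gl, 1.5)
  expect_length(vecs, 2L)  # one per (set, experiment)
  expect_setequal(names(vecs[["A.1"]]@values), c("1", "0.1", "0.01"))
})

test_that("curve state transitions are enforced in order", {
  cv <- amplificationCurve(c(rep(5, 10), 20, 40))
  expect_error(logTransform(cv), "normalized")
  expect_error(computeCt(cv, 1), "log")
  n <- baselineNormalize(cv)
  expect_error(computeCt(n, 1), "log")
  expect_identical(curveState(logTransform(n)), "log")
})
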