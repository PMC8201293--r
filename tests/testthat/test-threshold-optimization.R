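refVec <- c(`1` = 20, `0.1` = 23, `0.01` = 26)

test_that("Ct distance is the per-measurement RMS of paired differences", {
  expect_equal(as.numeric(ctDistance(refVec, refVec)), 0)
  expect_equal(as.numeric(ctDistance(refVec, refVec + 1)), 1)  # uniform offset
  est <- c(`1` = 20.5, `0.1` = 23, `0.01` = 26)
  expect_equal(as.numeric(ctDistance(refVec, est)),
               0.28867513459481287, tolerance = 1e-12)
  expect_equal(as.numeric(ctDistance(refVec, est, norm = "euclidean")), 0.5)

  # invariant to the ordering of concentration labels
  expect_equal(as.numeric(ctDistance(refVec, est[c(3, 1, 2)])),
               as.numeric(ctDistance(refVec, est)))

  # undetermined pairs are excluded and counted
  est2 <- c(`1` = NA, `0.1` = 23.5, `0.01` = 26)
  d <- ctDistance(refVec, est2)
  expect_equal(attr(d, "nExcluded"), 1L)
  expect_equal(as.numeric(d), sqrt(0.25 / 2), tolerance = 1e-12)
  expect_error(ctDistance(refVec, refVec * NA), "undetermined")
  expect_error(ctDistance(refVec, c(`1` = 20, `0.2` = 23, `0.01` = 26)),
               "different concentrations")

  # CtVector objects work like named vectors
  expect_equal(as.numeric(ctDistance(ctVector(refVec), ctVector(est))),
               as.numeric(ctDistance(refVec, est)))
})

test_that("a curve whose Ct matches the reference at t* is recovered", {
  g <- logTransform(baselineNormalize(
    cleanGrid(setGains = c(1, 1), nExperiments = 1L)))
  tStar <- ctReferenceLevel(amplificationModel())
  # reference = the Ct values this grid actually produces at t*
  ref <- ctVectors(g, tStar)[["A.1"]]@values
  ts <- sort(c(tStar, seq(tStar - 1, tStar + 1, by = 0.05)))
  r <- objectiveCurve(g, ref, ts, scope = "experiment",
                      set = "A", experiment = 1L)
  expect_equal(tOpt(r), tStar)
  expect_equal(dOpt(r), 0, tolerance = 1e-12)
})

test_that("scope 'all' on a single experiment equals scope 'experiment'", {
  d <- experimentDesign(nSets = 1L, nExperimentsPerSet = 1L,
                        setGains = 1, cqJitterSd = 0, gainJitterSd = 0)
  g <- logTransform(baselineNormalize(generateExperimentGrid(
    d, camera = cameraModel(noiseSd = 0), seed = 2)))
  ref <- referenceCt(d)
  ts <- seq(0.5, 2.5, by = 0.05)
  rAll <- objectiveCurve(g, ref, ts, scope = "all")
  rExp <- objectiveCurve(g, ref, ts, scope = "experiment",
                         set = "A", experiment = 1L)
  expect_equal(objectiveTable(rAll)$distance, objectiveTable(rExp)$distance)
  expect_equal(tOpt(rAll), tOpt(rExp))
  expect_equal(dOpt(rAll), dOpt(rExp))
})

test_that("the grid search matches a brute-force oracle exactly", {
  d <- experimentDesign(setGains = c(1, 1), nExperimentsPerSet = 2L,
                        cqJitterSd = 0.2, gainJitterSd = 0)
  g <- logTransform(baselineNormalize(generateExperimentGrid(
    d, camera = cameraModel(noiseSd = 0), seed = 8)))
  ref <- referenceCt(d)
  ts <- seq(0.8, 2.8, by = 0.1)
  r <- objectiveCurve(g, ref, ts, scope = "all")

  refs <- ref[as.character(colData(g)$concentration)]
  brute <- bruteObjective(assay(g, "log"), refs, ts)
  expect_equal(objectiveTable(r)$distance, brute, tolerance = 1e-12)
  expect_equal(dOpt(r), min(brute, na.rm = TRUE), tolerance = 1e-12)
})

test_that("refining the threshold grid never increases the optimum", {
  g <- logTransform(baselineNormalize(cleanGrid()))
  ref <- referenceCt(experimentDesign())
  coarse <- seq(0.5, 3, by = 0.2)
  fine <- sort(unique(c(coarse, seq(0.5, 3, by = 0.02))))
  dCoarse <- dOpt(objectiveCurve(g, ref, coarse))
  dFine <- dOpt(objectiveCurve(g, ref, fine))
  expect_lte(dFine, dCoarse + 1e-12)
})

test_that("the pooled RMS lies between the per-set RMS values", {
  d <- experimentDesign(cqJitterSd = 0.2)
  g <- logTransform(baselineNormalize(generateExperimentGrid(
    d, camera = cameraModel(noiseSd = 0.3), seed = 4)))
  ref <- referenceCt(d)
  ts <- seq(1, 2.5, by = 0.25)
  rA <- objectiveTable(objectiveCurve(g, ref, ts, scope = "set", set = "A"))
  rB <- objectiveTable(objectiveCurve(g, ref, ts, scope = "set", set = "B"))
  rAll <- objectiveTable(objectiveCurve(g, ref, ts, scope = "all"))
  ok <- !is.na(rA$distance) & !is.na(rB$distance) & !is.na(rAll$distance)
  expect_true(any(ok))
  lo <- pmin(rA$distance[ok], rB$distance[ok])
  hi <- pmax(rA$distance[ok], rB$distance[ok])
  expect_true(all(rAll$distance[ok] >= lo - 1e-9 &
                    rAll$distance[ok] <= hi + 1e-9))
})

test_that("the sum norm is the sum of per-experiment Euclidean norms", {
  g <- logTransform(baselineNormalize(cleanGrid(nExperiments = 2L)))
  ref <- referenceCt(experimentDesign())
  ts <- seq(1, 2.5, by = 0.25)
  rSum <- objectiveTable(objectiveCurve(g, ref, ts, norm = "sum"))
  manual <- vapply(ts, function(t) {
    vecs <- ctVectors(g, t)
    sum(vapply(vecs, function(v)
      as.numeric(ctDistance(ref, v@values, norm = "euclidean")),
      numeric(1)))
  }, numeric(1))
  expect_equal(rSum$distance, manual, tolerance = 1e-10)
})

test_that("per-experiment and per-set tables mirror the scoped searches", {
  g <- logTransform(baselineNormalize(cleanGrid(nExperiments = 2L)))
  tStar <- ctReferenceLevel(amplificationModel())
  ref <- referenceCt(experimentDesign())
  ts <- seq(tStar - 1, tStar + 1, by = 0.05)

  tab <- perExperimentTable(g, ref, ts)
  expect_equal(nrow(tab), 4L)  # 2 sets x 2 experiments
  # identical replicates give identical rows within a set
  for (s in c("A", "B")) {
    rows <- tab[tab$set_id == s, ]
    expect_equal(rows$t_opt[1], rows$t_opt[2])
    expect_equal(rows$d_opt[1], rows$d_opt[2])
  }

  stab <- perSetTable(g, ref, ts)
  expect_equal(stab$set_id, c("A", "B", "all"))
  rA <- objectiveCurve(g, ref, ts, scope = "set", set = "A")
  expect_equal(stab$t_opt[1], tOpt(rA))
  expect_equal(stab$d_opt[1], dOpt(rA))
})

test_that("strict undetermined handling invalidates affected thresholds", {
  g <- logTransform(baselineNormalize(cleanGrid(nExperiments = 1L)))
  # a threshold above the dim set's plateau: set B has no crossings there
  tHigh <- max(assay(g, "log")[, colData(g)$set_id == "B"], na.rm = TRUE) +
    0.05
  ref <- referenceCt(experimentDesign())
  rEx <- objectiveCurve(g, ref, c(1.5, tHigh), naAction = "exclude")
  obj <- objectiveTable(rEx)
  expect_gt(obj$n_excluded[obj$t == tHigh], 0)
  rSt <- objectiveCurve(g, ref, c(1.5, tHigh), naAction = "strict")
  expect_true(is.na(objectiveTable(rSt)$distance[2]))
  expect_equal(tOpt(rSt), 1.5)
})
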