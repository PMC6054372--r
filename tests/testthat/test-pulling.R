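test_that("a construct with no foldable domains gives a monotone loading curve", {
  con <- PolyproteinConstruct(list(), handleContour = 60)
  tr <- simulateTrace(con, studyProtocol(0), seed = 1, baselineSamples = 0)
  expect_identical(nrow(groundTruth(tr)), 0L)
  expect_true(all(diff(tr@force) > 0))
  expect_true(all(tr@force >= 0))
  ## extension = piezo - force / k at every pre-noise sample
  expect_equal(tr@extension, tr@piezo - tr@force / 7, tolerance = 1e-7)
})

test_that("pre-noise force is piecewise increasing with a strict drop per event", {
  tr <- simulateTrace(talinR7R8Construct(), studyProtocol(0), seed = 3,
                      baselineSamples = 0)
  gt <- groundTruth(tr)
  expect_gt(nrow(gt), 0)
  d <- diff(tr@force)
  evIdx <- gt$index
  expect_true(all(d[evIdx] < 0))                # drop right after rupture
  rising <- setdiff(seq_along(d), evIdx)
  ## between events the force balance reloads monotonically
  expect_true(all(d[rising] > -1e-9))
})

test_that("simulation is reproducible and dataset seeds derive from the master", {
  con <- talinR7R8Construct()
  pr <- studyProtocol(5)
  t1 <- simulateTrace(con, pr, seed = 11)
  t2 <- simulateTrace(con, pr, seed = 11)
  expect_identical(t1@force, t2@force)
  ds1 <- simulateDataset(con, pr, 3, seed = 99)
  ds2 <- simulateDataset(con, pr, 3, seed = 99)
  expect_identical(lapply(ds1, slot, "force"), lapply(ds2, slot, "force"))
  single <- simulateDataset(con, pr, 1, seed = 99)
  byhand <- simulateTrace(con, pr, seed = MechanoKit:::deriveSeeds(99, 1))
  expect_identical(single[[1]]@force, byhand@force)
})

test_that("WT and clamp share a trace until the R8 event; released contours differ by R8", {
  pr <- studyProtocol(5)
  wt <- simulateTrace(talinR7R8Construct(), pr, seed = 5)
  cl <- simulateTrace(talinR7R8Construct(clamped = TRUE), pr, seed = 5)
  gt <- groundTruth(wt)
  i8 <- gt$index[gt$domain == "R8"]
  expect_length(i8, 1)
  expect_identical(wt@force[seq_len(i8 - 1)], cl@force[seq_len(i8 - 1)])
  expect_false(isTRUE(all.equal(
    wt@force[seq_len(min(length(wt@force), length(cl@force)))],
    cl@force[seq_len(min(length(wt@force), length(cl@force)))])))
  r8 <- residuesToContourGain(124, 0.36, 4.5)
  ## exact contour bookkeeping for any seed
  for (s in c(1, 2, 3)) {
    w <- simulateTrace(talinR7R8Construct(), studyProtocol(0), seed = s)
    cc <- simulateTrace(talinR7R8Construct(clamped = TRUE), studyProtocol(0),
                        seed = s)
    expect_equal(sum(groundTruth(w)$deltaLc) - sum(groundTruth(cc)$deltaLc),
                 r8)
    expect_false("R8" %in% groundTruth(cc)$domain)
  }
})

test_that("huge zero-force rates unfold everything immediately at near-zero force", {
  con <- PolyproteinConstruct(list(
    FoldableDomain("fast1", 50, 20, 5e4, 0.5),
    FoldableDomain("fast2", 50, 20, 5e4, 0.5)), handleContour = 30)
  pr <- PullingProtocol(timestep = 1e-4, forceNoiseSd = 0)
  tr <- simulateTrace(con, pr, seed = 1)
  gt <- groundTruth(tr)
  expect_identical(nrow(gt), 2L)
  expect_true(all(gt$index <= 20))
  expect_true(all(gt$force < 1))
})

test_that("the accuracy guard refuses timesteps that cannot resolve rupture forces", {
  expect_error(
    simulateTrace(talinR7R8Construct(), PullingProtocol(timestep = 0.05),
                  seed = 1),
    "k\\(F\\)\\*dt")
  expect_error(
    simulateTrace(singleDomainConstruct(),
                  PullingProtocol("force_ramp", loadingRate = 100,
                                  timestep = 0.05), seed = 1),
    "k\\(F\\)\\*dt")
})

test_that("ramp-mode rupture forces follow the Bell-Evans distribution", {
  k0 <- 0.06; dx <- 1.5; rate <- 100
  pr <- PullingProtocol("force_ramp", loadingRate = rate, timestep = 5e-4,
                        detachForce = 60)
  ds <- simulateDataset(singleDomainConstruct(k0, dx), pr, 800, seed = 21)
  f <- vapply(ds, function(tr) groundTruth(tr)$force[1], numeric(1))
  expect_false(anyNA(f))
  ## Kolmogorov-Smirnov distance to the analytic rupture-force CDF
  fs <- sort(f)
  ec <- seq_along(fs) / length(fs)
  cdf <- bellEvansRuptureCDF(fs, k0, dx, rate)
  D <- max(pmax(abs(ec - cdf), abs(c(0, ec[-length(ec)]) - cdf)))
  expect_lt(D, 0.05)
})

test_that("equipartition calibration k = c * kBT / variance", {
  expect_equal(equipartitionStiffness(0.4114, 298, 1), 10.0, tolerance = 1e-3)
  expect_equal(equipartitionStiffness(0.4114, 298, 0.8), 8.0, tolerance = 1e-3)
  k1 <- equipartitionStiffness(0.2, 298)
  expect_equal(equipartitionStiffness(0.4, 298), k1 / 2)
  expect_error(equipartitionStiffness(0), "> 0")
  expect_error(equipartitionStiffness(-1), "> 0")
})
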