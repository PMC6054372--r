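test_that("the acquisition schedule brackets the bleach at t = 0", {
  sch <- frapSchedule()
  expect_identical(sch$times, c(-25, -20, -15, -10, -5, seq(0, 100, 5)))
  expect_identical(sch$nPrebleach, 5)
})

test_that("normalization maps prebleach mean to 1 and background to 0", {
  raw <- simulateFrapCurve(0.2, 0.7, 20, noiseSd = 0, scale = 800,
                           background = 120)
  expect_false(isNormalized(raw))
  nn <- normalizeFrap(raw)
  expect_true(isNormalized(nn))
  pre <- nn@intensities[1:5]
  expect_equal(mean(pre), 1, tolerance = 1e-12)
  ## round trip: raw curve built from known normalized truth
  truthCurve <- simulateFrapCurve(0.2, 0.7, 20, noiseSd = 0)
  expect_equal(nn@intensities, truthCurve@intensities, tolerance = 1e-12)
  ## a sample at background level normalizes to 0
  raw2 <- FRAPCurve(c(-10, -5, 0, 5, 10, 15, 20, 25, 30, 35),
                    c(800, 800, 120, 200, 300, 400, 450, 500, 520, 530),
                    nPrebleach = 2, background = 120)
  n2 <- normalizeFrap(raw2)
  expect_equal(n2@intensities[3], 0)
  ## idempotent once normalized
  again <- normalizeFrap(nn)
  expect_equal(again@intensities, nn@intensities, tolerance = 1e-14)
  expect_error(normalizeFrap(FRAPCurve(raw2@times, raw2@intensities,
                                       nPrebleach = 2, background = 900)),
               "below the prebleach")
})

test_that("noise-free recovery fits return exact parameters and immobile fraction", {
  fit <- fitRecovery(simulateFrapCurve(0, 0.7, 20))
  expect_lt(abs(fit@floor - 0), 1e-6)
  expect_lt(abs(fit@plateau - 0.7), 1e-6)
  expect_lt(abs(fit@tau - 20) / 20, 1e-6)
  expect_lt(abs(immobileFraction(fit) - 0.30), 1e-6)
  ## no recovery at all: immobile fraction 1
  none <- fitRecovery(simulateFrapCurve(0.4, 0.4, 20))
  expect_equal(immobileFraction(none), 1)
  ## full recovery: immobile fraction 0
  full <- fitRecovery(simulateFrapCurve(0, 1, 15))
  expect_lt(immobileFraction(full), 1e-6)
  expect_error(fitRecovery(simulateFrapCurve(0, 0.7, 20,
    schedule = frapSchedule(postDuration = 30))), "at least 8")
  expect_error(fitRecovery(simulateFrapCurve(0, 0.7, 20, scale = 100)),
               "normalized")
})

test_that("immobile fraction lies in [0,1] and decreases with the plateau", {
  prev <- Inf
  for (pl in seq(0.3, 1, 0.1)) {
    f <- fitRecovery(simulateFrapCurve(0.2, pl, 25))
    imm <- immobileFraction(f)
    expect_gte(imm, 0); expect_lte(imm, 1)
    expect_lt(imm, prev)
    prev <- imm
  }
})

test_that("the curve generator is deterministic and unbiased", {
  a <- simulateFrapCurve(0.1, 0.6, 20, noiseSd = 0.05, seed = 8)
  b <- simulateFrapCurve(0.1, 0.6, 20, noiseSd = 0.05, seed = 8)
  expect_identical(a@intensities, b@intensities)
  expect_false(identical(
    a@intensities,
    simulateFrapCurve(0.1, 0.6, 20, noiseSd = 0.05, seed = 9)@intensities))
  ## noise-free curve equals the analytic model exactly
  nf <- simulateFrapCurve(0.1, 0.6, 20)
  post <- nf@times >= 0
  expect_equal(nf@intensities[post],
               0.1 + 0.5 * (1 - exp(-nf@times[post] / 20)))
  expect_true(all(nf@intensities[!post] == 1))
  ## ensemble mean converges at the CLT rate
  sds <- MechanoKit:::deriveSeeds(123, 500)
  mat <- vapply(sds, function(s)
    simulateFrapCurve(0.1, 0.6, 20, noiseSd = 0.05, seed = s)@intensities,
    numeric(26))
  truth <- nf@intensities
  expect_lt(max(abs(rowMeans(mat) - truth)), 3 * 0.05 / sqrt(500))
})

test_that("identical groups give F near 0 and p near 1", {
  curves <- lapply(1:6, function(s)
    simulateFrapCurve(0.1, 0.6, 20, noiseSd = 0.03, seed = s))
  ft <- extraSSFTest(curves, curves)
  expect_lt(ft@fStatistic, 1e-6)
  expect_gt(ft@pValue, 0.999)
  expect_identical(ft@dfNum, 3)
})

test_that("the F test has power against distinct immobile fractions", {
  ## immobile fractions 0.2 vs 0.5 at 15 curves per group, noise sd 0.03
  rej <- withr::with_seed(99, {
    vapply(1:200, function(i) {
      sds <- sample.int(1e6, 30)
      a <- lapply(sds[1:15], function(s)
        simulateFrapCurve(0, 0.8, 20, 0.03, seed = s))
      b <- lapply(sds[16:30], function(s)
        simulateFrapCurve(0, 0.5, 20, 0.03, seed = s))
      extraSSFTest(a, b)@pValue < 0.001
    }, logical(1))
  })
  expect_gte(mean(rej), 0.95)
})

test_that("per-cell stain ratios are recovered from synthetic image pairs", {
  img <- matrix(200, 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[10:20, 10:20] <- TRUE
  expect_equal(intensityRatio(img, img, mask, 50, 50)$ratio, 1)
  expect_equal(intensityRatio(2 * img, img, mask)$ratio, 2)
  neg <- intensityRatio(img, img, mask, 0, 500)
  expect_true(neg$flagged)
  expect_true(is.na(neg$ratio))
  sim <- simulateStainImages(c(0.5, 0.8, 1.2, 1.6), noiseSd = 10, seed = 12)
  rt <- intensityRatio(sim$numerator, sim$denominator, sim$masks, 50, 50)
  expect_false(any(rt$flagged))
  expect_lt(max(abs(rt$ratio - sim$trueRatios) / sim$trueRatios), 0.03)
})
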