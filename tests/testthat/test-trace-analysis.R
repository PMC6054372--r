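test_that("noise-free events are detected at the ground-truth positions", {
  tr <- simulateTrace(talinR7R8Construct(), studyProtocol(0), seed = 7)
  gt <- groundTruth(tr)
  ev <- detectUnfoldingEvents(tr)
  ## every ground-truth rupture plus the final detachment
  expect_identical(nrow(ev), nrow(gt) + 1L)
  for (i in seq_len(nrow(gt)))
    expect_lte(abs(ev$ruptureIndex[i] - gt$index[i]), 6)
  ## rupture forces are pre-drop maxima inside the observed range
  expect_true(all(ev$ruptureForce >= 10))
  expect_true(all(ev$ruptureForce <= max(tr@force)))
})

test_that("a pure monotone WLC stretch yields no unfolding events", {
  tr <- pureWLCTrace()
  expect_identical(nrow(detectUnfoldingEvents(tr)), 0L)
  ## constant trace: empty result, not an error
  flat <- new("ForceExtensionTrace", time = 1:50 * 1e-3,
              piezo = rep(1, 50), force = rep(2, 50),
              extension = rep(1, 50), cantileverStiffness = 7,
              groundTruth = MechanoKit:::.emptyGroundTruth())
  expect_identical(nrow(detectUnfoldingEvents(flat)), 0L)
})

test_that("event detection recall and precision reach 0.99 on noisy cohorts", {
  pr <- PullingProtocol(forceNoiseSd = 2)
  ds <- simulateDataset(separatedConstruct(), pr, 200, seed = 31)
  tp <- fp <- fn <- 0
  for (tr in ds) {
    gt <- groundTruth(tr)$index
    ev <- detectUnfoldingEvents(tr)
    ## drop the detachment event (last, by construction)
    got <- ev$ruptureIndex
    if (length(got)) got <- got[-length(got)]
    hit <- vapply(gt, function(i) any(abs(got - i) <= 10), logical(1))
    tp <- tp + sum(hit)
    fn <- fn + sum(!hit)
    fp <- fp + sum(!vapply(got, function(i) any(abs(gt - i) <= 10),
                           logical(1)))
  }
  expect_gte(tp / (tp + fn), 0.99)   # recall
  expect_gte(tp / (tp + fp), 0.99)   # precision
})

test_that("segment WLC fits recover the contour length", {
  tr <- pureWLCTrace(lc = 150)
  fit <- fitSegmentWLC(tr, c(1, length(tr@force)))
  expect_false(fit$skipped)
  expect_lt(abs(fit$lc - 150), 0.1)
  expect_gt(fit$lc, max(tr@extension))
  ## median error under 2 pN noise stays below 2 nm
  errs <- vapply(1:100, function(s) {
    trn <- pureWLCTrace(lc = 150, noiseSd = 2, seed = s)
    abs(fitSegmentWLC(trn, c(1, length(trn@force)))$lc - 150)
  }, numeric(1))
  expect_lt(stats::median(errs), 2)
  ## too-short segments are skipped with a reason
  short <- fitSegmentWLC(tr, c(1, 5))
  expect_true(short$skipped)
  expect_match(short$reason, "short")
  low <- pureWLCTrace(fmax = 3)    # all force below the fit band
  lowfit <- fitSegmentWLC(low, c(1, length(low@force)))
  expect_true(lowfit$skipped)
  expect_match(lowfit$reason, "band")
})

test_that("classification separates fingerprints, talin and detachment", {
  ev <- data.frame(ruptureIndex = c(10, 50, 90, 130),
                   ruptureForce = c(190, 22, 150, 250),
                   extensionAtRupture = c(1, 2, 3, 4),
                   deltaLc = c(28, 104, 28, NA))
  out <- classifyEvents(ev)
  expect_identical(out$classification,
                   c("fingerprint", "talin", "fingerprint", "detachment"))
  ## low-force 28 nm increment is not a fingerprint
  ev2 <- ev; ev2$ruptureForce[1] <- 60
  expect_identical(classifyEvents(ev2)$classification[1], "talin")
  empty <- classifyEvents(ev[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("pipeline identity: recovered increments equal released contour, noise-free", {
  for (s in c(2, 9)) {
    tr <- simulateTrace(talinR7R8Construct(), studyProtocol(0), seed = s)
    res <- analyzeTrace(tr)
    expect_true(isAccepted(res))
    ev <- events(res)
    expect_equal(sum(ev$deltaLc, na.rm = TRUE),
                 sum(groundTruth(tr)$deltaLc), tolerance = 0.5 / 160)
    ## talin sum alone matches the talin ground truth
    gt <- groundTruth(tr)
    talinTruth <- sum(gt$deltaLc[gt$domain %in% c("R7", "R8")])
    expect_lt(abs(unfoldingLength(res) - talinTruth), 0.5)
  }
})

test_that("clamp contrast is exact on noise-free traces", {
  wt <- analyzeTrace(simulateTrace(talinR7R8Construct(), studyProtocol(0),
                                   seed = 4))
  cl <- analyzeTrace(simulateTrace(talinR7R8Construct(clamped = TRUE),
                                   studyProtocol(0), seed = 4))
  expect_true(isAccepted(wt) && isAccepted(cl))
  expect_equal(unfoldingLength(wt) - unfoldingLength(cl),
               residuesToContourGain(124, 0.36, 4.5), tolerance = 0.5 / 40)
})

test_that("traces without fingerprints or talin events are rejected with reasons", {
  tr <- pureWLCTrace()
  res <- analyzeTrace(tr)
  expect_false(isAccepted(res))
  expect_true(is.na(unfoldingLength(res)))
  expect_match(res@reason, "no events")
  ## talin-only construct: no fingerprints, so no single-molecule evidence
  talinOnly <- PolyproteinConstruct(list(
    FoldableDomain("R7", 190, 63.9, 0.06, 1.5),
    FoldableDomain("R8", 124, 40.14, 0.06, 1.5)), handleContour = 30)
  res2 <- analyzeTrace(simulateTrace(talinOnly, studyProtocol(0), seed = 1))
  expect_false(isAccepted(res2))
  expect_match(res2@reason, "fingerprint")
})

test_that("Gaussian histogram fit: degenerate input, sampling accuracy, bin robustness", {
  g0 <- fitGaussianHistogram(rep(62, 10))
  expect_true(g0@degenerate)
  expect_identical(g0@mean, 62)
  expect_identical(g0@sd, 0)
  v <- withr::with_seed(42, rnorm(10000, 20, 5))
  g <- fitGaussianHistogram(v, binWidth = 2)
  expect_lt(abs(g@mean - 20), 0.15)
  expect_lt(abs(g@sd - 5), 0.15)
  ## fitted mean tracks the sample mean within half a bin
  expect_lt(abs(g@mean - g@sampleMean), 0.5 * 2)
  ## halving the bin width moves the mean by less than half the new bin
  g2 <- fitGaussianHistogram(v, binWidth = 1)
  expect_lt(abs(g2@mean - g@mean), 0.5 * 1)
  expect_error(fitGaussianHistogram(c(1, 2)), "at least 3")
})
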