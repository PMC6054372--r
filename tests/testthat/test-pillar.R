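grid6 <- PillarGrid(nx = 6, ny = 6)

test_that("static movies are constant and drift moves every spot rigidly", {
  mv <- generatePillarMovie(grid6, nFrames = 3, noiseSd = 0, seed = 1)
  expect_identical(mv@frames[, , 1], mv@frames[, , 2])
  expect_identical(mv@frames[, , 1], mv@frames[, , 3])
  mvd <- generatePillarMovie(grid6, drift = c(0.3, -0.2), nFrames = 4,
                             noiseSd = 0, seed = 1)
  for (f in 2:4)
    expect_equal(mvd@truth[, , f] - mvd@truth[, , 1],
                 matrix(rep((f - 1) * c(0.3, -0.2), each = 36), ncol = 2))
})

test_that("displacement fields reaching half the spacing are refused", {
  mask <- circularCellMask(grid6)
  big <- radialContractionField(pillarNodes(grid6), mask,
                                amplitude = 0.6 * MechanoKit:::.spacingPx(grid6),
                                nFrames = 5)
  expect_error(generatePillarMovie(grid6, big, nFrames = 5), "half")
})

test_that("rendered spots match their ground truth when localized", {
  mask <- circularCellMask(grid6)
  field <- radialContractionField(pillarNodes(grid6), mask, 1.2, 6)
  mv <- generatePillarMovie(grid6, field, nFrames = 6, noiseSd = 0, seed = 2)
  est <- localizeSpots(mv@frames[, , 4], mv@nodes, psfSigma = grid6@psfSigma)
  expect_lt(max(abs(est - mv@truth[, , 4])), 0.01)
})

test_that("localization is exact for centred spots and invariant to intensity scale", {
  g1 <- PillarGrid(nx = 1, ny = 1)
  nodes <- pillarNodes(g1)
  render <- function(truth, amp = 1000, bg = 100) {
    wpx <- ceiling(nodes[1] + MechanoKit:::.spacingPx(g1))
    cols <- 0:(wpx - 1)
    bg + amp * outer(exp(-(cols - truth[2])^2 / (2 * g1@psfSigma^2)),
                     exp(-(cols - truth[1])^2 / (2 * g1@psfSigma^2)))
  }
  onPixel <- round(as.numeric(nodes))
  est <- localizeSpots(render(onPixel), nodes, psfSigma = g1@psfSigma)
  expect_lt(max(abs(est - onPixel)), 1e-6)
  ## subpixel phase grid, noise-free: bias below 0.02 px
  worst <- 0
  for (px in seq(0, 0.8, 0.2)) for (py in seq(0.1, 0.9, 0.2)) {
    truth <- as.numeric(nodes) + c(px, py)
    e <- localizeSpots(render(truth), nodes, psfSigma = g1@psfSigma)
    worst <- max(worst, abs(e - truth))
  }
  expect_lt(worst, 0.02)
  ## doubling all intensities leaves the centre unchanged
  truth <- as.numeric(nodes) + c(0.3, -0.4)
  e1 <- localizeSpots(render(truth), nodes, psfSigma = g1@psfSigma)
  e2 <- localizeSpots(2 * render(truth), nodes, psfSigma = g1@psfSigma)
  expect_equal(e1, e2, tolerance = 1e-8)
  ## a window with no signal above background is flagged missing
  flat <- matrix(100, nrow = 26, ncol = 26)
  expect_true(all(is.na(localizeSpots(flat, nodes))))
})

test_that("linking keeps static tracks constant and interpolates missing spots", {
  mv <- generatePillarMovie(grid6, nFrames = 4, noiseSd = 0, seed = 1)
  dets <- lapply(1:4, function(f)
    localizeSpots(mv@frames[, , f], mv@nodes, psfSigma = grid6@psfSigma))
  tracks <- linkTracks(dets, grid6)
  expect_lt(max(abs(tracks@positions -
                    tracks@positions[, , c(1, 1, 1, 1)])), 1e-6)
  expect_false(any(tracks@interpolated))
  ## knock out one detection in frame 3
  dets2 <- dets
  dets2[[3]][14, ] <- NA
  tracks2 <- linkTracks(dets2, grid6)
  expect_true(tracks2@interpolated[14, 3])
  expect_equal(tracks2@positions[14, , 3],
               unname((dets[[2]][14, ] + dets[[4]][14, ]) / 2),
               tolerance = 1e-6)
})

test_that("drift-only movies track the drift and correction removes it", {
  mv <- generatePillarMovie(grid6, drift = c(0.3, -0.2), nFrames = 5,
                            noiseSd = 0, seed = 1)
  tracks <- trackPillarMovie(mv, grid6)
  for (f in 2:5) {
    d <- tracks@positions[, , f] - tracks@positions[, , 1]
    expect_lt(max(abs(sweep(d, 2, (f - 1) * c(0.3, -0.2)))), 0.02)
  }
  corrected <- correctDrift(tracks, referenceIds = 1:6)
  disp <- corrected@positions - corrected@positions[, , rep(1, 5)]
  expect_lt(max(abs(disp)), 0.02)
  expect_error(correctDrift(tracks, referenceIds = 1:2), "at least 3")
})

test_that("drift correction preserves true cell displacements", {
  mask <- circularCellMask(grid6)
  field <- radialContractionField(pillarNodes(grid6), mask, 1.0, 5)
  mv <- generatePillarMovie(grid6, field, drift = c(0.25, 0.1), nFrames = 5,
                            noiseSd = 0, seed = 3, cellMask = mask)
  tracks <- correctDrift(trackPillarMovie(mv, grid6), which(!mask))
  truthDisp <- mv@truth - mv@truth[, , rep(1, 5)]   # includes drift
  driftPart <- aperm(array(rep(t(mv@drift), each = 36), c(36, 2, 5)),
                     c(1, 2, 3))
  cellDisp <- tracks@positions - tracks@positions[, , rep(1, 5)]
  expect_lt(max(abs(cellDisp[mask, , ] -
                    (truthDisp - driftPart)[mask, , ])), 0.03)
})

test_that("forces are exactly linear in displacement", {
  mask <- circularCellMask(grid6)
  field <- radialContractionField(pillarNodes(grid6), mask, 1.0, 5)
  mv <- generatePillarMovie(grid6, field, nFrames = 5, noiseSd = 0, seed = 2,
                            cellMask = mask)
  tracks <- correctDrift(trackPillarMovie(mv, grid6), which(!mask))
  map <- displacementsToForces(tracks, grid6, mask)
  ## componentwise F = k d with d in um
  expect_equal(map@forces, map@displacements * grid6@stiffness / 1000)
  ## 0.2 um at 15 nN/um is 3 nN
  expect_equal(15 * 0.2, 3.0)
  ## peak forces match stiffness times the known maximal displacement
  truthPeak <- grid6@stiffness * 1.0 * grid6@pixelSize
  expect_lt(max(abs(peakForces(map)[mask] - truthPeak)) / truthPeak, 0.01)
  ## zero displacement means zero force
  expect_equal(map@forces[, , 1], matrix(0, 36, 2))
  ## refuses uncorrected tracks
  raw <- trackPillarMovie(mv, grid6)
  expect_error(displacementsToForces(raw, grid6, mask), "drift")
})

test_that("pillar movies round-trip through multi-frame TIFF", {
  mv <- generatePillarMovie(grid6, nFrames = 3, noiseSd = 20, seed = 5)
  path <- withr::local_tempfile(fileext = ".tif")
  writePillarMovie(mv, path)
  back <- readPillarStack(path)
  expect_identical(dim(back), dim(mv@frames))
  expect_lt(max(abs(back - mv@frames)), 1.01)   # 16-bit quantization step
})
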