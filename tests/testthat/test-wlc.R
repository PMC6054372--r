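test_that("thermal energy matches kB * T", {
  expect_equal(thermalEnergy(298), 4.114, tolerance = 1e-3)
  expect_equal(thermalEnergy(1), 0.0138065)
  expect_error(thermalEnergy(0), "positive")
})

test_that("Marko-Siggia force: spot value, zero point, monotonicity", {
  p <- WLCParams(0.4, 100, 298)
  expect_identical(wlcForce(0, p), 0)
  ## half-extension: (kBT/Lp) * 1.25
  expect_equal(wlcForce(50, p), (0.0138065 * 298 / 0.4) * 1.25)
  expect_equal(round(wlcForce(50, p), 2), 12.86)
  xs <- seq(0, 99, length.out = 500)
  expect_true(all(diff(wlcForce(xs, p)) > 0))
  expect_gt(wlcForce(99.9, p), wlcForce(90, p))
  expect_error(wlcForce(-1, p), ">= 0")
  expect_error(wlcForce(100, p), "contour")
  expect_error(wlcForce(150, p), "contour")
})

test_that("wlcExtension inverts wlcForce to 1e-9 relative on a 1000-point grid", {
  p <- WLCParams(0.4, 100, 298)
  expect_identical(wlcExtension(0, p), 0)
  expect_lt(abs(wlcExtension(wlcForce(50, p), p) - 50), 1e-6)
  xs <- seq(1e-3, 0.99 * 100, length.out = 1000)
  back <- wlcExtension(wlcForce(xs, p), p)
  expect_lt(max(abs(back - xs) / xs), 1e-9)
  expect_error(wlcExtension(-5, p), ">= 0")
  ## other parameter sets round-trip too
  p2 <- WLCParams(0.8, 350, 310)
  xs2 <- seq(1, 0.99 * 350, length.out = 200)
  expect_lt(max(abs(wlcExtension(wlcForce(xs2, p2), p2) - xs2) / xs2), 1e-9)
})

test_that("residue-to-contour conversion is linear, floored and warns off-window", {
  expect_identical(residuesToContourGain(0, 0.4, 0), 0)
  expect_equal(residuesToContourGain(124, 0.40, 0), 49.6)
  expect_equal(residuesToContourGain(124, 0.34, 4.0), 38.16)
  ## linear in residue count at fixed conversion
  n <- c(10, 20, 40, 80)
  g <- residuesToContourGain(n, 0.365, 0)
  expect_equal(g, n * 0.365)
  ## floor at zero when the folded correction dominates
  expect_identical(residuesToContourGain(5, 0.365, 10), 0)
  expect_warning(residuesToContourGain(100, 0.2, 0), "plausible")
  expect_warning(residuesToContourGain(100, 0.5, 0), "plausible")
  expect_error(residuesToContourGain(-1, 0.4, 0), ">= 0")
})

test_that("WLCParams validity enforces physical values", {
  expect_error(WLCParams(0.4, 0.2), "smaller than")
  expect_error(WLCParams(-0.4, 100), "positive")
  expect_error(WLCParams(0.4, 100, temperature = -1), "positive")
})
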