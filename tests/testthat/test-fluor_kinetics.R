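# Photobleaching quantification from dual-wavelength fluorescence data.

test_that("segmentation recovers a bright disc and rejects empty frames", {
  fx <- discFrame()
  roi <- segmentFluorescingArea(fx$frame, 0.2)
  expect_identical(roi, fx$disc)
  expect_error(segmentFluorescingArea(matrix(0, 8, 8)), "no fluorescence")
})

test_that("segmentation threshold agrees with a brute-force pixel scan", {
  px <- matrix(seq(0, 1, length.out = 400), 20, 20)  # linear ramp
  roi <- segmentFluorescingArea(px, 0.5)
  thr <- 0.5 * quantile(px, 0.99, names = FALSE)
  manual <- px >= thr & px > 0
  # the kept component must be a subset of the thresholded pixels and the
  # largest connected one; on the ramp the upper half-range is one block
  expect_identical(sum(roi), sum(manual))
  expect_true(all(px[roi] >= thr))
})

test_that("segmentation keeps only the largest connected component", {
  px <- matrix(0, 20, 20)
  px[2:12, 2:12] <- 100    # 121 px block
  px[16:18, 16:18] <- 100  # 9 px block
  roi <- segmentFluorescingArea(px, 0.2)
  expect_identical(sum(roi), 121L)
  expect_true(all(which(roi, arr.ind = TRUE)[, 1] <= 12))
})

test_that("meanIntensity equals direct enumeration", {
  expect_identical(meanIntensity(matrix(7, 5, 5), matrix(TRUE, 5, 5)), 7)
  roi <- matrix(FALSE, 2, 2); roi[1, ] <- TRUE
  expect_identical(meanIntensity(matrix(c(4, 9, 6, 9), 2, 2), roi), 5)
  set.seed(1)
  px <- matrix(runif(300), 15, 20)
  m <- matrix(runif(300) > 0.5, 15, 20)
  expect_equal(meanIntensity(px, m), sum(px[m]) / sum(m))
  expect_error(meanIntensity(px, matrix(TRUE, 2, 2)), "shape")
})

test_that("photobleaching efficiency arithmetic and scale invariance", {
  expect_equal(photobleachingEfficiency(100, 58), 42)
  expect_equal(photobleachingEfficiency(3.7, 3.7), 0)
  # exponential model at D = 50 with the blue-regime 405-nm rate
  expect_equal(photobleachingEfficiency(1, exp(-0.011 * 50)),
               100 * (1 - exp(-0.55)), tolerance = 1e-12)
  expect_equal(round(photobleachingEfficiency(1, exp(-0.011 * 50)), 2), 42.31)
  for (c in c(0.01, 3, 1e4))
    expect_equal(photobleachingEfficiency(c * 80, c * 31),
                 photobleachingEfficiency(80, 31))
  expect_error(photobleachingEfficiency(0, 1), "ifBefore")
})

test_that("model-implied efficiency is increasing in dose from 0 to 100", {
  d <- seq(0, 400, 10)
  pe <- modelBleachEfficiency(0.014, d)
  expect_identical(pe[1], 0)
  expect_true(all(diff(pe) > 0))
  expect_lt(max(pe), 100)
  expect_equal(modelBleachEfficiency(0.014, 1e6), 100, tolerance = 1e-9)
})

test_that("rate fit is exact on noiseless model data", {
  d <- seq(0, 50, 10)
  fit <- fitBleachRate(doseSeries(d, 100 * exp(-0.017 * d), 660))
  expect_equal(fit@alpha, 0.017, tolerance = 1e-9)
  expect_equal(fit@if1, 100, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  # closed-form two-point solution, padded to the minimum 3 points
  d2 <- c(0, 25, 50)
  i2 <- c(100, 100 * exp(-0.011 * 25), 57.695)
  fit2 <- fitBleachRate(doseSeries(d2, i2, 405))
  expect_equal(fit2@alpha, log(100 / 57.695) / 50, tolerance = 1e-4)
  expect_equal(round(fit2@alpha, 3), 0.011)
  expect_error(fitBleachRate(doseSeries(c(0, 10), c(1, 0.5), 405)),
               "3 dose points")
})

test_that("rate fit recovers the generating rate from noisy replicates", {
  spec <- sessionSpec(alpha405 = 0.014, alpha660 = 0.014, seed = 42)
  reps <- generateBleachSeries(spec, 405)
  alphas <- vapply(reps, function(s) fitBleachRate(s)@alpha, numeric(1))
  expect_lt(abs(mean(alphas) - 0.014) / 0.014, 0.10)
})

test_that("red-to-blue ratio and its dose series behave as expected", {
  expect_equal(redBlueRatio(0.9, 1.0), 0.9)
  expect_equal(redBlueRatio(5.5, 5.5), 1.0)
  expect_error(redBlueRatio(1, 0), "if405")

  d <- seq(0, 50, 10)
  s405 <- doseSeries(d, 100 * exp(-0.011 * d), 405)
  s660 <- doseSeries(d, 100 * exp(-0.009 * d), 660)
  rising <- ratioSeries(s660, s405)
  expect_identical(attr(rising, "trend"), "rising")
  expect_true(all(diff(rising$ratio) > 0))

  # red-light regime rates: 660-excited bleaches faster, ratio falls
  s405r <- doseSeries(d, 100 * exp(-0.014 * d), 405)
  s660r <- doseSeries(d, 100 * exp(-0.017 * d), 660)
  falling <- ratioSeries(s660r, s405r)
  expect_identical(attr(falling, "trend"), "falling")
  expect_equal(falling$ratio, exp((0.014 - 0.017) * d))
  expect_true(all(diff(falling$ratio) < 0))

  same <- ratioSeries(doseSeries(d, 100 * exp(-0.01 * d), 660),
                      doseSeries(d, 100 * exp(-0.01 * d), 405))
  expect_equal(same$ratio, rep(1, length(d)))
  expect_identical(attr(same, "trend"), "flat")
})

test_that("ratio series interpolates mismatched dose grids", {
  d1 <- seq(0, 50, 10); d2 <- seq(0, 50, 5)
  s660 <- doseSeries(d1, 100 * exp(-0.009 * d1), 660)
  s405 <- doseSeries(d2, 100 * exp(-0.011 * d2), 405)
  rs <- ratioSeries(s660, s405)
  expect_identical(rs$dose, d1)  # coarser grid wins
  expect_equal(rs$ratio, exp((0.011 - 0.009) * d1), tolerance = 1e-6)
})

test_that("dose from exposure converts mW/cm2 and seconds to J/cm2", {
  expect_identical(doseFromExposure(200, 250), 50)
  expect_identical(doseFromExposure(200, 750), 150)
  expect_identical(doseFromExposure(123, 0), 0)
  expect_error(doseFromExposure(-1, 10), "non-negative")
})

test_that("tabulated rates give efficiencies bracketing the success level", {
  pe <- modelBleachEfficiency(tabulatedRates, 50)
  expect_true(all(pe >= 36 & pe <= 58))
  expect_gte(mean(pe), 40)
})

test_that("series CSV round-trips both excitations", {
  d <- seq(0, 50, 10)
  sl <- list(doseSeries(d, 100 * exp(-0.011 * d), 405),
             doseSeries(d, 90 * exp(-0.009 * d), 660))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSeriesCSV(sl, path)
  back <- readSeriesCSV(path)
  expect_setequal(names(back), c("405", "660"))
  expect_equal(intensities(back[["405"]]), intensities(sl[[1]]))
  expect_equal(doses(back[["660"]]), d)
  expect_equal(excitationNm(back[["660"]]), 660)
})
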