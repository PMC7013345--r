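# Synthetic session generator: decay series, images, outcome tables.

test_that("noise-free series are exact exponentials and runs are seeded", {
  spec <- sessionSpec(alpha405 = 0.011, alpha660 = 0.009, noiseCv = 0,
                      seed = 3)
  s <- generateBleachSeries(spec, 405)[[1]]
  expect_equal(intensities(s), 100 * exp(-0.011 * doses(s)), tolerance = 1e-12)
  spec2 <- sessionSpec(preset = "pdt_r", seed = 3)
  r1 <- generateBleachSeries(spec2, 660)
  r2 <- generateBleachSeries(spec2, 660)
  expect_identical(lapply(r1, intensities), lapply(r2, intensities))
  # different excitations draw from decoupled streams
  expect_false(identical(intensities(generateBleachSeries(spec2, 405)[[1]]),
                         intensities(r1[[1]])))
})

test_that("generated noise is unbiased: replicate mean approaches the model", {
  spec <- sessionSpec(alpha405 = 0.011, alpha660 = 0.011,
                      doses = c(0, 25, 50), nReplicates = 1000, seed = 12)
  reps <- generateBleachSeries(spec, 405)
  at50 <- vapply(reps, function(s) intensities(s)[3], numeric(1))
  expect_lt(abs(mean(at50) - 100 * exp(-0.55)) / (100 * exp(-0.55)), 0.01)
})

test_that("generator and estimator are consistent within stated bias", {
  spec <- sessionSpec(alpha405 = 0.014, alpha660 = 0.017, nReplicates = 60,
                      seed = 2024)
  for (ex in c(405, 660)) {
    a0 <- if (ex == 405) 0.014 else 0.017
    al <- vapply(generateBleachSeries(spec, ex),
                 function(s) fitBleachRate(s)@alpha, numeric(1))
    expect_lt(abs(mean(al) - a0) / a0, 0.05)
  }
})

test_that("image sessions round-trip through segmentation to the decay curve", {
  spec0 <- sessionSpec(preset = "pdt_b", noiseCv = 0, seed = 5)
  sess <- generateSessionImages(spec0)
  expect_identical(length(sess$frames), 2L * length(spec0@doses))
  for (i in seq_len(nrow(sess$manifest))) {
    f <- sess$frames[[i]]
    mu <- 100 * exp(-(if (f@excitationNm == 405) 0.011 else 0.009) *
                      f@cumulativeDose)
    roi <- segmentFluorescingArea(f)
    expect_equal(meanIntensity(f, roi), mu, tolerance = 1e-9)
  }
  # with noise, the recovered means stay within 2 CV of the model
  spec <- sessionSpec(preset = "pdt_b", noiseCv = 0.05, seed = 5)
  sessN <- generateSessionImages(spec)
  for (i in seq_len(nrow(sessN$manifest))) {
    f <- sessN$frames[[i]]
    mu <- 100 * exp(-(if (f@excitationNm == 405) 0.011 else 0.009) *
                      f@cumulativeDose)
    got <- meanIntensity(f, segmentFluorescingArea(f))
    expect_lt(abs(got - mu) / mu, 2 * spec@noiseCv)
  }
})

test_that("presets reproduce the opposite ratio trends end to end", {
  extract <- function(preset) {
    sess <- generateSessionImages(sessionSpec(preset = preset, seed = 11))
    man <- sess$manifest
    series <- lapply(c(405, 660), function(ex) {
      sel <- which(man$excitation_nm == ex)
      means <- vapply(sel, function(i) {
        f <- sess$frames[[i]]
        meanIntensity(f, segmentFluorescingArea(f))
      }, numeric(1))
      doseSeries(man$cumulative_dose_Jcm2[sel], means, ex)
    })
    ratioSeries(series[[2]], series[[1]])
  }
  expect_identical(attr(extract("pdt_b"), "trend"), "rising")
  expect_identical(attr(extract("pdt_r"), "trend"), "falling")
})

test_that("written sessions read back with quantization-level fidelity", {
  dir <- withr::local_tempdir()
  sess <- generateSessionImages(sessionSpec(preset = "pdt_r", seed = 9,
                                            doses = c(0, 25, 50)))
  manifest <- writeSession(sess, dir)
  back <- readSession(manifest)
  expect_identical(nrow(back$manifest), nrow(sess$manifest))
  for (i in seq_along(sess$frames)) {
    expect_equal(back$frames[[i]]@cumulativeDose,
                 sess$frames[[i]]@cumulativeDose)
    expect_equal(back$frames[[i]]@pixels, sess$frames[[i]]@pixels,
                 tolerance = 1e-3)
  }
  expect_error(readSession(file.path(dir, "nope.csv")), "manifest not found")
})

test_that("outcome tables respect the qualitative ordering rules", {
  for (seed in c(1, 7, 123)) {
    g <- generateOutcomeTable(seed)
    expect_identical(nrow(g), 60L)  # 20 regimes x 3 timepoints
    expect_true(all(g$grade %in% 0:3))
    expect_setequal(unique(g$regime), regimeCodes())
    # mildest regime: at most weak edema
    expect_true(all(g$grade[g$regime == "PDT_r50"] <= 1))
    # red never exceeds the equal-dose blue regime
    for (fam in c("PDT", "IRR")) for (dose in c(50, 75, 100, 150))
      for (tp in c("post", "day4", "day7")) {
        gr <- g$grade[g$regime == paste0(fam, "_r", dose) & g$timepoint == tp]
        gb <- g$grade[g$regime == paste0(fam, "_b", dose) & g$timepoint == tp]
        expect_lte(gr, gb)
      }
    # relaxation by day 7 except the severe blue regimes
    for (rg in setdiff(regimeCodes(), c("PDT_b100", "PDT_b150"))) {
      g4 <- g$grade[g$regime == rg & g$timepoint == "day4"]
      g7 <- g$grade[g$regime == rg & g$timepoint == "day7"]
      expect_lte(g7, g4)
    }
  }
})

test_that("session spec validity catches inconsistent geometry and rates", {
  expect_error(sessionSpec(seed = 1, alpha405 = -0.1), "non-negative")
  expect_error(sessionSpec(seed = 1, roiRadius = 40), "fit inside")
  expect_error(sessionSpec(seed = 1, doses = c(10, 20)), "start at 0")
  expect_error(sessionSpec(seed = 1, noiseCv = 1.5), "noiseCv")
})
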