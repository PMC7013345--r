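# Monte Carlo transport in the layered slab.

test_that("Fresnel reflectance matches closed forms and handles TIR", {
  # air onto skin at normal incidence: ((1.45-1)/(1.45+1))^2
  expect_equal(fresnelReflectance(1.0, 1.45, 1.0), (0.45 / 2.45)^2,
               tolerance = 1e-9)
  expect_identical(fresnelReflectance(1.4, 1.4, 0.3), 0)
  # beyond the critical angle from the dense side
  cosc <- sqrt(1 - (1 / 1.45)^2)           # cos at the critical angle
  expect_identical(fresnelReflectance(1.45, 1.0, cosc * 0.5), 1)
  expect_error(fresnelReflectance(1.0, 1.45, 1.2), "cos_theta_i")
  expect_error(fresnelReflectance(1.0, 1.45, -0.1), "cos_theta_i")
})

test_that("default rabbit-ear model carries the tabulated optics", {
  m405 <- defaultRabbitEarModel(405)
  ly <- tissueLayers(m405)
  expect_identical(nrow(ly), 3L)
  expect_equal(ly$thickness_mm, c(0.4, 0.2, 0.4))
  expect_equal(totalThickness(m405), 1.0)
  expect_equal(ly$mua[1], 1.3)
  expect_equal(ly$musp[1], 5.4)
  expect_equal(ly$n[1], 1.45)
  m660 <- defaultRabbitEarModel(660)
  ly6 <- tissueLayers(m660)
  expect_equal(ly6$mua[2], 0.01)
  expect_equal(ly6$musp[2], 1.0)
  expect_equal(ly6$thickness_mm[2], 0.2)
  expect_error(defaultRabbitEarModel(500), "405 and 660")
})

test_that("tissue model validity rejects unphysical layers", {
  bad <- data.frame(name = "x", thickness_mm = -1, n = 1.4, mua = 1, musp = 1)
  expect_error(tissueModel(bad), "thickness")
  bad$thickness_mm <- 1; bad$n <- 0.9
  expect_error(tissueModel(bad), "refractive")
  bad$n <- 1.4; bad$mua <- 0; bad$musp <- 0
  expect_error(tissueModel(bad), "mua = 0 and musp = 0")
})

test_that("tissue CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- defaultRabbitEarModel(660)
  writeTissueCSV(m, path)
  m2 <- readTissueCSV(path, wavelength = 660)
  expect_equal(tissueLayers(m2), tissueLayers(m))
})

test_that("absorption-only transport reproduces Beer-Lambert", {
  res <- simulateTransport(absorberModel(),
                           transportConfig(nPhotons = 1e6, zBin = 0.05,
                                           seed = 101))
  sel <- res@zCenters <= 3
  rms <- sqrt(mean((res@absorbedDensity[sel] - exp(-res@zCenters[sel]))^2))
  expect_lt(rms, 0.01)
  # analytic integral: everything but the transmitted tail is absorbed
  expect_equal(absorbedFraction(res, 0, 10.1), 1 - res@rSpecular,
               tolerance = 1e-3)
})

test_that("energy fractions conserve launched energy", {
  for (wl in c(405, 660)) {
    res <- simulateTransport(defaultRabbitEarModel(wl),
                             transportConfig(nPhotons = 2e5, seed = 11 + wl))
    tot <- res@rSpecular + res@rDiffuse + res@transmitted + res@absorbedTotal
    sigma <- sqrt(0.25 / res@nPhotons)
    expect_lt(abs(1 - tot), 3 * sigma)
    expect_true(all(c(res@rSpecular, res@rDiffuse, res@transmitted,
                      res@absorbedTotal) >= 0))
  }
})

test_that("transport is bit-identical for a fixed seed", {
  cfg <- transportConfig(nPhotons = 5e4, seed = 77)
  r1 <- simulateTransport(defaultRabbitEarModel(405), cfg)
  r2 <- simulateTransport(defaultRabbitEarModel(405), cfg)
  expect_identical(r1@absorbedDensity, r2@absorbedDensity)
  expect_identical(r1@rDiffuse, r2@rDiffuse)
  r3 <- simulateTransport(defaultRabbitEarModel(405),
                          transportConfig(nPhotons = 5e4, seed = 78))
  expect_false(identical(r1@absorbedDensity, r3@absorbedDensity))
})

test_that("absorbedFraction integrates half-open depth bins", {
  res <- simulateTransport(defaultRabbitEarModel(405),
                           transportConfig(nPhotons = 5e4, seed = 5))
  expect_equal(absorbedFraction(res, 0, totalThickness(defaultRabbitEarModel(405))),
               res@absorbedTotal, tolerance = 1e-12)
  expect_identical(absorbedFraction(res, 0.3, 0.3), 0)
  expect_error(absorbedFraction(res, 0.5, 0.1), "z1")
  # two disjoint intervals partition the whole
  expect_equal(absorbedFraction(res, 0, 0.5) + absorbedFraction(res, 0.5, 1),
               res@absorbedTotal, tolerance = 1e-12)
})

test_that("superficial absorption does not decrease with top-layer mua", {
  frac <- vapply(c(0.3, 1.3, 2.6), function(mua) {
    m <- tissueModel(data.frame(name = "skin", thickness_mm = 1, n = 1.45,
                                mua = mua, musp = 5))
    absorbedFraction(simulateTransport(m, transportConfig(2e5, seed = 31)),
                     0, 0.1)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("invalid transport configuration is rejected", {
  expect_error(transportConfig(nPhotons = 0, seed = 1), "nPhotons")
  expect_error(transportConfig(seed = 1, rouletteSurvival = 1.2),
               "rouletteSurvival")
  expect_error(transportConfig(nPhotons = 1e3), "seed")
})

test_that("dose profile output round-trips through CSV/JSON", {
  res <- simulateTransport(defaultRabbitEarModel(660),
                           transportConfig(nPhotons = 2e4, seed = 8))
  prefix <- file.path(withr::local_tempdir(), "dose660")
  writeDoseProfile(res, prefix)
  tb <- read.csv(paste0(prefix, ".csv"))
  expect_equal(tb$absorbed_per_mm, res@absorbedDensity)
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(js$absorbed_total, res@absorbedTotal)
  expect_equal(js$seed, 8L)
})
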