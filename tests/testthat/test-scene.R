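# Scene simulator: geometry, chromophore forward model, rendering, noise.

test_that("default zone truths land exactly in the ROI masks", {
  sc <- smallScene()
  s <- sto2Map(sc); roi <- roiMasks(sc)
  expect_lt(abs(mean(s[roi == 1]) - 0.3008), 1e-3)
  expect_lt(abs(mean(s[roi %in% c(2, 4)]) - 0.4567), 1e-3)
  expect_lt(abs(mean(s[roi %in% c(3, 5)]) - 0.4808), 1e-3)
  # masks disjoint by construction (single label matrix), five of them
  expect_setequal(setdiff(unique(as.vector(roi)), 0L), 1:5)
})

test_that("zero gradient width gives piecewise-constant zone StO2", {
  sc <- smallScene(gradientWidth = 0)
  s <- sto2Map(sc); roi <- roiMasks(sc)
  for (k in 1:5) expect_equal(sd(s[roi == k]), 0)
  expect_equal(unique(s[roi == 1]), 0.3008)
  expect_equal(unique(s[roi == 2]), 0.4567)
  expect_equal(unique(s[roi == 5]), 0.4808)
})

test_that("scene geometry is deterministic; texture follows the seed", {
  a <- smallScene(seed = 1, textureSd = 0.05)
  b <- smallScene(seed = 2, textureSd = 0.05)
  expect_identical(roiMasks(a), roiMasks(b))
  expect_identical(sto2Map(a), sto2Map(b))
  expect_false(identical(a@thbMap, b@thbMap))
  expect_identical(smallScene(seed = 1, textureSd = 0.05)@thbMap, a@thbMap)
})

test_that("ROIs that cannot fit the field raise a geometry error", {
  expect_error(makeBowelScene(shape = c(64, 64), pixelPitch = 0.2),
               "geometry")
})

test_that("scene absorption follows the haemoglobin mixing model", {
  tab <- hbExtinction()
  e <- extinctionAt(tab, 665)
  # pure oxyhaemoglobin: only eps_HbO2 contributes
  muaOxy <- hbMuA(1, 60, 665, tab, backgroundMuA = 0)
  expect_equal(muaOxy, e[["epsHbO2"]] * 60 * log(10) * 1e-7, tolerance = 1e-12)
  # deoxygenated tissue absorbs more red light than oxygenated tissue
  expect_gt(hbMuA(0, 60, 665, tab), hbMuA(1, 60, 665, tab))
  # ... and the order flips in the NIR
  expect_lt(hbMuA(0, 60, 860, tab), hbMuA(1, 60, 860, tab))
  expect_error(hbMuA(0.5, 60, 700, tab), "not present")
})

test_that("chromophore synthesis and unmixing are mutual inverses", {
  sc <- smallScene()
  s <- unmixSto2(sceneToMuA(sc, 665), sceneToMuA(sc, 860))
  expect_lt(max(abs(sto2(s) - sto2Map(sc))), 1e-6)
  expect_lt(max(abs(thb(s) - sc@thbMap)), 1e-9 * max(sc@thbMap))
})

test_that("zero modulation renders a flat field at (I0/2) R_DC", {
  op <- OpticalProperties(0.01, 1.1)
  fr <- homoFrame(op, fx = 0, m = 0)
  expect_equal(unique(as.vector(frameImage(fr))),
               15000 * diffusionRd(0.01, 1.1, 0), tolerance = 1e-12)
})

test_that("noiseless homogeneous pattern has spectral energy only at DC and fx", {
  op <- OpticalProperties(0.02, 1.5)
  fr <- homoFrame(op, fx = FX, shape = c(4, 512))
  row <- frameImage(fr)[1, ]
  spec <- Mod(fft(row))
  freqs <- seq(0, length(row) - 1) / (length(row) * PITCH)
  freqs <- pmin(freqs, 1 / PITCH - freqs)  # two-sided
  nearCarrier <- abs(freqs - FX) < 0.02 | freqs < 0.02
  # energy away from DC and the +/- fx bins is pure spectral leakage
  expect_lt(max(spec[!nearCarrier]) / max(spec), 0.02)
})

test_that("the three phase-shifted frames average to the planar frame", {
  op <- OpticalProperties(0.015, 2)
  set <- sfdiSet(op)
  avg <- Reduce(`+`, lapply(set$ac, frameImage)) / 3
  flat <- frameImage(homoFrame(op, fx = 0, m = 0))
  expect_lt(max(abs(avg - flat)), 1e-8 * max(flat))
})

test_that("calibration-set planar mean matches the forward model at both wavelengths", {
  ph <- calibrationPhantom()
  # planar acquisition: unmodulated flat field
  pats <- list(PatternSpec(0, 0, modulationDepth = 0, pixelPitch = PITCH))
  f665 <- renderCalibrationSet(ph, pats, 665, c(16, 64), noiseOff)[[1]]
  f860 <- renderCalibrationSet(ph, pats, 860, c(16, 64), noiseOff)[[1]]
  expect_equal(mean(frameImage(f665)), 15000 * diffusionRd(0.01, 1.1, 0),
               tolerance = 1e-12)
  # the two wavelengths differ exactly by the forward-model ratio
  expect_equal(mean(frameImage(f860)) / mean(frameImage(f665)),
               diffusionRd(0.02, 0.8, 0) / diffusionRd(0.01, 1.1, 0),
               tolerance = 1e-12)
})

test_that("rendered noise matches the shot + read model", {
  op <- OpticalProperties(0.01, 1.1)
  fr <- homoFrame(op, fx = 0, m = 0, shape = c(128, 128),
                  noise = noiseModel(readSd = 2, shot = TRUE), seed = 6)
  level <- 15000 * diffusionRd(0.01, 1.1, 0)
  expected <- sqrt(level + 2^2)
  expect_lt(abs(sd(frameImage(fr)) - expected) / expected, 0.1)
})

test_that("saturated pixels are clipped and recorded", {
  op <- OpticalProperties(0.005, 3)   # bright: R_d near maximal
  fr <- homoFrame(op, fx = 0, m = 0, dcLevel = 2^18)
  expect_true(all(frameImage(fr) <= 2^16 - 1))
  expect_false(is.null(fr@saturationMask))
  expect_true(all(fr@saturationMask))
})

test_that("patterns beyond Nyquist are rejected at construction", {
  expect_error(PatternSpec(fx = 4, pixelPitch = 0.2), "Nyquist")
})

test_that("study generator hits its design targets and is reproducible", {
  st0 <- simulateStudy(sto2Sd = 0, lactateSd = 0)
  n0 <- normaliseLactates(st0)
  # noiseless: zone means equal the generator targets exactly
  expect_equal(mean(n0$normalisedLactate[n0$zone == 1]), 4.804)
  expect_equal(mean(n0$normalisedLactate[n0$zone == 2]), 1.026)
  expect_equal(mean(n0$normalisedLactate[n0$zone == 3]), 0.749)
  expect_identical(simulateStudy(seed = 44), simulateStudy(seed = 44))
  expect_error(simulateStudy(seed = NULL), "seed")
})
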