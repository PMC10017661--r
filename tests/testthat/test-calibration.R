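# Phantom calibration and LUT inversion.

phant <- calibrationPhantom()

ssopMaps <- function(op, wl = 665, shape = c(32, 256), noise = noiseOff,
                     seed = NULL)
  ssopDemodulate(homoFrame(op, FX, shape = shape, wl = wl, noise = noise,
                           seed = seed))

test_that("self-calibration returns the phantom's model reflectance", {
  ref <- ssopMaps(phantomProps(phant, 665))
  refl <- calibrate(ref, ref, phant)
  ok <- validityMask(refl)
  expect_true(any(ok))
  expect_lt(max(abs(rDc(refl)[ok] - diffusionRd(0.01, 1.1, 0))), 1e-9)
  expect_lt(max(abs(rAc(refl)[ok] - diffusionRd(0.01, 1.1, FX))), 1e-9)
})

test_that("calibrating one phantom against another recovers its reflectance", {
  opB <- OpticalProperties(0.03, 2.2)
  sample <- ssopMaps(opB)
  ref <- ssopMaps(phantomProps(phant, 665))
  refl <- calibrate(sample, ref, phant)
  ok <- validityMask(refl)
  expect_lt(max(abs(rDc(refl)[ok] / diffusionRd(0.03, 2.2, 0) - 1)), 0.01)
  expect_lt(max(abs(rAc(refl)[ok] / diffusionRd(0.03, 2.2, FX) - 1)), 0.01)
})

test_that("calibration rejects inconsistent inputs", {
  s <- ssopMaps(OpticalProperties(0.02, 1))
  r860 <- ssopMaps(phantomProps(phant, 860), wl = 860)
  expect_error(calibrate(s, r860, phant), "wavelength")
  ph700 <- new("CalibrationPhantom",
               props = list("700" = OpticalProperties(0.01, 1)),
               description = "wrong wavelength")
  r <- ssopMaps(phantomProps(phant, 665))
  expect_error(calibrate(s, r, ph700), "no properties")
})

test_that("reflectance above 1 is flagged invalid, not clipped", {
  s <- ssopMaps(OpticalProperties(0.005, 3))
  r <- ssopMaps(phantomProps(phant, 665))
  bright <- s
  bright@mDc <- s@mDc * 3  # force nonphysical calibrated reflectance
  refl <- calibrate(bright, r, phant)
  sel <- centralCols(s)
  expect_true(all(rDc(refl)[, sel] > 1))
  expect_false(any(validityMask(refl)[, sel]))
})

test_that("a reflectance pair generated at a grid node inverts to that node", {
  i <- 20L; j <- 40L
  shape <- c(4, 8)
  maps <- new("DiffuseReflectanceMaps",
              rDc = matrix(lutDefault@rDc[i, j], shape[1], shape[2]),
              rAc = matrix(lutDefault@rAc[i, j], shape[1], shape[2]),
              wavelength = 665, fxPair = c(0, FX),
              validityMask = matrix(TRUE, shape[1], shape[2]))
  props <- invertLut(maps, lutDefault)
  expect_false(any(outOfLutMask(props)))
  expect_lt(max(abs(muA(props) - lutDefault@muAGrid[i])) /
              lutDefault@muAGrid[i], 1e-6)
  expect_lt(max(abs(muSPrime(props) - lutDefault@muSPrimeGrid[j])) /
              lutDefault@muSPrimeGrid[j], 1e-6)
})

test_that("off-grid optical properties round-trip through the LUT within 2%", {
  truths <- list(c(0.0137, 1.21), c(0.0291, 2.63), c(0.0072, 0.77))
  for (tr in truths) {
    maps <- new("DiffuseReflectanceMaps",
                rDc = matrix(diffusionRd(tr[1], tr[2], 0), 2, 2),
                rAc = matrix(diffusionRd(tr[1], tr[2], FX), 2, 2),
                wavelength = 665, fxPair = c(0, FX),
                validityMask = matrix(TRUE, 2, 2))
    props <- invertLut(maps, lutDefault)
    expect_false(any(outOfLutMask(props)))
    expect_lt(abs(muA(props)[1, 1] - tr[1]) / tr[1], 0.02)
    expect_lt(abs(muSPrime(props)[1, 1] - tr[2]) / tr[2], 0.02)
  }
})

test_that("nonphysical reflectance lands in the out-of-LUT mask", {
  maps <- new("DiffuseReflectanceMaps",
              rDc = matrix(c(1.5, diffusionRd(0.01, 1.1, 0)), 1, 2),
              rAc = matrix(c(0.9, diffusionRd(0.01, 1.1, FX)), 1, 2),
              wavelength = 665, fxPair = c(0, FX),
              validityMask = matrix(TRUE, 1, 2))
  props <- invertLut(maps, lutDefault)
  expect_true(outOfLutMask(props)[1, 1])
  expect_true(is.na(muA(props)[1, 1]))
  expect_false(outOfLutMask(props)[1, 2])
})

test_that("inversion is deterministic and validates its inputs", {
  maps <- new("DiffuseReflectanceMaps",
              rDc = matrix(diffusionRd(0.02, 1.5, 0), 3, 3),
              rAc = matrix(diffusionRd(0.02, 1.5, FX), 3, 3),
              wavelength = 665, fxPair = c(0, FX),
              validityMask = matrix(TRUE, 3, 3))
  p1 <- invertLut(maps, lutDefault)
  p2 <- invertLut(maps, lutDefault)
  expect_identical(muA(p1), muA(p2))
  empty <- maps
  empty@validityMask[] <- FALSE
  expect_error(invertLut(empty, lutDefault), "no valid pixels")
  wrongFx <- lutDefault
  wrongFx@fxPair <- c(0, 0.3)
  expect_error(invertLut(maps, wrongFx), "fx pair")
})

test_that("full noiseless pipeline recovers homogeneous truths within 2%", {
  for (tr in list(c(0.012, 1.4), c(0.033, 0.9))) {
    op <- OpticalProperties(tr[1], tr[2])
    sample <- ssopMaps(op)
    ref <- ssopMaps(phantomProps(phant, 665))
    refl <- calibrate(sample, ref, phant)
    props <- invertLut(refl, lutDefault)
    ok <- !outOfLutMask(props)
    # essentially all calibration-valid pixels must invert
    expect_gt(sum(ok) / sum(validityMask(refl)), 0.99)
    expect_lt(median(abs(muA(props)[ok] - tr[1]) / tr[1]), 0.02)
    expect_lt(median(abs(muSPrime(props)[ok] - tr[2]) / tr[2]), 0.02)
  }
})
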