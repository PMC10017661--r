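# Diffusion forward model, Hankel transform, LUT construction/serialization.

test_that("diffusion reflectance obeys its physical limits", {
  # zero absorption, planar illumination: everything that entered comes
  # back (the deficit scales as sqrt(mu_a), hence the tiny limit value)
  expect_lt(abs(diffusionRd(1e-14, 1.0, 0) - 1), 1e-6)
  # high-frequency attenuation at fixed properties
  expect_gt(diffusionRd(0.01, 1.1, 0.1), diffusionRd(0.01, 1.1, 0.3))
  # bounded in (0, 1]
  r <- diffusionRd(0.05, 0.5, 0.4)
  expect_gt(r, 0)
  expect_lte(r, 1)
})

test_that("diffusion reflectance against an independently coded evaluation", {
  # closed form re-derived step by step, kept separate from the package path
  oracle <- function(mua, mus, fx, n) {
    reff <- 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
    A <- (1 - reff) / (2 * (1 + reff))
    mutr <- mua + mus
    mueff <- sqrt(3 * mua * mutr)
    mueffp <- sqrt(mueff^2 + (2 * pi * fx)^2)
    (3 * A * (mus / mutr)) / ((mueffp / mutr + 1) * (mueffp / mutr + 3 * A))
  }
  grid <- expand.grid(mua = c(0.005, 0.0137, 0.05), mus = c(0.5, 1.21, 3),
                      fx = c(0, 0.2, 0.3))
  for (i in seq_len(nrow(grid)))
    expect_equal(diffusionRd(grid$mua[i], grid$mus[i], grid$fx[i]),
                 oracle(grid$mua[i], grid$mus[i], grid$fx[i], 1.4),
                 tolerance = 1e-12)
})

test_that("diffusion reflectance decreases with fx, and with muA in its sensitive domain", {
  muas <- seq(0.005, 0.05, length.out = 20)
  muss <- seq(0.5, 3, length.out = 20)
  fxs <- seq(0, 0.4, length.out = 5)
  # attenuation with spatial frequency holds everywhere
  for (s in muss) for (a in muas[c(1, 10, 20)])
    expect_true(all(diff(diffusionRd(a, s, fxs)) < 0))
  # muA sensitivity: strict on the planar channel across the whole grid;
  # at fx > 0 it saturates (and marginally reverses) once (2 pi fx)
  # dominates mu_tr — the low-scattering corner at the working frequency —
  # so the strict check applies below that regime
  for (s in muss) expect_true(all(diff(diffusionRd(muas, s, 0)) < 0))
  for (f in c(0.05, 0.1, 0.15)) for (s in muss)
    expect_true(all(diff(diffusionRd(muas, s, f)) < 0))
  # what inversion actually relies on: the DC/AC ratio is strictly
  # monotone in muA at every scattering level, working pair (0, 0.2)
  for (s in muss) {
    ratio <- diffusionRd(muas, s, 0) / diffusionRd(muas, s, 0.2)
    expect_true(all(diff(ratio) < 0))
  }
})

test_that("invalid optical properties are rejected", {
  expect_error(diffusionRd(-0.01, 1, 0), "> 0")
  expect_error(diffusionRd(0.01, 0, 0), "> 0")
  expect_error(diffusionRd(NaN, 1, 0), "finite")
  expect_error(diffusionRd(0.01, 1, -0.1), ">= 0")
  expect_error(OpticalProperties(0, 1))
})

test_that("Hankel transform reduces to the binned total at fx = 0", {
  prof <- mcRd(0.01, 1.1, nPhotons = 5000, seed = 21)
  edges <- prof@rhoEdges
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  manual <- 2 * pi * sum(prof@rPerArea * centres * diff(edges))
  expect_equal(as.numeric(hankelRd(prof, 0)), manual, tolerance = 1e-12)
  # ... and that equals the total diffuse reflected fraction up to
  # binning error and the overflow tail
  expect_equal(manual,
               (prof@totalReflectedWeight - prof@overflowWeight) /
                 prof@launchedWeight,
               tolerance = 0.02)
})

test_that("Hankel transform of a point-like profile is flat in fx", {
  prof <- mcRd(0.01, 1.1, nPhotons = 5000, seed = 3)
  # concentrate all weight in the first bin: a delta at the origin
  delta <- prof
  delta@rPerArea[] <- 0
  area1 <- pi * diff(prof@rhoEdges[1:2]^2)
  delta@rPerArea[1] <- 1 / area1
  vals <- hankelRd(delta, c(0, 0.1, 0.3, 0.5))
  expect_lt(max(abs(vals - vals[1])) / vals[1], 0.02)
})

test_that("Hankel spectrum of a simulated profile decreases with fx", {
  prof <- mcRd(0.01, 1.5, nPhotons = 20000, seed = 8)
  fxs <- seq(0, 0.5, by = 0.05)
  vals <- hankelRd(prof, fxs)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals <= vals[1]))
})

test_that("unresolvable frequency is flagged on the Hankel result", {
  prof <- mcRd(0.01, 1.1, nPhotons = 2000, seed = 4, dRho = 0.5, maxRho = 20)
  expect_warning(v <- hankelRd(prof, 1.0), "resolution")
  expect_true(attr(v, "unresolved"))
})

test_that("a 2x2 diffusion LUT equals pointwise forward evaluations", {
  lut <- buildLut(gridSizes = c(2, 2))
  for (i in 1:2) for (j in 1:2) {
    expect_equal(lut@rDc[i, j],
                 diffusionRd(lut@muAGrid[i], lut@muSPrimeGrid[j], 0),
                 tolerance = 1e-14)
    expect_equal(lut@rAc[i, j],
                 diffusionRd(lut@muAGrid[i], lut@muSPrimeGrid[j], 0.2),
                 tolerance = 1e-14)
  }
})

test_that("every default-grid LUT node obeys 0 < R_AC <= R_DC <= 1", {
  expect_true(all(lutDefault@rAc > 0))
  expect_true(all(lutDefault@rAc <= lutDefault@rDc))
  expect_true(all(lutDefault@rDc <= 1))
  # R_DC strictly decreasing in muA along every muS' line
  expect_true(all(apply(lutDefault@rDc, 2, diff) < 0))
})

test_that("LUT construction rejects malformed ranges", {
  expect_error(buildLut(muARange = c(0.05, 0.005)), "ascending")
  expect_error(buildLut(muSPrimeRange = c(-1, 3)), "ascending|positive")
})

test_that("LUT serialization round-trips bit-identically", {
  dir <- withr::local_tempdir()
  base <- file.path(dir, "lut")
  writeLut(lutDefault, base)
  back <- readLut(base)
  expect_identical(back@rDc, lutDefault@rDc)
  expect_identical(back@rAc, lutDefault@rAc)
  expect_identical(back@muAGrid, lutDefault@muAGrid)
  expect_identical(back@muSPrimeGrid, lutDefault@muSPrimeGrid)
  expect_identical(back@fxPair, lutDefault@fxPair)
  expect_identical(back@engine, lutDefault@engine)
})
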