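#' Camera noise model
#'
#' Poisson shot noise plus Gaussian read noise on a 16-bit sensor, the
#' minimal realistic CMOS model. \code{noiseModel(readSd = 0, shot = FALSE)}
#' gives noiseless rendering.
#'
#' @param readSd Gaussian read-noise SD, counts (default 2)
#' @param shot apply Poisson shot noise?
#' @param bitDepth sensor bit depth (counts clip at 2^bitDepth - 1 and
#'   clipped pixels are recorded in the frame's saturation mask)
#' @return a list consumed by the rendering functions
#' @export
noiseModel <- function(readSd = 2, shot = TRUE, bitDepth = 16) {
  stopifnot(readSd >= 0, bitDepth > 0)
  list(readSd = readSd, shot = shot, bitDepth = bitDepth)
}

.noiseless <- function(bitDepth = 16) noiseModel(readSd = 0, shot = FALSE,
                                                 bitDepth = bitDepth)

#' Synthetic ischaemic-bowel digital phantom
#'
#' Builds the ground-truth scene the pipeline is validated on: a
#' horizontal bowel segment on a darker background, with a central
#' ischaemic zone whose StO2 relaxes smoothly (over \code{gradientWidth}
#' mm along the segment) through marginal zones into vascularised
#' tissue. Five 1 x 1 cm square ROIs are placed along the segment at
#' 2.5 cm spacing: ROI 1 central ischaemic, ROIs 2/4 marginal (left /
#' right), ROIs 3/5 vascularised. Default zone StO2 values (0.3008,
#' 0.4567, 0.4808) are the study means the scene is designed to emulate.
#'
#' The default pixel pitch is chosen so the field of view matches the
#' instrument's 15 cm along image rows regardless of raster size.
#'
#' @param shape c(rows, cols) in pixels
#' @param roiSto2 length-3: StO2 of the ischaemic / marginal /
#'   vascularised zones, fractions
#' @param thb total haemoglobin on the segment, uM
#' @param muSPrime named per-wavelength reduced scattering on the
#'   segment, mm^-1 (names = wavelengths in nm)
#' @param gradientWidth width of the smooth StO2 transition between
#'   zones, mm (0 = piecewise constant)
#' @param pixelPitch mm per pixel (default scales 15 cm over the rows)
#' @param roiSizeMm ROI square side, mm
#' @param roiSpacingMm centre-to-centre ROI spacing along the segment, mm
#' @param seed optional seed for stochastic texture; geometry is
#'   deterministic and seed-independent
#' @param textureSd SD of multiplicative lognormal-like texture on tHb
#'   (0 = none)
#' @return a [ScenePhantom-class]
#' @export
makeBowelScene <- function(shape = c(1024, 1280),
                           roiSto2 = c(0.3008, 0.4567, 0.4808),
                           thb = 60,
                           muSPrime = c("665" = 1.3, "860" = 1.0),
                           gradientWidth = 10,
                           pixelPitch = 150 / shape[1],
                           roiSizeMm = 10, roiSpacingMm = 25,
                           seed = NULL, textureSd = 0) {
  if (any(roiSto2 < 0 | roiSto2 > 1)) stop("roiSto2 values must lie in [0, 1]")
  nr <- shape[1]; nc <- shape[2]
  heightMm <- nr * pixelPitch; widthMm <- nc * pixelPitch
  # the segment: a horizontal band through the image centre, wide enough
  # to contain the ROI squares with margin
  bandHalf <- min(15, max(heightMm * 0.2, roiSizeMm / 2 + 1))
  needW <- 4 * roiSpacingMm + roiSizeMm + 4   # ROI5 centre +2*spacing +half
  if (widthMm < needW || heightMm < 2 * bandHalf)
    stop("geometry error: five ", roiSizeMm, " mm ROIs at ", roiSpacingMm,
         " mm spacing do not fit a ", round(widthMm), " x ", round(heightMm),
         " mm field")
  rowMm <- (seq_len(nr) - 0.5) * pixelPitch
  colMm <- (seq_len(nc) - 0.5) * pixelPitch
  cy <- heightMm / 2; cx <- widthMm / 2
  tissue <- outer(abs(rowMm - cy) <= bandHalf, rep(TRUE, nc))
  # along-segment StO2 profile: ischaemic plateau at centre, smooth ramp
  # to marginal by |u| = spacing, on to vascularised by |u| = 2*spacing
  u <- abs(colMm - cx)
  ramp <- function(u, u0, w) {
    if (w <= 0) as.numeric(u >= u0)
    else pmin(1, pmax(0, (u - (u0 - w / 2)) / w))
  }
  # transitions centred midway between ROI 1-2 and ROI 2-3 positions
  f1 <- ramp(u, roiSpacingMm / 2, gradientWidth)       # isch -> marginal
  f2 <- ramp(u, 3 * roiSpacingMm / 2, gradientWidth)   # marginal -> vasc
  profile <- roiSto2[1] + (roiSto2[2] - roiSto2[1]) * f1 +
    (roiSto2[3] - roiSto2[2]) * f2
  sto2 <- matrix(profile, nr, nc, byrow = TRUE)
  # background: darker, poorly oxygenated surround
  bgSto2 <- 0.2; bgThb <- 110
  sto2[!tissue] <- bgSto2
  thbMap <- matrix(ifelse(tissue, thb, bgThb), nr, nc)
  if (textureSd > 0) {
    if (is.null(seed)) stop("textureSd > 0 requires a seed")
    set.seed(as.integer(seed))
    thbMap <- thbMap * exp(matrix(rnorm(nr * nc, 0, textureSd), nr, nc))
  }
  musMaps <- lapply(muSPrime, function(ms)
    matrix(ifelse(tissue, ms, 0.7 * ms), nr, nc))
  names(musMaps) <- names(muSPrime)
  # ROI squares centred on the band axis at 0, -1, -2, +1, +2 spacings
  roi <- matrix(0L, nr, nc)
  centres <- c(0, -1, -2, 1, 2) * roiSpacingMm + cx  # ROI 1..5
  half <- roiSizeMm / 2
  for (k in seq_along(centres)) {
    rows <- which(abs(rowMm - cy) <= half)
    cols <- which(abs(colMm - centres[k]) <= half)
    roi[rows, cols] <- k
  }
  new("ScenePhantom", sto2Map = sto2, thbMap = thbMap,
      muSPrimeMaps = musMaps, roiMasks = roi,
      tissueMask = tissue, pixelPitch = pixelPitch)
}

#' Per-pixel absorption map of a scene at one wavelength
#'
#' The forward chromophore model: converts the scene's StO2 and tHb
#' truth maps to \eqn{\mu_a} at the requested wavelength via [hbMuA()].
#' The exact algebraic inverse is [unmixSto2()].
#'
#' @param scene a [ScenePhantom-class]
#' @param wl wavelength, nm (must exist in the extinction table and in
#'   the scene's scattering maps)
#' @param table an [ExtinctionTable-class]
#' @param backgroundMuA background absorption offset, mm^-1
#' @return matrix of absorption coefficients, mm^-1
#' @export
sceneToMuA <- function(scene, wl, table = hbExtinction(),
                       backgroundMuA = 0.001) {
  stopifnot(is(scene, "ScenePhantom"))
  hbMuA(scene@sto2Map, scene@thbMap, wl, table, backgroundMuA)
}

.sceneMuSPrime <- function(scene, wl) {
  key <- as.character(wl)
  if (!key %in% names(scene@muSPrimeMaps))
    stop("scene has no scattering map at ", wl, " nm")
  scene@muSPrimeMaps[[key]]
}

# core renderer shared by scene and homogeneous-phantom paths:
# counts = (I0/2) * (R_DC + m * R_AC * cos(2 pi fx x + phi)) + noise
.renderCounts <- function(rdcMap, racMap, pattern, noise, seed) {
  nr <- nrow(rdcMap); nc <- ncol(rdcMap)
  xMm <- (seq_len(nc) - 1) * pattern@pixelPitch  # phase referenced to col 0
  carrier <- cos(2 * pi * pattern@fx * xMm + pattern@phase)
  ideal <- (pattern@dcLevel / 2) *
    (rdcMap + pattern@modulationDepth * racMap *
       matrix(carrier, nr, nc, byrow = TRUE))
  img <- ideal
  if (noise$shot || noise$readSd > 0) {
    if (is.null(seed)) stop("noisy rendering requires a seed")
    set.seed(as.integer(seed))
    if (noise$shot) img <- matrix(rpois(nr * nc, pmax(ideal, 0)), nr, nc)
    if (noise$readSd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise$readSd),
                                              nr, nc)
  }
  maxC <- 2^noise$bitDepth - 1
  sat <- img > maxC
  img <- pmin(pmax(img, 0), maxC)
  list(image = img, saturation = if (any(sat)) sat else NULL)
}

#' Render one structured-illumination camera frame of a scene
#'
#' Computes per-pixel diffuse reflectance at the pattern's two working
#' frequencies (0 and \code{fx}) from the scene's optical-property truth
#' via the diffusion forward model, modulates with the sinusoidal
#' pattern, and applies the camera noise model:
#' counts = (I0/2) (R_DC + m R_AC cos(2 pi fx x + phi)) + noise.
#'
#' @param scene a [ScenePhantom-class]
#' @param pattern a [PatternSpec-class] (its pixelPitch must match the
#'   scene's)
#' @param wl wavelength, nm
#' @param table extinction table for the chromophore forward model
#' @param noise a [noiseModel()] list
#' @param seed RNG seed (required when noise is on)
#' @param nTissue refractive index for the forward model
#' @param backgroundMuA background absorption offset, mm^-1
#' @return a [RawFrame-class]
#' @export
renderFrame <- function(scene, pattern, wl, table = hbExtinction(),
                        noise = noiseModel(), seed = NULL, nTissue = 1.4,
                        backgroundMuA = 0.001) {
  stopifnot(is(scene, "ScenePhantom"), is(pattern, "PatternSpec"))
  if (abs(pattern@pixelPitch - scene@pixelPitch) > 1e-9)
    stop("pattern pixelPitch does not match the scene")
  muAMap <- sceneToMuA(scene, wl, table, backgroundMuA)
  musMap <- .sceneMuSPrime(scene, wl)
  rdc <- diffusionRd(muAMap, musMap, 0, nTissue)
  rac <- if (pattern@fx > 0) diffusionRd(muAMap, musMap, pattern@fx, nTissue)
         else rdc
  out <- .renderCounts(rdc, rac, pattern, noise, seed)
  new("RawFrame", image = out$image, wavelength = as.numeric(wl),
      pattern = pattern, readNoiseSd = noise$readSd, shotNoise = noise$shot,
      bitDepth = noise$bitDepth, saturationMask = out$saturation,
      seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' Render a frame of a homogeneous medium (calibration-phantom style)
#'
#' @param op an [OpticalProperties-class]
#' @param pattern a [PatternSpec-class]
#' @param shape c(rows, cols)
#' @param wl wavelength, nm (metadata only; the props are given directly)
#' @inheritParams renderFrame
#' @return a [RawFrame-class]
#' @export
renderHomogeneousFrame <- function(op, pattern, shape, wl,
                                   noise = noiseModel(), seed = NULL,
                                   nTissue = 1.4) {
  stopifnot(is(op, "OpticalProperties"), is(pattern, "PatternSpec"))
  rdcV <- diffusionRd(op@muA, op@muSPrime, 0, nTissue)
  racV <- if (pattern@fx > 0) diffusionRd(op@muA, op@muSPrime, pattern@fx,
                                          nTissue) else rdcV
  rdc <- matrix(rdcV, shape[1], shape[2])
  rac <- matrix(racV, shape[1], shape[2])
  out <- .renderCounts(rdc, rac, pattern, noise, seed)
  new("RawFrame", image = out$image, wavelength = as.numeric(wl),
      pattern = pattern, readNoiseSd = noise$readSd, shotNoise = noise$shot,
      bitDepth = noise$bitDepth, saturationMask = out$saturation,
      seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' The instrument's calibration phantom
#'
#' Silicone reference phantom with known optical properties:
#' muA = 0.01, muS' = 1.1 mm^-1 at 665 nm and muA = 0.02,
#' muS' = 0.8 mm^-1 at 860 nm.
#'
#' @return a [CalibrationPhantom-class]
#' @export
calibrationPhantom <- function() {
  new("CalibrationPhantom",
      props = list("665" = OpticalProperties(0.01, 1.1),
                   "860" = OpticalProperties(0.02, 0.8)),
      description = "silicone reference phantom, known optical properties")
}

#' @rdname calibrationPhantom
#' @param phantom a [CalibrationPhantom-class]
#' @param wl wavelength, nm
#' @export
phantomProps <- function(phantom, wl) {
  key <- as.character(wl)
  if (!key %in% names(phantom@props))
    stop("calibration phantom has no properties at ", wl, " nm")
  phantom@props[[key]]
}

#' Render a calibration acquisition of the reference phantom
#'
#' One set of frames of the homogeneous reference phantom per requested
#' pattern, at one wavelength. Used to produce the reference
#' measurement that [calibrate()] divides by.
#'
#' @param phantom a [CalibrationPhantom-class]
#' @param patterns list of [PatternSpec-class]
#' @param wl wavelength, nm
#' @param shape c(rows, cols)
#' @inheritParams renderFrame
#' @return list of [RawFrame-class], one per pattern
#' @export
renderCalibrationSet <- function(phantom, patterns, wl, shape,
                                 noise = noiseModel(), seed = NULL,
                                 nTissue = 1.4) {
  op <- phantomProps(phantom, wl)
  lapply(seq_along(patterns), function(i)
    renderHomogeneousFrame(op, patterns[[i]], shape, wl, noise,
                           seed = if (is.null(seed)) NULL
                                  else as.integer(seed) + i,
                           nTissue = nTissue))
}

#' Simulate a bowel-ischaemia perfusion study table
#'
#' Generates one record per (animal, ROI, time point): StO2 as measured
#' on the scene's three perfusion zones plus noise, capillary lactate
#' rising over the ischaemic hour in proportion to the zone's normalised
#' target while systemic lactate stays near baseline, and a Park/Chiu
#' histology grade per zone. Default targets are the zone means the
#' generator is designed around: normalised lactate 4.804 (ischaemic),
#' 1.026 (marginal), 0.749 mmol/L (vascularised); Park/Chiu 4.5 / 1.583
#' / 0.667. The time course is linear from 0 at T0 to twice the target
#' at T60, so the T0-T60 average equals the target.
#'
#' @param nAnimals number of animals
#' @param timePoints minutes of ischaemia
#' @param roiSto2 zone StO2 truths (ischaemic, marginal, vascularised)
#' @param normLactateTargets per-zone mean normalised capillary lactate
#'   over the study, mmol/L
#' @param parkChiuMeans per-zone mean histology grade (0..8)
#' @param systemicBaseline mean systemic lactate, mmol/L
#' @param sto2Sd SD of StO2 measurement noise (absolute fraction);
#'   0 gives exact zone values
#' @param lactateSd SD of capillary lactate noise, mmol/L
#' @param seed RNG seed (required unless all noise SDs are 0)
#' @return data.frame with columns animal, roi, zone, timePoint,
#'   capillaryLactate, systemicLactate, parkChiu, sto2Measured
#' @export
simulateStudy <- function(nAnimals = 6,
                          timePoints = c(0, 15, 30, 45, 60),
                          roiSto2 = c(0.3008, 0.4567, 0.4808),
                          normLactateTargets = c(4.804, 1.026, 0.749),
                          parkChiuMeans = c(4.5, 1.583, 0.667),
                          systemicBaseline = 1.5,
                          sto2Sd = 0.07, lactateSd = 0.8, seed = NULL) {
  stopifnot(all(normLactateTargets > 0), systemicBaseline > 0)
  noisy <- sto2Sd > 0 || lactateSd > 0
  if (noisy) {
    if (is.null(seed)) stop("noisy simulation requires a seed")
    set.seed(as.integer(seed))
  }
  zoneOf <- c(1L, 2L, 3L, 2L, 3L)  # ROI -> zone (isch / marginal / vasc)
  grid <- expand.grid(animal = seq_len(nAnimals), roi = 1:5,
                      timePoint = timePoints)
  zone <- zoneOf[grid$roi]
  # systemic lactate: near-baseline, mild animal-level wobble
  sysNoise <- if (noisy) rnorm(nrow(grid), 0, 0.15) else 0
  systemic <- pmax(systemicBaseline + sysNoise, 0.2)
  # capillary = systemic + zone target * (2 t / 60), mean over T0..T60 = target
  tFactor <- 2 * grid$timePoint / max(timePoints)
  capNoise <- if (noisy) rnorm(nrow(grid), 0, lactateSd * tFactor / 2) else 0
  capillary <- pmax(systemic + normLactateTargets[zone] * tFactor + capNoise,
                    0.1)
  sto2Noise <- if (noisy) rnorm(nrow(grid), 0, sto2Sd) else 0
  sto2Meas <- pmin(pmax(roiSto2[zone] + sto2Noise, 0), 1)
  pcNoise <- if (noisy) rnorm(nrow(grid), 0, 0.8) else 0
  parkChiu <- pmin(pmax(as.integer(round(parkChiuMeans[zone] + pcNoise)), 0L),
                   8L)
  data.frame(animal = grid$animal, roi = grid$roi, zone = zone,
             timePoint = grid$timePoint,
             capillaryLactate = capillary, systemicLactate = systemic,
             parkChiu = parkChiu, sto2Measured = sto2Meas)
}
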