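#' @import methods
#' @importFrom stats rnorm rpois runif sd cor.test t.test ks.test qt pt quantile median approx mvfft fft pnorm setNames complete.cases
#' @importFrom utils read.csv write.csv
#' @importFrom tools md5sum
#' @useDynLib ssopOx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Optical properties of a homogeneous medium at one wavelength
#'
#' Holds the absorption coefficient \eqn{\mu_a} and the reduced scattering
#' coefficient \eqn{\mu_s'}, both in mm\eqn{^{-1}}.
#'
#' @slot muA absorption coefficient, mm^-1 (> 0)
#' @slot muSPrime reduced scattering coefficient, mm^-1 (> 0)
#' @export
setClass("OpticalProperties",
  representation(muA = "numeric", muSPrime = "numeric"))

setValidity("OpticalProperties", function(object) {
  if (length(object@muA) != 1L || length(object@muSPrime) != 1L)
    return("muA and muSPrime must be scalars")
  if (!is.finite(object@muA) || object@muA <= 0)
    return("muA must be finite and > 0")
  if (!is.finite(object@muSPrime) || object@muSPrime <= 0)
    return("muSPrime must be finite and > 0")
  TRUE
})

#' @param muA absorption coefficient, mm^-1
#' @param muSPrime reduced scattering coefficient, mm^-1
#' @rdname OpticalProperties-class
#' @export
OpticalProperties <- function(muA, muSPrime) {
  new("OpticalProperties", muA = as.numeric(muA), muSPrime = as.numeric(muSPrime))
}

#' Sinusoidal illumination pattern specification
#'
#' Describes one projected pattern: spatial frequency, phase, source
#' intensity, modulation depth and the pixel pitch that maps columns to
#' millimetres. The pattern varies along image columns (physical x =
#' column index * pixelPitch), phase referenced to column 0.
#'
#' @slot fx spatial frequency of the projected sinusoid, mm^-1 (>= 0)
#' @slot phase pattern phase, radians
#' @slot dcLevel source intensity I0, camera counts
#' @slot modulationDepth modulation depth m in [0, 1]
#' @slot pixelPitch mm per pixel (> 0); fx * pixelPitch must stay below
#'   the Nyquist limit 0.5
#' @export
setClass("PatternSpec",
  representation(fx = "numeric", phase = "numeric", dcLevel = "numeric",
                 modulationDepth = "numeric", pixelPitch = "numeric"))

setValidity("PatternSpec", function(object) {
  if (object@fx < 0) return("fx must be >= 0")
  if (object@modulationDepth < 0 || object@modulationDepth > 1)
    return("modulationDepth must lie in [0, 1]")
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  if (object@fx * object@pixelPitch >= 0.5)
    return("fx * pixelPitch violates the Nyquist limit (must be < 0.5)")
  TRUE
})

#' @param fx spatial frequency, mm^-1
#' @param phase phase in radians
#' @param dcLevel source intensity I0 in camera counts
#' @param modulationDepth modulation depth m in [0, 1]
#' @param pixelPitch mm per pixel
#' @rdname PatternSpec-class
#' @export
PatternSpec <- function(fx, phase = 0, dcLevel = 30000, modulationDepth = 0.9,
                        pixelPitch = 150 / 1024) {
  new("PatternSpec", fx = as.numeric(fx), phase = as.numeric(phase),
      dcLevel = as.numeric(dcLevel), modulationDepth = as.numeric(modulationDepth),
      pixelPitch = as.numeric(pixelPitch))
}

#' Forward-model lookup table for LUT inversion
#'
#' Maps a grid of (\eqn{\mu_a}, \eqn{\mu_s'}) pairs to calibrated diffuse
#' reflectance at the two working spatial frequencies (R_DC at fxPair[1],
#' R_AC at fxPair[2]).
#'
#' @slot muAGrid ascending absorption grid, mm^-1
#' @slot muSPrimeGrid ascending reduced-scattering grid, mm^-1
#' @slot fxPair the (fx_dc, fx_ac) working frequencies, mm^-1
#' @slot rDc matrix (length(muAGrid) x length(muSPrimeGrid)) of R_DC
#' @slot rAc matrix of R_AC, same shape
#' @slot nTissue refractive index used by the forward model
#' @slot engine "diffusion" or "monte-carlo" provenance tag
#' @slot seed creation seed (monte-carlo engine), or NULL
#' @export
setClass("ReflectanceLUT",
  representation(muAGrid = "numeric", muSPrimeGrid = "numeric",
                 fxPair = "numeric", rDc = "matrix", rAc = "matrix",
                 nTissue = "numeric", engine = "character",
                 seed = "integerOrNULL"))

setValidity("ReflectanceLUT", function(object) {
  if (is.unsorted(object@muAGrid, strictly = TRUE) ||
      is.unsorted(object@muSPrimeGrid, strictly = TRUE))
    return("grids must be strictly ascending")
  if (any(object@muAGrid <= 0) || any(object@muSPrimeGrid <= 0))
    return("grid values must be > 0")
  if (length(object@fxPair) != 2L) return("fxPair must have length 2")
  dm <- c(length(object@muAGrid), length(object@muSPrimeGrid))
  if (!identical(dim(object@rDc), dm) || !identical(dim(object@rAc), dm))
    return("table dimensions do not match the grids")
  if (any(object@rAc <= 0) || any(object@rAc > object@rDc + 1e-12) ||
      any(object@rDc > 1))
    return("every node must obey 0 < R_AC <= R_DC <= 1")
  if (any(apply(object@rDc, 2, diff) >= 0))
    return("R_DC must be strictly decreasing in muA at fixed muSPrime")
  if (!object@engine %in% c("diffusion", "monte-carlo"))
    return("engine must be 'diffusion' or 'monte-carlo'")
  TRUE
})

#' Radially binned diffuse reflectance from the Monte-Carlo oracle
#'
#' @slot rhoEdges radial bin edges, mm
#' @slot rPerArea diffuse reflectance per unit area in each bin, mm^-2
#'   (fraction of launched weight per mm^2)
#' @slot nPhotons photon count
#' @slot totalReflectedWeight total diffusely reflected fraction of the
#'   launched (post-specular) weight
#' @slot totalAbsorbedWeight absorbed fraction
#' @slot launchedWeight launched weight after specular loss (per photon = 1 - R_sp)
#' @slot overflowWeight reflected weight beyond the last bin edge
#' @slot seed RNG seed used
#' @export
setClass("RadialReflectanceProfile",
  representation(rhoEdges = "numeric", rPerArea = "numeric",
                 nPhotons = "integer", totalReflectedWeight = "numeric",
                 totalAbsorbedWeight = "numeric", launchedWeight = "numeric",
                 overflowWeight = "numeric", seed = "integer"))

setValidity("RadialReflectanceProfile", function(object) {
  if (length(object@rPerArea) != length(object@rhoEdges) - 1L)
    return("rPerArea must have one value per bin")
  if (any(object@rPerArea < 0)) return("bin values must be >= 0")
  bal <- abs(object@totalReflectedWeight + object@totalAbsorbedWeight -
             object@launchedWeight) / object@launchedWeight
  if (bal > 1e-6)
    return("weight not conserved: reflected + absorbed != launched")
  TRUE
})

#' Synthetic tissue scene: per-pixel chromophore truth plus ROI masks
#'
#' Ground-truth digital phantom for recovery tests: per-pixel StO2 and
#' total haemoglobin, per-wavelength reduced scattering, labelled ROI
#' masks (1..5, 0 = background) and the tissue mask.
#'
#' @slot sto2Map per-pixel oxygen saturation fraction in [0, 1]
#' @slot thbMap per-pixel total haemoglobin, uM (> 0)
#' @slot muSPrimeMaps named list (wavelength nm as name) of mu_s' maps, mm^-1
#' @slot roiMasks integer matrix, 0 background / 1..5 ROI labels
#' @slot tissueMask logical matrix, TRUE on the bowel segment
#' @slot pixelPitch mm per pixel
#' @export
setClass("ScenePhantom",
  representation(sto2Map = "matrix", thbMap = "matrix",
                 muSPrimeMaps = "list", roiMasks = "matrix",
                 tissueMask = "matrix", pixelPitch = "numeric"))

setValidity("ScenePhantom", function(object) {
  dm <- dim(object@sto2Map)
  same <- function(m) identical(dim(m), dm)
  if (!same(object@thbMap) || !same(object@roiMasks) || !same(object@tissueMask))
    return("all maps must share one shape")
  if (!all(vapply(object@muSPrimeMaps, same, logical(1))))
    return("muSPrimeMaps shapes differ from sto2Map")
  if (any(object@sto2Map < 0 | object@sto2Map > 1))
    return("sto2 must lie in [0, 1]")
  if (any(object@thbMap <= 0)) return("thb must be > 0")
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  TRUE
})

#' One raw camera frame under structured illumination
#'
#' @slot image 2-D matrix of camera counts
#' @slot wavelength nm
#' @slot pattern the [PatternSpec-class] used
#' @slot readNoiseSd Gaussian read-noise SD, counts
#' @slot shotNoise logical, Poisson shot noise applied
#' @slot bitDepth camera bit depth
#' @slot saturationMask logical matrix of clipped pixels, or NULL
#' @slot seed RNG seed (NULL for noiseless)
#' @export
setClass("RawFrame",
  representation(image = "matrix", wavelength = "numeric",
                 pattern = "PatternSpec", readNoiseSd = "numeric",
                 shotNoise = "logical", bitDepth = "numeric",
                 saturationMask = "matrixOrNULL", seed = "integerOrNULL"))

setValidity("RawFrame", function(object) {
  if (any(object@image < 0)) return("counts must be >= 0")
  if (any(object@image > 2^object@bitDepth - 1))
    return("counts exceed the bit-depth maximum")
  TRUE
})

#' Demodulated instrument-space modulation amplitude maps
#'
#' M_DC and M_AC in camera counts, before phantom calibration.
#'
#' @slot mDc planar (DC) amplitude map, counts
#' @slot mAc AC amplitude map at the pattern frequency, counts
#' @slot fxPair working frequencies (fx_dc, fx_ac), mm^-1
#' @slot edgeMargin pixels of reduced validity at the left/right field
#'   edges (0 for the 3-phase path)
#' @slot wavelength nm
#' @export
setClass("ModulationMaps",
  representation(mDc = "matrix", mAc = "matrix", fxPair = "numeric",
                 edgeMargin = "integer", wavelength = "numeric"))

setValidity("ModulationMaps", function(object) {
  if (!identical(dim(object@mDc), dim(object@mAc)))
    return("mDc and mAc shapes differ")
  if (any(object@mDc < 0) || any(object@mAc < 0))
    return("modulation amplitudes must be >= 0")
  if (object@edgeMargin < 0L) return("edgeMargin must be >= 0")
  TRUE
})

#' Calibration phantom with known per-wavelength optical properties
#'
#' @slot props named list: wavelength (nm, as character) ->
#'   [OpticalProperties-class]
#' @slot description free text
#' @export
setClass("CalibrationPhantom",
  representation(props = "list", description = "character"))

setValidity("CalibrationPhantom", function(object) {
  if (!all(vapply(object@props, is, logical(1), "OpticalProperties")))
    return("props must all be OpticalProperties")
  if (is.null(names(object@props)) || any(names(object@props) == ""))
    return("props must be named by wavelength (nm)")
  TRUE
})

#' Calibrated diffuse-reflectance maps
#'
#' Per-pixel R_DC and R_AC, dimensionless, after phantom calibration.
#' Values above 1 are flagged in the validity mask, never clipped.
#'
#' @slot rDc per-pixel R_DC
#' @slot rAc per-pixel R_AC
#' @slot wavelength nm
#' @slot fxPair working frequencies, mm^-1
#' @slot validityMask logical, TRUE = usable pixel
#' @export
setClass("DiffuseReflectanceMaps",
  representation(rDc = "matrix", rAc = "matrix", wavelength = "numeric",
                 fxPair = "numeric", validityMask = "matrix"))

setValidity("DiffuseReflectanceMaps", function(object) {
  if (!identical(dim(object@rDc), dim(object@rAc)) ||
      !identical(dim(object@rDc), dim(object@validityMask)))
    return("map shapes differ")
  if (any(object@rDc[object@validityMask] < 0, na.rm = TRUE) ||
      any(object@rAc[object@validityMask] < 0, na.rm = TRUE))
    return("valid reflectance values must be >= 0")
  TRUE
})

#' Per-pixel optical-property maps recovered by LUT inversion
#'
#' @slot muAMap absorption map, mm^-1
#' @slot muSPrimeMap reduced-scattering map, mm^-1
#' @slot wavelength nm
#' @slot outOfLutMask logical, TRUE = reflectance pair fell outside the
#'   LUT image set (value maps are NA there)
#' @export
setClass("OpticalPropertyMaps",
  representation(muAMap = "matrix", muSPrimeMap = "matrix",
                 wavelength = "numeric", outOfLutMask = "matrix"))

setValidity("OpticalPropertyMaps", function(object) {
  if (!identical(dim(object@muAMap), dim(object@muSPrimeMap)) ||
      !identical(dim(object@muAMap), dim(object@outOfLutMask)))
    return("map shapes differ")
  TRUE
})

#' Tissue oxygen saturation map with quality mask
#'
#' The pipeline's headline output: per-pixel StO2 (fraction) and total
#' haemoglobin (uM). The quality mask is the union of out-of-LUT,
#' negative-concentration and saturation flags; flagged pixels keep
#' their raw values in the stored maps (use [displaySto2()] for a
#' clamped copy).
#'
#' @slot sto2 per-pixel StO2 fraction
#' @slot thb per-pixel total haemoglobin, uM
#' @slot qualityMask logical, TRUE = flagged (unreliable) pixel
#' @export
setClass("StO2Map",
  representation(sto2 = "matrix", thb = "matrix", qualityMask = "matrix"))

setValidity("StO2Map", function(object) {
  if (!identical(dim(object@sto2), dim(object@thb)) ||
      !identical(dim(object@sto2), dim(object@qualityMask)))
    return("map shapes differ")
  ok <- !object@qualityMask
  s <- object@sto2[ok]
  if (any(s < -1e-9 | s > 1 + 1e-9, na.rm = TRUE))
    return("unflagged StO2 must lie in [0, 1]")
  if (any(object@thb[ok] <= 0, na.rm = TRUE))
    return("unflagged tHb must be > 0")
  TRUE
})

#' Haemoglobin molar extinction coefficient table
#'
#' Rows of (wavelength nm, eps_HbO2, eps_Hb) in cm^-1 (mol/L)^-1, with
#' provenance. Red wavelengths must have eps_Hb > eps_HbO2 and NIR
#' wavelengths the reverse, which guarantees an invertible 2x2 unmixing
#' system.
#'
#' @slot table data.frame with columns wavelength, epsHbO2, epsHb
#' @slot source citation string for the compilation
#' @slot version version tag
#' @export
setClass("ExtinctionTable",
  representation(table = "data.frame", source = "character",
                 version = "character"))

setValidity("ExtinctionTable", function(object) {
  tb <- object@table
  need <- c("wavelength", "epsHbO2", "epsHb")
  if (!all(need %in% names(tb))) return("missing required columns")
  if (any(tb$epsHbO2 <= 0) || any(tb$epsHb <= 0))
    return("extinction coefficients must be > 0")
  TRUE
})

#' Two-sample comparison result (Student's t with KS normality check)
#'
#' @slot groups labels
#' @slot means group means
#' @slot sds group SDs
#' @slot tStatistic pooled-variance t statistic
#' @slot df degrees of freedom
#' @slot pValue two-sided p
#' @slot ksStatistic per-group one-sample KS statistics vs a normal reference
#' @slot ksPass per-group logical, KS p > 0.05
#' @export
setClass("GroupComparison",
  representation(groups = "character", means = "numeric", sds = "numeric",
                 tStatistic = "numeric", df = "numeric", pValue = "numeric",
                 ksStatistic = "numeric", ksPass = "logical"))

setValidity("GroupComparison", function(object) {
  if (any(object@sds < 0)) return("SDs must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) return("p must lie in [0, 1]")
  TRUE
})

#' Correlation result
#'
#' @slot r correlation coefficient in [-1, 1]
#' @slot n pair count
#' @slot pValue two-sided p from the t transform with n - 2 df
#' @slot method "pearson" or "spearman"
#' @export
setClass("CorrelationResult",
  representation(r = "numeric", n = "integer", pValue = "numeric",
                 method = "character"))

setValidity("CorrelationResult", function(object) {
  if (abs(object@r) > 1 + 1e-12) return("r must lie in [-1, 1]")
  if (object@n < 3L) return("need n >= 3 pairs")
  TRUE
})
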