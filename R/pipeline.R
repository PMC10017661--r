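#' Simulate a complete acquisition (sample + calibration reference)
#'
#' Renders, at each wavelength, the frame set a real acquisition would
#' produce: in \code{"ssop"} mode one patterned frame; in \code{"sfdi"}
#' mode three planar and three patterned frames (phases 0, 2pi/3,
#' 4pi/3). The calibration reference is rendered the same way from the
#' homogeneous reference phantom.
#'
#' @param scene a [ScenePhantom-class]
#' @param fx working pattern frequency, mm^-1
#' @param mode "ssop" or "sfdi"
#' @param wavelengths nm, must exist in scene scattering maps, the
#'   extinction table and the calibration phantom
#' @param phantom a [CalibrationPhantom-class]
#' @param noise a [noiseModel()]
#' @param dcLevel source intensity I0, counts
#' @param modulationDepth pattern modulation depth m
#' @param seed base RNG seed (required with noise); per-frame seeds are
#'   derived deterministically from it
#' @param table extinction table for the chromophore forward model
#' @param nTissue refractive index
#' @param backgroundMuA background absorption, mm^-1
#' @return list with elements \code{sample} and \code{reference}, each a
#'   named-by-wavelength list; in ssop mode each entry is one
#'   [RawFrame-class], in sfdi mode a list \code{dc} + \code{ac} of
#'   three frames each
#' @export
simulateAcquisition <- function(scene, fx = 0.2, mode = c("ssop", "sfdi"),
                                wavelengths = c(665, 860),
                                phantom = calibrationPhantom(),
                                noise = noiseModel(), dcLevel = 30000,
                                modulationDepth = 0.9, seed = NULL,
                                table = hbExtinction(), nTissue = 1.4,
                                backgroundMuA = 0.001) {
  mode <- match.arg(mode)
  stopifnot(is(scene, "ScenePhantom"))
  pitch <- scene@pixelPitch
  shape <- dim(scene@sto2Map)
  mkPat <- function(f, ph) PatternSpec(f, ph, dcLevel, modulationDepth, pitch)
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  noisy <- noise$shot || noise$readSd > 0
  if (noisy && is.null(seed)) stop("noisy simulation requires a seed")
  sub <- 0L
  nextSeed <- function() {
    if (!noisy) return(NULL)
    sub <<- sub + 1L
    (as.integer(seed) * 131L + sub * 7919L) %% .Machine$integer.max
  }
  onePath <- function(renderOne) {
    if (mode == "ssop") {
      renderOne(mkPat(fx, 0), nextSeed())
    } else {
      list(dc = lapply(phases, function(p) renderOne(mkPat(0, p), nextSeed())),
           ac = lapply(phases, function(p) renderOne(mkPat(fx, p), nextSeed())))
    }
  }
  sample <- lapply(wavelengths, function(wl)
    onePath(function(pat, s) renderFrame(scene, pat, wl, table, noise, s,
                                         nTissue, backgroundMuA)))
  reference <- lapply(wavelengths, function(wl) {
    op <- phantomProps(phantom, wl)
    onePath(function(pat, s) renderHomogeneousFrame(op, pat, shape, wl,
                                                    noise, s, nTissue))
  })
  names(sample) <- names(reference) <- as.character(wavelengths)
  list(sample = sample, reference = reference, mode = mode, fx = fx)
}

.demodOne <- function(entry, mode, filterCfg) {
  if (mode == "ssop") ssopDemodulate(entry, filterCfg)
  else sfdiDemodulate(entry$dc, entry$ac)
}

#' Run the full processing pipeline on an acquisition
#'
#' Demodulate (SSOP single-frame or 3-phase SFDI) at each wavelength,
#' calibrate against the reference-phantom acquisition, invert through
#' the LUT to per-wavelength optical-property maps, and unmix the two
#' absorption maps to an StO2 map. Per-stage pixel-mask attrition counts
#' are returned for logging.
#'
#' @param acq an acquisition list as produced by [simulateAcquisition()]
#'   (elements \code{sample}, \code{reference}, \code{mode})
#' @param lut a [ReflectanceLUT-class]
#' @param phantom a [CalibrationPhantom-class]
#' @param filterCfg SSOP filter configuration, see [ssopFilterConfig()]
#' @param table extinction table for unmixing
#' @param backgroundMuA background absorption subtracted in unmixing
#' @param nTissue refractive index
#' @return list: \code{sto2} ([StO2Map-class]), \code{opticalProps}
#'   (named list of [OpticalPropertyMaps-class]), \code{reflectance}
#'   (named list of [DiffuseReflectanceMaps-class]), \code{attrition}
#'   (per-stage masked-pixel counts)
#' @export
processAcquisition <- function(acq, lut, phantom = calibrationPhantom(),
                               filterCfg = ssopFilterConfig(),
                               table = hbExtinction(),
                               backgroundMuA = 0.001, nTissue = 1.4) {
  wls <- names(acq$sample)
  if (!all(c("665", "860") %in% wls))
    stop("missing-channel error: acquisition must carry 665 and 860 nm")
  mode <- acq$mode
  perWl <- lapply(wls, function(wl) {
    ms <- .demodOne(acq$sample[[wl]], mode, filterCfg)
    mr <- .demodOne(acq$reference[[wl]], mode, filterCfg)
    refl <- calibrate(ms, mr, phantom, nTissue)
    props <- invertLut(refl, lut)
    list(refl = refl, props = props)
  })
  names(perWl) <- wls
  props665 <- perWl[["665"]]$props
  props860 <- perWl[["860"]]$props
  sto2 <- unmixSto2(props665, props860, table, backgroundMuA)
  attrition <- lapply(perWl, function(p) c(
    calibrationMasked = sum(!p$refl@validityMask),
    outOfLut = sum(p$props@outOfLutMask)))
  attrition$negativeConcentration <-
    sum(qualityMask(sto2)) - sum(props665@outOfLutMask | props860@outOfLutMask)
  list(sto2 = sto2,
       opticalProps = lapply(perWl, `[[`, "props"),
       reflectance = lapply(perWl, `[[`, "refl"),
       attrition = attrition)
}
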