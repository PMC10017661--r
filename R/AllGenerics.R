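# Accessor generics. Slot access stays internal; user code goes through
# these.

#' @rdname OpticalProperties-class
#' @param object,x an object
#' @export
setGeneric("muA", function(object) standardGeneric("muA"))
#' @rdname OpticalProperties-class
#' @export
setGeneric("muSPrime", function(object) standardGeneric("muSPrime"))
#' @export
#' @rdname ModulationMaps-class
setGeneric("mDc", function(object) standardGeneric("mDc"))
#' @export
#' @rdname ModulationMaps-class
setGeneric("mAc", function(object) standardGeneric("mAc"))
#' @export
#' @rdname ModulationMaps-class
setGeneric("edgeMargin", function(object) standardGeneric("edgeMargin"))
#' @export
#' @rdname ReflectanceLUT-class
setGeneric("fxPair", function(object) standardGeneric("fxPair"))
#' @export
#' @rdname DiffuseReflectanceMaps-class
setGeneric("rDc", function(object) standardGeneric("rDc"))
#' @export
#' @rdname DiffuseReflectanceMaps-class
setGeneric("rAc", function(object) standardGeneric("rAc"))
#' @export
#' @rdname DiffuseReflectanceMaps-class
setGeneric("validityMask", function(object) standardGeneric("validityMask"))
#' @export
#' @rdname StO2Map-class
setGeneric("sto2", function(object) standardGeneric("sto2"))
#' @export
#' @rdname StO2Map-class
setGeneric("thb", function(object) standardGeneric("thb"))
#' @export
#' @rdname StO2Map-class
setGeneric("qualityMask", function(object) standardGeneric("qualityMask"))
#' @export
#' @rdname ScenePhantom-class
setGeneric("roiMasks", function(object) standardGeneric("roiMasks"))
#' @export
#' @rdname ScenePhantom-class
setGeneric("sto2Map", function(object) standardGeneric("sto2Map"))
#' @export
#' @rdname ScenePhantom-class
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @export
#' @rdname RawFrame-class
setGeneric("frameImage", function(object) standardGeneric("frameImage"))
#' @export
#' @rdname OpticalPropertyMaps-class
setGeneric("outOfLutMask", function(object) standardGeneric("outOfLutMask"))

setMethod("muA", "OpticalProperties", function(object) object@muA)
setMethod("muSPrime", "OpticalProperties", function(object) object@muSPrime)
setMethod("muA", "OpticalPropertyMaps", function(object) object@muAMap)
setMethod("muSPrime", "OpticalPropertyMaps", function(object) object@muSPrimeMap)
setMethod("outOfLutMask", "OpticalPropertyMaps", function(object) object@outOfLutMask)
setMethod("mDc", "ModulationMaps", function(object) object@mDc)
setMethod("mAc", "ModulationMaps", function(object) object@mAc)
setMethod("edgeMargin", "ModulationMaps", function(object) object@edgeMargin)
setMethod("fxPair", "ReflectanceLUT", function(object) object@fxPair)
setMethod("fxPair", "ModulationMaps", function(object) object@fxPair)
setMethod("fxPair", "DiffuseReflectanceMaps", function(object) object@fxPair)
setMethod("rDc", "DiffuseReflectanceMaps", function(object) object@rDc)
setMethod("rAc", "DiffuseReflectanceMaps", function(object) object@rAc)
setMethod("validityMask", "DiffuseReflectanceMaps", function(object) object@validityMask)
setMethod("sto2", "StO2Map", function(object) object@sto2)
setMethod("thb", "StO2Map", function(object) object@thb)
setMethod("qualityMask", "StO2Map", function(object) object@qualityMask)
setMethod("roiMasks", "ScenePhantom", function(object) object@roiMasks)
setMethod("sto2Map", "ScenePhantom", function(object) object@sto2Map)
setMethod("pixelPitch", "ScenePhantom", function(object) object@pixelPitch)
setMethod("frameImage", "RawFrame", function(object) object@image)

#' Wavelength accessor
#' @param object an object carrying a wavelength
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))
setMethod("wavelength", "RawFrame", function(object) object@wavelength)
setMethod("wavelength", "ModulationMaps", function(object) object@wavelength)
setMethod("wavelength", "DiffuseReflectanceMaps", function(object) object@wavelength)
setMethod("wavelength", "OpticalPropertyMaps", function(object) object@wavelength)

setMethod("show", "OpticalProperties", function(object) {
  cat(sprintf("OpticalProperties: muA = %.4g mm^-1, muS' = %.4g mm^-1\n",
              object@muA, object@muSPrime))
})

setMethod("show", "ReflectanceLUT", function(object) {
  cat(sprintf(
    "ReflectanceLUT (%s engine)\n  grid: %d x %d (muA %.4g..%.4g, muS' %.4g..%.4g mm^-1)\n  fx pair: (%.3g, %.3g) mm^-1, n = %.3g\n",
    object@engine, length(object@muAGrid), length(object@muSPrimeGrid),
    min(object@muAGrid), max(object@muAGrid),
    min(object@muSPrimeGrid), max(object@muSPrimeGrid),
    object@fxPair[1], object@fxPair[2], object@nTissue))
})

setMethod("show", "ScenePhantom", function(object) {
  dm <- dim(object@sto2Map)
  cat(sprintf(
    "ScenePhantom: %d x %d px (%.1f x %.1f mm), %d ROIs, tissue fraction %.2f\n",
    dm[1], dm[2], dm[1] * object@pixelPitch, dm[2] * object@pixelPitch,
    length(setdiff(unique(as.vector(object@roiMasks)), 0L)),
    mean(object@tissueMask)))
})

setMethod("show", "RawFrame", function(object) {
  dm <- dim(object@image)
  cat(sprintf(
    "RawFrame: %d x %d px @ %g nm, fx = %.3g mm^-1, phase = %.3g rad\n",
    dm[1], dm[2], object@wavelength, object@pattern@fx, object@pattern@phase))
})

setMethod("show", "ModulationMaps", function(object) {
  dm <- dim(object@mDc)
  cat(sprintf(
    "ModulationMaps: %d x %d px @ %g nm, fx pair (%.3g, %.3g), edge margin %d px\n",
    dm[1], dm[2], object@wavelength, object@fxPair[1], object@fxPair[2],
    object@edgeMargin))
})

setMethod("show", "StO2Map", function(object) {
  ok <- !object@qualityMask
  cat(sprintf(
    "StO2Map: %d x %d px, %.1f%% valid; median StO2 (valid) = %.3f\n",
    nrow(object@sto2), ncol(object@sto2), 100 * mean(ok),
    if (any(ok)) median(object@sto2[ok]) else NA_real_))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison: %s (%.3f +/- %.3f) vs %s (%.3f +/- %.3f)\n  t = %.4f, df = %g, p = %.4g; KS pass: %s\n",
    object@groups[1], object@means[1], object@sds[1],
    object@groups[2], object@means[2], object@sds[2],
    object@tStatistic, object@df, object@pValue,
    paste(object@ksPass, collapse = ", ")))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult (%s): r = %.4f, n = %d, p = %.4g\n",
              object@method, object@r, object@n, object@pValue))
})
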