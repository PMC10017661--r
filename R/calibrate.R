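#' Phantom calibration of modulation maps to diffuse reflectance
#'
#' Converts instrument-space modulation amplitudes to calibrated diffuse
#' reflectance by ratioing against a measurement of the reference
#' phantom and multiplying by the forward-model prediction for the
#' phantom's known optical properties:
#' \deqn{R_{X,sample} = \frac{M_{X,sample}}{M_{X,reference}}
#'   R_{X,model}(\mu_a^{ph}, \mu_s'^{ph}, f_X), \quad X \in \{DC, AC\}.}
#' Source intensity and modulation depth cancel in the ratio. Reference
#' pixels below 1 percent of the field median modulation are masked for
#' division stability; reflectance values above 1 are flagged in the
#' validity mask, never clipped.
#'
#' @param sample [ModulationMaps-class] of the sample
#' @param reference [ModulationMaps-class] of the reference phantom,
#'   same wavelength and fx pair
#' @param phantom a [CalibrationPhantom-class] knowing the reference's
#'   optical properties at this wavelength
#' @param nTissue refractive index for the forward model
#' @param referenceFloor mask reference pixels whose modulation falls
#'   below this fraction of the field median
#' @return a [DiffuseReflectanceMaps-class]
#' @export
calibrate <- function(sample, reference, phantom, nTissue = 1.4,
                      referenceFloor = 0.01) {
  stopifnot(is(sample, "ModulationMaps"), is(reference, "ModulationMaps"),
            is(phantom, "CalibrationPhantom"))
  if (!identical(dim(sample@mDc), dim(reference@mDc)))
    stop("sample and reference shapes differ")
  if (max(abs(sample@fxPair - reference@fxPair)) > 1e-9)
    stop("sample and reference fx pairs differ")
  if (sample@wavelength != reference@wavelength)
    stop("sample and reference wavelengths differ")
  op <- phantomProps(phantom, sample@wavelength)  # errors if absent
  fxp <- sample@fxPair
  rModel <- c(diffusionRd(op@muA, op@muSPrime, fxp[1], nTissue),
              diffusionRd(op@muA, op@muSPrime, fxp[2], nTissue))
  floorDc <- referenceFloor * median(reference@mDc)
  floorAc <- referenceFloor * median(reference@mAc)
  badRef <- reference@mDc <= floorDc | reference@mAc <= floorAc
  if (any(badRef))
    warning(sum(badRef), " reference pixels below the calibration floor; masked")
  rdc <- sample@mDc / reference@mDc * rModel[1]
  rac <- sample@mAc / reference@mAc * rModel[2]
  valid <- !badRef & is.finite(rdc) & is.finite(rac) &
    rdc >= 0 & rac >= 0 & rdc <= 1 & rac <= 1
  rdc[badRef] <- NA_real_
  rac[badRef] <- NA_real_
  margin <- max(sample@edgeMargin, reference@edgeMargin)
  if (margin > 0) {
    nc <- ncol(valid)
    m <- min(margin, floor(nc / 2))
    valid[, c(seq_len(m), (nc - m + 1):nc)] <- FALSE
  }
  new("DiffuseReflectanceMaps", rDc = rdc, rAc = rac,
      wavelength = sample@wavelength, fxPair = fxp, validityMask = valid)
}

# bilinear interpolation of both LUT tables and their gradients at
# fractional grid coordinates (ia, is) in [1, nA] x [1, nS]
.lutBilinear <- function(lut, ia, is) {
  nA <- length(lut@muAGrid); nS <- length(lut@muSPrimeGrid)
  i0 <- pmin(pmax(floor(ia), 1L), nA - 1L)
  j0 <- pmin(pmax(floor(is), 1L), nS - 1L)
  fa <- ia - i0; fs <- is - j0
  idx <- function(i, j) cbind(i, j)
  g <- function(tab) {
    v00 <- tab[idx(i0, j0)]; v10 <- tab[idx(i0 + 1L, j0)]
    v01 <- tab[idx(i0, j0 + 1L)]; v11 <- tab[idx(i0 + 1L, j0 + 1L)]
    val <- v00 * (1 - fa) * (1 - fs) + v10 * fa * (1 - fs) +
      v01 * (1 - fa) * fs + v11 * fa * fs
    dA <- (v10 - v00) * (1 - fs) + (v11 - v01) * fs   # d/d ia
    dS <- (v01 - v00) * (1 - fa) + (v11 - v10) * fa   # d/d is
    list(val = val, dA = dA, dS = dS)
  }
  list(dc = g(lut@rDc), ac = g(lut@rAc))
}

#' Per-pixel LUT inversion of diffuse reflectance to optical properties
#'
#' Finds, for every valid pixel, the (\eqn{\mu_a}, \eqn{\mu_s'}) whose
#' forward-model reflectance pair best matches the measured
#' (R_DC, R_AC), using a Euclidean metric normalised by the table's
#' median reflectance in each channel. Search is nearest grid node
#' (two-level coarse-to-fine) followed by damped bilinear Newton
#' refinement on the local cell. Reflectance pairs outside the LUT's
#' image set land in the out-of-LUT mask; values are never extrapolated.
#' Deterministic: identical inputs give identical maps.
#'
#' @param maps a [DiffuseReflectanceMaps-class]
#' @param lut a [ReflectanceLUT-class] with a matching fx pair
#' @return an [OpticalPropertyMaps-class]
#' @export
invertLut <- function(maps, lut) {
  stopifnot(is(maps, "DiffuseReflectanceMaps"), is(lut, "ReflectanceLUT"))
  if (max(abs(maps@fxPair - lut@fxPair)) > 1e-9)
    stop("LUT fx pair does not match the reflectance maps")
  valid <- maps@validityMask & is.finite(maps@rDc) & is.finite(maps@rAc)
  if (!any(valid)) stop("no valid pixels to invert")
  nA <- length(lut@muAGrid); nS <- length(lut@muSPrimeGrid)
  if (nA < 2L || nS < 2L) stop("degenerate LUT: need at least a 2x2 grid")
  rdc <- maps@rDc[valid]; rac <- maps@rAc[valid]
  wDc <- 1 / median(lut@rDc); wAc <- 1 / median(lut@rAc)
  # level 1: coarse nearest node
  strideA <- max(1L, floor(nA / 12)); strideS <- max(1L, floor(nS / 12))
  ci <- unique(c(seq(1L, nA, strideA), nA))
  cj <- unique(c(seq(1L, nS, strideS), nS))
  coarse <- as.matrix(expand.grid(i = ci, j = cj))
  d <- (outer(rdc, lut@rDc[coarse], "-") * wDc)^2 +
       (outer(rac, lut@rAc[coarse], "-") * wAc)^2
  best <- coarse[max.col(-d, ties.method = "first"), , drop = FALSE]
  # level 2: refine nearest node within the coarse stride neighbourhood
  iBest <- best[, 1]; jBest <- best[, 2]
  for (di in -strideA:strideA) for (dj in -strideS:strideS) {
    if (di == 0L && dj == 0L) next
    ii <- pmin(pmax(best[, 1] + di, 1L), nA)
    jj <- pmin(pmax(best[, 2] + dj, 1L), nS)
    dNew <- ((rdc - lut@rDc[cbind(ii, jj)]) * wDc)^2 +
            ((rac - lut@rAc[cbind(ii, jj)]) * wAc)^2
    dOld <- ((rdc - lut@rDc[cbind(iBest, jBest)]) * wDc)^2 +
            ((rac - lut@rAc[cbind(iBest, jBest)]) * wAc)^2
    upd <- dNew < dOld
    iBest[upd] <- ii[upd]; jBest[upd] <- jj[upd]
  }
  # Newton refinement on the bilinear surface in grid coordinates
  ia <- as.numeric(iBest); js <- as.numeric(jBest)
  for (it in 1:4) {
    bl <- .lutBilinear(lut, ia, js)
    fDc <- bl$dc$val - rdc
    fAc <- bl$ac$val - rac
    j11 <- bl$dc$dA; j12 <- bl$dc$dS
    j21 <- bl$ac$dA; j22 <- bl$ac$dS
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-30] <- NA_real_
    dIa <- (j22 * fDc - j12 * fAc) / det
    dIs <- (-j21 * fDc + j11 * fAc) / det
    # damp to at most one cell per iteration
    dIa <- pmin(pmax(dIa, -1), 1); dIs <- pmin(pmax(dIs, -1), 1)
    dIa[is.na(dIa)] <- 0; dIs[is.na(dIs)] <- 0
    ia <- pmin(pmax(ia - dIa, 1), nA)
    js <- pmin(pmax(js - dIs, 1), nS)
  }
  # residual check: pixels whose best match stays poor are outside the
  # LUT's image set (never extrapolate)
  bl <- .lutBilinear(lut, ia, js)
  resRel <- sqrt(((bl$dc$val - rdc) * wDc)^2 + ((bl$ac$val - rac) * wAc)^2)
  tol <- 0.02 * sqrt(2)
  atEdge <- ia <= 1 + 1e-9 | ia >= nA - 1e-9 | js <= 1 + 1e-9 | js >= nS - 1e-9
  outside <- resRel > tol & atEdge
  outside <- outside | resRel > 10 * tol
  # map grid coordinates back to physical values (muA grid is log-spaced)
  muAofIa <- function(v) exp(approx(seq_len(nA), log(lut@muAGrid), v,
                                    rule = 2)$y)
  muSofIs <- function(v) approx(seq_len(nS), lut@muSPrimeGrid, v, rule = 2)$y
  muAV <- muAofIa(ia); muSV <- muSofIs(js)
  muAV[outside] <- NA_real_; muSV[outside] <- NA_real_
  shape <- dim(maps@rDc)
  muAMap <- matrix(NA_real_, shape[1], shape[2])
  muSMap <- matrix(NA_real_, shape[1], shape[2])
  oMask <- matrix(TRUE, shape[1], shape[2])  # invalid input counts as out
  muAMap[valid] <- muAV
  muSMap[valid] <- muSV
  oMask[valid] <- outside
  new("OpticalPropertyMaps", muAMap = muAMap, muSPrimeMap = muSMap,
      wavelength = maps@wavelength, outOfLutMask = oMask)
}
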