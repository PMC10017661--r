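#' Three-phase SFDI demodulation
#'
#' The reference demodulation path. From three planar frames (fx = 0)
#' and three patterned frames at phases 0, 2pi/3, 4pi/3:
#' \deqn{M_{DC} = (I_1 + I_2 + I_3)/3}
#' over the planar set and
#' \deqn{M_{AC} = \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2}}
#' over the patterned set. Exact (machine precision) on noiseless input;
#' no edge margin.
#'
#' @param framesDc list of three [RawFrame-class] at fx = 0
#' @param framesAc list of three [RawFrame-class] at the working fx,
#'   phases 0, 2pi/3, 4pi/3 (any order; spacing is checked)
#' @return a [ModulationMaps-class]
#' @export
sfdiDemodulate <- function(framesDc, framesAc) {
  if (length(framesDc) != 3L || length(framesAc) != 3L)
    stop("three planar and three patterned frames are required")
  all6 <- c(framesDc, framesAc)
  dims <- lapply(all6, function(f) dim(f@image))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("frame shapes differ")
  wls <- vapply(all6, function(f) f@wavelength, numeric(1))
  if (length(unique(wls)) != 1L) stop("frame wavelengths differ")
  if (any(vapply(framesDc, function(f) f@pattern@fx, numeric(1)) != 0))
    stop("planar frames must have fx = 0")
  fxs <- vapply(framesAc, function(f) f@pattern@fx, numeric(1))
  if (length(unique(fxs)) != 1L || fxs[1] <= 0)
    stop("patterned frames must share one fx > 0")
  phases <- sort(vapply(framesAc, function(f) f@pattern@phase, numeric(1)) %%
                   (2 * pi))
  if (max(abs(phases - c(0, 2 * pi / 3, 4 * pi / 3))) > 1e-9)
    stop("patterned phases must be 0, 2pi/3, 4pi/3")
  mDc <- (framesDc[[1]]@image + framesDc[[2]]@image + framesDc[[3]]@image) / 3
  i1 <- framesAc[[1]]@image; i2 <- framesAc[[2]]@image; i3 <- framesAc[[3]]@image
  mAc <- sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
  new("ModulationMaps", mDc = mDc, mAc = mAc,
      fxPair = c(0, fxs[1]), edgeMargin = 0L, wavelength = wls[1])
}

#' SSOP filter configuration
#'
#' Fourier-domain filter shapes for single-frame demodulation. Cutoffs
#' are fractions of the pattern frequency fx; the window tapers the
#' filter skirts to limit ringing.
#'
#' @param dcCutoff low-pass cutoff for the DC channel, as a fraction of fx
#' @param acHalfWidth half-width of the band about +/- fx, fraction of fx
#' @param window taper family ("blackman" or "hann")
#' @param padMode edge padding before the transform ("mirror")
#' @export
ssopFilterConfig <- function(dcCutoff = 0.5, acHalfWidth = 0.5,
                             window = c("blackman", "hann"),
                             padMode = "mirror") {
  window <- match.arg(window)
  if (dcCutoff <= 0 || acHalfWidth <= 0) stop("cutoffs must be > 0")
  if (dcCutoff + acHalfWidth > 1 + 1e-12)
    stop("configuration error: DC and AC filter bands overlap")
  list(dcCutoff = dcCutoff, acHalfWidth = acHalfWidth,
       window = window, padMode = padMode)
}

# smooth band response: 1 inside the flat half of the band, tapering to 0
# at the band edge with a raised-cosine / blackman profile
.bandResponse <- function(f, centre, halfWidth, window) {
  u <- pmin(abs(f - centre) / halfWidth, 1)
  if (window == "blackman") {
    # blackman-shaped skirt from 1 at u=0 to ~0 at u=1
    0.42 + 0.5 * cos(pi * u) + 0.08 * cos(2 * pi * u)
  } else {
    0.5 * (1 + cos(pi * u))
  }
}

#' Single-snapshot (SSOP) Fourier-filter demodulation
#'
#' Extracts both modulation maps from one patterned frame. Each image
#' row (the direction the pattern varies along) is mirror-padded and
#' transformed; a windowed low-pass about 0 yields M_DC, and a windowed
#' band about the pattern frequency, kept single-sided so its inverse
#' transform is the analytic signal, yields the AC envelope
#' M_AC = 2 |analytic|. The returned edge margin is the effective filter
#' support: artefacts from field edges and sharp steps are confined
#' within it.
#'
#' @param frame a [RawFrame-class] at fx > 0
#' @param filterCfg a [ssopFilterConfig()]
#' @return a [ModulationMaps-class] with a nonzero \code{edgeMargin}
#' @export
ssopDemodulate <- function(frame, filterCfg = ssopFilterConfig()) {
  stopifnot(is(frame, "RawFrame"))
  fx <- frame@pattern@fx
  pitch <- frame@pattern@pixelPitch
  if (fx <= 0) stop("SSOP demodulation needs a patterned frame (fx > 0)")
  pxPerPeriod <- 1 / (fx * pitch)
  if (pxPerPeriod < 8)
    stop("fx not resolvable: fewer than 8 pixels per pattern period")
  img <- frame@image
  nr <- nrow(img); nc <- ncol(img)
  pad <- min(nc, ceiling(2 * pxPerPeriod))  # two periods of mirror padding
  # mirror-pad along columns
  left <- img[, pad:1, drop = FALSE]
  right <- img[, nc:(nc - pad + 1), drop = FALSE]
  ext <- cbind(left, img, right)
  n <- ncol(ext)
  freqs <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / (n * pitch)
  hDc <- .bandResponse(freqs, 0, filterCfg$dcCutoff * fx, filterCfg$window)
  hAcPos <- .bandResponse(freqs, fx, filterCfg$acHalfWidth * fx,
                          filterCfg$window)
  hAcPos[freqs < 0] <- 0  # single-sided: inverse transform = analytic signal
  # FFT along rows: operate on the transposed matrix so mvfft works per row
  spec <- stats::mvfft(t(ext))
  mDcExt <- Re(stats::mvfft(spec * hDc, inverse = TRUE)) / n
  acExt <- stats::mvfft(spec * hAcPos, inverse = TRUE) / n
  mAcExt <- 2 * Mod(acExt)
  sel <- (pad + 1):(pad + nc)
  mDc <- t(mDcExt)[, sel, drop = FALSE]
  mAc <- t(mAcExt)[, sel, drop = FALSE]
  mDc[mDc < 0] <- 0
  new("ModulationMaps", mDc = mDc, mAc = mAc,
      fxPair = c(0, fx), edgeMargin = as.integer(pad),
      wavelength = frame@wavelength)
}
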