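#' Shipped haemoglobin extinction table
#'
#' Molar extinction coefficients of oxy- and deoxy-haemoglobin at the
#' instrument's two working wavelengths (665 and 860 nm), in
#' cm^-1 (mol/L)^-1, from the OMLC (Prahl) haemoglobin absorption
#' compilation. All package defaults and tests reference this shipped
#' table, so unmixing results are self-consistent with it.
#'
#' @return an [ExtinctionTable-class]
#' @export
hbExtinction <- function() {
  path <- system.file("extdata", "hb_extinction.csv", package = "ssopOx",
                      mustWork = TRUE)
  new("ExtinctionTable", table = read.csv(path),
      source = "OMLC haemoglobin extinction compilation (S. Prahl)",
      version = "1")
}

#' @rdname hbExtinction
#' @param table an [ExtinctionTable-class]
#' @param wl wavelength, nm
#' @export
extinctionAt <- function(table, wl) {
  tb <- table@table
  row <- tb[tb$wavelength == wl, ]
  if (nrow(row) != 1L)
    stop("wavelength ", wl, " nm not present in the extinction table")
  c(epsHbO2 = row$epsHbO2, epsHb = row$epsHb)
}

# Single place where extinction units meet concentration and length units:
# eps [cm^-1 / (mol/L)], concentration [uM], muA [mm^-1].
# muA[mm^-1] = ln(10) * eps * (c * 1e-6 M) / 10.
.MUA_PER_EPS_UM <- log(10) * 1e-7

#' Haemoglobin absorption from StO2 and total haemoglobin
#'
#' The forward direction of the oximetry pair:
#' \deqn{\mu_a(\lambda) = \ln 10\,[\epsilon_{HbO2}(\lambda)\,StO_2 +
#'   \epsilon_{Hb}(\lambda)(1 - StO_2)]\,tHb + \mu_{a,bg}}
#' with unit conversion handled internally (eps in cm^-1/M, tHb in uM,
#' muA in mm^-1).
#'
#' @param sto2 StO2 fraction (scalar, vector or matrix)
#' @param thbUM total haemoglobin, uM
#' @param wl wavelength, nm
#' @param table an [ExtinctionTable-class]
#' @param backgroundMuA non-haemoglobin background absorption, mm^-1
#' @return absorption coefficient map/value, mm^-1
#' @export
hbMuA <- function(sto2, thbUM, wl, table = hbExtinction(),
                  backgroundMuA = 0.001) {
  eps <- extinctionAt(table, wl)
  (eps[["epsHbO2"]] * sto2 + eps[["epsHb"]] * (1 - sto2)) *
    thbUM * .MUA_PER_EPS_UM + backgroundMuA
}

#' Two-wavelength haemoglobin unmixing to an StO2 map
#'
#' Solves, per pixel, the 2x2 linear system
#' \deqn{\mu_a(\lambda_i) - \mu_{a,bg} = \ln 10\,[\epsilon_{HbO2}(\lambda_i)
#'   c_{HbO2} + \epsilon_{Hb}(\lambda_i) c_{Hb}]}
#' for the oxy- and deoxy-haemoglobin concentrations and reports
#' \eqn{StO_2 = c_{HbO2}/(c_{HbO2}+c_{Hb})} and \eqn{tHb} (uM). Pixels
#' with a negative concentration, or flagged out-of-LUT at either
#' wavelength, enter the quality mask; their raw values are kept in the
#' stored maps (use [displaySto2()] for a clamped display copy).
#'
#' @param muA665 absorption map at 665 nm, mm^-1 — a matrix or an
#'   [OpticalPropertyMaps-class] (whose out-of-LUT mask is honoured)
#' @param muA860 absorption map at 860 nm, likewise
#' @param table an [ExtinctionTable-class] containing both wavelengths
#' @param backgroundMuA background absorption subtracted before
#'   unmixing, mm^-1 (must match the value used when synthesising or
#'   interpreting the scene)
#' @return an [StO2Map-class]
#' @export
unmixSto2 <- function(muA665, muA860, table = hbExtinction(),
                      backgroundMuA = 0.001) {
  badIn <- NULL
  asMap <- function(m) {
    if (is(m, "OpticalPropertyMaps")) {
      badIn <<- if (is.null(badIn)) m@outOfLutMask else badIn | m@outOfLutMask
      m@muAMap
    } else m
  }
  a665 <- asMap(muA665)
  a860 <- asMap(muA860)
  if (!identical(dim(a665), dim(a860)))
    stop("absorption maps must be co-registered (same shape)")
  e1 <- extinctionAt(table, 665)
  e2 <- extinctionAt(table, 860)
  # muA = k * (eO2*cO2 + eHb*cHb) + bg, k = .MUA_PER_EPS_UM, c in uM
  E <- rbind(c(e1[["epsHbO2"]], e1[["epsHb"]]),
             c(e2[["epsHbO2"]], e2[["epsHb"]]))
  det <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  if (abs(det) < .Machine$double.eps * max(abs(E))^2)
    stop("singular extinction matrix: wavelengths do not separate Hb species")
  b1 <- (a665 - backgroundMuA) / .MUA_PER_EPS_UM
  b2 <- (a860 - backgroundMuA) / .MUA_PER_EPS_UM
  cO2 <- (E[2, 2] * b1 - E[1, 2] * b2) / det
  cHb <- (-E[2, 1] * b1 + E[1, 1] * b2) / det
  thb <- cO2 + cHb
  sto2 <- cO2 / thb
  neg <- (cO2 < 0) | (cHb < 0) | !is.finite(sto2)
  bad <- neg | (if (is.null(badIn)) FALSE else badIn) |
    is.na(a665) | is.na(a860)
  dim(bad) <- dim(a665)
  new("StO2Map", sto2 = sto2, thb = thb, qualityMask = bad)
}

#' Display copy of an StO2 map, clamped to [0, 1]
#'
#' The stored map keeps raw (possibly nonphysical) values for flagged
#' pixels; this returns a copy clamped to [0, 1] with flagged pixels set
#' to NA, suitable for rendering.
#'
#' @param x an [StO2Map-class]
#' @export
displaySto2 <- function(x) {
  stopifnot(is(x, "StO2Map"))
  out <- pmin(pmax(x@sto2, 0), 1)
  out[x@qualityMask] <- NA_real_
  out
}

#' Per-ROI summary of an StO2 map
#'
#' Mean and SD over quality-valid pixels of each labelled ROI. An ROI
#' whose pixels are all flagged is reported with \code{flagged = TRUE}
#' rather than silently dropped.
#'
#' @param x an [StO2Map-class]
#' @param masks integer ROI label matrix (0 = background), e.g.
#'   \code{roiMasks(scene)}
#' @return data.frame with columns roi, nPixels, nValid, mean, sd, flagged
#' @export
roiSummary <- function(x, masks) {
  stopifnot(is(x, "StO2Map"))
  if (!identical(dim(masks), dim(x@sto2)))
    stop("ROI masks do not match the map shape")
  labels <- sort(setdiff(unique(as.vector(masks)), 0L))
  ok <- !x@qualityMask
  rows <- lapply(labels, function(l) {
    inRoi <- masks == l
    v <- x@sto2[inRoi & ok]
    data.frame(roi = l, nPixels = sum(inRoi), nValid = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               flagged = length(v) == 0L)
  })
  do.call(rbind, rows)
}
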