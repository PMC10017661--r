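#' Diffusion-approximation diffuse reflectance in the spatial frequency domain
#'
#' Closed-form diffuse reflectance of a semi-infinite homogeneous medium
#' under sinusoidal illumination at spatial frequency \code{fx}:
#' \deqn{R_d(f_x) = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)}}
#' with \eqn{\mu_{tr} = \mu_a + \mu_s'}, \eqn{a' = \mu_s'/\mu_{tr}},
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a \mu_{tr}}},
#' \eqn{\mu_{eff}' = \sqrt{\mu_{eff}^2 + (2\pi f_x)^2}} and the
#' internal-reflection parameter \eqn{A = (1 - R_{eff}) / (2 (1 + R_{eff}))},
#' \eqn{R_{eff} \approx 0.0636 n + 0.668 + 0.710/n - 1.440/n^2}.
#'
#' All arguments are vectorised and recycled.
#'
#' @param muA absorption coefficient, mm^-1 (> 0); an
#'   [OpticalProperties-class] object may be given instead, in which case
#'   \code{muSPrime} is taken from it and the second argument is the
#'   spatial frequency
#' @param muSPrime reduced scattering coefficient, mm^-1 (> 0)
#' @param fx spatial frequency, mm^-1 (>= 0)
#' @param nTissue tissue refractive index (default 1.4)
#' @return diffuse reflectance in (0, 1], dimensionless; strictly
#'   decreasing in both \code{muA} and \code{fx}
#' @examples
#' diffusionRd(0.01, 1.1, fx = 0)      # calibration phantom, planar
#' diffusionRd(0.01, 1.1, fx = 0.2)    # at the working AC frequency
#' @export
diffusionRd <- function(muA, muSPrime, fx = 0, nTissue = 1.4) {
  if (is(muA, "OpticalProperties")) {
    op <- muA
    if (!missing(fx) || missing(muSPrime)) {
      # called as diffusionRd(op, fx = ...) or diffusionRd(op)
      if (missing(muSPrime)) muSPrime <- op@muSPrime
      else stop("give either an OpticalProperties object or two numerics")
    } else {
      fx <- muSPrime  # positional: diffusionRd(op, fx)
      muSPrime <- op@muSPrime
    }
    muA <- op@muA
  }
  if (!is.numeric(muA) || !is.numeric(muSPrime) || !is.numeric(fx))
    stop("muA, muSPrime and fx must be numeric")
  if (any(!is.finite(muA)) || any(!is.finite(muSPrime)) || any(!is.finite(fx)))
    stop("non-finite optical properties or frequency")
  if (any(muA <= 0) || any(muSPrime <= 0))
    stop("muA and muSPrime must be > 0")
  if (any(fx < 0)) stop("fx must be >= 0")
  rEff <- 0.0636 * nTissue + 0.668 + 0.710 / nTissue - 1.440 / nTissue^2
  A <- (1 - rEff) / (2 * (1 + rEff))
  muTr <- muA + muSPrime
  aPrime <- muSPrime / muTr
  muEff <- sqrt(3 * muA * muTr)
  muEffP <- sqrt(muEff^2 + (2 * pi * fx)^2)
  x <- muEffP / muTr
  3 * A * aPrime / ((x + 1) * (x + 3 * A))
}

#' Monte-Carlo radial diffuse reflectance of a pencil beam
#'
#' Photon-packet simulation on a semi-infinite homogeneous medium:
#' Henyey-Greenstein scattering with anisotropy \code{g} (so
#' \eqn{\mu_s = \mu_s'/(1-g)}), implicit-capture absorption weighting,
#' unpolarised Fresnel treatment of the refractive-index-mismatched top
#' surface, and deterministic termination below a weight floor with the
#' residual tallied as absorbed, so launched weight is conserved exactly.
#' Reflected weight is binned radially; see [hankelRd()] to move to the
#' spatial frequency domain.
#'
#' @param muA absorption coefficient, mm^-1
#' @param muSPrime reduced scattering coefficient, mm^-1
#' @param nTissue refractive index of the medium (outside medium = 1)
#' @param g Henyey-Greenstein anisotropy factor
#' @param nPhotons number of photon packets (>= 1000)
#' @param seed RNG seed (required: every stochastic operation here takes
#'   an explicit seed)
#' @param dRho radial bin width, mm
#' @param maxRho outermost bin edge, mm (weight beyond it is tracked as
#'   overflow and still counted in the totals)
#' @param weightFloor termination threshold on packet weight
#' @return a [RadialReflectanceProfile-class]
#' @export
mcRd <- function(muA, muSPrime, nTissue = 1.4, g = 0.9,
                 nPhotons = 1e5, seed, dRho = 0.1, maxRho = 30,
                 weightFloor = 1e-4) {
  if (missing(seed)) stop("mcRd requires an explicit seed")
  if (!is.finite(muA) || muA <= 0 || !is.finite(muSPrime) || muSPrime <= 0)
    stop("muA and muSPrime must be finite and > 0")
  nPhotons <- as.integer(nPhotons)
  if (nPhotons < 1000L) stop("nPhotons must be >= 1000")
  nBins <- as.integer(ceiling(maxRho / dRho))
  set.seed(as.integer(seed))
  res <- mc_semiinf_cpp(muA, muSPrime, g, nTissue, nPhotons,
                        dRho, nBins, weightFloor)
  edges <- seq(0, by = dRho, length.out = nBins + 1L)
  areas <- pi * (edges[-1]^2 - edges[-(nBins + 1L)]^2)
  # rPerArea is normalised per unit *launched* (post-specular) weight so
  # the Hankel transform matches the diffusion R_d convention, whose
  # mu_a -> 0 limit is 1 for the light that entered the medium
  new("RadialReflectanceProfile",
      rhoEdges = edges,
      rPerArea = res$bin_weights / (areas * res$launched_weight),
      nPhotons = nPhotons,
      totalReflectedWeight = res$reflected_weight / nPhotons,
      totalAbsorbedWeight = res$absorbed_weight / nPhotons,
      launchedWeight = res$launched_weight / nPhotons,
      overflowWeight = res$overflow_weight / nPhotons,
      seed = as.integer(seed))
}

#' Order-0 Hankel transform of a radial reflectance profile
#'
#' Converts the radially binned Monte-Carlo output to the spatial
#' frequency domain:
#' \deqn{R_d(f_x) = 2\pi \int_0^\infty R(\rho) J_0(2\pi f_x \rho)\, \rho\, d\rho,}
#' evaluated by the trapezoid rule over bin centres. At \code{fx = 0}
#' this reduces to the total diffuse reflected fraction (up to binning
#' error). If the requested frequency is too high for the radial binning
#' to resolve the Bessel oscillations, the result carries attribute
#' \code{unresolved = TRUE} and a warning is raised.
#'
#' @param profile a [RadialReflectanceProfile-class]
#' @param fx spatial frequency, mm^-1 (vectorised)
#' @return numeric reflectance(s), attribute \code{unresolved} flags
#'   frequencies beyond the binning resolution
#' @export
hankelRd <- function(profile, fx) {
  stopifnot(is(profile, "RadialReflectanceProfile"))
  edges <- profile@rhoEdges
  dRho <- diff(edges)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  # resolution: need >~ 4 bins per Bessel oscillation (period 1/fx in rho)
  unres <- fx > 0 & (1 / pmax(fx, .Machine$double.eps)) < 4 * max(dRho)
  if (any(unres))
    warning("fx beyond the resolution of the radial binning; flagged")
  vals <- vapply(fx, function(f) {
    integrand <- profile@rPerArea * besselJ(2 * pi * f * centres, 0) * centres
    2 * pi * sum(integrand * dRho)
  }, numeric(1))
  attr(vals, "unresolved") <- unres
  vals
}

#' Build a reflectance lookup table for optical-property inversion
#'
#' Evaluates the forward model on a (\eqn{\mu_a}, \eqn{\mu_s'}) grid at
#' the two working spatial frequencies. The default grid spans the
#' phantom-calibrated working ranges \eqn{\mu_a \in [0.005, 0.05]} and
#' \eqn{\mu_s' \in [0.5, 3]} mm\eqn{^{-1}}, log-spaced in \eqn{\mu_a} and
#' linear in \eqn{\mu_s'}.
#'
#' @param muARange length-2 ascending range of muA, mm^-1
#' @param muSPrimeRange length-2 ascending range of muS', mm^-1
#' @param gridSizes c(nMuA, nMuSPrime)
#' @param fxPair working frequencies c(fx_dc, fx_ac), mm^-1
#' @param nTissue refractive index
#' @param engine "diffusion" (closed form) or "monte-carlo"
#'   (pencil-beam simulation + Hankel transform per node)
#' @param nPhotons photons per node for the monte-carlo engine
#' @param seed seed for the monte-carlo engine
#' @return a [ReflectanceLUT-class]
#' @export
buildLut <- function(muARange = c(0.005, 0.05), muSPrimeRange = c(0.5, 3),
                     gridSizes = c(64, 64), fxPair = c(0, 0.2),
                     nTissue = 1.4, engine = c("diffusion", "monte-carlo"),
                     nPhotons = 1e4, seed = 1L) {
  engine <- match.arg(engine)
  if (length(muARange) != 2L || muARange[1] <= 0 || diff(muARange) <= 0)
    stop("muARange must be a positive ascending pair")
  if (length(muSPrimeRange) != 2L || muSPrimeRange[1] <= 0 ||
      diff(muSPrimeRange) <= 0)
    stop("muSPrimeRange must be a positive ascending pair")
  if (length(fxPair) != 2L || any(fxPair < 0))
    stop("fxPair must be two non-negative frequencies")
  aGrid <- exp(seq(log(muARange[1]), log(muARange[2]),
                   length.out = gridSizes[1]))
  sGrid <- seq(muSPrimeRange[1], muSPrimeRange[2],
               length.out = gridSizes[2])
  if (engine == "diffusion") {
    aM <- matrix(aGrid, gridSizes[1], gridSizes[2])
    sM <- matrix(sGrid, gridSizes[1], gridSizes[2], byrow = TRUE)
    rdc <- diffusionRd(aM, sM, fxPair[1], nTissue)
    rac <- diffusionRd(aM, sM, fxPair[2], nTissue)
    lutSeed <- NULL
  } else {
    rdc <- rac <- matrix(NA_real_, gridSizes[1], gridSizes[2])
    for (j in seq_along(sGrid)) for (i in seq_along(aGrid)) {
      nodeSeed <- (as.integer(seed) + 7993L * i + 104729L * j) %% .Machine$integer.max
      # radial extent scaled to the node's effective attenuation length so
      # the binned profile captures the full diffuse halo at low absorption
      muEff <- sqrt(3 * aGrid[i] * (aGrid[i] + sGrid[j]))
      prof <- mcRd(aGrid[i], sGrid[j], nTissue = nTissue,
                   nPhotons = nPhotons, seed = nodeSeed,
                   maxRho = max(30, 8 / muEff))
      rr <- hankelRd(prof, fxPair)
      rdc[i, j] <- rr[1]
      rac[i, j] <- min(rr[2], rr[1])  # MC noise can leave rAc a hair above rDc
    }
    lutSeed <- as.integer(seed)
  }
  lut <- new("ReflectanceLUT", muAGrid = aGrid, muSPrimeGrid = sGrid,
             fxPair = as.numeric(fxPair), rDc = rdc, rAc = rac,
             nTissue = nTissue, engine = engine, seed = lutSeed)
  # invertibility guard: the ratio rAc/rDc must be monotone along grid lines
  ratio <- rdc / rac  # strictly decreasing in muA when invertible
  if (engine == "diffusion" && any(apply(ratio, 2, diff) >= 0))
    stop("grid too coarse: R_AC/R_DC ratio not monotone along muA lines")
  lut
}

#' Serialize / load a reflectance LUT (portable text container)
#'
#' The LUT is written as two CSV files (grid nodes and the reflectance
#' table) plus a JSON metadata sidecar (engine, refractive index,
#' frequency pair, seed). Numbers are printed with 17 significant digits
#' so a round trip is bit-identical.
#'
#' @param lut a [ReflectanceLUT-class]
#' @param path base path; files \code{<path>_grid.csv},
#'   \code{<path>_table.csv} and \code{<path>_meta.json} are written
#' @return \code{writeLut} invisibly returns the file paths;
#'   \code{readLut} returns the [ReflectanceLUT-class]
#' @export
writeLut <- function(lut, path) {
  stopifnot(is(lut, "ReflectanceLUT"))
  f17 <- function(x) sprintf("%.17g", x)
  gridDf <- data.frame(
    axis = c(rep("muA", length(lut@muAGrid)),
             rep("muSPrime", length(lut@muSPrimeGrid))),
    value = f17(c(lut@muAGrid, lut@muSPrimeGrid)))
  idx <- expand.grid(i = seq_along(lut@muAGrid), j = seq_along(lut@muSPrimeGrid))
  tabDf <- data.frame(i = idx$i, j = idx$j,
                      rDc = f17(lut@rDc[cbind(idx$i, idx$j)]),
                      rAc = f17(lut@rAc[cbind(idx$i, idx$j)]))
  paths <- paste0(path, c("_grid.csv", "_table.csv", "_meta.json"))
  write.csv(gridDf, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(tabDf, paths[2], row.names = FALSE, quote = FALSE)
  meta <- list(engine = lut@engine, nTissue = f17(lut@nTissue),
               fxPair = f17(lut@fxPair),
               seed = if (is.null(lut@seed)) NULL else lut@seed,
               format = "ssopOx-lut-v1")
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, null = "null")
  invisible(paths)
}

#' @rdname writeLut
#' @export
readLut <- function(path) {
  paths <- paste0(path, c("_grid.csv", "_table.csv", "_meta.json"))
  if (!all(file.exists(paths))) stop("LUT files not found at ", path)
  gridDf <- read.csv(paths[1], colClasses = c("character", "character"))
  tabDf <- read.csv(paths[2],
                    colClasses = c("integer", "integer", "character", "character"))
  meta <- jsonlite::read_json(paths[3])
  aGrid <- as.numeric(gridDf$value[gridDf$axis == "muA"])
  sGrid <- as.numeric(gridDf$value[gridDf$axis == "muSPrime"])
  rdc <- rac <- matrix(NA_real_, length(aGrid), length(sGrid))
  rdc[cbind(tabDf$i, tabDf$j)] <- as.numeric(tabDf$rDc)
  rac[cbind(tabDf$i, tabDf$j)] <- as.numeric(tabDf$rAc)
  new("ReflectanceLUT", muAGrid = aGrid, muSPrimeGrid = sGrid,
      fxPair = as.numeric(unlist(meta$fxPair)), rDc = rdc, rAc = rac,
      nTissue = as.numeric(meta$nTissue), engine = meta$engine,
      seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed))
}
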