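# File-format plumbing: 16-bit TIFF raw frames with JSON sidecars,
# 32-bit float TIFF maps, 8-bit mask TIFFs, CSV study tables.

#' Write / read a raw frame as 16-bit TIFF with a JSON sidecar
#'
#' Counts are stored losslessly as 16-bit little-endian TIFF; the
#' sidecar \code{<path>.json} records wavelength, fx, phase, modulation
#' depth, dc level, pixel pitch, noise metadata and seed, so a frame
#' round-trips exactly.
#'
#' @param frame a [RawFrame-class]
#' @param path output TIFF path
#' @return \code{writeFrameTiff} invisibly returns \code{path};
#'   \code{readFrameTiff} returns the [RawFrame-class]
#' @export
writeFrameTiff <- function(frame, path) {
  stopifnot(is(frame, "RawFrame"))
  img <- round(frame@image)
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  meta <- list(wavelength = frame@wavelength, fx = frame@pattern@fx,
               phase = frame@pattern@phase,
               dcLevel = frame@pattern@dcLevel,
               modulationDepth = frame@pattern@modulationDepth,
               pixelPitch = frame@pattern@pixelPitch,
               readNoiseSd = frame@readNoiseSd, shotNoise = frame@shotNoise,
               bitDepth = frame@bitDepth,
               seed = if (is.null(frame@seed)) NULL else frame@seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeFrameTiff
#' @export
readFrameTiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  pat <- PatternSpec(meta$fx, meta$phase, meta$dcLevel, meta$modulationDepth,
                     meta$pixelPitch)
  new("RawFrame", image = matrix(as.numeric(img), nrow(img), ncol(img)),
      wavelength = as.numeric(meta$wavelength), pattern = pat,
      readNoiseSd = as.numeric(meta$readNoiseSd),
      shotNoise = isTRUE(meta$shotNoise), bitDepth = as.numeric(meta$bitDepth),
      saturationMask = NULL,
      seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed))
}

#' Write / read a float map as 32-bit float TIFF
#'
#' The TIFF writer stores normalised [0, 1] floats, so the map is
#' min-max scaled into [0, 0.9] and the affine range recorded in a JSON
#' sidecar \code{<path>.json}; NA pixels are stored as 1 and restored on
#' read. Round-trip accuracy is single precision relative to the map's
#' range.
#'
#' @param map numeric matrix
#' @param path output path
#' @export
writeMapTiff <- function(map, path) {
  fin <- is.finite(map)
  lo <- if (any(fin)) min(map[fin]) else 0
  hi <- if (any(fin)) max(map[fin]) else 1
  span <- if (hi > lo) hi - lo else 1
  m <- (map - lo) / span * 0.9
  m[!fin] <- 1
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(list(min = lo, max = hi, span = span, naValue = 1),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMapTiff
#' @export
readMapTiff <- function(path) {
  m <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  out <- m / 0.9 * as.numeric(meta$span) + as.numeric(meta$min)
  out[m > 0.95] <- NA_real_
  matrix(as.numeric(out), nrow(m), ncol(m))
}

#' Write a logical mask as 8-bit TIFF
#' @param mask logical matrix
#' @param path output path
#' @export
writeMaskTiff <- function(mask, path) {
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Write / read a study table as CSV
#'
#' Column names are the documented StudyRecord fields: animal, roi,
#' zone, timePoint, capillaryLactate, systemicLactate, parkChiu,
#' sto2Measured (plus any normalisation columns already added).
#'
#' @param records study data.frame
#' @param path CSV path
#' @export
writeStudyCsv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStudyCsv
#' @export
readStudyCsv <- function(path) {
  df <- read.csv(path)
  need <- c("roi", "timePoint", "capillaryLactate", "systemicLactate")
  if (!all(need %in% names(df)))
    stop("study CSV is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Manifest of files with checksums
#'
#' @param paths file paths
#' @param outPath JSON manifest path
#' @export
writeManifest <- function(paths, outPath) {
  entries <- lapply(paths, function(p)
    list(file = basename(p), md5 = unname(tools::md5sum(p))))
  jsonlite::write_json(entries, outPath, auto_unbox = TRUE)
  invisible(outPath)
}
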