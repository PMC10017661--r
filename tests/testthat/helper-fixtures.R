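# Shared fixtures: a working pixel pitch with >= 8 px per pattern period
# at fx = 0.2 mm^-1, small frame shapes, and the default diffusion LUT
# (cheap to build, reused across tests).

PITCH <- 150 / 1024          # instrument pitch, mm/px
FX <- 0.2                    # working pattern frequency, mm^-1
PHASES3 <- c(0, 2 * pi / 3, 4 * pi / 3)

noiseOff <- noiseModel(readSd = 0, shot = FALSE)

lutDefault <- buildLut()

homoFrame <- function(op, fx, phase = 0, shape = c(32, 256), wl = 665,
                      noise = noiseOff, seed = NULL, dcLevel = 30000,
                      m = 0.9, pitch = PITCH) {
  renderHomogeneousFrame(op, PatternSpec(fx, phase, dcLevel, m, pitch),
                         shape, wl, noise, seed)
}

sfdiSet <- function(op, fx = FX, shape = c(32, 256), wl = 665,
                    noise = noiseOff, seeds = NULL, ...) {
  s <- function(i) if (is.null(seeds)) NULL else seeds[i]
  list(dc = lapply(1:3, function(i) homoFrame(op, 0, PHASES3[i], shape, wl,
                                              noise, s(i), ...)),
       ac = lapply(1:3, function(i) homoFrame(op, fx, PHASES3[i], shape, wl,
                                              noise, s(i + 3), ...)))
}

# small bowel scene that still fits five 1 cm ROIs at 2.5 cm spacing
smallScene <- function(shape = c(96, 640), pitch = 0.2, ...) {
  makeBowelScene(shape = shape, pixelPitch = pitch, ...)
}

centralCols <- function(maps) {
  m <- edgeMargin(maps)
  nc <- ncol(mDc(maps))
  (m + 1):(nc - m)
}
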