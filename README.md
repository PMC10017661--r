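# ssopOx

Spatial frequency domain imaging (SFDI) and single-snapshot imaging of
optical properties (SSOP) processing for multispectral tissue oximetry,
with a full structured-illumination simulator so every stage can be
validated end to end without instrument data.

## The problem and who this is for

SFDI projects sinusoidal light patterns onto tissue and measures how
strongly the pattern is attenuated in the diffusely back-reflected
light. Because absorption and scattering attenuate different spatial
frequencies differently, a pair of calibrated diffuse-reflectance
measurements — R_DC at spatial frequency 0 and R_AC at the pattern
frequency f_x — separates the absorption coefficient μa from the reduced
scattering coefficient μs′ per pixel. Classic SFDI needs six frames (two
frequencies × three phases); SSOP recovers both modulation amplitudes
from a **single** patterned frame by Fourier-domain filtering, enabling
video-rate imaging at the cost of some image quality and edge artefacts.
Measuring μa at two wavelengths (665 and 860 nm) and unmixing against
the haemoglobin extinction spectra yields tissue oxygen saturation
(StO2), a perfusion biomarker used intraoperatively, e.g. to grade bowel
ischaemia.

The package is aimed at biomedical-optics researchers and method
developers who need a tested, scriptable SFDI/SSOP processing chain and
a ground-truthed digital phantom to exercise it.

## What it implements

- **Forward models**: the standard SFDI diffusion closed form
  R_d(f_x) = 3Aa′ / [(μ_eff′/μ_tr + 1)(μ_eff′/μ_tr + 3A)] with
  μ_tr = μa + μs′, a′ = μs′/μ_tr, μ_eff′ = √(μ_eff² + (2πf_x)²), and a
  photon-packet Monte-Carlo oracle (Henyey–Greenstein g = 0.9, Fresnel
  boundary, radial binning + order-0 Hankel transform) for
  cross-validation (`diffusionRd`, `mcRd`, `hankelRd`).
- **Lookup table**: `buildLut` maps a (μa, μs′) grid (defaults
  0.005–0.05 and 0.5–3 mm⁻¹) to (R_DC, R_AC); `invertLut` inverts
  per-pixel reflectance pairs with nearest-node search plus bilinear
  Newton refinement, masking out-of-table pixels instead of
  extrapolating.
- **Demodulation**: exact 3-phase SFDI (`sfdiDemodulate`) and
  single-frame SSOP via windowed Fourier filters and analytic-signal
  envelope extraction (`ssopDemodulate`), with explicit edge-margin
  accounting.
- **Calibration**: reference-phantom ratio calibration (`calibrate`)
  against a silicone phantom with known properties (μa = 0.01,
  μs′ = 1.1 mm⁻¹ at 665 nm; μa = 0.02, μs′ = 0.8 mm⁻¹ at 860 nm).
- **Oximetry**: two-wavelength haemoglobin unmixing to StO2 and total
  haemoglobin with quality masking (`unmixSto2`, `roiSummary`).
- **Scene simulator**: an ischaemic-bowel digital phantom with five
  ROIs (central ischaemic / marginal / vascularised), a calibration
  phantom renderer, shot + read camera noise, and a perfusion-study
  table generator (`makeBowelScene`, `renderFrame`, `simulateStudy`).
- **Study statistics**: capillary-lactate normalisation, Pearson
  correlation and pooled-variance Student's t with a
  Kolmogorov–Smirnov normality check (`normaliseLactates`,
  `pearsonCor`, `studentsT`, `roiStats`).
- **CLI**: `inst/scripts/ssop` with `simulate`, `build-lut`, `process`
  and `roi-stats` subcommands over YAML/JSON configs.

## Worked example

```r
library(ssopOx)

lut <- buildLut()                      # diffusion engine, 64 x 64 grid
scene <- makeBowelScene(shape = c(192, 640), pixelPitch = 0.2)
acq <- simulateAcquisition(scene, mode = "ssop", noise = noiseModel(), seed = 3)
res <- processAcquisition(acq, lut)
roiSummary(res$sto2, roiMasks(scene))
```

```
  roi nPixels nValid      mean          sd flagged
1   1    2500   2500 0.3067950 0.010650994   FALSE
2   2    2500   2500 0.4520007 0.010997999   FALSE
3   3    2500   2250 0.4811176 0.008779684   FALSE
4   4    2500   2500 0.4540703 0.009250695   FALSE
5   5    2500   2250 0.4808210 0.009339179   FALSE
```

The scene's ground-truth StO2 is 0.3008 in the central ischaemic ROI 1,
0.4567 in the marginal ROIs 2/4 and 0.4808 in the vascularised ROIs
3/5; the single-snapshot path recovers each ROI mean to well within
0.01 despite shot + read noise. ROIs 3/5 lose 250 pixels to the
demodulation edge margin, which is reported rather than hidden.

The statistics module reproduces the analysis shape of a perfusion
study on a simulated table:

```r
out <- roiStats(simulateStudy(seed = 5))
out$correlations$sto2VsLactate
# CorrelationResult (pearson): r = -0.5047, n = 150, p = 4.555e-11
out$comparisons$sto2IschVsMarg
# GroupComparison: ischaemic (0.301 +/- 0.077) vs marginal (0.455 +/- 0.070)
#   t = -9.4528, df = 88, p = 4.794e-15; KS pass: TRUE, TRUE
```

StO2 falls and normalised capillary lactate rises with ischaemia, so
their correlation is negative; the ischaemic zone separates sharply
from the perfused zones.

## Layout

- `R/`, `src/` — implementation (S4 classes; Rcpp Monte-Carlo kernel)
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/ssop-pipeline.Rmd` — methods: models, assumptions,
  parameter choices, numerical details, limitations
- `inst/extdata/hb_extinction.csv` — haemoglobin extinction table
  (OMLC/Prahl compilation) used by all defaults and tests
- `inst/scripts/ssop` — command-line entry point
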