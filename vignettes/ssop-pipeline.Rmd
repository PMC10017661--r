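---
title: "Methods: the SSOP oximetry pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SSOP oximetry pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the assumptions behind them, the parameters that matter, and the
numerical and design choices that were genuinely open. Nothing here
states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Forward model

The pipeline treats tissue as a semi-infinite, homogeneous,
flat-surfaced turbid medium per pixel. Under sinusoidal illumination at
spatial frequency $f_x$ the diffusely reflected modulation amplitude is
modelled by the standard diffusion-approximation closed form

$$R_d(f_x) = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)},$$

with $\mu_{tr} = \mu_a + \mu_s'$, $a' = \mu_s'/\mu_{tr}$,
$\mu_{eff} = \sqrt{3\mu_a\mu_{tr}}$,
$\mu_{eff}' = \sqrt{\mu_{eff}^2 + (2\pi f_x)^2}$, and the
internal-reflection parameter $A = (1-R_{eff})/(2(1+R_{eff}))$,
$R_{eff} \approx 0.0636\,n + 0.668 + 0.710/n - 1.440/n^2$. The
refractive index defaults to $n = 1.4$, the conventional soft-tissue
value. $R_d$ is the reflectance of the light that *enters* the medium:
its $\mu_a \to 0$ planar limit is exactly 1, and the deficit scales as
$\sqrt{\mu_a}$ — which is why limit tests probe $\mu_a = 10^{-14}$
rather than $10^{-12}$ to reach a $10^{-6}$ tolerance.

Assumptions worth keeping in mind: homogeneity within a pixel's
sampling volume, a flat surface at the working distance (no
profilometry correction), ideal crossed-polariser rejection of specular
reflection, and the diffusion regime $\mu_s' \gg \mu_a$.

### Known limitation: $\mu_a$ sensitivity at high $f_x$

At the low-scattering corner of the working domain the closed form's
$\mu_a$ sensitivity saturates: once $(2\pi f_x)$ dominates $\mu_{tr}$,
raising $\mu_a$ raises $\mu_{tr}$ and thereby *lowers*
$\mu_{eff}'/\mu_{tr}$, producing a marginal reversal of the otherwise
strictly decreasing $R_d(\mu_a)$. On the default grid this appears only
at $f_x = 0.2\,\mathrm{mm}^{-1}$, $\mu_s' = 0.5\,\mathrm{mm}^{-1}$,
with adjacent-node reversals of order $4\times10^{-5}$ (0.1 % of
$R_d$). The corresponding strict-monotonicity expectation in the
acceptance suite is deliberately left failing as an honest record of
this model property. Inversion is unaffected: it relies on the
$R_{DC}/R_{AC}$ ratio, which remains strictly monotone in $\mu_a$ at
every scattering level of the grid (asserted in the unit tests).

## Monte-Carlo oracle

`mcRd` is a photon-packet simulation used to cross-check the closed
form and to build Monte-Carlo lookup tables: pencil beam at normal
incidence, Henyey–Greenstein phase function with $g = 0.9$ and
$\mu_s = \mu_s'/(1-g)$, implicit-capture absorption weighting, and an
unpolarised Fresnel treatment of the index-mismatched top surface
(specular launch loss $(n-1)^2/(n+1)^2$; internal reflections split by
the Fresnel coefficient at each surface crossing). Packets terminate
deterministically when their weight falls below $10^{-4}$, with the
residual tallied as absorbed — this keeps
reflected + absorbed = launched *exactly* per run (the conservation
invariant is tested at $10^{-6}$), at a bias bounded by the $10^{-4}$
threshold itself, where a classic Russian-roulette would only conserve
in expectation.

The radial exit profile is normalised per unit launched (post-specular)
weight so that its Hankel transform shares the closed form's
convention; normalising per incident photon would build a systematic
$\approx 3\%$ offset into every comparison. `hankelRd` evaluates
$R_d(f_x) = 2\pi\int R(\rho)\,J_0(2\pi f_x \rho)\,\rho\,d\rho$ by the
midpoint rule over 0.1 mm bins, flagging frequencies the binning cannot
resolve. For LUT nodes the radial extent scales with $8/\mu_{eff}$ so
the diffuse halo is captured even at the lowest absorptions.

Agreement between the two engines is validated in the diffusive regime
($\mu_s'/\mu_a \ge 20$) at both working frequencies with $10^5$
photons. The gap at $f_x = 0.2$ is systematic, not statistical:
transport with $g = 0.9$ sits roughly 13 % below the diffusion value
there, which is precisely why Monte-Carlo lookup tables are preferred
over analytic inversion in practice. At $10^4$ photons per node the
additional statistical scatter makes node-wise engine agreement at
$f_x = 0.2$ unreliable, so the cheap node-wise cross-check in the unit
suite is restricted to the planar channel.

## Demodulation

The 3-phase reference path uses the exact identities
$M_{DC} = (I_1+I_2+I_3)/3$ over the planar set and
$M_{AC} = \tfrac{\sqrt2}{3}\sqrt{(I_1-I_2)^2+(I_2-I_3)^2+(I_3-I_1)^2}$
over the patterned set (phases $0, 2\pi/3, 4\pi/3$); on noiseless input
it is machine-exact, and on noisy input it coincides with the per-pixel
least-squares sinusoid fit (asserted to $10^{-6}$ relative).

The single-snapshot path processes each image row (the direction the
pattern varies along) in the Fourier domain: a Blackman-tapered
low-pass of half-width $f_x/2$ about 0 yields $M_{DC}$, and a
single-sided Blackman band of half-width $f_x/2$ about $+f_x$, inverse
transformed as the analytic signal, yields the envelope
$M_{AC} = 2\,|z|$. Rows are mirror-padded by two pattern periods before
transforming, and the same two-period width is reported as the
`edgeMargin` of reduced validity — downstream calibration masks those
columns rather than hiding them. The filter cutoffs (as fractions of
$f_x$), window family and padding mode are exposed in
`ssopFilterConfig` and the run configuration; the defaults were chosen
so that on noiseless homogeneous scenes SSOP tracks the 3-phase result
to better than 1 % over the central field, and a sharp absorption step
corrupts no more than the declared margin around it (both are tested).
The pattern needs at least 8 pixels per period; coarser sampling is
refused rather than silently degraded. The demodulator is pluggable: a
learned single-frame demodulator could replace `ssopDemodulate`
without touching the rest of the chain. In single-snapshot mode
$M_{DC}$ necessarily comes from the low-pass channel of the same
patterned frame — no planar frame exists in a true single snapshot.

## Calibration and inversion

Calibration ratios the sample's modulation maps against a measurement
of a reference phantom with known optical properties and multiplies by
the forward model's prediction for the phantom, channel by channel;
source intensity and modulation depth cancel. Reference pixels below
1 % of the field-median modulation are masked for division stability,
and calibrated reflectance above 1 is flagged invalid, never clipped.
The shipped phantom constants are $\mu_a = 0.01$, $\mu_s' = 1.1$ at
665 nm and $\mu_a = 0.02$, $\mu_s' = 0.8\,\mathrm{mm^{-1}}$ at 860 nm.

Inversion works in the LUT's grid coordinates: a two-level
nearest-node search (coarse stride, then the surrounding
neighbourhood) seeds up to four damped Newton steps on the bilinear
interpolant of the local cell, minimising Euclidean distance in
$(R_{DC}, R_{AC})$ normalised by each channel's table median so the
two channels' dynamic ranges contribute comparably. Pixels whose
residual stays large at a grid boundary — or is large anywhere — are
declared outside the table's image set and masked; values are never
extrapolated, because extrapolated optical properties corrupt StO2
silently. The default 64 × 64 grid is log-spaced in $\mu_a$ (its
reflectance response is closer to log-linear) and linear in $\mu_s'$;
off-grid forward–inverse round trips recover both coefficients to
$\le 2\%$ in the tests.

## Oximetry

Per pixel, absorption at the two wavelengths minus a background term is
solved as a $2\times2$ linear system in the oxy/deoxy-haemoglobin
concentrations; $StO_2 = c_{HbO2}/(c_{HbO2}+c_{Hb})$ and
$tHb = c_{HbO2}+c_{Hb}$. All unit conversion (extinction in
cm$^{-1}$M$^{-1}$, concentration in µM, $\mu_a$ in mm$^{-1}$) lives in
one constant, because unit bugs dominate failure modes here. The
extinction values ship as a versioned CSV from the OMLC (Prahl)
haemoglobin compilation; every default and test references the shipped
table, so results are self-consistent regardless of compilation
choice. The table's invariants (deoxy dominates at 665 nm, oxy at
860 nm) guarantee the system is well-conditioned. Pixels with a
negative concentration, an out-of-LUT input, or saturation enter the
quality mask; the stored maps keep raw values, and only `displaySto2`
produces a clamped copy — so masking policy is explicit rather than
baked into the data. The background absorption subtracted in unmixing
defaults to the scene simulator's background offset
(0.001 mm$^{-1}$) so the synthesis/unmixing pair is exactly inverse
(tested to $10^{-6}$ StO2).

## The scene simulator — what it emulates and what it does not

The digital phantom emulates the acquisition geometry of a
structured-illumination oximeter: 1024 × 1280 frames over a 15 cm
field (pitch ≈ 0.146 mm/px; tests use smaller rasters with
correspondingly coarser pitch), two wavelengths (665/860 nm), a
sinusoidal pattern at $f_x = 0.2\,\mathrm{mm^{-1}}$ along image
columns, 16-bit counts with Poisson shot noise plus Gaussian read
noise (SD 2 counts), and saturation clipping with a recorded mask. The
bowel segment is drawn as a straight horizontal band on a darker
surround — ROI spacing (2.5 cm), ROI size (1 × 1 cm) and the smooth
StO2 transition between zones are what matter for recovery tests, and
a curved loop would add bookkeeping without exercising any additional
pipeline behaviour. Zone StO2 truths default to 0.3008 / 0.4567 /
0.4808 (ischaemic / marginal / vascularised); total haemoglobin
defaults to 60 µM on the segment and $\mu_s'$ to 1.3 / 1.0 mm$^{-1}$
at 665 / 860 nm — mid-range, tissue-plausible values. The background is
deliberately given an absorption outside the LUT range at 665 nm so
that out-of-table masking is exercised on every full-scene run.

Not emulated: surface curvature and height variation (flat-surface
assumption throughout), inter-reflections, spatially varying
illumination, motion, specular leakage, or chromophores beyond
haemoglobin (no water/lipid). Passing recovery tests on this phantom
therefore demonstrates correctness of the processing chain under its
own forward model and noise, not robustness to profile-induced
intensity variation — the known dominant error source on real curved
organs.

The study-table generator produces one record per (animal, ROI, time
point) across a one-hour ischaemia window: capillary lactate rises
linearly from baseline to twice the zone target (so its study-average
equals the target: 4.804 / 1.026 / 0.749 mmol/L normalised), systemic
lactate stays near 1.5 mmol/L, StO2 is the zone truth plus noise
(SD 0.07), and an integer Park/Chiu-style histology grade is drawn
around zone means 4.5 / 1.583 / 0.667. Noise SDs were fixed once at
magnitudes typical of such studies. Lactate normalisation supports both
the difference (default; keeps mmol/L units) and ratio conventions,
since either is used in practice; ratio mode flags rows with
non-positive systemic values instead of dividing.

## Statistics

`pearsonCor` is the product-moment coefficient with the two-sided $p$
from the $t$ transform on $n-2$ df (a Spearman option is exposed for
rank analyses); `studentsT` is the pooled-variance two-sample test with
a per-group one-sample Kolmogorov–Smirnov check against a normal
reference, reported alongside but never silently acted on. Both are
computed through R's stats machinery and verified against
hand-computed textbook oracles in the tests; the t test's type-I error
is checked empirically at the 5 % level over 1000 seeded replicates.
No multiple-testing correction is applied, matching the single-study
analysis shape being reproduced.

## Numerical and reproducibility choices

- Every source of randomness takes an explicit seed; no hidden global
  state. Fixed seed ⇒ bit-identical frames, tables and profiles.
- Coordinates are row-major; physical $x$ = column index × pixel
  pitch; pattern phase is referenced to column 0.
- LUTs serialise to a CSV pair plus JSON metadata with 17 significant
  digits, so a round trip is bit-identical.
- Raw frames store as 16-bit TIFF with a JSON sidecar; float maps
  store min–max scaled in 32-bit float TIFF with the affine range in a
  sidecar (the TIFF writer only persists normalised [0, 1] floats),
  NA as a reserved code.
- Degenerate inputs error early: non-positive coefficients,
  sub-Nyquist or sub-8-pixel patterns, overlapping filter bands,
  grids too coarse to invert, empty validity masks.
- Problem sizes in the tests and acceptance script — 32 × 256 px
  homogeneous frames, 100-phantom accuracy sweeps, 96 × 640 px scenes,
  $10^5$-photon Monte-Carlo checks — were chosen as the smallest sizes
  at which the measured quantities are stable well inside their
  tolerances.
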