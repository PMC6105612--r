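---
title: "Models and methods behind ppixquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ppixquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppixquant)
```

`ppixquant` models the chain from microscope illumination to rater
agreement for quantitative protoporphyrin IX (PpIX) fluorescence imaging.
This vignette records the models, the tunable parameters, and the design
choices made where the underlying measurements leave the functional form
open.

## Illumination

Peak incident blue-light power density is modelled as

$$P(s, D) = g \cdot s \cdot P_{\mathrm{ref}} \left(\frac{D_{\mathrm{ref}}}{D}\right)^{\gamma},$$

with light setting $s \in [0,1]$, working distance $D$ (cm), and a
per-microscope gain $g$. Power versus setting is taken **linear through the
origin**: the measurements establish a monotone association but no
functional form, and linearity is the simplest monotone choice (the
response is a single pluggable factor, so a measured curve can replace it).
Distance dependence is a **power law rather than inverse-square**: the
source is an imaging illuminator, not a point source, and the two anchor
measurements (25.2 mW/cm² at 20 cm, 4.7 mW/cm² at 35 cm) calibrate
$\gamma \approx 3.0$ by log–log least squares
(`calibrate_distance_exponent()`). The reference point is pinned to the
nearest anchor, so a two-anchor fit passes through both exactly; the model
then predicts 12.9 mW/cm² at 25 cm, inside the 8.9–18.4 mW/cm² spread
measured across microscopes at that distance (that spread is what the gain
$g$ represents). Calibration rejects non-decreasing anchors, since a
non-positive exponent would violate the physics the model encodes.

The beam profile (`beam_field()`) is a **two-sided Gaussian**: horizontal
half-width $\sigma_x$, vertical half-width $\sigma_y$ below the centre and
$\sigma_y \cdot \text{tilt\_skew}$ above it (default 1.15). The measured
profile is bell-shaped and skewed along the vertical axis because the
microscope sits tilted; the two-sided Gaussian is the simplest profile with
exactly those properties. Half-widths scale linearly with distance
(cone-shaped beam, default 1 mm of spot radius per cm of distance;
$\sigma_x = \sigma_y = 20$ mm at 20 cm so the four corner standards of the
default scene still receive roughly half the peak irradiance). Units are
explicit everywhere: mW/cm² for power density, J/cm² for radiant exposure
(`dose_to_time()`/`time_to_dose()`, exact inverses), cm for distance, mm
for field coordinates.

## Scene and cameras

**Standards.** A dye-in-polymer sheet emits
$E = k \cdot c_{\mathrm{ppt}} \cdot d_{\mathrm{in}} \cdot (P/P_{\mathrm{ref}}) \cdot (1 + \delta(t))$:
linear in thickness $d$ with slope increasing in pigment concentration $c$,
proportional to local excitation, with a linear drift ramp $\delta(t)$
capped at ±3.5 % over 30 min (the largest change observed in any standard;
the −0.3 %/10 min, +3.5 %/30 min measurements are statistically
indistinguishable from photostability). The absolute radiance scale
(`slope_per_ppt`, default 100 a.u. per inch·ppt) is conventional — only
ratios matter downstream.

**Tissue.** Fluorescing tissue bleaches logarithmically with an
irradiance-scaled rate:
$I(t) = \max\{0, I_0 + c \cdot (P/P_{\mathrm{ref}}) \cdot \ln(t+1)\}$.
The default glioma constants are solved from the published group
trajectories as two-point constraints: tumor $36.8 - 8.94\ln(t+1)$ and
brain $8.0 - 1.048\ln(t+1)$ reproduce a tumor-to-background ratio of 4.6
at $t=0$ and 2.8 at 10 min and brain decay from 8.0 to 4.4 a.u. over
30 min; the constant dark floor of 1.54 a.u. gives brain-to-background 5.2
at $t=0$ and 2.85 at 30 min. The irradiance scaling makes central regions
bleach faster than peripheral ones under the bell-shaped field, matching
the observed centre-to-periphery ordering of decay coefficients.

**Specimen variability.** One lognormal gain (σ = 0.3) common to tumor and
brain — it cancels in the tumor-to-background ratio, keeping that
distribution centred — plus an independent tumor-only lognormal jitter
(σ = 0.15) that spreads per-specimen ratios over roughly the observed
3.2–7.8 range. A consequence worth noting: a lognormal with unit median has
mean $e^{\sigma^2/2}$, so grand means of simulated ratios sit 1–5 % above
the deterministic values; together with ROI discs averaging irradiance
slightly below the peak (which damps bleaching off-centre), simulated
grand-mean ratios land a few percent above the two-point calibration
targets at later time points.

**Geometry.** Default 512×512 pixels at 0.1 mm/pixel (a 51.2 mm field);
standards at the four corners, tumor and brain discs (5.6 mm radius)
flanking the field centre at ±5.7 mm so the 51-pixel analysis ROIs fit
inside them while staying near peak irradiance, and a dark-background ROI
on the floor — seven ROIs in all: the six from the animal experiment
(standards 1, 4, 6, 9, tumor, adjacent brain) plus the floor ROI that the
brain-to-dark-background ratio needs. Tests and quick examples use the same
physical layout at 128×128 / 0.4 mm with 12-pixel ROIs, which renders ~16×
faster with identical closed-form ground truth.

**Cameras.** Rendering is linear before 8-bit quantization; read noise is
additive Gaussian (default SD 1 count). Shot noise is omitted: every
downstream statistic averages thousands of ROI pixels, so the noise model
only needs to dither quantization, and additive noise keeps the renderer
exactly linear in expectation. Green carries no signal (red PpIX emission,
blue excitation). The ">1000× attenuation" of the external camera's filter
is implemented as leak ≤ 10⁻³ of the blue signal into red; the internal
CCD's leak defaults to 0.05 — a free parameter, since only the qualitative
collapse of the internal-camera tumor-to-background ratio constrains it
(for any leak β > 0, $(r_t + \beta b)/(r_b + \beta b) < r_t/r_b$, so the
ordering is structural). No Bayer mosaic, gamma curve, or auto-exposure:
camera settings were held fixed in the experiment being emulated.

## Quantification and normalization

ROIs are circles (default radius 51 pixels) with the **centre-in-circle**
pixel inclusion rule — the simplest deterministic rule; the original
FIJI-based analysis does not record which rule it used. Coordinates are
1-based `(row, col)` with origin top-left, the R array convention, and are
written as such by the I/O helpers. Means use the sample SD. The
tumor-to-background ratio divides tumor by adjacent-brain ROI means per
time point; the dark-floor ROI serves the brain-to-background ratio. No
autofluorescence subtraction is applied, matching the analysis being
reproduced.

Ratiometric normalization assigns the reference standard a nominal
constant (default 10 %) **per time point**:
$\mathrm{norm}(r, t) = 10 \cdot \bar{I}(r,t) / \bar{I}(\mathrm{ref}, t)$.
Because the division is per frame, any multiplicative per-frame factor —
lamp fluctuation, exposure change, ambient light acting multiplicatively —
cancels to machine precision, and normalizing an already-normalized series
is the identity. What it cannot fix is field-of-view non-uniformity: ROIs
at different positions see different excitation, and no flat-field map is
applied (a deliberate non-goal). The nominal 10 % is a free parameter; the
published convention is kept as the default.

## Kinetics

`fit_log_decay()` fits $y = c\ln(t + \text{offset}) + y_0$ by least
squares. The default offset of 1 min makes the $t=0$ frame usable (the
acquisition schedule starts at 0); with offset 0 the $t=0$ sample is
dropped with a warning. The goodness of fit is reported as the Cox–Snell
pseudo-R² from the Gaussian likelihood ratio,
$1 - \exp\{2(\ell_0 - \ell_1)/n\}$ — which for Gaussian maximum-likelihood
variances reduces algebraically to the classical $1 - SSE/SST$; the
implementation computes both routes and the tests assert their equality,
resolving the otherwise surprising use of a pseudo-R² for an ordinary
least-squares model. Zero-variance input returns $c = 0$ with R² = 0
rather than NaN.

The logarithmic model has no finite half-life from $t=0$, so
`half_life_two_point()` uses the exponential-through-two-points
convention $t_{1/2} = \Delta t \ln 2 / \ln(y_1/y_2)$ — scale-invariant in
$y$, translation-invariant in $t$, and the convention under which a
0-vs-30-min pair with $y_0/y_{30} \approx 4.23$ yields ≈14.4 min. Group
comparisons wrap the two-sided t-test (Student's equal-variance form by
default); p-values are reported raw, with no multiple-testing correction,
matching the original analysis.

## Agreement

Scores live on the fixed five-category 0–4 scale; the category space stays
$k = 5$ even when a table uses fewer categories, which is required for the
free-marginal kappa to reproduce its published value. "Interobserver
agreement" is the **mean pairwise agreement** $P_o$ (fraction of agreeing
rater pairs pooled over items) — this, not the mean of the per-item modal
column, reproduces the published 81.5 %; both statistics are exposed. The
fixed-marginal kappa uses $P_e = \sum_j p_j^2$ over pooled category
proportions; the free-marginal kappa uses $P_e = 1/k$. All-identical
ratings make the fixed-marginal kappa undefined ($P_e = 1$); `NA` is
returned with a warning. Percentages print rounded to one decimal; raw
fractions are retained. The first-attempt scores behind the intrarater
summary are not published — only per-observer agreement percentages are —
so `synthetic_first_attempt()` reconstructs a synthetic attempt consistent
with those percentages (it is labelled synthetic and used only for the
summary arithmetic, which depends on the agreement counts alone).

## What the simulations do and do not show

The generator reproduces the *structure* of the experiment: corner
standards, central tissue, bell-shaped skewed illumination,
irradiance-dependent logarithmic bleaching, two camera models, the
1-min×10-then-5-min schedule, and per-specimen lognormal variability. It
deliberately omits anatomical texture, specular reflections, motion,
heterogeneous within-tumor fluorescence, and spectral structure beyond
scalar channel weights. Passing tests therefore demonstrate that the
*pipeline* — quantification, normalization, kinetics, agreement — recovers
known ground truth under realistic geometry and noise; they cannot certify
performance on real surgical images, where field non-uniformity couples to
non-flat anatomy and the tissue model is only an approximation.

Problem sizes used by the test suite and the acceptance script: the
replicate-study summary simulates 20 independent 6-specimen studies at the
default 512×512 geometry through the external camera (~2 min on one CPU);
parameter-recovery checks use 100 replicates of 14–15-point series;
property checks run on the 128×128 variant of the same physical scene.
Seeds are fixed throughout; every stochastic entry point takes an explicit
seed and restores the caller's RNG state.
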