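# ppixquant

Quantifying protoporphyrin IX (PpIX) fluorescence through a neurosurgical
operating microscope is confounded by the instrument itself: incident
blue-light power density varies several-fold between microscopes, falls
steeply with working distance, and is distributed unevenly across the field
of view, while the internal colour CCD lets reflected blue light spill into
the red channel. `ppixquant` implements the full measurement chain that
addresses this — for researchers developing quantitative
fluorescence-guided-surgery protocols — as a tested, simulation-driven R
pipeline:

- **Optics.** Peak power density follows a power law
  `P(D) = P_ref (D_ref/D)^γ`, calibrated by log–log least squares to
  power-meter anchors (25.2 mW/cm² at 20 cm, 4.7 mW/cm² at 35 cm ⇒
  γ ≈ 3.0). The beam profile is a two-sided Gaussian, bell-shaped with a
  widened upper half (vertical skew from microscope angulation). Radiant
  exposure converts as `t = dose/P`.
- **Scene simulation.** Photostable dye-in-polymer standards (radiance
  linear in sheet thickness with concentration-dependent slope, |drift| ≤
  3.5 % over 30 min) and tumor/brain tissue with logarithmic,
  irradiance-dependent photobleaching `I(t) = max(0, I₀ + c·(P/P_ref)·ln(t+1))`,
  rendered to 8-bit RGB by two camera models: an external filtered camera
  (≥1000× blue rejection) and an internal CCD with blue→red spillover.
- **Quantification and normalization.** Circular-ROI (51-pixel radius)
  red-channel means ± SD over the acquisition schedule; tumor-to-background
  ratios; ratiometric normalization that fixes a reference standard at a
  nominal 10 % per time point, cancelling any per-frame multiplicative gain
  exactly.
- **Kinetics.** Fits `y = c·ln(t + offset) + y₀` with a Cox–Snell
  pseudo-R² (identical to classical 1 − SSE/SST under Gaussian likelihood),
  two-point exponential half-life `t½ = Δt·ln2/ln(y₁/y₂)`, percent decay,
  and t-test group comparisons.
- **Agreement.** For 0–4 ordinal fluorescence grades by multiple raters:
  per-item modal agreement, overall pairwise agreement `P_o`, fixed-marginal
  (Fleiss-type) kappa `(P_o − P_e)/(1 − P_e)`, free-marginal kappa
  `(P_o − 1/k)/(1 − 1/k)`, and intrarater repeat-scoring summaries.

## Worked example

```r
library(ppixquant)

# Calibrate the illumination model from the packaged power-meter anchors
model <- calibrate_distance_exponent(power_anchors()[c("distance_cm", "power_mw_cm2")])
incident_power_density(microscope_config(1, 25), model)
#> [1] 12.90017            # mW/cm^2 at 25 cm, inside the measured 8.9-18.4 range

dose_to_time(14.4, 25.2) / 60
#> [1] 9.52381             # minutes to deliver 14.4 J/cm^2 at the 20-cm peak

# Simulate a 6-specimen glioma study and quantify it end to end
ts <- run_study(study_design(seed = 20180822))$timeseries
ratios <- study_ratios(ts[ts$camera == "external", ])
colMeans(ratios[c("tbr_0", "tbr_10", "brain_dark_30")])
#>  tbr_0        tbr_10 brain_dark_30
#>  4.67          2.98          3.15  # tumor-to-background collapses ~4.6 -> ~2.8-3

# Rater agreement on the packaged grading scores
agreement_summary(ppix_grading_scores())[2:4]
#> $overall_pairwise_pct  81.5
#> $fleiss_kappa_pct      75.1
#> $free_marginal_kappa_pct 76.9
```

The tumor-to-background ratio means say that tumor fluorescence starts
~4.6× brighter than adjacent brain and loses over a third of that contrast
within 10 min of continuous blue-light exposure; the agreement values say
four observers agree on 81.5 % of rater pairs, well above the 20 % expected
by chance for five categories.

The `analysis/` directory holds the numbered drivers of the full analysis
(calibration → simulation → quantification/normalization → kinetics →
agreement → camera comparison); each writes its tables under `results/`.

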