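# serrsmap

Quantitative analysis of hyperspectral Raman maps acquired with
surface-enhanced resonance Raman scattering (SERRS) nanoparticle contrast
agents. Antibody-functionalized SERRS nanoparticles bind cell-surface
markers (e.g. EGFR, HER2) in tumor tissue; a Raman microscope then raster
scans the tissue and records one spectrum per grid point. Each
nanoparticle carries a reporter dye with a sharp multi-peak fingerprint
whose dominant line sits at 950 cm⁻¹, superimposed on a broad fluorescence
background and substrate (well-plate plastic) lines around 1020 cm⁻¹. The
analytical task — and what this package implements for spectroscopists and
image analysts working with such probes — is to turn those raw maps into
biomarker readouts: where is the probe, how much is there, and do regions
of a tumor differ significantly in expression level.

## The method

Each point spectrum *y* is baseline-corrected with a Whittaker
penalized-least-squares smoother with asymmetric reweighting: the baseline
*z* minimises

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z)_i^2,
\qquad \lambda = 200,$$

where iteratively $w_i = p = 0.001$ for channels above the baseline and
$1-p$ below, so *z* relaxes onto the smooth lower envelope (the
fluorescence) and passes under the sharp Raman peaks. The banded normal
equations are solved exactly by an in-band Cholesky factorisation (Rcpp).
Negative corrected channels are clipped to zero ("noise rectification"),
which leaves a positive intensity floor (~2 × noise sd ≈ 50 cts/s at
defaults) in signal-free areas.

The quantification statistic is the **band intensity**: the mean corrected
intensity over 950–960 cm⁻¹ ("indicative intensity"). From it the package
derives intensity maps, rectangular-ROI summaries (channel-wise mean
spectra over all grid points in a region), a three-way expression
classification (high > 200 cts/s, negative ≤ 75 cts/s, low between),
pooled or Welch two-sample t-tests between ROIs, cosine-similarity
signature matching against a unit-norm reference fingerprint, and a
saturating (Langmuir-type) calibration

$$I(C) = \mathrm{floor} + I_{\max}\,\frac{C}{C + K_{1/2}},$$

whose algebraic inversion at threshold (blank mean + 3 × blank sd) gives
the limit of detection.

A deterministic synthetic generator (`generator_config()`,
`simulate_spectrum()`, `simulate_dilution_series()`, `simulate_phantom()`)
emulates the study inputs — fingerprint, fluorescence, substrate lines,
noise, saturating response, 150 × 130 µm map grid — with per-point random
streams keyed to coordinates, so the whole pipeline is exercisable end to
end with known ground truth and no instrument data.

## Worked example

```r
library(serrsmap)

cfg      <- generator_config(seed = 1)          # study conditions
phantom  <- simulate_phantom(config = cfg)      # 3 planted regions, 210 points
corrected <- correct_map(phantom$map)           # Whittaker baseline removal
heterogeneity_report(corrected, default_phantom_rois())
```

```
<heterogeneity_report> band 950-960 cm-1, thresholds high > 200, negative <= 75 cts/s
    label n_points indicative_intensity    class
     high       70            214.50211     high
      low       70             85.38822      low
 negative       70             49.29738 negative
pairwise comparisons:
 group_a  group_b   t_stat  df       p_value n_a n_b
    high      low 52.38792 138  5.879615e-93  70  70
    high negative 72.88462 138 4.743226e-112  70  70
     low negative 16.44356 138  2.550436e-34  70  70
```

Each ROI (1500 × 900 µm, 70 point spectra) is classified from its
indicative intensity; the planted high/low/negative regions are recovered,
and the pairwise Student t-tests on per-point intensities are all
significant. The "negative" region's ~49 cts/s is the rectified-noise
floor, not probe signal. A dilution series gives the detection limit:

```r
series <- simulate_dilution_series(config = cfg)
tab    <- quantify_series(series)               # correct + band-quantify
fit    <- fit_calibration(tab)
fit
limit_of_detection(tab, fit = fit)
```

```
<calibration_fit> I(C) = 47.79 + 888.3 * C / (C + 32.77 pM)
  residual SSE 4200; lod 1.263 pM
[1] 1.263221
```

i.e. a limit of detection of about 1 pM under the default noise model.

The numbered scripts under `analysis/` run these steps as a narrative
workflow (simulate → baseline → calibration/LOD → heterogeneity) and write
their tables under `results/`.

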