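---
title: "Methods: baseline removal, band quantification and ROI statistics for SERRS nanoparticle Raman maps"
author: "serrsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SERRS map analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serrsmap)
```

## The measurement and the analytical model

A hyperspectral Raman map is a grid of point spectra: at each (x, y)
position (micrometres; origin lower-left, y upward) the instrument records
counts per second against Raman shift (cm⁻¹). With SERRS nanoparticle
contrast agents the spectrum at each point is, to good approximation, an
additive mixture:

* a *nanoparticle fingerprint* — sharp reporter-dye lines, the dominant
  one at 950 cm⁻¹ — whose amplitude tracks the local probe concentration;
* a *broad fluorescence background*, smooth on the ~100 cm⁻¹ scale and
  much larger than the Raman lines;
* *substrate lines* (well-plate plastic, strongest near 1020 cm⁻¹),
  visible wherever the probe signal is low;
* noise.

Every downstream quantity in this package is a functional of the
baseline-corrected spectrum, so the analysis decomposes into: estimate and
subtract the background per point; summarise each corrected spectrum by
its 950–960 cm⁻¹ band mean (the *indicative intensity*); then aggregate —
spatially (intensity maps), over rectangular ROIs (mean spectra,
expression classes, t-tests), or over a dilution series (calibration curve
and limit of detection).

## Baseline estimation

`whittaker_smooth()` solves the penalized least-squares problem
$\min_z \sum_i w_i (y_i-z_i)^2 + \lambda \sum_i (\Delta^d z_i)^2$ exactly:
the normal equations $(W + \lambda D^\top D) z = W y$ are symmetric
positive definite and banded with bandwidth $d$, and are factorised by a
banded Cholesky routine (Rcpp) in $O(n d^2)$. A dense `solve()` on the
same normal equations serves as the independent oracle in the tests.

`estimate_baseline()` wraps the smoother in asymmetric reweighting:
starting from unit weights, channels above the current fit get weight
`asym_p` and channels below it `1 − asym_p`, iterated until the weight
pattern is stable (`tol`) or `max_iter` is reached; non-convergence
returns the last iterate flagged in `meta`. With `asym_p` small the fit
relaxes onto the smooth *lower envelope* of the spectrum — the
fluorescence — and bridges under the sharp peaks.

Parameters, defaults, and why:

| parameter | default | meaning |
|---|---|---|
| `lam` | 200 | smoothness penalty; dimensionless (penalty acts on channel index) |
| `diff_order` | 2 | order of the difference penalty |
| `asym_p` | 0.001 | weight of above-baseline channels |
| `max_iter` / `tol` | 20 / 1e-6 | reweighting iterations / weight-change stop |
| `clip_negative` | TRUE | rectify negative corrected channels |

λ = 200 is the filter setting used for fluorescence removal in this
pipeline; with d = 2 it corresponds to an equivalent smoothing bandwidth
of roughly λ^{1/4} ≈ 4 channels for equally weighted data, and about
(λ/asym_p)^{1/4} ≈ 21 channels when bridging under a peak where all
weights are `asym_p`. The penalty operates on channel index, not
wavenumber: non-uniform axes are accepted but penalized by index, a
deliberate simplification shared with common implementations and adequate
for the near-uniform 1.07 cm⁻¹ gratings this targets.

### Two systematic effects worth knowing about

**The rectified floor.** On noise-only regions the asymmetric fit tracks
the lower noise envelope, converging ≈ 2σ *below* the true background (σ =
noise sd; the self-consistent envelope depth for `asym_p` = 0.001 at λ =
200). The corrected, clipped intensity of signal-free areas therefore sits
near 2σ — *not* near the clipped-Gaussian mean σ/√(2π) ≈ 0.4σ that an
unbiased baseline would leave. With the generator's σ = 25 cts/s this
floor lands at ≈ 50 cts/s, and it is *additive*: a region with clean
in-band signal S reads ≈ S + floor.

**Peak flank pull.** The small but nonzero weight on above-baseline
channels lets tall peaks pull the baseline up locally (for a 1500 cts/s
peak of default width, ≈ 7% of the background level at the peak centre).
The net effect on recovered band intensities is a downward bias growing
with signal, partially cancelling the floor: at the half-saturation
concentration recovered intensities are within 10% of ground truth for
~96% of spectra, degrading towards low concentrations where the floor
dominates relative error.

**Stiff-limit behaviour.** As λ → ∞ the d = 2 smoother tends to the
ordinary least-squares line, but only at rate 1/(1 + λμ_min) with
μ_min ≈ 16 sin⁴(π/2n): reaching the line to 1e-6 at n = 50 requires
λ ≳ 1e10, i.e. λ must grow like n⁴. Tests of the limit therefore use
short series or very large λ.

## Quantification

`band_intensity()` is the arithmetic mean over channels whose *centre*
lies in the closed interval [lo, hi] (default 950–960 cm⁻¹, covering the
main fingerprint peak); inclusive edges and centre-based membership make
the statistic deterministic and exactly linear in the spectrum — the basis
for the identity `band(mean spectrum) = mean(per-point bands)` asserted on
every ROI summary. `signature_similarity()` linearly resamples a spectrum
onto the reference axis and returns the cosine similarity, invariant to
positive scaling of either side.

`fit_calibration()` fits $I(C) = \mathrm{floor} + I_{\max} C/(C+K_{1/2})$
by Levenberg–Marquardt (`minpack.lm::nlsLM`) with all parameters bounded
below by 0, so the fitted curve is monotone increasing by construction.
The saturating two-parameter form is the simplest monotone model
consistent with the observed nonlinear concentration response; the fit
interface is the single place the form enters, so other monotone curves
could be swapped in. Flat series return a degenerate fit (i_max = 0, LOD
= ∞) rather than an error. `limit_of_detection()` uses the conventional
3σ criterion — lowest C with fitted I(C) ≥ blank mean + k·sd(blank),
k = 3 by default — solved by algebraic inversion of the model; ∞ when the
curve never reaches the threshold, 0 when the threshold does not exceed
the fitted floor, and an error (unless an external sd is supplied) when
the blank replicates are identical.

## ROI statistics

ROI membership is half-open (`x0 ≤ x < x0+width`, same in y) so adjacent
tiled ROIs partition a map without double counting. `compare_rois()`
performs a two-sided two-sample t-test on *per-point band intensities*
(the regional quantity being compared is a mean intensity, not a
spectrum), pooled-variance Student by default with Welch as an option; a
textbook implementation of the pooled statistic is kept in the test suite
as an independent oracle. Degenerate zero-variance inputs follow fixed
conventions (p = 1 for equal means, p = 0 flagged otherwise).
`classify_expression()` maps intensity to high (> 200 cts/s) / low /
negative (≤ 75 cts/s): 200 cts/s reflects the high-expression regime and
75 cts/s splits the ~100 cts/s low-expression and ~50 cts/s floor regimes
at their midpoint — the low/negative cut is an interpretation, exposed as
a parameter. No multiple-testing correction is applied across ROI pairs
(reports involve a handful of planned comparisons; callers doing many
comparisons should adjust downstream).

## The synthetic generator, and what it does and does not emulate

`generator_config()` fixes the study conditions: axis 600–1800 cm⁻¹ at
1.07 cm⁻¹; a nine-line Gaussian fingerprint (σ = 8–12 cm⁻¹) dominant at
950 cm⁻¹; five plastic lines, strongest at 1020 cm⁻¹, peak 8 cts/s; a
broad Gaussian fluorescence (amplitude 2000 cts/s, sd 450 cm⁻¹, offset
300 cts/s); additive Gaussian noise σ = 25 cts/s (chosen so the rectified
floor lands near 50 cts/s; an optional shot-noise term adds variance equal
to the clean counts); and a saturating response with K½ = 30 pM scaled so
the in-band intensity saturates at 1000 cts/s — together these put the 3σ
detection limit of a triplicate half-decade dilution series near 1 pM.
The default 150 × 130 µm pixel pitch makes a 1500 × 900 µm half-open ROI
hold exactly 10 × 7 = 70 grid points, matching the per-region spectrum
count the ROI statistics are designed around. Phantom regions planted by
`target` intensity subtract the expected floor before inverting the
response, so targets of 250/100/50 cts/s yield clean signals of 200/50/0.

Determinism: one integer seed drives everything; each point's noise
stream is seeded from a mix of the global seed and its (x, y) coordinates
(exact 31-bit integer arithmetic), so regenerating a map — in any point
order, or embedded in a larger map — reproduces byte-identical spectra.

What the generator does *not* emulate: cosmic-ray spikes, detector
saturation and étaloning, wavenumber miscalibration drift, spatially
correlated fluorescence (each point's background is identical in shape),
optical effects of tissue depth, and probe pharmacokinetics. Passing
tests on phantoms therefore validate the *algorithms* under the stated
noise model, not instrument- or tissue-specific robustness.

## Numerical choices and degenerate inputs

* Banded Cholesky requires positive definiteness: guaranteed for weights
  > 0 and λ ≥ 0; all-zero weights are rejected before the solve.
* `D^T D` bands are built from closed-form binomial products and memoized
  per (length, order).
* Readers sort points by (y, x) and rows by shift, so file row order never
  matters; duplicate shifts and ragged per-point axes are errors naming
  the offending line or point.
* Values are written with 9 significant digits; round-trips are exact at
  that precision.
* Calibration starting values come from the blank mean, the intensity
  range and the concentration nearest half-range; the fit requires ≥ 4
  distinct concentrations including a blank.
* Boundary rules: band edges inclusive; classification strict at
  `t_high`, inclusive at `t_neg`; ROI edges half-open.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: solver oracles on ≤ 50-channel instances; 50-spectrum
recovery runs at the half-saturation concentration (mid dynamic range,
where relative recovery is cleanest); triplicate 10-point dilution
series; and 20–50 replicate phantoms of 210 spectra (three 70-point
regions) for classification accuracy and test power. These sizes give
stable statistics for every property checked while keeping a full run in
minutes on one core.

## Known limitations

* λ interpreted as dimensionless (penalty on channel index); the "cm⁻¹"
  sometimes attached to Whittaker λ values is treated as a labeling
  artifact.
* The floor/flank biases described above mean absolute corrected
  intensities carry a systematic component of order 2σ; comparisons and
  classifications that operate on the same footing (as here) are
  unaffected, but cross-instrument absolute comparisons would need the
  floor characterised.
* Single-species quantification only: no spectral unmixing of multiple
  nanoparticle flavors, no Lorentzian/Voigt peak fitting, no wavenumber
  recalibration.
* Expression classes depend on instrument-specific count scales; the
  defaults are meaningful only for data acquired and corrected
  consistently with this pipeline.
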