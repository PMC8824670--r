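#!/usr/bin/env Rscript
# Step 2 — fluorescence-baseline removal and band quantification.
#
# Regenerates the phantom of step 1, removes the broad fluorescence
# background from every point spectrum with the asymmetrically reweighted
# Whittaker smoother (lambda = 200), and maps the 950-960 cm^-1 band
# intensity. Reports how well corrected intensities track the generator's
# ground truth and where the rectified-noise background floor sits.

library(serrsmap)
seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = seed)
ph <- simulate_phantom(config = cfg)
corrected <- correct_map(ph$map)
im <- intensity_map(corrected)
utils::write.csv(im, "results/intensity_map.csv", row.names = FALSE)

# observed intensity = clean in-band signal + rectified-noise floor, so
# compare each region's mean against (planted clean value + floor)
floor_est <- mean(im$intensity[ph$truth$clean_band == 0])
cat(sprintf("corrected %d spectra; background floor (rectified noise): %.1f cts/s\n",
            n_points(ph$map), floor_est))
for (lbl in unique(ph$truth$label)) {
  sel <- ph$truth$label == lbl
  expected <- mean(ph$truth$clean_band[sel]) + floor_est
  cat(sprintf("  region %-8s mean %6.1f cts/s (planted clean %3.0f; clean + floor = %.0f)\n",
              lbl, mean(im$intensity[sel]), mean(ph$truth$clean_band[sel]),
              expected))
}
cat("  (means sit slightly below clean + floor: the asymmetric baseline is\n",
    "  pulled up by the peak flanks, an effect that grows with signal)\n")
# quantitative recovery at mid dynamic range (half-saturation concentration)
cfg2 <- generator_config(seed = seed + 1L)
truth_mid <- clean_band_intensity(cfg2$response$k_half, cfg2)
err_mid <- vapply(1:25, function(i) {
  s <- simulate_spectrum(cfg2$response$k_half, cfg2, seed = 600 + i)
  abs(band_intensity(subtract_baseline(s)) - truth_mid) / truth_mid
}, numeric(1))
cat(sprintf("mid-range recovery (C = k_half): %.0f%% of spectra within 10%% of truth\n",
            100 * mean(err_mid < 0.10)))
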