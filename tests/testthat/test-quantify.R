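test_that("band_intensity is the mean over channels inside the closed band", {
  s_const <- spectrum(seq(940, 970, by = 1.07), rep(42, 29))
  expect_equal(band_intensity(s_const, band(950, 960)), 42)

  # single hot channel: value / number of channels in the band,
  # channel count by independent enumeration
  axis <- seq(940, 970, by = 1.07)
  inten <- rep(0, length(axis))
  hot <- which.min(abs(axis - 950.6))
  inten[hot] <- 110
  n_in_band <- sum(vapply(axis, function(a) a >= 950 && a <= 960, logical(1)))
  expect_equal(band_intensity(spectrum(axis, inten), band(950, 960)),
               110 / n_in_band)

  expect_error(band_intensity(s_const, band(2000, 2100)), "overlaps no channel")
})

test_that("band_intensity is linear in the spectrum", {
  set.seed(11)
  axis <- seq(600, 1800, by = 1.07)
  bd <- band(950, 960)
  for (i in 1:20) {
    i1 <- rexp(length(axis), 1 / 100); i2 <- rnorm(length(axis), 50, 10)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    comb <- spectrum(axis, a * i1 + b * i2)
    expect_equal(band_intensity(comb, bd),
                 a * band_intensity(spectrum(axis, i1), bd) +
                   b * band_intensity(spectrum(axis, i2), bd),
                 tolerance = 1e-12)
  }
})

test_that("intensity_map preserves coordinates and finds planted hot spots", {
  vals <- matrix(c(rep(10, 3), rep(10, 3), rep(99, 3), rep(10, 3)), 4, 3,
                 byrow = TRUE)
  m <- toy_map(vals)
  im <- intensity_map(m, band(940, 960))
  expect_equal(nrow(im), 4L)
  expect_equal(im$x, m$x)
  expect_equal(im$intensity, rowMeans(vals))
  expect_error(intensity_map(m, band(2000, 2100)), "overlaps no channel")

  # synthetic disk of nanoparticle signal: top-decile points stay inside
  # the disk dilated by one pixel
  cfg <- generator_config(seed = 31, pixel_pitch = c(100, 100))
  layout <- list(list(label = "disk", shape = "disk", cx = 1000, cy = 1000,
                      r = 500, concentration = 100))
  ph <- simulate_phantom(layout, cfg, map_size = c(2000, 2000))
  cm <- correct_map(ph$map)
  im2 <- intensity_map(cm)
  top <- im2[order(-im2$intensity), ][seq_len(ceiling(nrow(im2) / 10)), ]
  pitch <- max(cfg$pixel_pitch)
  inside_dilated <- sqrt((top$x - 1000)^2 + (top$y - 1000)^2) <= 500 + pitch
  expect_true(all(inside_dilated))
})

test_that("signature similarity is scale-invariant and separates shapes", {
  cfg <- generator_config(seed = 41)
  ref <- make_signature(cfg)
  scaled <- spectrum(ref$spectrum$shift, 37.5 * ref$spectrum$intensity)
  expect_equal(signature_similarity(scaled, ref), 1.0, tolerance = 1e-12)

  # disjoint single-channel supports are orthogonal
  axis <- seq(940, 960, by = 1)
  a <- rep(0, 21); a[5] <- 1
  b <- rep(0, 21); b[15] <- 1
  ref_b <- reference_signature(spectrum(axis, b))
  expect_equal(signature_similarity(spectrum(axis, a), ref_b), 0)

  # nanoparticle spectrum vs substrate-only spectrum, both corrected
  np <- subtract_baseline(simulate_spectrum(300, cfg, seed = 1))
  plastic_cfg <- generator_config(seed = 41, substrate_amplitude = 60)
  plastic <- subtract_baseline(simulate_spectrum(0, plastic_cfg, seed = 2))
  expect_lt(signature_similarity(plastic, ref), 0.5)
  expect_gt(signature_similarity(np, ref), 0.9)

  expect_error(
    signature_similarity(spectrum(axis, rep(0, 21)), ref_b), "zero norm")
})

test_that("fit_calibration recovers exact parameters from noiseless data", {
  conc <- c(0, 0, 10, 100, 1000, 10000)
  inten <- 50 + 1000 * conc / (conc + 100)
  fit <- fit_calibration(data.frame(concentration = conc, intensity = inten))
  expect_lt(abs(fit$i_max - 1000) / 1000, 0.01)
  expect_lt(abs(fit$k_half - 100) / 100, 0.01)
  expect_lt(abs(fit$floor - 50) / 50, 0.01)
  expect_false(fit$degenerate)
  expect_equal(predict(fit, 100), 50 + 1000 * 100 / 200, tolerance = 1e-6)
})

test_that("degenerate and invalid series are handled", {
  flat <- data.frame(concentration = c(0, 0, 1, 10, 100),
                     intensity = rep(77, 5))
  fit <- fit_calibration(flat)
  expect_true(fit$degenerate)
  expect_equal(fit$i_max, 0)
  expect_equal(fit$lod, Inf)

  blank_only <- data.frame(concentration = rep(0, 5), intensity = rnorm(5))
  expect_error(fit_calibration(blank_only), "distinct concentrations")
  expect_error(
    fit_calibration(data.frame(concentration = c(-1, 0, 1, 10),
                               intensity = 1:4)), "negative")
  expect_error(
    fit_calibration(data.frame(concentration = c(1, 10, 100, 1000),
                               intensity = 1:4)), "blank")
})

test_that("limit_of_detection inverts the fitted curve algebraically", {
  fit <- structure(list(i_max = 1000, k_half = 100, floor = 50,
                        degenerate = FALSE), class = "calibration_fit")
  series <- data.frame(concentration = c(0, 0, 10, 100, 1000),
                       intensity = c(50, 50, 140, 560, 950))
  # threshold floor + 3 * 2 = 56 -> C* = 100 * 6 / (1000 - 6)
  expect_equal(limit_of_detection(series, k_sigma = 3, fit = fit,
                                  sd_blank = 2),
               600 / 994, tolerance = 1e-6)
  # never reached
  expect_equal(limit_of_detection(series, fit = fit, sd_blank = 1000), Inf)
  # k_sigma = 0: threshold at the blank mean, exceeded for any C > 0
  expect_equal(limit_of_detection(series, k_sigma = 0, fit = fit,
                                  sd_blank = 2), 0)
  # identical blanks without an external sd are degenerate
  expect_error(limit_of_detection(series, fit = fit), "identical")
})

test_that("LOD is monotone non-decreasing in the blank spread", {
  fit <- structure(list(i_max = 1000, k_half = 100, floor = 50,
                        degenerate = FALSE), class = "calibration_fit")
  series <- data.frame(concentration = c(0, 0, 10, 100, 1000),
                       intensity = c(50, 50, 140, 560, 950))
  lods <- vapply(c(0.5, 1, 2, 5, 20, 100, 400),
                 function(s) limit_of_detection(series, fit = fit,
                                                sd_blank = s), numeric(1))
  expect_true(all(diff(lods) >= 0))
})

test_that("calibration recovery stays accurate under multiplicative noise", {
  set.seed(13)
  conc <- rep(c(0, 1, 3, 10, 30, 100, 300, 1000, 3000), each = 3)
  errs <- t(replicate(100, {
    inten <- (50 + 1000 * conc / (conc + 100)) * (1 + rnorm(length(conc), 0, 0.05))
    fit <- fit_calibration(data.frame(concentration = conc, intensity = inten))
    c(abs(fit$i_max - 1000) / 1000, abs(fit$k_half - 100) / 100)
  }))
  expect_lt(stats::median(errs[, 1]), 0.10)
  expect_lt(stats::median(errs[, 2]), 0.10)
})
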