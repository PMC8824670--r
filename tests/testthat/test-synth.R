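test_that("reference signature peaks at 950 cm-1 and has unit norm", {
  single <- generator_config(
    np_signature = data.frame(center = 950, width = 8, height = 1))
  sig1 <- make_signature(single)
  expect_equal(sqrt(sum(sig1$spectrum$intensity^2)), 1, tolerance = 1e-12)
  expect_lt(abs(sig1$spectrum$shift[which.max(sig1$spectrum$intensity)] - 950),
            1.07)

  sig <- make_signature(generator_config())
  expect_lt(abs(sig$spectrum$shift[which.max(sig$spectrum$intensity)] - 950),
            1.07 + 1e-9)

  bad_lines <- data.frame(center = c(950, 3000), width = 8, height = c(1, 0.5))
  expect_error(generator_config(np_signature = bad_lines), "outside the axis")
  off_dominant <- data.frame(center = c(950, 1200), width = 8,
                             height = c(0.5, 1))
  expect_error(generator_config(np_signature = off_dominant), "dominant")
})

test_that("simulated spectra decompose as response + background + substrate", {
  cfg <- generator_config(noise_sd = 0)
  blank <- simulate_spectrum(0, cfg)
  no_substrate <- generator_config(noise_sd = 0, substrate_amplitude = 1e-12)
  background_only <- simulate_spectrum(0, no_substrate)
  substrate <- blank$intensity - background_only$intensity
  # blank minus the true background leaves only substrate lines, whose
  # contribution inside the quantification band is negligible
  expect_equal(max(substrate) / cfg$substrate_amplitude, 1, tolerance = 0.01)
  expect_lt(band_intensity(spectrum(cfg$axis, substrate), band(950, 960)), 1)

  # saturation: in-band excess approaches sat_band as concentration grows
  sat <- simulate_spectrum(1e9, cfg)
  excess <- band_intensity(spectrum(cfg$axis, sat$intensity - blank$intensity),
                           band(950, 960))
  expect_equal(excess, cfg$sat_band, tolerance = 1e-4)

  expect_error(simulate_spectrum(-1, cfg), ">= 0")
})

test_that("expected in-band intensity follows the saturating response", {
  cfg <- generator_config(noise_sd = 0)
  for (C in c(0, 1, 30, 500)) {
    s <- simulate_spectrum(C, cfg)
    blank <- simulate_spectrum(0, cfg)
    measured <- band_intensity(
      spectrum(cfg$axis, s$intensity - blank$intensity), band(950, 960))
    expect_equal(measured, clean_band_intensity(C, cfg), tolerance = 1e-9)
  }
  # inversion round trip
  expect_equal(clean_band_intensity(
    concentration_for_intensity(200, cfg), cfg), 200, tolerance = 1e-9)
  expect_error(concentration_for_intensity(2000, cfg), "saturating")
})

test_that("generation is deterministic and independent of point order", {
  cfg <- generator_config(seed = 77)
  s1 <- simulate_spectrum(10, cfg, seed = 5)
  s2 <- simulate_spectrum(10, cfg, seed = 5)
  expect_identical(s1$intensity, s2$intensity)

  layout <- list(list(label = "spot", shape = "rect", x0 = 0, y0 = 0,
                      width = 600, height = 260, concentration = 20))
  ph1 <- simulate_phantom(layout, cfg, map_size = c(1200, 400))
  ph2 <- simulate_phantom(layout, cfg, map_size = c(1200, 400))
  f1 <- tempfile(); f2 <- tempfile()
  write_map_long(ph1$map, f1)
  write_map_long(ph2$map, f2)
  expect_identical(readLines(f1), readLines(f2))

  # a point's spectrum depends only on its coordinates and the seed,
  # not on how large the surrounding map is
  ph3 <- simulate_phantom(layout, config = cfg, map_size = c(600, 400))
  key1 <- paste(ph1$map$x, ph1$map$y)
  key3 <- paste(ph3$map$x, ph3$map$y)
  shared <- intersect(key1, key3)
  expect_gt(length(shared), 0)
  expect_identical(ph1$map$intensities[match(shared, key1), ],
                   ph3$map$intensities[match(shared, key3), ])
})

test_that("dilution series are reproducible and carry ground truth", {
  cfg <- generator_config(seed = 101)
  ser1 <- simulate_dilution_series(c(0, 1, 10, 100), replicates = 2,
                                   config = cfg)
  ser2 <- simulate_dilution_series(c(0, 1, 10, 100), replicates = 2,
                                   config = cfg)
  expect_identical(ser1$spectrum[[3]]$intensity, ser2$spectrum[[3]]$intensity)
  expect_equal(attr(ser1, "truth")$i_max_band, cfg$sat_band)
  expect_error(simulate_dilution_series(c(1, 10, 100), config = cfg), "blank")
  expect_error(simulate_dilution_series(c(0, 1), replicates = 1, config = cfg),
               "replicates")
})

test_that("phantom layouts plant concentrations with last-wins overlap", {
  cfg <- generator_config(seed = 3, noise_sd = 0)
  # empty layout: uniform blank map, everything classifies negative
  ph0 <- simulate_phantom(list(), cfg, map_size = c(600, 400))
  expect_true(all(ph0$truth$concentration == 0))
  expect_true(all(ph0$truth$label == "negative"))
  cm <- correct_map(ph0$map)
  expect_true(all(classify_expression(intensity_map(cm)$intensity) ==
                    "negative"))

  # overlapping regions: the later region overwrites the earlier
  layout <- list(
    list(label = "big", shape = "rect", x0 = 0, y0 = 0, width = 600,
         height = 400, concentration = 10),
    list(label = "inner", shape = "rect", x0 = 150, y0 = 130, width = 150,
         height = 130, concentration = 99))
  ph <- simulate_phantom(layout, cfg, map_size = c(600, 400))
  inner <- ph$truth$x >= 150 & ph$truth$x < 300 &
    ph$truth$y >= 130 & ph$truth$y < 260
  expect_true(all(ph$truth$concentration[inner] == 99))
  expect_true(all(ph$truth$label[inner] == "inner"))
  expect_true(all(ph$truth$concentration[!inner] == 10))

  expect_error(
    simulate_phantom(list(list(label = "out", shape = "rect", x0 = 500,
                               y0 = 0, width = 200, height = 100,
                               concentration = 1)),
                     cfg, map_size = c(600, 400)), "outside map bounds")
})

test_that("noisy band intensities converge to the noiseless value", {
  cfg <- generator_config(seed = 55)
  clean_cfg <- generator_config(noise_sd = 0)
  target <- band_intensity(simulate_spectrum(30, clean_cfg), band(950, 960))
  vals <- vapply(seq_len(500), function(i)
    band_intensity(simulate_spectrum(30, cfg, seed = 7000 + i),
                   band(950, 960)),
    numeric(1))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - target), 3 * se)
})

test_that("planted regions are recovered by the full pipeline across seeds", {
  correct <- 0L
  for (s in 1:5) {
    cfg <- generator_config(seed = 400 + s)
    ph <- simulate_phantom(config = cfg)
    rep_ <- heterogeneity_report(correct_map(ph$map), default_phantom_rois())
    correct <- correct +
      sum(rep_$summary$class == c("high", "low", "negative"))
  }
  expect_gte(correct / 15, 0.95)
})
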