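#' Synthetic SERRS map generator configuration
#'
#' Collects every knob of the synthetic hyperspectral generator: the shared
#' Raman-shift axis, the nanoparticle fingerprint (a sum of Gaussian lines
#' with its dominant line at 950 cm^-1), the substrate (well-plate plastic)
#' lines around 1020 cm^-1, a broad smooth fluorescence background, the
#' noise model, the saturating concentration-to-amplitude response and the
#' map grid pitch. With a fixed seed the generator is fully deterministic,
#' and per-point random streams are derived from the point coordinates so
#' that point order never changes the output.
#'
#' @param axis_start,axis_stop,axis_step Raman-shift axis in cm^-1; the
#'   default 600-1800 cm^-1 at 1.07 cm^-1 spacing mimics a dispersive
#'   instrument's fingerprint window.
#' @param np_signature Data frame `center, width, height` (cm^-1, cm^-1
#'   Gaussian sd, relative height) of the nanoparticle reporter lines; the
#'   dominant line must be at 950 cm^-1.
#' @param substrate_signature Data frame of substrate (plastic) lines,
#'   relative heights, strongest at 1020 cm^-1.
#' @param substrate_amplitude Peak substrate intensity in cts/s.
#' @param bg_amplitude,bg_center,bg_width,bg_offset Broad Gaussian
#'   fluorescence background (cts/s, cm^-1, cm^-1 sd, cts/s constant offset).
#' @param noise_sd Additive Gaussian noise sd in cts/s. The default 25 cts/s
#'   makes the rectified-noise background floor of the correction pipeline
#'   land near 50 cts/s.
#' @param shot_noise Add a heteroscedastic (Gaussian-approximated shot)
#'   component with variance equal to the clean total counts.
#' @param k_half Concentration at half-maximal response, pM.
#' @param sat_band Saturating in-band (950-960 cm^-1) intensity in cts/s at
#'   infinite concentration; the amplitude scale `i_max` of the response is
#'   derived from it and the band mean of the unit-norm signature.
#' @param response_floor Concentration-independent response offset
#'   (amplitude units); default 0.
#' @param pixel_pitch Map grid spacing `c(dx, dy)` in micrometres. The
#'   default `c(150, 130)` makes a 1500 x 900 um ROI hold exactly 10 x 7 =
#'   70 grid points.
#' @param expected_floor Rectified-noise background floor in cts/s that the
#'   defaults produce after baseline correction (used when planting regions
#'   by target observed intensity).
#' @param seed Integer seed driving all randomness.
#' @return A list of class `generator_config`; `$response$i_max` holds the
#'   derived amplitude scale and `$band_mean` the in-band mean of the
#'   unit-norm signature.
#' @export
generator_config <- function(axis_start = 600, axis_stop = 1800,
                             axis_step = 1.07,
                             np_signature = default_np_signature(),
                             substrate_signature = default_substrate_signature(),
                             substrate_amplitude = 8,
                             bg_amplitude = 2000, bg_center = 1250,
                             bg_width = 450, bg_offset = 300,
                             noise_sd = 25, shot_noise = FALSE,
                             k_half = 30, sat_band = 1000,
                             response_floor = 0,
                             pixel_pitch = c(150, 130),
                             expected_floor = 50,
                             seed = 1L) {
  if (!(axis_step > 0)) stop("axis_step must be positive")
  axis <- seq(axis_start, axis_stop, by = axis_step)
  check_lines <- function(df, what) {
    if (!all(c("center", "width", "height") %in% names(df)))
      stop(what, " must have columns center, width, height")
    if (nrow(df) < 1L) stop(what, " must define at least one line")
    if (any(df$width <= 0) || any(df$height <= 0))
      stop(what, " widths and heights must be positive")
    if (any(df$center < axis_start | df$center > axis_stop))
      stop(what, " line centers outside the axis: ",
           paste(df$center[df$center < axis_start | df$center > axis_stop],
                 collapse = ", "))
  }
  check_lines(np_signature, "np_signature")
  check_lines(substrate_signature, "substrate_signature")
  dom <- np_signature$center[which.max(np_signature$height)]
  if (abs(dom - 950) > 1e-9)
    stop("the dominant nanoparticle line must be at 950 cm-1, got ", dom)
  if (!(noise_sd >= 0)) stop("noise_sd must be >= 0")
  if (!(k_half > 0)) stop("k_half must be > 0")
  if (!(sat_band > 0)) stop("sat_band must be > 0")
  if (length(pixel_pitch) != 2L || any(pixel_pitch <= 0))
    stop("pixel_pitch must be c(dx, dy), both positive")

  sig <- gaussian_lines(axis, np_signature)
  sig <- sig / sqrt(sum(sig^2))
  in_band <- axis >= 950 & axis <= 960
  band_mean <- mean(sig[in_band])
  cfg <- list(axis = axis,
              np_signature = np_signature,
              substrate_signature = substrate_signature,
              substrate_amplitude = substrate_amplitude,
              background = c(amplitude = bg_amplitude, center = bg_center,
                             width = bg_width, offset = bg_offset),
              noise = list(sd = noise_sd, shot = shot_noise),
              response = list(i_max = sat_band / band_mean, k_half = k_half,
                              floor = response_floor),
              band_mean = band_mean,
              sat_band = sat_band,
              pixel_pitch = as.numeric(pixel_pitch),
              expected_floor = expected_floor,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config> axis %g-%g cm-1 (%d channels), ",
                     "noise sd %g cts/s,\n  response sat %g cts/s in-band, ",
                     "k_half %g pM, pitch %g x %g um, seed %d\n"),
              min(x$axis), max(x$axis), length(x$axis), x$noise$sd,
              x$sat_band, x$response$k_half,
              x$pixel_pitch[1], x$pixel_pitch[2], x$seed))
  invisible(x)
}

#' @rdname generator_config
#' @export
default_np_signature <- function() {
  data.frame(
    center = c(820, 882, 950, 1008, 1128, 1204, 1342, 1524, 1598),
    width  = c(  8,   9,   8,    8,    9,   10,   12,   10,    9),
    height = c(0.30, 0.25, 1.00, 0.20, 0.35, 0.40, 0.30, 0.25, 0.20))
}

#' @rdname generator_config
#' @export
default_substrate_signature <- function() {
  data.frame(
    center = c(810, 1020, 1062, 1295, 1450),
    width  = c(  7,    6,    7,    9,    9),
    height = c(0.30, 1.00, 0.45, 0.25, 0.50))
}

gaussian_lines <- function(axis, lines) {
  out <- numeric(length(axis))
  for (i in seq_len(nrow(lines)))
    out <- out + lines$height[i] *
      exp(-(axis - lines$center[i])^2 / (2 * lines$width[i]^2))
  out
}

# evaluate code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derived per-point seed: mixes the global seed with the (x, y) coordinates
# (0.1 um resolution) so that point order never changes a point's spectrum.
# Multipliers stay below 2^16 so all products are exact in doubles.
point_seed <- function(seed, x, y) {
  xi <- round(x * 10) %% 1048576
  yi <- round(y * 10) %% 1048576
  h <- seed %% 2147483647
  h <- (h * 69069 + xi + 1) %% 2147483647
  h <- (h %% 1048576 * 69069 + yi + 1) %% 2147483647
  h <- (h %% 1048576 * 69069 + 97) %% 2147483647
  as.integer(h)
}

#' Build the nanoparticle reference signature
#'
#' Sum of the configured Gaussian reporter lines on the configured axis,
#' scaled to unit L2 norm. The dominant line sits at 950 cm^-1 by
#' construction (enforced by [generator_config]).
#'
#' @param config A [generator_config].
#' @param name Signature name.
#' @return A [reference_signature].
#' @export
make_signature <- function(config = generator_config(), name = "SERRS-NP") {
  stopifnot(inherits(config, "generator_config"))
  sig <- gaussian_lines(config$axis, config$np_signature)
  reference_signature(spectrum(config$axis, sig), name = name)
}

# saturating concentration -> signature amplitude
response_amplitude <- function(concentration, config) {
  r <- config$response
  r$floor + r$i_max * concentration / (concentration + r$k_half)
}

#' Expected noiseless in-band intensity at a concentration
#'
#' The band (950-960 cm^-1) intensity an ideal baseline removal would leave:
#' `response(concentration) * band_mean(signature)`.
#'
#' @param concentration Concentration(s) in pM.
#' @param config A [generator_config].
#' @return Intensity in counts/s.
#' @export
clean_band_intensity <- function(concentration, config = generator_config()) {
  response_amplitude(concentration, config) * config$band_mean
}

#' Concentration producing a target clean in-band intensity
#'
#' Inverts the saturating response: returns the concentration whose
#' noiseless in-band intensity equals `target` cts/s.
#'
#' @param target Clean in-band intensity in cts/s, below the saturating
#'   value `sat_band`.
#' @param config A [generator_config].
#' @return Concentration in pM.
#' @export
concentration_for_intensity <- function(target, config = generator_config()) {
  if (any(target < 0)) stop("target intensity must be >= 0")
  if (any(target >= config$sat_band))
    stop("target intensity at or above the saturating in-band value (",
         config$sat_band, " cts/s)")
  config$response$k_half * target / (config$sat_band - target)
}

#' Simulate one raw spectrum
#'
#' Raw spectrum = response(concentration) x unit signature + broad
#' fluorescence background + substrate lines + noise, all in counts/s.
#'
#' @param concentration Nanoparticle concentration in pM, `>= 0`.
#' @param config A [generator_config].
#' @param seed Seed for this spectrum's noise; defaults to `config$seed`.
#' @return A raw (uncorrected) [spectrum]; `meta$concentration` and
#'   `meta$clean_band` record the ground truth.
#' @export
simulate_spectrum <- function(concentration, config = generator_config(),
                              seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (concentration < 0) stop("concentration must be >= 0")
  axis <- config$axis
  sig <- gaussian_lines(axis, config$np_signature)
  sig <- sig / sqrt(sum(sig^2))
  np <- response_amplitude(concentration, config) * sig
  substrate <- config$substrate_amplitude *
    gaussian_lines(axis, config$substrate_signature)
  bg <- config$background
  background <- bg["amplitude"] *
    exp(-(axis - bg["center"])^2 / (2 * bg["width"]^2)) + bg["offset"]
  clean <- np + substrate + unname(background)
  noisy <- with_seed(seed, {
    out <- clean
    if (config$noise$sd > 0)
      out <- out + stats::rnorm(length(axis), 0, config$noise$sd)
    if (isTRUE(config$noise$shot))
      out <- out + stats::rnorm(length(axis), 0, sqrt(pmax(clean, 0)))
    out
  })
  spectrum(axis, noisy,
           meta = list(concentration = concentration,
                       clean_band = clean_band_intensity(concentration, config),
                       seed = seed))
}

#' Simulate a dilution series
#'
#' Generates `replicates` raw spectra at each concentration, including the
#' mandatory blank, in the layout consumed by [quantify_series] /
#' [fit_calibration].
#'
#' @param concentrations Concentrations in pM; must include 0.
#' @param replicates Replicates per concentration, `>= 2`.
#' @param config A [generator_config].
#' @return Data frame with columns `concentration`, `replicate` and list
#'   column `spectrum`; the true response parameters are attached as
#'   attribute `truth`.
#' @export
simulate_dilution_series <- function(concentrations = c(0, 0.1, 0.3, 1, 3,
                                                        10, 30, 100, 300, 1000),
                                     replicates = 3,
                                     config = generator_config()) {
  if (!any(concentrations == 0)) stop("concentrations must include a blank (0 pM)")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (replicates < 2) stop("need at least 2 replicates per concentration")
  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration = sort(concentrations))
  grid <- grid[, c("concentration", "replicate")]
  seeds <- vapply(seq_len(nrow(grid)), function(i)
    point_seed(config$seed, grid$concentration[i] * 37 + i, i), integer(1))
  grid$spectrum <- lapply(seq_len(nrow(grid)), function(i)
    simulate_spectrum(grid$concentration[i], config, seed = seeds[i]))
  attr(grid, "truth") <- list(i_max_band = config$sat_band,
                              k_half = config$response$k_half,
                              band_mean = config$band_mean)
  grid
}

#' Simulate a tumor phantom map with known ground truth
#'
#' Lays out labeled regions of constant nanoparticle concentration on a
#' regular grid (pitch from the config) and simulates a raw spectrum at
#' every point. Later regions overwrite earlier ones where they overlap;
#' points outside every region are signal-free background (0 pM,
#' label `"negative"`).
#'
#' Regions are lists with fields `label`, `shape` (`"rect"` or `"disk"`),
#' the geometry (`x0, y0, width, height` for rectangles; `cx, cy, r` for
#' disks, all micrometres) and either `concentration` (pM) or `target`
#' (expected observed indicative intensity in cts/s; the planted
#' concentration is derived by subtracting the configured rectified-noise
#' floor and inverting the response).
#'
#' @param layout List of region definitions; see
#'   [default_phantom_layout] for the standard three-region phantom.
#' @param config A [generator_config].
#' @param map_size `c(width, height)` of the map in micrometres.
#' @return A list with `map` (raw [spectral_map]) and `truth` (data frame
#'   `x, y, concentration, label, clean_band`, aligned with the map points).
#' @export
simulate_phantom <- function(layout = default_phantom_layout(),
                             config = generator_config(),
                             map_size = c(4500, 910)) {
  stopifnot(inherits(config, "generator_config"))
  dx <- config$pixel_pitch[1]; dy <- config$pixel_pitch[2]
  # half-open coverage of [0, width) x [0, height)
  xs <- (seq_len(max(1L, floor(map_size[1] / dx + 1e-9))) - 1L) * dx
  ys <- (seq_len(max(1L, floor(map_size[2] / dy + 1e-9))) - 1L) * dy
  g <- expand.grid(x = xs, y = ys)
  n <- nrow(g)
  conc <- rep(0, n)
  label <- rep("negative", n)
  for (reg in layout) {
    if (is.null(reg$label)) stop("every region needs a label")
    shape <- if (is.null(reg$shape)) "rect" else reg$shape
    inside <- if (shape == "rect") {
      if (reg$x0 < 0 || reg$y0 < 0 ||
          reg$x0 + reg$width > map_size[1] + 1e-9 ||
          reg$y0 + reg$height > map_size[2] + 1e-9)
        stop("region '", reg$label, "' outside map bounds")
      g$x >= reg$x0 & g$x < reg$x0 + reg$width &
        g$y >= reg$y0 & g$y < reg$y0 + reg$height
    } else if (shape == "disk") {
      if (reg$cx - reg$r < 0 || reg$cy - reg$r < 0 ||
          reg$cx + reg$r > map_size[1] || reg$cy + reg$r > map_size[2])
        stop("region '", reg$label, "' outside map bounds")
      (g$x - reg$cx)^2 + (g$y - reg$cy)^2 <= reg$r^2
    } else stop("unknown region shape: ", shape)
    ci <- if (!is.null(reg$concentration)) reg$concentration
    else if (!is.null(reg$target))
      concentration_for_intensity(max(reg$target - config$expected_floor, 0),
                                  config)
    else stop("region '", reg$label, "' needs concentration or target")
    conc[inside] <- ci
    label[inside] <- reg$label
  }
  inten <- matrix(0, n, length(config$axis))
  for (i in seq_len(n)) {
    s <- simulate_spectrum(conc[i], config,
                           seed = point_seed(config$seed, g$x[i], g$y[i]))
    inten[i, ] <- s$intensity
  }
  map <- spectral_map(g$x, g$y, inten, config$axis,
                      pixel_pitch = config$pixel_pitch,
                      meta = list(generator_seed = config$seed))
  truth <- data.frame(x = g$x, y = g$y, concentration = conc, label = label,
                      clean_band = clean_band_intensity(conc, config))
  list(map = map, truth = truth)
}

#' Standard three-region heterogeneity phantom
#'
#' Three 1500 x 900 um rectangles side by side, planted so that the
#' pipeline's observed indicative intensities land near the reported
#' regimes: high ~250 cts/s, low ~100 cts/s, negative ~50 cts/s (the
#' rectified-noise floor).
#'
#' @return A list of region definitions for [simulate_phantom].
#' @export
default_phantom_layout <- function() {
  list(
    list(label = "high", shape = "rect", x0 = 0, y0 = 0,
         width = 1500, height = 910, target = 250),
    list(label = "low", shape = "rect", x0 = 1500, y0 = 0,
         width = 1500, height = 910, target = 100),
    list(label = "negative", shape = "rect", x0 = 3000, y0 = 0,
         width = 1500, height = 910, target = 50))
}

#' ROIs matching the standard phantom layout
#' @return A list of three [roi] objects (1500 x 900 um each).
#' @export
default_phantom_rois <- function() {
  list(roi(0, 0, 1500, 900, "high"),
       roi(1500, 0, 1500, 900, "low"),
       roi(3000, 0, 1500, 900, "negative"))
}
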