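#' Band intensity of a spectrum
#'
#' The quantification statistic used throughout this pipeline: the arithmetic
#' mean of the (baseline-corrected) intensity over the channels whose centre
#' wavenumber falls in the closed interval `[lo, hi]`. The default band
#' 950-960 cm^-1 covers the main peak of the nanoparticle fingerprint and
#' its mean is the "indicative intensity" of a spectrum.
#'
#' @param s A [spectrum] (normally baseline-corrected).
#' @param bd A [band]; default `band(950, 960)`.
#' @return Band intensity in counts/s.
#' @export
band_intensity <- function(s, bd = band(950, 960)) {
  stopifnot(is_spectrum(s), inherits(bd, "band"))
  idx <- which(s$shift >= bd$lo & s$shift <= bd$hi)
  if (length(idx) == 0L)
    stop(sprintf("band %g-%g cm-1 overlaps no channel of the spectrum (%g-%g cm-1)",
                 bd$lo, bd$hi, min(s$shift), max(s$shift)))
  mean(s$intensity[idx])
}

#' Band-intensity map
#'
#' Evaluates [band_intensity] at every point of a (corrected) spectral map.
#'
#' @param map A baseline-corrected [spectral_map].
#' @param bd A [band].
#' @return A data frame with columns `x`, `y`, `intensity` (counts/s), of
#'   class `intensity_map`; the band and any baseline parameters recorded in
#'   the map metadata are attached as attributes `band` and `provenance`.
#' @export
intensity_map <- function(map, bd = band(950, 960)) {
  stopifnot(inherits(map, "spectral_map"))
  idx <- which(map$axis >= bd$lo & map$axis <= bd$hi)
  if (length(idx) == 0L)
    stop(sprintf("band %g-%g cm-1 overlaps no channel of the map axis",
                 bd$lo, bd$hi))
  vals <- rowMeans(map$intensities[, idx, drop = FALSE])
  out <- data.frame(x = map$x, y = map$y, intensity = vals)
  attr(out, "band") <- bd
  attr(out, "provenance") <- map$meta$baseline_params
  class(out) <- c("intensity_map", class(out))
  out
}

#' Build a reference signature from a spectrum
#'
#' A reference signature is a baseline-corrected spectrum scaled to unit
#' Euclidean (L2) norm, used for shape matching of in-vivo spectra against
#' the known nanoparticle fingerprint.
#'
#' @param s A baseline-corrected [spectrum].
#' @param name Identity of the signature (e.g. the antibody conjugate).
#' @return An object of class `reference_signature` wrapping the normalised
#'   [spectrum].
#' @export
reference_signature <- function(s, name = "reference") {
  stopifnot(is_spectrum(s))
  nrm <- sqrt(sum(s$intensity^2))
  if (nrm == 0) stop("cannot normalise an all-zero spectrum")
  structure(list(spectrum = spectrum(s$shift, s$intensity / nrm, s$meta),
                 name = as.character(name)),
            class = "reference_signature")
}

#' @export
print.reference_signature <- function(x, ...) {
  cat(sprintf("<reference_signature '%s'> %d channels\n", x$name,
              length(x$spectrum$shift)))
  invisible(x)
}

#' Cosine similarity between a spectrum and a reference signature
#'
#' The spectrum is linearly interpolated onto the reference axis and the
#' normalised dot product is returned: 1 means identical shape, 0 no shared
#' structure. Invariant to positive scaling of either argument.
#'
#' @param s A baseline-corrected [spectrum].
#' @param ref A [reference_signature].
#' @return Cosine similarity in `[-1, 1]`.
#' @export
signature_similarity <- function(s, ref) {
  stopifnot(is_spectrum(s), inherits(ref, "reference_signature"))
  v <- stats::approx(s$shift, s$intensity, xout = ref$spectrum$shift,
                     rule = 2)$y
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("similarity undefined: spectrum has zero norm on the reference axis")
  r <- ref$spectrum$intensity
  sum(v * r) / (nv * sqrt(sum(r^2)))
}

#' Band intensities of a dilution series
#'
#' Baseline-corrects each spectrum of a dilution series and computes its
#' band intensity, producing the table consumed by [fit_calibration] and
#' [limit_of_detection].
#'
#' @param series A dilution series as returned by
#'   [simulate_dilution_series]: a data frame with columns `concentration`
#'   (pM) and a list column `spectrum`.
#' @param bd A [band].
#' @param params A [baseline_params] object.
#' @param clip_negative Passed to [subtract_baseline].
#' @return Data frame with columns `concentration` (pM) and `intensity`
#'   (counts/s), one row per replicate.
#' @export
quantify_series <- function(series, bd = band(950, 960),
                            params = baseline_params(), clip_negative = TRUE) {
  stopifnot(is.data.frame(series), "spectrum" %in% names(series))
  inten <- vapply(series$spectrum, function(s)
    band_intensity(subtract_baseline(s, params, clip_negative), bd), numeric(1))
  data.frame(concentration = series$concentration, intensity = inten)
}

#' Fit a saturating calibration curve to a dilution series
#'
#' Fits the monotone saturating (Langmuir-type) model
#' \deqn{I(C) = \mathrm{floor} + I_{max}\, C / (C + K_{half})}
#' to band intensities measured at known nanoparticle concentrations, by
#' nonlinear least squares. The model is monotone increasing by construction
#' (all parameters constrained non-negative). When the series contains at
#' least two blank (0 pM) replicates, the three-sigma limit of detection is
#' derived from the fit as well.
#'
#' @param series Data frame with columns `concentration` (pM, `>= 0`) and
#'   `intensity` (counts/s); at least 4 distinct concentrations including a
#'   blank, at least one replicate each.
#' @param k_sigma Multiplier of the blank standard deviation used for the
#'   limit of detection carried in the fit (default 3).
#' @return An object of class `calibration_fit`: a list with `i_max`,
#'   `k_half` (pM), `floor`, `lod` (pM; `Inf` when the threshold is never
#'   reached, `NA` when no blank spread is available), `residual_sse`,
#'   `degenerate` flag and the fitted `model` (or `NULL` when degenerate).
#' @export
fit_calibration <- function(series, k_sigma = 3) {
  stopifnot(is.data.frame(series),
            all(c("concentration", "intensity") %in% names(series)))
  conc <- series$concentration
  inten <- series$intensity
  if (any(conc < 0)) stop("negative concentrations are not allowed")
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations, got ", length(unique(conc)))
  if (!any(conc == 0))
    stop("series must include a blank (0 pM)")
  if (all(conc == 0))
    stop("series must include non-blank concentrations")

  # flat data: no concentration dependence to fit
  if (stats::sd(inten) < 1e-12 * max(1, abs(mean(inten)))) {
    fit <- structure(list(i_max = 0, k_half = NA_real_,
                          floor = mean(inten), lod = Inf,
                          residual_sse = 0, degenerate = TRUE, model = NULL),
                     class = "calibration_fit")
    return(fit)
  }

  floor0 <- mean(inten[conc == 0])
  i_max0 <- max(inten) - floor0
  if (i_max0 <= 0) i_max0 <- max(abs(inten - floor0), 1e-6)
  # half-max concentration guess: where the excess crosses half its range
  excess <- inten - floor0
  pos <- conc > 0
  k0 <- stats::median(conc[pos][which.min(abs(excess[pos] - i_max0 / 2))])
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(conc[pos])

  df <- data.frame(conc = conc, inten = inten)
  model <- tryCatch(
    minpack.lm::nlsLM(inten ~ fl + imax * conc / (conc + khalf),
                      data = df,
                      start = list(fl = max(floor0, 0), imax = i_max0, khalf = k0),
                      lower = c(fl = 0, imax = 0, khalf = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("calibration fit failed to converge: ", conditionMessage(e),
           call. = FALSE))
  p <- stats::coef(model)
  fit <- structure(list(i_max = unname(p["imax"]), k_half = unname(p["khalf"]),
                        floor = unname(p["fl"]), lod = NA_real_,
                        residual_sse = sum(stats::resid(model)^2),
                        degenerate = FALSE, model = model),
                   class = "calibration_fit")
  n_blank <- sum(conc == 0)
  if (n_blank >= 2L) {
    sd_blank <- stats::sd(inten[conc == 0])
    if (sd_blank > 0)
      fit$lod <- invert_calibration(fit, mean(inten[conc == 0]) +
                                      k_sigma * sd_blank)
  }
  fit
}

#' @export
print.calibration_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<calibration_fit> degenerate (flat series); lod = Inf\n")
  } else {
    cat(sprintf(paste0("<calibration_fit> I(C) = %.4g + %.4g * C / (C + %.4g pM)\n",
                       "  residual SSE %.4g; lod %s pM\n"),
                x$floor, x$i_max, x$k_half, x$residual_sse,
                format(x$lod, digits = 4)))
  }
  invisible(x)
}

#' Predict intensity from a calibration fit
#' @param object A `calibration_fit`.
#' @param concentration Concentrations in pM.
#' @param ... Unused.
#' @return Predicted intensities in counts/s.
#' @export
predict.calibration_fit <- function(object, concentration, ...) {
  if (object$degenerate) return(rep(object$floor, length(concentration)))
  object$floor + object$i_max * concentration / (concentration + object$k_half)
}

# lowest C with fitted I(C) >= threshold, by algebraic inversion of the
# saturating model; Inf when the curve never reaches the threshold
invert_calibration <- function(fit, threshold) {
  if (fit$degenerate || fit$i_max <= 0)
    return(if (threshold <= fit$floor) 0 else Inf)
  excess <- threshold - fit$floor
  if (excess <= 0) return(0)
  if (excess >= fit$i_max) return(Inf)
  fit$k_half * excess / (fit$i_max - excess)
}

#' Limit of detection from a dilution series
#'
#' The limit of detection is the lowest concentration whose fitted intensity
#' reaches `mean(blank) + k_sigma * sd(blank)`, obtained by algebraically
#' inverting the saturating calibration model. `Inf` is returned when the
#' fitted curve never reaches the threshold.
#'
#' @param series Data frame with columns `concentration` (pM) and
#'   `intensity` (counts/s), including blank (0 pM) rows.
#' @param k_sigma Blank-spread multiplier defining the detection threshold;
#'   default 3 (the conventional three-sigma criterion). `k_sigma = 0` puts
#'   the threshold at the blank mean.
#' @param fit Optional pre-computed [fit_calibration] result; fitted from
#'   `series` when omitted.
#' @param sd_blank Optional externally supplied blank standard deviation,
#'   required when the series has fewer than 2 blank replicates or an
#'   identically-zero blank spread.
#' @return Limit of detection in pM (possibly `Inf`).
#' @export
limit_of_detection <- function(series, k_sigma = 3, fit = NULL,
                               sd_blank = NULL) {
  stopifnot(is.data.frame(series),
            all(c("concentration", "intensity") %in% names(series)))
  if (!(k_sigma >= 0)) stop("k_sigma must be >= 0")
  blank <- series$intensity[series$concentration == 0]
  if (is.null(sd_blank)) {
    if (length(blank) < 2L)
      stop("need >= 2 blank replicates to estimate the blank spread, ",
           "or supply sd_blank")
    sd_blank <- stats::sd(blank)
    if (sd_blank == 0 && k_sigma > 0)
      stop("blank replicates are identical (sd = 0); supply sd_blank")
  }
  if (is.null(fit)) fit <- fit_calibration(series, k_sigma = k_sigma)
  mean_blank <- if (length(blank)) mean(blank) else fit$floor
  invert_calibration(fit, mean_blank + k_sigma * sd_blank)
}
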