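#' Baseline-estimation parameters
#'
#' Parameters of the asymmetrically reweighted Whittaker smoother used to
#' estimate the broad fluorescence background under the sharp Raman bands.
#' The smoother minimises
#' \deqn{\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^d z)_i^2,}
#' and the asymmetric reweighting gives channels above the current baseline
#' a small weight `asym_p` and channels below it weight `1 - asym_p`, so the
#' fit relaxes onto the lower envelope of the spectrum and passes under the
#' Raman peaks.
#'
#' The penalty operates on channel index, not wavenumber spacing: non-uniform
#' axes are accepted but penalized by index (a documented limitation shared
#' with common implementations).
#'
#' @param lam Smoothness penalty weight, dimensionless, `>= 0`. Default 200,
#'   the value used for fluorescence removal in this pipeline.
#' @param diff_order Order `d` of the difference penalty, 1, 2 or 3.
#' @param asym_p Asymmetry weight in (0, 1) given to channels above the
#'   baseline. Default 0.001.
#' @param max_iter Maximum reweighting iterations, `>= 1`.
#' @param tol Convergence threshold on the maximum absolute weight change.
#' @return An object of class `baseline_params`.
#' @export
baseline_params <- function(lam = 200, diff_order = 2, asym_p = 0.001,
                            max_iter = 20, tol = 1e-6) {
  if (!(lam >= 0)) stop("lam must be >= 0")
  if (!diff_order %in% 1:3) stop("diff_order must be 1, 2 or 3")
  if (!(asym_p > 0 && asym_p < 1)) stop("asym_p must be in (0, 1)")
  if (!(max_iter >= 1)) stop("max_iter must be >= 1")
  if (!(tol > 0)) stop("tol must be > 0")
  structure(list(lam = lam, diff_order = as.integer(diff_order),
                 asym_p = asym_p, max_iter = as.integer(max_iter), tol = tol),
            class = "baseline_params")
}

# Bands of D'D where D is the d-th order difference matrix (n-d) x n.
# D[k, k+m] = s_m = (-1)^m choose(d, m); band b of D'D:
#   (D'D)[i, i+b] = sum_k D[k,i] D[k,i+b] over rows k covering both columns.
# Memoized per (n, d); O(n * d^2) to build.
.dtd_cache <- new.env(parent = emptyenv())

dtd_bands <- function(n, d) {
  key <- paste(n, d)
  hit <- .dtd_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- (-1)^(0:d) * choose(d, 0:d)
  bands <- matrix(0, n, d + 1L)
  for (b in 0:d) {
    for (i in seq_len(n - b)) {
      k_lo <- max(1L, i + b - d)
      k_hi <- min(n - d, i)
      if (k_lo > k_hi) next
      k <- k_lo:k_hi
      bands[i, b + 1L] <- sum(s[i - k + 1L] * s[i + b - k + 1L])
    }
  }
  .dtd_cache[[key]] <- bands
  bands
}

#' Whittaker penalized least-squares smoother
#'
#' Returns the vector `z` minimising
#' `sum(w * (y - z)^2) + lam * sum(diff(z, differences = d)^2)`, solved
#' exactly via a banded Cholesky factorisation of the normal equations
#' `(diag(w) + lam * D'D) z = w * y`.
#'
#' @param y Numeric vector to smooth, length `>= diff_order + 1`.
#' @param weights Per-channel non-negative weights, same length as `y`, not
#'   all zero. Default unit weights.
#' @param lam Penalty weight; `lam = 0` reproduces `y` wherever `weights > 0`.
#' @param diff_order Difference order `d` in 1..3.
#' @return Numeric vector `z`, same length as `y`.
#' @export
whittaker_smooth <- function(y, weights = rep(1, length(y)), lam = 200,
                             diff_order = 2) {
  n <- length(y)
  d <- as.integer(diff_order)
  if (!d %in% 1:3) stop("diff_order must be 1, 2 or 3")
  if (length(weights) != n)
    stop("weights must have the same length as y")
  if (n < d + 1L) stop("y must have length >= diff_order + 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("weights must not be all zero (singular system)")
  if (!(lam >= 0)) stop("lam must be >= 0")
  bands <- lam * dtd_bands(n, d)
  bands[, 1L] <- bands[, 1L] + weights
  banded_spd_solve(bands, weights * y)
}

#' Estimate the fluorescence baseline of a spectrum
#'
#' Iterative asymmetric reweighting: starting from unit weights, each
#' iteration smooths with [whittaker_smooth] and then assigns weight
#' `asym_p` to channels above the current baseline and `1 - asym_p` to
#' channels below it, stopping when the weights change by less than `tol`
#' or after `max_iter` iterations. Non-convergence is not an error: the last
#' iterate is returned and flagged in `meta$converged`.
#'
#' @param s A [spectrum].
#' @param params A [baseline_params] object.
#' @return A [spectrum] holding the baseline on the same axis, with
#'   `meta$iterations` and `meta$converged`.
#' @export
estimate_baseline <- function(s, params = baseline_params()) {
  stopifnot(is_spectrum(s), inherits(params, "baseline_params"))
  y <- s$intensity
  n <- length(y)
  w <- rep(1, n)
  z <- y
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(params$max_iter)) {
    z <- whittaker_smooth(y, w, params$lam, params$diff_order)
    w_new <- ifelse(y - z > 0, params$asym_p, 1 - params$asym_p)
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < params$tol) { converged <- TRUE; break }
  }
  spectrum(s$shift, z,
           meta = c(s$meta, list(iterations = iter, converged = converged)))
}

#' Subtract the estimated baseline from a spectrum
#'
#' Corrected spectrum = spectrum - estimated baseline. With `clip_negative`
#' (the default) channels that fall below zero after subtraction are set to
#' zero. This rectification introduces a small positive bias on signal-free
#' regions — the background "floor" seen in corrected maps — and is kept on
#' by default to match how corrected intensities are reported.
#'
#' @param s A [spectrum].
#' @param params A [baseline_params] object.
#' @param clip_negative Set negative corrected channels to zero. Default `TRUE`.
#' @return The corrected [spectrum]; baseline convergence flags are carried
#'   in `meta`.
#' @export
subtract_baseline <- function(s, params = baseline_params(),
                              clip_negative = TRUE) {
  bl <- estimate_baseline(s, params)
  corrected <- s$intensity - bl$intensity
  if (clip_negative) corrected <- pmax(corrected, 0)
  spectrum(s$shift, corrected, meta = bl$meta)
}

#' Baseline-correct every point of a spectral map
#'
#' Applies [subtract_baseline] independently to each point spectrum; the
#' result does not depend on point order. Errors are reported with the
#' (x, y) coordinates of the offending point.
#'
#' @param map A [spectral_map].
#' @param params A [baseline_params] object.
#' @param clip_negative Passed to [subtract_baseline].
#' @return A [spectral_map] of corrected spectra; `meta$baseline_params`
#'   records the parameters used.
#' @export
correct_map <- function(map, params = baseline_params(), clip_negative = TRUE) {
  stopifnot(inherits(map, "spectral_map"))
  out <- map$intensities
  for (i in seq_len(n_points(map))) {
    ci <- tryCatch(
      subtract_baseline(map_spectrum(map, i), params, clip_negative),
      error = function(e)
        stop(sprintf("baseline correction failed at point (%g, %g): %s",
                     map$x[i], map$y[i], conditionMessage(e)), call. = FALSE))
    out[i, ] <- ci$intensity
  }
  spectral_map(map$x, map$y, out, map$axis, pixel_pitch = map$pixel_pitch,
               meta = c(map$meta,
                        list(baseline_params = params,
                             clip_negative = clip_negative)))
}
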