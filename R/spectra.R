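#' Construct a point spectrum
#'
#' A `spectrum` is a single Raman point measurement: a strictly increasing
#' Raman-shift axis (cm^-1) with one intensity value (counts/s) per channel.
#' Channel spacing may be non-uniform but must be positive everywhere.
#'
#' @param shift Numeric vector of Raman shifts in cm^-1, strictly increasing,
#'   length >= 2.
#' @param intensity Numeric vector of intensities in counts/s, same length as
#'   `shift`.
#' @param meta Named list of free-form annotations (e.g. acquisition time in
#'   seconds, laser power in percent). Informational only.
#'
#' @return An object of class `spectrum`: a list with elements `shift`,
#'   `intensity` and `meta`.
#' @examples
#' s <- spectrum(c(940, 950, 960), c(10, 200, 12))
#' band_intensity(s, band(945, 955))
#' @export
spectrum <- function(shift, intensity, meta = list()) {
  shift <- as.numeric(shift)
  intensity <- as.numeric(intensity)
  if (length(shift) < 2L)
    stop("a spectrum needs at least 2 channels, got ", length(shift))
  if (length(shift) != length(intensity))
    stop("shift and intensity differ in length (", length(shift), " vs ",
         length(intensity), ")")
  if (anyNA(shift) || anyNA(intensity))
    stop("shift and intensity must not contain NA")
  d <- diff(shift)
  if (any(d == 0))
    stop("duplicate Raman shifts: ",
         paste(unique(shift[which(d == 0)]), collapse = ", "))
  if (any(d < 0))
    stop("shift axis must be strictly increasing")
  structure(list(shift = shift, intensity = intensity, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d channels, %.2f-%.2f cm-1, max %.3g cts/s\n",
              length(x$shift), min(x$shift), max(x$shift), max(x$intensity)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(shift = x$shift, intensity = x$intensity)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Construct a spectral map
#'
#' A `spectral_map` is a collection of point spectra on a shared Raman-shift
#' axis, each at a physical (x, y) position in micrometres. The origin is at
#' the lower-left of the map with y increasing upward. Intensities are stored
#' as a points-by-channels matrix, one row per map point.
#'
#' @param x,y Numeric vectors of point coordinates in micrometres; the pairs
#'   `(x, y)` must be unique.
#' @param intensities Numeric matrix, `length(x)` rows by `length(axis)`
#'   columns, in counts/s.
#' @param axis Shared Raman-shift axis in cm^-1 (strictly increasing).
#' @param pixel_pitch Optional `c(dx, dy)` grid spacing in micrometres, for
#'   gridded maps; `NULL` when unknown or non-gridded.
#' @param meta Named list of annotations.
#'
#' @return An object of class `spectral_map`.
#' @export
spectral_map <- function(x, y, intensities, axis, pixel_pitch = NULL,
                         meta = list()) {
  x <- as.numeric(x); y <- as.numeric(y)
  axis <- as.numeric(axis)
  intensities <- as.matrix(intensities)
  if (length(x) != length(y))
    stop("x and y differ in length")
  if (length(x) < 1L)
    stop("a spectral map needs at least one point")
  if (length(axis) < 2L || any(diff(axis) <= 0))
    stop("shared axis must be strictly increasing with length >= 2")
  if (nrow(intensities) != length(x) || ncol(intensities) != length(axis))
    stop(sprintf("intensity matrix is %d x %d but map has %d points and %d channels",
                 nrow(intensities), ncol(intensities), length(x), length(axis)))
  if (anyDuplicated(paste(x, y)))
    stop("duplicate (x, y) coordinates in map")
  if (!is.null(pixel_pitch)) {
    pixel_pitch <- as.numeric(pixel_pitch)
    if (length(pixel_pitch) != 2L || any(pixel_pitch <= 0))
      stop("pixel_pitch must be c(dx, dy) with positive entries")
  }
  dimnames(intensities) <- NULL
  structure(list(x = x, y = y, intensities = intensities, axis = axis,
                 pixel_pitch = pixel_pitch, meta = meta),
            class = "spectral_map")
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("<spectral_map> %d points, %d channels (%.2f-%.2f cm-1)\n",
              n_points(x), length(x$axis), min(x$axis), max(x$axis)))
  if (!is.null(x$pixel_pitch))
    cat(sprintf("  pixel pitch %g x %g um\n", x$pixel_pitch[1], x$pixel_pitch[2]))
  invisible(x)
}

#' Number of points in a spectral map
#' @param map A `spectral_map`.
#' @return Integer point count.
#' @export
n_points <- function(map) {
  stopifnot(inherits(map, "spectral_map"))
  length(map$x)
}

#' Extract one point spectrum from a map
#' @param map A `spectral_map`.
#' @param i Point index (row in the intensity matrix).
#' @return A `spectrum` with the point coordinates recorded in `meta`.
#' @export
map_spectrum <- function(map, i) {
  stopifnot(inherits(map, "spectral_map"), i >= 1, i <= n_points(map))
  spectrum(map$axis, map$intensities[i, ],
           meta = list(x = map$x[i], y = map$y[i]))
}

#' Define a wavenumber band
#'
#' A closed wavenumber interval `[lo, hi]` used as the quantification
#' statistic: the band intensity of a spectrum is the mean intensity over
#' channels whose centre falls inside the interval.
#'
#' @param lo,hi Band edges in cm^-1, `lo < hi`. Edges are inclusive.
#' @return An object of class `band`.
#' @examples
#' band(950, 960)  # the nanoparticle fingerprint band
#' @export
band <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != 1L || length(hi) != 1L || is.na(lo) || is.na(hi) || lo >= hi)
    stop("band requires scalar lo < hi")
  structure(list(lo = lo, hi = hi), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %g-%g cm-1\n", x$lo, x$hi)); invisible(x)
}

#' Define a rectangular region of interest
#'
#' Axis-aligned rectangle in map coordinates (micrometres). Membership is
#' half-open: a map point belongs to the ROI when `x0 <= x < x0 + width` and
#' `y0 <= y < y0 + height`, so adjacent tiled ROIs partition a map without
#' double counting.
#'
#' @param x0,y0 Lower-left corner, micrometres.
#' @param width,height Extents in micrometres, both positive.
#' @param label Text label for the region.
#' @return An object of class `roi`.
#' @export
roi <- function(x0, y0, width, height, label = "roi") {
  x0 <- as.numeric(x0); y0 <- as.numeric(y0)
  width <- as.numeric(width); height <- as.numeric(height)
  if (width <= 0 || height <= 0)
    stop("roi width and height must be positive")
  structure(list(x0 = x0, y0 = y0, width = width, height = height,
                 label = as.character(label)), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi '%s'> [%g, %g) x [%g, %g) um\n", x$label,
              x$x0, x$x0 + x$width, x$y0, x$y0 + x$height))
  invisible(x)
}

# half-open membership; shared by summarize_roi and the phantom generator
roi_members <- function(map, r) {
  which(map$x >= r$x0 & map$x < r$x0 + r$width &
        map$y >= r$y0 & map$y < r$y0 + r$height)
}
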