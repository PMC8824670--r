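#' @title Plain-text spectrum and map formats
#' @description
#' Two on-disk dialects are supported for maps, covering typical text exports
#' of mapping spectrometers:
#' * long format: a one-line header `x,y,shift,intensity`, then one row per
#'   (point, channel);
#' * matrix format: first row `x,y` followed by the shift axis, then one row
#'   per point: `x`, `y`, intensities.
#'
#' Single spectra are two-column text (shift, intensity), with an optional
#' non-numeric header line. The delimiter is auto-detected among comma, tab
#' and whitespace. Values are written with 9 significant digits so that
#' write/read round-trips are numerically faithful.
#' @name spectra_io
NULL

# split a line on the detected delimiter
split_fields <- function(lines, delim) {
  if (delim == "whitespace") strsplit(trimws(lines), "[ \t]+")
  else strsplit(lines, delim, fixed = TRUE)
}

detect_delim <- function(line) {
  if (grepl(",", line, fixed = TRUE)) ","
  else if (grepl("\t", line, fixed = TRUE)) "\t"
  else "whitespace"
}

read_text_table <- function(path, expect_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ", what, " file: ", path)
  delim <- detect_delim(lines[[1]])
  fields <- split_fields(lines, delim)
  first <- suppressWarnings(as.numeric(fields[[1]]))
  header <- anyNA(first)
  start <- if (header) 2L else 1L
  if (start > length(fields)) stop("no data rows in ", what, " file: ", path)
  rows <- vector("list", length(fields) - start + 1L)
  for (i in seq_along(rows)) {
    li <- start + i - 1L
    v <- suppressWarnings(as.numeric(fields[[li]]))
    if (length(v) < expect_cols || anyNA(v[seq_len(expect_cols)]))
      stop(sprintf("malformed row at line %d of %s: '%s'", li, path, lines[[li]]))
    rows[[i]] <- v[seq_len(expect_cols)]
  }
  do.call(rbind, rows)
}

#' Read a single spectrum from two-column text
#'
#' Parses a file of `shift, intensity` pairs (comma-, tab- or
#' whitespace-separated; optional header line). Rows are sorted by shift;
#' duplicate shifts are an error.
#'
#' @param path Path to the text file.
#' @return A [spectrum].
#' @export
read_spectrum <- function(path) {
  m <- read_text_table(path, 2L, "spectrum")
  if (nrow(m) < 2L)
    stop("a spectrum file needs at least 2 data rows, got ", nrow(m))
  o <- order(m[, 1])
  spectrum(m[o, 1], m[o, 2], meta = list(source = path))
}

#' Write a single spectrum as two-column CSV
#' @param s A [spectrum].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is_spectrum(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("shift,intensity", con)
  writeLines(sprintf("%.9g,%.9g", s$shift, s$intensity), con)
  invisible(path)
}

#' Read a spectral map in long format
#'
#' Long format has columns `x, y, shift, intensity` (one-line header, any of
#' the supported delimiters). Every point must carry the identical set of
#' shifts; points with ragged axes are reported. Row order in the file is
#' irrelevant: the map is canonicalised by sorting points by (y, x).
#'
#' @param path Path to the long-format file.
#' @return A [spectral_map] with the shared axis set and, when the points
#'   form a regular grid, the inferred pixel pitch.
#' @export
read_map_long <- function(path) {
  m <- read_text_table(path, 4L, "map")
  key <- paste(m[, 1], m[, 2])
  pts <- unique(key)
  axis <- sort(unique(m[, 3]))
  counts <- table(key)
  per_point <- tapply(m[, 3], key, function(s) {
    length(s) == length(axis) && !anyDuplicated(s) && all(sort(s) == axis)
  })
  if (!all(per_point)) {
    bad <- names(per_point)[!per_point]
    stop("ragged shift axes across points; offending (x, y): ",
         paste(head(bad, 5L), collapse = "; "),
         if (length(bad) > 5L) sprintf(" ... and %d more", length(bad) - 5L))
  }
  xy <- do.call(rbind, strsplit(pts, " ", fixed = TRUE))
  x <- as.numeric(xy[, 1]); y <- as.numeric(xy[, 2])
  o <- order(y, x)
  x <- x[o]; y <- y[o]
  inten <- matrix(0, length(x), length(axis))
  row_of <- match(key, paste(x, y))
  col_of <- match(m[, 3], axis)
  inten[cbind(row_of, col_of)] <- m[, 4]
  spectral_map(x, y, inten, axis, pixel_pitch = infer_pitch(x, y),
               meta = list(source = path))
}

infer_pitch <- function(x, y) {
  one_step <- function(v) {
    u <- sort(unique(v))
    if (length(u) < 2L) return(NA_real_)
    d <- unique(round(diff(u), 9))
    if (length(d) == 1L) d else NA_real_
  }
  dx <- one_step(x); dy <- one_step(y)
  if (is.na(dx) || is.na(dy)) NULL else c(dx, dy)
}

#' Write a spectral map in long format
#' @param map A [spectral_map].
#' @param path Output path.
#' @param header_comment Optional comment line(s) written before the header,
#'   each prefixed with `#` (ignored by the readers).
#' @return `path`, invisibly.
#' @export
write_map_long <- function(map, path, header_comment = NULL) {
  stopifnot(inherits(map, "spectral_map"))
  if (n_points(map) < 1L) stop("cannot write an empty map")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  writeLines("x,y,shift,intensity", con)
  nch <- length(map$axis)
  for (i in seq_len(n_points(map))) {
    writeLines(sprintf("%.9g,%.9g,%.9g,%.9g",
                       rep(map$x[i], nch), rep(map$y[i], nch),
                       map$axis, map$intensities[i, ]), con)
  }
  invisible(path)
}

#' Read a spectral map in matrix format
#'
#' Matrix format: first row is `x, y` followed by the shift axis; each later
#' row is a point's x, y and its intensities.
#'
#' @param path Path to the matrix-format file.
#' @return A [spectral_map].
#' @export
read_map_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) < 2L) stop("matrix map file needs an axis row and >=1 point row")
  delim <- detect_delim(lines[[1]])
  fields <- split_fields(lines, delim)
  axis <- suppressWarnings(as.numeric(fields[[1]][-(1:2)]))
  if (anyNA(axis)) stop("malformed axis row in ", path)
  n <- length(lines) - 1L
  x <- y <- numeric(n)
  inten <- matrix(0, n, length(axis))
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(fields[[i + 1L]]))
    if (length(v) != length(axis) + 2L || anyNA(v))
      stop(sprintf("malformed row at line %d of %s", i + 1L, path))
    x[i] <- v[1]; y[i] <- v[2]; inten[i, ] <- v[-(1:2)]
  }
  o <- order(y, x)
  spectral_map(x[o], y[o], inten[o, , drop = FALSE], axis,
               pixel_pitch = infer_pitch(x, y), meta = list(source = path))
}

#' Write a spectral map in matrix format
#' @inheritParams write_map_long
#' @return `path`, invisibly.
#' @export
write_map_matrix <- function(map, path, header_comment = NULL) {
  stopifnot(inherits(map, "spectral_map"))
  if (n_points(map) < 1L) stop("cannot write an empty map")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  writeLines(paste(c("x", "y", sprintf("%.9g", map$axis)), collapse = ","), con)
  for (i in seq_len(n_points(map)))
    writeLines(paste(sprintf("%.9g", c(map$x[i], map$y[i], map$intensities[i, ])),
                     collapse = ","), con)
  invisible(path)
}

#' Read ROIs from a CSV table
#'
#' Expects columns `label, x0, y0, width, height` (header required).
#'
#' @param path Path to the ROI table.
#' @return A list of [roi] objects.
#' @export
read_rois <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x0", "y0", "width", "height")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    roi(df$x0[i], df$y0[i], df$width[i], df$height[i], df$label[i]))
}
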