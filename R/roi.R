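#' Summarise a rectangular ROI of a corrected map
#'
#' Averages the spectra of all map points inside the ROI (half-open
#' membership, see [roi]) channel-wise, and computes the indicative
#' intensity: the band intensity of the mean spectrum, which by linearity
#' equals the mean of the per-point band intensities. Both are returned;
#' the identity is asserted to machine precision.
#'
#' @param map A baseline-corrected [spectral_map].
#' @param r An [roi].
#' @param bd A [band].
#' @return An object of class `roi_summary`: list with `roi`, `n_points`,
#'   `mean_spectrum` ([spectrum]), `indicative_intensity` (counts/s) and
#'   `point_intensities` (per-point band intensities).
#' @export
summarize_roi <- function(map, r, bd = band(950, 960)) {
  stopifnot(inherits(map, "spectral_map"), inherits(r, "roi"))
  idx <- roi_members(map, r)
  if (length(idx) == 0L)
    stop(sprintf("ROI '%s' contains no map point", r$label))
  sub <- map$intensities[idx, , drop = FALSE]
  mean_int <- colMeans(sub)
  ms <- spectrum(map$axis, mean_int, meta = list(roi = r$label))
  ch <- which(map$axis >= bd$lo & map$axis <= bd$hi)
  if (length(ch) == 0L)
    stop(sprintf("band %g-%g cm-1 overlaps no channel of the map axis",
                 bd$lo, bd$hi))
  pts <- rowMeans(sub[, ch, drop = FALSE])
  ind <- mean(mean_int[ch])
  stopifnot(isTRUE(all.equal(ind, mean(pts), tolerance = 1e-12)))
  structure(list(roi = r, n_points = length(idx), mean_spectrum = ms,
                 indicative_intensity = ind, point_intensities = unname(pts),
                 band = bd),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("<roi_summary '%s'> n = %d points, indicative intensity %.1f cts/s (band %g-%g cm-1)\n",
              x$roi$label, x$n_points, x$indicative_intensity,
              x$band$lo, x$band$hi))
  invisible(x)
}

#' Classify biomarker expression level from indicative intensity
#'
#' Maps a band intensity to one of three expression classes:
#' `high` when intensity is strictly greater than `t_high`, `negative` when
#' it is at or below `t_neg`, `low` otherwise. The defaults follow the
#' reported regimes (high areas >200 cts/s, low around 100 cts/s, signal-free
#' background around 50 cts/s); the low/negative cut of 75 cts/s is the
#' midpoint of the 50 and 100 cts/s regimes.
#'
#' @param intensity Band intensity (or vector of them), counts/s, `>= 0`.
#' @param t_high High-expression threshold (strict), default 200 cts/s.
#' @param t_neg Negative threshold (inclusive), default 75 cts/s; must
#'   satisfy `t_high > t_neg > 0`.
#' @return Character vector of class labels among `"high"`, `"low"`,
#'   `"negative"`.
#' @export
classify_expression <- function(intensity, t_high = 200, t_neg = 75) {
  if (!(t_high > t_neg && t_neg > 0))
    stop("thresholds must satisfy t_high > t_neg > 0")
  if (any(intensity < 0)) stop("intensity must be >= 0")
  ifelse(intensity > t_high, "high",
         ifelse(intensity <= t_neg, "negative", "low"))
}

#' Two-sample t-test between two ROIs
#'
#' Compares the per-point band intensities of two ROIs with a two-sided
#' two-sample Student t-test, pooled-variance by default (Welch optional).
#' Degenerate inputs (zero variance in both groups) return p = 1 when the
#' means are equal, and p = 0 flagged `degenerate` when they differ.
#'
#' @param a,b `roi_summary` objects (or plain numeric vectors of
#'   intensities), each with at least 2 values.
#' @param variant `"pooled"` (Student, default) or `"welch"`.
#' @return An object of class `roi_comparison`: list with `group_a`,
#'   `group_b`, `t_stat`, `df`, `p_value`, `n_a`, `n_b`, `variant`,
#'   `degenerate`.
#' @export
compare_rois <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  ga <- if (inherits(a, "roi_summary"))
    list(label = a$roi$label, v = a$point_intensities)
  else list(label = "a", v = as.numeric(a))
  gb <- if (inherits(b, "roi_summary"))
    list(label = b$roi$label, v = b$point_intensities)
  else list(label = "b", v = as.numeric(b))
  n_a <- length(ga$v); n_b <- length(gb$v)
  if (n_a < 2L || n_b < 2L)
    stop("each group needs at least 2 point intensities")
  res <- list(group_a = ga$label, group_b = gb$label,
              n_a = n_a, n_b = n_b, variant = variant, degenerate = FALSE)
  if (stats::var(ga$v) == 0 && stats::var(gb$v) == 0) {
    if (mean(ga$v) == mean(gb$v)) {
      res$t_stat <- 0; res$df <- n_a + n_b - 2L; res$p_value <- 1
    } else {
      res$t_stat <- sign(mean(ga$v) - mean(gb$v)) * Inf
      res$df <- n_a + n_b - 2L; res$p_value <- 0; res$degenerate <- TRUE
    }
    return(structure(res, class = "roi_comparison"))
  }
  tt <- stats::t.test(ga$v, gb$v, var.equal = (variant == "pooled"))
  res$t_stat <- unname(tt$statistic)
  res$df <- unname(tt$parameter)
  res$p_value <- tt$p.value
  structure(res, class = "roi_comparison")
}

#' @export
print.roi_comparison <- function(x, ...) {
  cat(sprintf("<roi_comparison> %s vs %s (%s): t = %.3f, df = %.3g, p = %.4g\n",
              x$group_a, x$group_b, x$variant, x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Intratumoral heterogeneity report
#'
#' Summarises each labeled ROI of a corrected map, classifies its expression
#' level from the indicative intensity, and tests all pairwise differences
#' in mean per-point intensity. ROIs are processed in alphabetical label
#' order for deterministic output.
#'
#' @param map A baseline-corrected [spectral_map].
#' @param rois List of [roi] objects with unique labels; at least 2.
#' @param bd A [band].
#' @param t_high,t_neg Classification thresholds, see [classify_expression].
#' @param variant t-test variant, see [compare_rois].
#' @return A list of class `heterogeneity_report`: `summary` (data frame
#'   with one row per ROI: label, n_points, indicative_intensity, class),
#'   `comparisons` (data frame of all pairwise tests) and the per-ROI
#'   `roi_summaries`.
#' @export
heterogeneity_report <- function(map, rois, bd = band(950, 960),
                                 t_high = 200, t_neg = 75,
                                 variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(rois) < 2L) stop("need at least 2 ROIs")
  labels <- vapply(rois, function(r) r$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate ROI labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rois <- rois[order(labels)]
  summaries <- lapply(rois, summarize_roi, map = map, bd = bd)
  names(summaries) <- sort(labels)
  tab <- data.frame(
    label = sort(labels),
    n_points = vapply(summaries, `[[`, integer(1), "n_points"),
    indicative_intensity = vapply(summaries, `[[`, numeric(1),
                                  "indicative_intensity"),
    row.names = NULL)
  tab$class <- classify_expression(tab$indicative_intensity, t_high, t_neg)
  pairs <- utils::combn(seq_along(summaries), 2L)
  comps <- lapply(seq_len(ncol(pairs)), function(j) {
    cr <- compare_rois(summaries[[pairs[1, j]]], summaries[[pairs[2, j]]],
                       variant)
    data.frame(group_a = cr$group_a, group_b = cr$group_b,
               t_stat = cr$t_stat, df = cr$df, p_value = cr$p_value,
               n_a = cr$n_a, n_b = cr$n_b)
  })
  structure(list(summary = tab, comparisons = do.call(rbind, comps),
                 roi_summaries = summaries, band = bd,
                 thresholds = c(t_high = t_high, t_neg = t_neg)),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("<heterogeneity_report> band %g-%g cm-1, thresholds high > %g, negative <= %g cts/s\n",
              x$band$lo, x$band$hi, x$thresholds["t_high"], x$thresholds["t_neg"]))
  print(x$summary, row.names = FALSE)
  cat("pairwise comparisons:\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
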