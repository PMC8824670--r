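# Independent oracles used across the suite. These deliberately use naive
# dense linear algebra / textbook formulas, not the package's code paths.

# dense normal-equations solve of the Whittaker system
dense_whittaker <- function(y, w, lam, d) {
  n <- length(y)
  D <- diff(diag(n), differences = d)
  as.numeric(solve(diag(w, n) + lam * t(D) %*% D, w * y))
}

# textbook pooled-variance two-sample t-test
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

# penalty roughness of a smoothed vector
roughness <- function(z, d = 2) sum(diff(z, differences = d)^2)

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# small deterministic map: points on a grid with given per-point spectra
toy_map <- function(values, axis = c(940, 950, 960), pitch = c(10, 10)) {
  n <- nrow(values)
  g <- expand.grid(x = seq(0, by = pitch[1], length.out = ceiling(sqrt(n))),
                   y = seq(0, by = pitch[2], length.out = ceiling(sqrt(n))))
  g <- g[seq_len(n), ]
  spectral_map(g$x, g$y, values, axis, pixel_pitch = pitch)
}
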