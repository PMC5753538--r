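# Shared fixtures and independent oracles used across the test files.

# A small, fast phantom: 32 px grid keeps per-test simulation cheap while
# leaving ~250 myocardial pixels.
small_spec <- function(sigma = 0, ...) {
  lv_phantom_spec(grid_size = 32, sigma = sigma, ...)
}

# Reduced-averages protocols for tests that only need the geometry of the
# acquisition, not its full averaging scheme.
tiny_steam <- function(...) steam_protocol(averages_main = 1, ...)

# Uniform coordinate field: radial along +x, circumferential along +y,
# longitudinal along +z, every pixel in the mask. Lets metric tests place
# hand-constructed tensors in a known frame.
uniform_coords <- function(n) {
  radial <- array(0, c(n, n, 3)); radial[, , 1] <- 1
  circ <- array(0, c(n, n, 3)); circ[, , 2] <- 1
  structure(list(radial = radial, circ = circ, long = c(0, 0, 1),
                 depth = matrix(0.5, n, n), mask = matrix(TRUE, n, n),
                 centre = c((n - 1) / 2, (n - 1) / 2), pixdim = 1),
            class = "cardiac_coords")
}

# Wrap per-pixel tensors (list of 3x3 matrices or a single matrix recycled)
# into a tensor_field on an n x n grid.
tensor_field_from <- function(mats, n) {
  if (is.matrix(mats)) mats <- rep(list(mats), n * n)
  D <- array(NA_real_, c(n, n, 6))
  comp <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (k in seq_along(comp)) {
    plane <- matrix(vapply(mats, function(m)
      m[comp[[k]][1], comp[[k]][2]], numeric(1)), n, n)
    D[, , k] <- plane
  }
  structure(list(D = D, mask = matrix(TRUE, n, n),
                 valid = matrix(TRUE, n, n), lnS0 = NULL, rms = NULL),
            class = "tensor_field")
}

# In-plane rotation matrix (3D, about the slice normal).
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# Exact two-sided p-value of the Wilcoxon signed-rank statistic by
# enumeration of all 2^n sign patterns (n <= 12), midranks not needed
# because callers supply tie-free data. Zero differences are dropped as in
# the Wilcoxon convention.
wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
  min(1, p)
}

# Numeric quadrature oracle for gradient moments: samples the effective
# (polarity-corrected) waveform at dt_ms resolution and integrates
# G_eff(t) * t^n by the trapezoidal rule.
moment_quadrature <- function(w, order, dt_ms = 1e-3) {
  bp <- w$breakpoints
  tt <- seq(bp[1, 1], bp[nrow(bp), 1], by = dt_ms)
  g <- stats::approx(bp[, 1], bp[, 2], xout = tt, ties = "ordered")$y
  pol <- (-1)^vapply(tt, function(t) sum(w$refocus <= t), numeric(1))
  integrand <- pol * g * tt^order
  sum((integrand[-1] + integrand[-length(integrand)]) / 2) * dt_ms
}

# Maximum absolute discrepancy between two maps over non-NA pixels.
max_map_diff <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  max(abs(a[ok] - b[ok]))
}
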