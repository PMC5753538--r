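# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Fold an angle to the axial range (-90, 90] degrees
#'
#' Eigenvectors are axial quantities (defined up to sign), so any angle
#' derived from them is only meaningful modulo 180 degrees.
#'
#' @param a Angle(s) in degrees.
#' @return Angle(s) folded into (-90, 90].
#' @keywords internal
fold_axial_deg <- function(a) {
  a <- ((a + 90) %% 180) - 90
  a[a == -90] <- 90
  a
}

# Bilinear interpolation on a matrix. x is the 0-based column coordinate,
# y the 0-based row coordinate (pixel-centred). Out-of-grid points and
# points with any non-finite neighbour return NA.
bilinear_interp <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  j0 <- floor(x); i0 <- floor(y)
  fx <- x - j0; fy <- y - i0
  ok <- j0 >= 0 & i0 >= 0 & j0 <= nc - 2 & i0 <= nr - 2
  # allow exact top/right edge
  edge_x <- j0 == nc - 1 & fx == 0 & i0 >= 0 & i0 <= nr - 2
  edge_y <- i0 == nr - 1 & fy == 0 & j0 >= 0 & j0 <= nc - 2
  corner <- j0 == nc - 1 & fx == 0 & i0 == nr - 1 & fy == 0
  ok <- ok | edge_x | edge_y | corner
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  j0c <- pmin(j0[ok], nc - 2); i0c <- pmin(i0[ok], nr - 2)
  fxc <- x[ok] - j0c; fyc <- y[ok] - i0c
  v00 <- img[cbind(i0c + 1L, j0c + 1L)]
  v01 <- img[cbind(i0c + 1L, j0c + 2L)]
  v10 <- img[cbind(i0c + 2L, j0c + 1L)]
  v11 <- img[cbind(i0c + 2L, j0c + 2L)]
  out[ok] <- (1 - fyc) * ((1 - fxc) * v00 + fxc * v01) +
    fyc * ((1 - fxc) * v10 + fxc * v11)
  out
}

# Translate an image so that content moves by (dy, dx) pixels:
# out[r, c] = in[r - dy, c - dx], bilinear for fractional shifts,
# `fill` outside the source grid.
translate_image <- function(img, dy, dx, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  if (dy == 0 && dx == 0) return(img)
  if (dy == round(dy) && dx == round(dx)) {
    out <- matrix(fill, nr, nc)
    sr <- max(1, 1 + dy):min(nr, nr + dy)
    sc <- max(1, 1 + dx):min(nc, nc + dx)
    if (length(sr) > 0 && length(sc) > 0)
      out[sr, sc] <- img[sr - dy, sc - dx]
    return(out)
  }
  grid <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  v <- bilinear_interp(img, grid$c - 1 - dx, grid$r - 1 - dy)
  v[is.na(v)] <- fill
  matrix(v, nr, nc)
}

# Pixel-centre coordinate grids (mm) relative to a centre given in 0-based
# pixel coordinates c(x = col, y = row).
grid_xy_mm <- function(grid_size, pixdim, centre) {
  n <- grid_size
  xs <- (seq_len(n) - 1 - centre[1]) * pixdim
  ys <- (seq_len(n) - 1 - centre[2]) * pixdim
  list(x = matrix(rep(xs, each = n), n, n),
       y = matrix(rep(ys, times = n), n, n))
}

# Normal-approximation truncated-positive Gaussian draw.
rnorm_truncpos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}
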