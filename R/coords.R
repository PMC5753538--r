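#' Cardiac coordinate field
#'
#' Per-pixel orthonormal local cardiac directions on a short-axis slice:
#' `radial` (outward wall normal), `circ` (circumferential,
#' counter-clockwise in image axes, equal to long x radial) and the
#' slice-normal `long`, together with the normalised transmural depth
#' (0 at the epicardium, 1 at the endocardium). These directions are the
#' reference frame for the helix, transverse and second-eigenvector angle
#' maps.
#'
#' @name cardiac_coords
#' @keywords internal
NULL

new_cardiac_coords <- function(radial, circ, depth, mask, centre, pixdim) {
  structure(list(radial = radial, circ = circ, long = c(0, 0, 1),
                 depth = depth, mask = mask, centre = centre,
                 pixdim = pixdim),
            class = "cardiac_coords")
}

#' Analytic coordinates for a circular annulus
#'
#' Exact radial/circumferential directions and transmural depth for the
#' circular-ring geometry of [lv_phantom_spec()]. The depth field is
#' defined on the whole grid (clipped to [0, 1] inside the wall) so that
#' transmural profile extraction can interpolate it continuously.
#'
#' @param spec An [lv_phantom_spec()].
#' @param phase Cardiac phase label present in the spec.
#' @return A `cardiac_coords` object.
#' @export
annulus_coordinates <- function(spec, phase) {
  phase <- match.arg(phase, names(spec$endo_radius_mm))
  n <- spec$grid_size
  g <- grid_xy_mm(n, spec$pixdim, spec$centre)
  rho <- sqrt(g$x^2 + g$y^2)
  ri <- spec$endo_radius_mm[[phase]]
  ro <- spec$epi_radius_mm[[phase]]
  mask <- rho >= ri & rho <= ro
  if (any(mask & rho < 1e-9))
    stop("degenerate geometry: myocardial pixel at the LV centre")
  rx <- ifelse(rho > 0, g$x / rho, NA_real_)
  ry <- ifelse(rho > 0, g$y / rho, NA_real_)
  radial <- array(0, c(n, n, 3))
  radial[, , 1] <- rx; radial[, , 2] <- ry
  circ <- array(0, c(n, n, 3))
  circ[, , 1] <- -ry; circ[, , 2] <- rx   # long x radial
  depth <- (ro - rho) / (ro - ri)
  new_cardiac_coords(radial, circ, depth, mask, spec$centre, spec$pixdim)
}

# Minimum distance (mm) from each grid pixel to a closed polygon given in
# 0-based pixel coordinates (columns x, y).
polygon_distance_mm <- function(grid_size, pixdim, poly) {
  n <- grid_size
  px <- matrix(rep(seq_len(n) - 1, each = n), n, n)
  py <- matrix(rep(seq_len(n) - 1, times = n), n, n)
  p1 <- poly
  p2 <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  d2 <- matrix(Inf, n, n)
  for (k in seq_len(nrow(poly))) {
    ax <- p1[k, 1]; ay <- p1[k, 2]
    bx <- p2[k, 1]; by <- p2[k, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2) * pixdim
}

#' Build cardiac coordinates from segmentation contours
#'
#' Constructs the per-pixel radial/circumferential frame and transmural
#' depth from closed epicardial and endocardial contours. Depth is the
#' normalised distance between the contours
#' (`d_epi / (d_epi + d_endo)`, 0 on the epicardial contour and 1 on the
#' endocardial contour) and the local wall normal is taken from the
#' gradient of the signed inter-contour distance, which stays meaningful
#' for non-circular walls; the circumferential direction is the in-plane
#' perpendicular (long x radial).
#'
#' @param mask Logical myocardial mask (matrix).
#' @param epi_contour,endo_contour Closed polygons, n x 2 matrices of
#'   0-based pixel coordinates (x = column, y = row).
#' @param pixdim Pixel spacing (mm).
#' @param centre Optional LV centre (0-based pixel `c(x, y)`); defaults to
#'   the mask centroid.
#' @return A `cardiac_coords` object.
#' @export
build_cardiac_coordinates <- function(mask, epi_contour, endo_contour,
                                      pixdim = 1, centre = NULL) {
  epi_contour <- as.matrix(epi_contour)
  endo_contour <- as.matrix(endo_contour)
  if (nrow(epi_contour) < 3 || nrow(endo_contour) < 3)
    stop("contours must be closed polygons with at least 3 vertices")
  n <- nrow(mask)
  if (ncol(mask) != n) stop("mask must be square")
  if (is.null(centre)) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("empty myocardial mask")
    centre <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  }
  d_epi <- polygon_distance_mm(n, pixdim, epi_contour)
  d_endo <- polygon_distance_mm(n, pixdim, endo_contour)
  depth <- d_epi / (d_epi + d_endo)
  # signed distance-like field increasing outward: negative of depth works,
  # but use (d_endo - d_epi) whose gradient points outward across the wall
  phi <- d_endo - d_epi
  gx <- matrix(0, n, n); gy <- matrix(0, n, n)
  gx[, 2:(n - 1)] <- (phi[, 3:n] - phi[, 1:(n - 2)]) / (2 * pixdim)
  gx[, 1] <- (phi[, 2] - phi[, 1]) / pixdim
  gx[, n] <- (phi[, n] - phi[, n - 1]) / pixdim
  gy[2:(n - 1), ] <- (phi[3:n, ] - phi[1:(n - 2), ]) / (2 * pixdim)
  gy[1, ] <- (phi[2, ] - phi[1, ]) / pixdim
  gy[n, ] <- (phi[n, ] - phi[n - 1, ]) / pixdim
  gn <- sqrt(gx^2 + gy^2)
  bad <- gn < 1e-9
  gn[bad] <- 1
  rx <- gx / gn; ry <- gy / gn
  rx[bad] <- NA_real_; ry[bad] <- NA_real_
  radial <- array(0, c(n, n, 3))
  radial[, , 1] <- rx; radial[, , 2] <- ry
  circ <- array(0, c(n, n, 3))
  circ[, , 1] <- -ry; circ[, , 2] <- rx
  new_cardiac_coords(radial, circ, depth, mask, centre, pixdim)
}

#' Circular contour helper
#'
#' @param radius_mm Radius (mm).
#' @param centre 0-based pixel centre `c(x, y)`.
#' @param pixdim Pixel spacing (mm).
#' @param n_vertices Number of polygon vertices.
#' @return An n x 2 matrix of 0-based pixel coordinates.
#' @export
circle_contour <- function(radius_mm, centre, pixdim, n_vertices = 180) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cbind(centre[1] + radius_mm * cos(th) / pixdim,
        centre[2] + radius_mm * sin(th) / pixdim)
}
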