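#' Ground-truth diffusion tensor field for the LV phantom
#'
#' At every myocardial pixel the primary eigenvector lies in the
#' wall-tangent (circumferential-longitudinal) plane at the helix angle
#' prescribed for the pixel's transmural depth (linear interpolation from
#' `ha_endo` at depth 1 to `ha_epi` at depth 0); the secondary eigenvector
#' is rotated out of the tangent plane towards the radial direction by the
#' per-phase sheetlet angle `e2a`; eigenvalues equal the spec values.
#' Non-myocardial pixels carry no tensor.
#'
#' @param spec An [lv_phantom_spec()].
#' @param phase Cardiac phase label present in the spec.
#' @return A list with elements `tensors` (a `tensor_field`: array
#'   `D[n, n, 6]` with components xx, yy, zz, xy, xz, yz in mm^2/s plus
#'   masks) and `coords` (the matching [annulus_coordinates()]).
#' @export
#' @examples
#' tf <- build_tensor_field(lv_phantom_spec(grid_size = 32), "systole")
#' sum(tf$tensors$mask)
build_tensor_field <- function(spec, phase) {
  stopifnot(inherits(spec, "lv_phantom_spec"))
  phase <- match.arg(phase, names(spec$endo_radius_mm))
  coords <- annulus_coordinates(spec, phase)
  n <- spec$grid_size
  idx <- which(coords$mask)
  if (length(idx) == 0) stop("spec produces an empty myocardium")
  ha <- deg2rad(spec$ha_epi +
                  coords$depth[idx] * (spec$ha_endo - spec$ha_epi))
  e2a <- deg2rad(spec$e2a[[phase]])
  r <- cbind(coords$radial[, , 1][idx], coords$radial[, , 2][idx],
             coords$radial[, , 3][idx])
  cc <- cbind(coords$circ[, , 1][idx], coords$circ[, , 2][idx],
              coords$circ[, , 3][idx])
  if (any(!is.finite(r)))
    stop("degenerate geometry: undefined radial direction in the wall")
  zz <- matrix(rep(coords$long, each = length(idx)), ncol = 3)
  e1 <- cos(ha) * cc + sin(ha) * zz
  # in-wall direction perpendicular to e1 (radial x e1)
  w <- cbind(r[, 2] * e1[, 3] - r[, 3] * e1[, 2],
             r[, 3] * e1[, 1] - r[, 1] * e1[, 3],
             r[, 1] * e1[, 2] - r[, 2] * e1[, 1])
  e2 <- cos(e2a) * w + sin(e2a) * r
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  l <- spec$evals
  D6 <- function(v1, v2, v3) {
    l[1] * v1[, 1] * v1[, 2] + l[2] * v2[, 1] * v2[, 2] +
      l[3] * v3[, 1] * v3[, 2]
  }
  D <- array(NA_real_, c(n, n, 6))
  comp <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (k in seq_along(comp)) {
    a <- comp[[k]][1]; b <- comp[[k]][2]
    plane <- matrix(NA_real_, n, n)
    plane[idx] <- l[1] * e1[, a] * e1[, b] + l[2] * e2[, a] * e2[, b] +
      l[3] * e3[, a] * e3[, b]
    D[, , k] <- plane
  }
  masks <- phantom_masks(spec, phase)
  tensors <- structure(list(D = D, mask = coords$mask,
                            valid = coords$mask,
                            lnS0 = NULL, rms = NULL),
                       class = "tensor_field")
  list(tensors = tensors, coords = coords)
}

#' Myocardial, blood-pool and background masks of the phantom
#'
#' @param spec An [lv_phantom_spec()].
#' @param phase Cardiac phase label.
#' @return List of logical matrices `myocardium`, `blood`, `exclusion`.
#' @export
phantom_masks <- function(spec, phase) {
  phase <- match.arg(phase, names(spec$endo_radius_mm))
  g <- grid_xy_mm(spec$grid_size, spec$pixdim, spec$centre)
  rho <- sqrt(g$x^2 + g$y^2)
  ri <- spec$endo_radius_mm[[phase]]
  ro <- spec$epi_radius_mm[[phase]]
  list(myocardium = rho >= ri & rho <= ro,
       blood = rho < ri,
       exclusion = matrix(FALSE, spec$grid_size, spec$grid_size))
}

# Assemble a symmetric 3x3 matrix from the 6-component storage order.
tensor6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}
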