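#' Eigen-decompose a tensor field
#'
#' Per-pixel symmetric eigendecomposition with eigenvalues sorted in
#' descending order. Pixels with a negative eigenvalue keep their raw
#' eigensystem but are flagged (excluded from anisotropy and angle
#' summaries downstream); MD remains computable from the raw values so the
#' linear-fit statistics are preserved.
#'
#' @param tensors A `tensor_field` (from [fit_tensor_lls()] or
#'   [build_tensor_field()]).
#' @return An `eigen_field`: `vals` (`[n, n, 3]`, descending),
#'   `vecs` (`[n, n, 3, 3]`, `vecs[,,k,]` the unit eigenvector of the
#'   k-th eigenvalue, sign-arbitrary), `valid` and `spd` (no negative
#'   eigenvalue) masks.
#' @export
eig_decompose <- function(tensors) {
  n <- dim(tensors$D)[1]
  vals <- array(NA_real_, c(n, n, 3))
  vecs <- array(NA_real_, c(n, n, 3, 3))
  spd <- matrix(FALSE, n, n)
  idx <- which(tensors$valid %||% tensors$mask)
  Dm <- matrix(tensors$D, nrow = n * n)
  for (p in idx) {
    d6 <- Dm[p, ]
    if (any(!is.finite(d6))) stop("non-finite tensor entries at fitted pixel")
    e <- eigen(tensor6_to_mat(d6), symmetric = TRUE)
    r <- (p - 1) %% n + 1; cc <- (p - 1) %/% n + 1
    vals[r, cc, ] <- e$values
    for (k in 1:3) vecs[r, cc, k, ] <- e$vectors[, k]
    spd[r, cc] <- e$values[3] > 0
  }
  structure(list(vals = vals, vecs = vecs,
                 valid = tensors$valid %||% tensors$mask, spd = spd),
            class = "eigen_field")
}

#' Tensor scalar invariants: MD, FA and mode
#'
#' Mean diffusivity `MD = (l1 + l2 + l3) / 3`; fractional anisotropy
#' `FA = sqrt(3/2) * ||l - MD|| / ||l||`; tensor mode
#' `mode = 3 sqrt(6) det(Dev / ||Dev||)` with `Dev` the deviatoric tensor,
#' ranging from -1 (oblate, pancake) through 0 to +1 (prolate, cigar).
#' Isotropic pixels get FA = 0 and mode defined as 0. Pixels flagged
#' non-SPD get MD (unclamped) but NA anisotropy measures.
#'
#' @param eigen An `eigen_field`.
#' @return List of matrices `md`, `fa`, `mode`.
#' @export
scalar_invariants <- function(eigen) {
  l1 <- eigen$vals[, , 1]; l2 <- eigen$vals[, , 2]; l3 <- eigen$vals[, , 3]
  md <- (l1 + l2 + l3) / 3
  d1 <- l1 - md; d2 <- l2 - md; d3 <- l3 - md
  devn <- sqrt(d1^2 + d2^2 + d3^2)
  nrm <- sqrt(l1^2 + l2^2 + l3^2)
  fa <- ifelse(devn > 0 & nrm > 0, sqrt(1.5) * devn / nrm, 0)
  fa[is.na(l1)] <- NA_real_
  mode <- ifelse(devn > 0, 3 * sqrt(6) * (d1 * d2 * d3) / devn^3, 0)
  mode[is.na(l1)] <- NA_real_
  bad <- !eigen$spd & eigen$valid
  fa[bad] <- NA_real_
  mode[bad] <- NA_real_
  list(md = md, fa = pmin(pmax(fa, 0), 1), mode = pmin(pmax(mode, -1), 1))
}

# dot products of a per-pixel vector field [n,n,3] with eigenvector k
eigvec_dot <- function(eigen, k, field3) {
  eigen$vecs[, , k, 1] * field3[, , 1] +
    eigen$vecs[, , k, 2] * field3[, , 2] +
    eigen$vecs[, , k, 3] * field3[, , 3]
}

#' Helix and transverse angle maps
#'
#' The helix angle (HA) is the signed angle between the circumferential
#' direction and the projection of the primary eigenvector onto the
#' wall-tangent (circumferential-longitudinal) plane, positive towards the
#' local longitudinal direction; the transverse angle (TA) is the signed
#' angle between the circumferential direction and the projection onto the
#' short-axis (circumferential-radial) plane, positive towards the outward
#' radial direction. Both are folded to (-90, 90] degrees and invariant to
#' eigenvector sign flips. The positive-HA convention corresponds to a
#' helix rising counter-clockwise when viewed from the base; it is a
#' convention of this implementation, configurable by negating the
#' longitudinal axis.
#'
#' Pixels whose primary eigenvector is (numerically) parallel to the
#' radial direction have no defined HA and are flagged `NA`; pixels with
#' e1 parallel to the longitudinal direction have HA +/-90 but no defined
#' TA.
#'
#' @param eigen An `eigen_field`.
#' @param coords A `cardiac_coords` field on the same grid.
#' @param tol Degeneracy tolerance on the projection norm.
#' @return List of matrices `ha`, `ta` (degrees).
#' @export
helix_transverse_angles <- function(eigen, coords, tol = 1e-8) {
  e1c <- eigvec_dot(eigen, 1, coords$circ)
  e1r <- eigvec_dot(eigen, 1, coords$radial)
  e1l <- eigen$vecs[, , 1, 3] * coords$long[3]
  ha <- fold_axial_deg(rad2deg(atan2(e1l, e1c)))
  ha[sqrt(e1c^2 + e1l^2) < tol] <- NA_real_   # e1 parallel to radial
  ta <- fold_axial_deg(rad2deg(atan2(e1r, e1c)))
  ta[sqrt(e1c^2 + e1r^2) < tol] <- NA_real_   # e1 parallel to longitudinal
  bad <- !eigen$spd & eigen$valid
  ha[bad] <- NA_real_; ta[bad] <- NA_real_
  list(ha = ha, ta = ta)
}

#' Absolute second-eigenvector (sheetlet) angle map
#'
#' E2A is the absolute angle, in the cross-myocyte plane, between the
#' projection of the secondary eigenvector and the plane's in-wall axis.
#' The cross-myocyte plane is spanned by the radial direction and the
#' in-wall direction perpendicular to the projection of e1 onto the
#' wall-tangent plane (the default construction here; an alternative takes
#' the plane orthogonal to e1 itself, available via
#' `plane = "e1_orthogonal"`, which differs only when e1 leaves the
#' tangent plane). The result lies in [0, 90] degrees and is invariant to
#' eigenvector sign flips.
#'
#' @param eigen An `eigen_field`.
#' @param coords A `cardiac_coords` field.
#' @param plane `"cross_myocyte"` (default) or `"e1_orthogonal"`.
#' @param tol Pixels whose e2 projection norm is below `tol` are flagged.
#' @return Matrix of E2A values (degrees, `[0, 90]`).
#' @export
e2a_map <- function(eigen, coords, plane = c("cross_myocyte", "e1_orthogonal"),
                    tol = 1e-8) {
  plane <- match.arg(plane)
  n <- dim(eigen$vals)[1]
  e1 <- eigen$vecs[, , 1, ]
  e2 <- eigen$vecs[, , 2, ]
  r <- coords$radial
  if (plane == "cross_myocyte") {
    # in-tangent-plane unit vector along projected e1
    e1r <- e1[, , 1] * r[, , 1] + e1[, , 2] * r[, , 2] + e1[, , 3] * r[, , 3]
    tx <- e1[, , 1] - e1r * r[, , 1]
    ty <- e1[, , 2] - e1r * r[, , 2]
    tz <- e1[, , 3] - e1r * r[, , 3]
    tn <- sqrt(tx^2 + ty^2 + tz^2)
    tx <- tx / tn; ty <- ty / tn; tz <- tz / tn
  } else {
    tx <- e1[, , 1]; ty <- e1[, , 2]; tz <- e1[, , 3]
    tn <- matrix(1, n, n)
  }
  # in-wall axis of the cross-myocyte plane: radial x t
  wx <- r[, , 2] * tz - r[, , 3] * ty
  wy <- r[, , 3] * tx - r[, , 1] * tz
  wz <- r[, , 1] * ty - r[, , 2] * tx
  p_w <- e2[, , 1] * wx + e2[, , 2] * wy + e2[, , 3] * wz
  p_r <- e2[, , 1] * r[, , 1] + e2[, , 2] * r[, , 2] + e2[, , 3] * r[, , 3]
  e2a <- rad2deg(atan2(abs(p_r), abs(p_w)))
  e2a[sqrt(p_w^2 + p_r^2) < tol] <- NA_real_
  e2a[tn < tol] <- NA_real_
  bad <- !eigen$spd & eigen$valid
  e2a[bad] <- NA_real_
  e2a
}

#' All scalar maps from a tensor field
#'
#' Convenience wrapper chaining [eig_decompose()], [scalar_invariants()],
#' [helix_transverse_angles()] and [e2a_map()].
#'
#' @param tensors A `tensor_field`.
#' @param coords A `cardiac_coords` field.
#' @return List with `md`, `fa`, `mode`, `ha`, `ta`, `e2a`, `evals`
#'   (`[n, n, 3]`) and the underlying `eigen` field.
#' @export
compute_scalar_maps <- function(tensors, coords) {
  eigen <- eig_decompose(tensors)
  inv <- scalar_invariants(eigen)
  ang <- helix_transverse_angles(eigen, coords)
  list(md = inv$md, fa = inv$fa, mode = inv$mode,
       ha = ang$ha, ta = ang$ta, e2a = e2a_map(eigen, coords),
       evals = eigen$vals, eigen = eigen)
}
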