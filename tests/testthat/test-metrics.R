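test_that("eigendecomposition orders, reconstructs and is rotation-similar", {
  d <- diag(c(2, 1, 1)) * 1e-3
  ef <- eig_decompose(tensor_field_from(d, 2))
  expect_equal(ef$vals[1, 1, ], c(2, 1, 1) * 1e-3)
  expect_equal(abs(ef$vecs[1, 1, 1, ]), c(1, 0, 0), tolerance = 1e-12)
  # similarity invariance: a rotated tensor keeps its eigenvalues
  R <- rot_z(0.7)
  ef2 <- eig_decompose(tensor_field_from(R %*% d %*% t(R), 2))
  expect_equal(ef2$vals[1, 1, ], ef$vals[1, 1, ], tolerance = 1e-14)
  # reconstruction oracle on random SPD tensors
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3)
    spd <- crossprod(A) + diag(3) * 0.1
    e <- eig_decompose(tensor_field_from(spd, 2))
    recon <- Reduce(`+`, lapply(1:3, function(k)
      e$vals[1, 1, k] * tcrossprod(e$vecs[1, 1, k, ])))
    expect_lt(max(abs(recon - spd)), 1e-12)
  }
})

test_that("scalar invariants match closed forms and bounds", {
  mk <- function(l) scalar_invariants(
    eig_decompose(tensor_field_from(diag(l), 2)))
  iso <- mk(c(1, 1, 1) * 1e-3)
  expect_equal(iso$md[1, 1], 1e-3)
  expect_equal(iso$fa[1, 1], 0)
  expect_equal(iso$mode[1, 1], 0)
  pro <- mk(c(2, 1, 1) * 1e-3)
  expect_equal(pro$md[1, 1], 4 / 3 * 1e-3, tolerance = 1e-12)
  expect_equal(pro$fa[1, 1], sqrt(1 / 6), tolerance = 1e-12)
  expect_equal(pro$mode[1, 1], 1, tolerance = 1e-12)
  obl <- mk(c(1, 1, 0.5) * 1e-3)
  expect_equal(obl$mode[1, 1], -1, tolerance = 1e-12)
  # MD and FA invariant under rotation of the tensor
  set.seed(1)
  d <- diag(c(1.7, 0.9, 0.5)) * 1e-3
  R <- rot_z(1.1)
  a <- scalar_invariants(eig_decompose(tensor_field_from(d, 2)))
  b <- scalar_invariants(eig_decompose(tensor_field_from(R %*% d %*% t(R), 2)))
  expect_equal(a$md[1, 1], b$md[1, 1], tolerance = 1e-14)
  expect_equal(a$fa[1, 1], b$fa[1, 1], tolerance = 1e-12)
})

test_that("helix and transverse angles follow their construction", {
  n <- 2
  coords <- uniform_coords(n)   # radial = x, circ = y, long = z
  mk_e1 <- function(v) {
    v <- v / sqrt(sum(v^2))
    # prolate tensor with e1 = v
    tensor_field_from(1.5e-3 * tcrossprod(v) +
                        0.5e-3 * (diag(3) - tcrossprod(v)), n)
  }
  ang <- function(v) helix_transverse_angles(eig_decompose(mk_e1(v)), coords)
  circ <- ang(c(0, 1, 0))
  expect_equal(circ$ha[1, 1], 0, tolerance = 1e-9)
  expect_equal(circ$ta[1, 1], 0, tolerance = 1e-9)
  long <- ang(c(0, 0, 1))
  expect_equal(abs(long$ha[1, 1]), 90, tolerance = 1e-9)
  expect_true(is.na(long$ta[1, 1]))  # degenerate short-axis projection
  diag45 <- ang(c(0, 1, 1))
  expect_equal(diag45$ha[1, 1], 45, tolerance = 1e-9)
  # sign-flip invariance
  flip <- ang(-c(0, 1, 1))
  expect_equal(flip$ha[1, 1], 45, tolerance = 1e-9)
  # e1 parallel to radial: HA undefined, flagged
  rad <- ang(c(1, 0, 0))
  expect_true(is.na(rad$ha[1, 1]))
  # TA is signed towards radial
  ta45 <- ang(c(1, 1, 0))
  expect_equal(ta45$ta[1, 1], 45, tolerance = 1e-9)
})

test_that("E2A map measures the out-of-plane tilt of the second eigenvector", {
  n <- 2
  coords <- uniform_coords(n)
  mk <- function(e1, e2) {
    e1 <- e1 / sqrt(sum(e1^2)); e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    tensor_field_from(1.5e-3 * tcrossprod(e1) + 1.0e-3 * tcrossprod(e2) +
                        0.5e-3 * tcrossprod(e3), n)
  }
  # e2 in the wall-tangent plane -> 0; e2 radial -> 90
  expect_equal(e2a_map(eig_decompose(mk(c(0, 1, 0), c(0, 0, 1))),
                       coords)[1, 1], 0, tolerance = 1e-9)
  expect_equal(e2a_map(eig_decompose(mk(c(0, 1, 0), c(1, 0, 0))),
                       coords)[1, 1], 90, tolerance = 1e-9)
  # 30 degrees tilt, invariant to sign flips
  e2 <- c(sin(pi / 6), 0, cos(pi / 6))
  expect_equal(e2a_map(eig_decompose(mk(c(0, 1, 0), e2)), coords)[1, 1],
               30, tolerance = 1e-9)
  expect_equal(e2a_map(eig_decompose(mk(c(0, -1, 0), -e2)), coords)[1, 1],
               30, tolerance = 1e-9)
})

test_that("angle maps are invariant under in-plane rotation of the dataset", {
  spec <- small_spec(e2a = c(systole = 35, sweetspot = 30, diastole = 20))
  tf <- build_tensor_field(spec, "systole")
  maps <- compute_scalar_maps(tf$tensors, tf$coords)
  # rotate the whole dataset by 90 degrees: pixel (i, j) -> (j, n + 1 - i),
  # tensors conjugated by the rotation
  n <- spec$grid_size
  R <- rot_z(pi / 2)
  rot90_mat <- function(m) {
    out <- matrix(NA_real_, n, n)
    for (i in 1:n) for (j in 1:n) out[j, n + 1 - i] <- m[i, j]
    out
  }
  Drot <- array(NA_real_, dim(tf$tensors$D))
  idx <- which(tf$coords$mask, arr.ind = TRUE)
  Dm <- tf$tensors$D
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    d6 <- c(Dm[i, j, 1], Dm[i, j, 2], Dm[i, j, 3],
            Dm[i, j, 4], Dm[i, j, 5], Dm[i, j, 6])
    M <- R %*% matrix(c(d6[1], d6[4], d6[5], d6[4], d6[2], d6[6],
                        d6[5], d6[6], d6[3]), 3, 3) %*% t(R)
    Drot[j, n + 1 - i, ] <- c(M[1, 1], M[2, 2], M[3, 3],
                              M[1, 2], M[1, 3], M[2, 3])
  }
  mask_rot <- rot90_mat(tf$coords$mask * 1) > 0.5
  tensors_rot <- structure(list(D = Drot, mask = mask_rot,
                                valid = mask_rot, lnS0 = NULL, rms = NULL),
                           class = "tensor_field")
  # the annulus is symmetric, so the coordinate field is unchanged
  maps_rot <- compute_scalar_maps(tensors_rot, tf$coords)
  for (m in c("ha", "ta", "e2a", "md", "fa"))
    expect_lt(max_map_diff(maps_rot[[m]], rot90_mat(maps[[m]])), 1e-6)
})

test_that("negative eigenvalues keep MD but flag anisotropy measures", {
  d <- diag(c(2e-3, 1e-3, -1e-4))
  tfield <- tensor_field_from(d, 2)
  ef <- eig_decompose(tfield)
  expect_false(ef$spd[1, 1])
  inv <- scalar_invariants(ef)
  expect_equal(inv$md[1, 1], mean(diag(d)))  # unclamped
  expect_true(is.na(inv$fa[1, 1]))
  expect_true(is.na(inv$mode[1, 1]))
})

test_that("cardiac coordinates from contours match the analytic annulus", {
  spec <- small_spec()
  coords <- annulus_coordinates(spec, "diastole")
  epi <- circle_contour(spec$epi_radius_mm[["diastole"]], spec$centre,
                        spec$pixdim, 360)
  endo <- circle_contour(spec$endo_radius_mm[["diastole"]], spec$centre,
                         spec$pixdim, 360)
  built <- build_cardiac_coordinates(coords$mask, epi, endo,
                                     pixdim = spec$pixdim)
  idx <- which(coords$mask)
  # radial direction agrees with the outward centroid ray
  dots <- built$radial[, , 1][idx] * coords$radial[, , 1][idx] +
    built$radial[, , 2][idx] * coords$radial[, , 2][idx]
  expect_gt(min(dots), 0.99)
  # depth agrees with the analytic normalised distance
  expect_lt(max(abs(built$depth[idx] - coords$depth[idx])), 0.05)
  # triad orthonormality
  rr <- cbind(built$radial[, , 1][idx], built$radial[, , 2][idx],
              built$radial[, , 3][idx])
  cc <- cbind(built$circ[, , 1][idx], built$circ[, , 2][idx],
              built$circ[, , 3][idx])
  expect_lt(max(abs(rowSums(rr * cc))), 1e-12)
  expect_lt(max(abs(rowSums(rr^2) - 1)), 1e-12)
  expect_error(build_cardiac_coordinates(coords$mask, epi[1:2, ], endo,
                                         spec$pixdim), "polygon")
})
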