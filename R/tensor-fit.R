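#' b-matrix design row
#'
#' Expands a (b, g) pair into the 6-vector multiplying the unique tensor
#' elements in the log-linear model
#' `ln S = ln S0 - b g' D g`, with storage order
#' (xx, yy, zz, xy, xz, yz):
#' `(b gx^2, b gy^2, b gz^2, 2 b gx gy, 2 b gx gz, 2 b gy gz)`.
#' The trace of the implied matrix equals b for unit g.
#'
#' @param b b-value (s/mm^2).
#' @param g Unit direction vector, length 3.
#' @return Numeric length-6 expansion.
#' @export
b_matrix_row <- function(b, g) {
  c(b * g[1]^2, b * g[2]^2, b * g[3]^2,
    2 * b * g[1] * g[2], 2 * b * g[1] * g[3], 2 * b * g[2] * g[3])
}

#' Pixelwise linear least-squares diffusion tensor fit
#'
#' Ordinary least squares of the log signal on `[1, -b_matrix_row]` at
#' every myocardial pixel, with each frame entering the inversion as a
#' separate observation (no prior averaging). Both shells (reference and
#' main b-value) contribute; no separate b = 0 image is used. Pixels with
#' any non-positive signal inside the mask are flagged invalid rather than
#' silently log-clipped. A global intensity scale is absorbed by the
#' `ln S0` intercept.
#'
#' @param series A preprocessed [dwi_series()] with at least 7 frames
#'   spanning at least 6 non-coplanar directions over two shells.
#' @param mask Optional logical fit mask; defaults to the series
#'   myocardial mask.
#' @return A `tensor_field`: list with `D` (`[n, n, 6]`, mm^2/s), `lnS0`,
#'   `rms` (per-pixel residual RMS of the log fit), `mask` and `valid`.
#' @export
fit_tensor_lls <- function(series, mask = NULL) {
  mask <- mask %||% series$masks$myocardium
  if (is.null(mask) || !any(mask)) stop("empty fit mask")
  nf <- n_frames(series)
  if (nf < 7) stop("need at least 7 frames for the tensor fit")
  X <- cbind(1, -t(vapply(seq_len(nf), function(i)
    b_matrix_row(series$b[i], series$dirs[i, ]), numeric(6))))
  if (qr(X)$rank < 7) stop("rank-deficient design matrix")
  idx <- which(mask)
  nr <- dim(series$frames)[1]
  S <- matrix(series$frames, nrow = nr * dim(series$frames)[2])[idx, ,
                                                                drop = FALSE]
  S <- t(S)  # frames x pixels
  valid_px <- colSums(S <= 0) == 0
  n <- dim(series$frames)[1]
  D <- array(NA_real_, c(n, n, 6))
  lnS0 <- matrix(NA_real_, n, n)
  rms <- matrix(NA_real_, n, n)
  if (any(valid_px)) {
    Y <- log(S[, valid_px, drop = FALSE])
    beta <- qr.coef(qr(X), Y)
    resid <- Y - X %*% beta
    vidx <- idx[valid_px]
    lnS0[vidx] <- beta[1, ]
    for (k in 1:6) {
      plane <- D[, , k]
      plane[vidx] <- beta[k + 1, ]
      D[, , k] <- plane
    }
    rms[vidx] <- sqrt(colMeans(resid^2))
  }
  valid <- mask
  valid[idx[!valid_px]] <- FALSE
  structure(list(D = D, lnS0 = lnS0, rms = rms, mask = mask, valid = valid),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d x %d grid, %d fitted pixels (%d valid)\n",
              dim(x$D)[1], dim(x$D)[2], sum(x$mask), sum(x$valid)))
  invisible(x)
}
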