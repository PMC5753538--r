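#' Null hyperintense blood pixels before registration
#'
#' Pixels whose intensity exceeds `threshold_factor` times the median
#' myocardial intensity of their frame are set to zero and their original
#' values recorded in a restore ledger, so the bright blood pool does not
#' bias the similarity metric during rigid registration. The original
#' intensities are returned after registration with
#' [restore_blood_pixels()].
#'
#' @param series A [dwi_series()] with a myocardial mask.
#' @param threshold_factor Multiple of the per-frame median myocardial
#'   intensity above which a pixel is nulled (default 2).
#' @return List with elements `series` (nulled) and `ledger` (per-frame
#'   linear indices and original values).
#' @export
null_blood_pixels <- function(series, threshold_factor = 2) {
  myo <- series$masks$myocardium
  if (is.null(myo) || !any(myo)) stop("empty myocardial mask")
  ledger <- vector("list", n_frames(series))
  for (i in seq_len(n_frames(series))) {
    img <- series$frames[, , i]
    thr <- threshold_factor * stats::median(img[myo])
    hit <- which(img > thr)
    ledger[[i]] <- list(idx = hit, values = img[hit])
    if (length(hit) > 0) {
      img[hit] <- 0
      series$frames[, , i] <- img
    }
  }
  list(series = series, ledger = ledger)
}

#' Restore nulled blood intensities after registration
#'
#' Writes the original intensities back at their nulled locations,
#' displaced by the (rounded) translation applied to each frame during
#' registration so the restored values follow the registered image.
#'
#' @param series Registered [dwi_series()].
#' @param ledger Restore ledger from [null_blood_pixels()].
#' @param shifts Optional `n_frames x 2` matrix of applied shifts
#'   (`c(dy, dx)` per frame, as returned by [register_frames()]); zero if
#'   missing.
#' @return The series with blood intensities restored.
#' @export
restore_blood_pixels <- function(series, ledger, shifts = NULL) {
  nr <- dim(series$frames)[1]; nc <- dim(series$frames)[2]
  for (i in seq_len(n_frames(series))) {
    entry <- ledger[[i]]
    if (length(entry$idx) == 0) next
    dy <- 0; dx <- 0
    if (!is.null(shifts)) { dy <- round(shifts[i, 1]); dx <- round(shifts[i, 2]) }
    r <- ((entry$idx - 1) %% nr) + 1 + dy
    cc <- ((entry$idx - 1) %/% nr) + 1 + dx
    ok <- r >= 1 & r <= nr & cc >= 1 & cc <= nc
    if (!all(ok))
      warning("some restored blood pixels fell outside the grid")
    img <- series$frames[, , i]
    img[cbind(r[ok], cc[ok])] <- entry$values[ok]
    series$frames[, , i] <- img
  }
  series
}

# Normalized cross-correlation between two images over their overlap after
# shifting `img` by (dy, dx).
ncc_at_shift <- function(img, ref, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  r1 <- max(1, 1 + dy):min(nr, nr + dy)
  c1 <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(r1) < 4 || length(c1) < 4) return(-Inf)
  a <- img[r1 - dy, c1 - dx]
  b <- ref[r1, c1]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(-Inf)
  stats::cor(as.vector(a), as.vector(b))
}

# Estimate the shift that moves `img` content onto `ref`: integer search
# over +/- max_shift followed by parabolic subpixel refinement of the NCC
# surface around the integer peak.
estimate_shift <- function(img, ref, max_shift = 10, subpixel = TRUE) {
  m <- max_shift
  cc <- matrix(-Inf, 2 * m + 1, 2 * m + 1)
  for (iy in -m:m)
    for (ix in -m:m)
      cc[iy + m + 1, ix + m + 1] <- ncc_at_shift(img, ref, iy, ix)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  dy <- pk[1] - m - 1; dx <- pk[2] - m - 1
  if (subpixel) {
    refine <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (!is.finite(den) || den >= 0) return(0)
      d <- 0.5 * (cm - cp) / den
      max(-0.5, min(0.5, d))
    }
    if (pk[1] > 1 && pk[1] < nrow(cc))
      dy <- dy + refine(cc[pk[1] - 1, pk[2]], cc[pk[1], pk[2]],
                        cc[pk[1] + 1, pk[2]])
    if (pk[2] > 1 && pk[2] < ncol(cc))
      dx <- dx + refine(cc[pk[1], pk[2] - 1], cc[pk[1], pk[2]],
                        cc[pk[1], pk[2] + 1])
  }
  c(dy, dx)
}

#' Rigid-translation registration of a diffusion series
#'
#' Each frame is translated (no rotation or scaling) to maximise its
#' normalized cross-correlation with the pixelwise median image of the
#' series, searching integer shifts up to `max_shift` pixels with
#' parabolic subpixel refinement. NCC is invariant to the global intensity
#' differences between shells and directions, so the median image is a
#' usable structural reference across all frames.
#'
#' @param series A [dwi_series()] with at least 2 frames.
#' @param max_shift Integer search radius (pixels).
#' @param subpixel Apply parabolic subpixel refinement (default TRUE).
#' @return List with `series` (registered) and `shifts` (`n_frames x 2`
#'   matrix of the applied translations `c(dy, dx)`).
#' @export
register_frames <- function(series, max_shift = 10, subpixel = TRUE) {
  nf <- n_frames(series)
  if (nf < 2) stop("need at least 2 frames to register")
  if (all(series$frames == 0)) stop("all-zero frames cannot be registered")
  ref <- apply(series$frames, c(1, 2), stats::median)
  shifts <- matrix(0, nf, 2)
  for (i in seq_len(nf)) {
    # estimate_shift returns the corrective translation directly (the
    # negation of the frame's displacement)
    shifts[i, ] <- estimate_shift(series$frames[, , i], ref, max_shift,
                                  subpixel)
    if (any(shifts[i, ] != 0))
      series$frames[, , i] <- translate_image(series$frames[, , i],
                                              shifts[i, 1], shifts[i, 2])
  }
  list(series = series, shifts = shifts)
}

#' Reject residually corrupted frames
#'
#' Automated surrogate for visual quality control: after registration,
#' each frame is correlated with the pixelwise median image of its
#' (b-value, direction) condition (conditions with fewer than 3 frames
#' fall back to the series-wide median) and frames below `min_correlation`
#' are dropped.
#'
#' @param series Registered [dwi_series()].
#' @param min_correlation Pearson correlation threshold (default 0.8).
#' @return List with `series` (survivors only) and `rejected` (original
#'   frame indices dropped).
#' @export
reject_frames <- function(series, min_correlation = 0.8) {
  nf <- n_frames(series)
  key <- paste(signif(series$b, 6),
               apply(round(series$dirs, 6), 1, paste, collapse = ","))
  global_med <- apply(series$frames, c(1, 2), stats::median)
  keep <- rep(TRUE, nf)
  for (g in unique(key)) {
    members <- which(key == g)
    ref <- if (length(members) >= 3)
      apply(series$frames[, , members, drop = FALSE], c(1, 2), stats::median)
    else global_med
    for (i in members) {
      r <- stats::cor(as.vector(series$frames[, , i]), as.vector(ref))
      if (!is.finite(r) || r < min_correlation) keep[i] <- FALSE
    }
  }
  rejected <- which(!keep)
  survivors <- which(keep)
  if (length(survivors) < 7 ||
      length(unique(key[survivors])) < 7)
    stop("frame rejection would leave a rank-deficient tensor fit (< 7 ",
         "usable frames/conditions)")
  series$frames <- series$frames[, , survivors, drop = FALSE]
  series$b <- series$b[survivors]
  series$dirs <- series$dirs[survivors, , drop = FALSE]
  series$rr_ms <- series$rr_ms[survivors]
  series$corrupted <- series$corrupted[survivors]
  if (!is.null(series$truth$b_true))
    series$truth$b_true <- series$truth$b_true[survivors]
  list(series = series, rejected = rejected)
}

#' Beat-to-beat b-value correction for STEAM
#'
#' For a stimulated-echo acquisition the diffusion time equals the RR
#' interval of the encoding beat, so the effective b-value of frame i is
#' `b_i' = b_nominal * (RR_i - delta/3) / (RR_nominal - delta/3)`
#' (Stejskal-Tanner dependence `b = gamma^2 G^2 delta^2 (Delta - delta/3)`
#' with `Delta = RR`). Frames of an M2-SE series pass through unchanged:
#' its diffusion time is set by the gradient lobes, not the beat length.
#'
#' @param series A [dwi_series()].
#' @param nominal_rr Nominal RR interval (ms).
#' @param delta Diffusion gradient duration (ms).
#' @return The series with per-frame `b` replaced by corrected values
#'   (STEAM only).
#' @export
#' @examples
#' # b = 450, RR 1100 vs nominal 1000, delta = 2.4 ms -> about 495 s/mm^2
correct_b_values <- function(series, nominal_rr = 1000, delta = 2.4) {
  if (series$tag != "STEAM") return(series)
  d3 <- delta / 3
  if (any(series$rr_ms <= d3))
    stop("RR interval not exceeding delta/3; corrected b undefined")
  series$b <- series$b * (series$rr_ms - d3) / (nominal_rr - d3)
  series
}
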