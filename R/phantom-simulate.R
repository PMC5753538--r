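#' Simulate a diffusion-weighted acquisition of the phantom
#'
#' Forward model: each frame follows the monoexponential tensor signal
#' `S = S0 * exp(-b_true * g' D g)` at the ground-truth tensor of its
#' pixel, with one frame per (shell, direction, average). The RR interval
#' of each frame's encoding beat is drawn from a truncated Gaussian
#' `N(rr_nominal, jitter^2)`; for STEAM the diffusion time spans the
#' drawn beat, so the true encoding b scales with
#' `(RR - delta/3) / (RR_nominal - delta/3)` while the stored nominal b
#' does not (mirroring what a scanner records) - the beat-to-beat
#' correction in [correct_b_values()] recovers the true values. Blood-pool
#' pixels carry a constant hyperintense signal (`blood_mult * s0`,
#' flow-dominated rather than diffusion-attenuated), emulating incomplete
#' nulling of the blood signal. Magnitude (Rician) noise is the modulus of
#' the complex signal after adding independent Gaussian noise of standard
#' deviation `sigma` to each channel.
#'
#' @param field Output of [build_tensor_field()] (tensors + coords).
#' @param protocol An [acquisition_protocol()].
#' @param seed Integer seed; the series is reproducible bitwise.
#' @param spec The generating [lv_phantom_spec()] (for s0, sigma,
#'   blood_mult and masks). Defaults to attributes carried by `field` if
#'   present.
#' @param phase Cardiac phase label (for the blood mask).
#' @return A [dwi_series()] with ground truth in `$truth`.
#' @export
simulate_dwis <- function(field, protocol, seed, spec, phase) {
  stopifnot(inherits(protocol, "acquisition_protocol"),
            inherits(spec, "lv_phantom_spec"))
  if (spec$sigma < 0) stop("sigma must be non-negative")
  if (spec$s0 <= 0) stop("s0 must be positive")
  tensors <- field$tensors
  n <- dim(tensors$D)[1]
  masks <- phantom_masks(spec, phase)
  if (!identical(dim(masks$myocardium), dim(tensors$mask)))
    stop("tensor field and protocol grids are inconsistent")
  set.seed(as.integer(seed))
  shells <- rbind(
    data.frame(b = rep(protocol$b_main, protocol$averages_main *
                         nrow(protocol$directions)),
               dir = rep(seq_len(nrow(protocol$directions)),
                         times = protocol$averages_main)),
    data.frame(b = rep(protocol$b_ref, protocol$averages_ref *
                         nrow(protocol$directions)),
               dir = rep(seq_len(nrow(protocol$directions)),
                         times = protocol$averages_ref)))
  nf <- nrow(shells)
  rr <- rnorm_truncpos(nf, protocol$rr_nominal_ms, protocol$rr_jitter_ms)
  d3 <- protocol$delta_ms / 3
  b_true <- shells$b
  if (protocol$sequence == "STEAM") {
    if (any(rr <= d3)) stop("drawn RR interval shorter than delta/3")
    b_true <- shells$b * (rr - d3) / (protocol$rr_nominal_ms - d3)
  }
  idx <- which(tensors$mask)
  # per-pixel projected diffusivity g' D g for each direction
  gdg <- matrix(0, length(idx), nrow(protocol$directions))
  for (k in seq_len(nrow(protocol$directions))) {
    g <- protocol$directions[k, ]
    gdg[, k] <- tensors$D[, , 1][idx] * g[1]^2 +
      tensors$D[, , 2][idx] * g[2]^2 +
      tensors$D[, , 3][idx] * g[3]^2 +
      2 * tensors$D[, , 4][idx] * g[1] * g[2] +
      2 * tensors$D[, , 5][idx] * g[1] * g[3] +
      2 * tensors$D[, , 6][idx] * g[2] * g[3]
  }
  frames <- array(0, c(n, n, nf))
  blood_sig <- spec$blood_mult * spec$s0
  for (i in seq_len(nf)) {
    img <- matrix(0, n, n)
    img[idx] <- spec$s0 * exp(-b_true[i] * gdg[, shells$dir[i]])
    img[masks$blood] <- blood_sig
    if (spec$sigma > 0) {
      re <- img + stats::rnorm(n * n, 0, spec$sigma)
      im <- stats::rnorm(n * n, 0, spec$sigma)
      img <- sqrt(re^2 + im^2)
    }
    frames[, , i] <- img
  }
  dwi_series(frames, b = shells$b,
             dirs = protocol$directions[shells$dir, , drop = FALSE],
             rr_ms = rr, tag = protocol$sequence, masks = masks,
             pixdim = spec$pixdim,
             truth = list(tensors = tensors, coords = field$coords,
                          spec = spec, phase = phase, b_true = b_true),
             provenance = list(seed = as.integer(seed),
                               protocol = protocol))
}

#' Inject motion corruption into selected frames
#'
#' Corrupts a random subset of frames and records which ones in the
#' provenance ledger, so registration and rejection stages can be audited
#' against known corruption. Two corruption modes: `"shift"` translates
#' the frame by a fixed (possibly subpixel) displacement, emulating bulk
#' motion that rigid registration can recover; `"noise"` replaces the
#' frame with pure noise at its own intensity scale, emulating motion
#' signal loss that only frame rejection can handle.
#'
#' @param series A [dwi_series()].
#' @param n_shifted Number of frames to corrupt.
#' @param shift Length-2 shift `c(dy, dx)` in pixels (content moves by
#'   `+shift`); ignored for `mode = "noise"`.
#' @param seed Integer seed for the frame selection.
#' @param mode `"shift"` (default) or `"noise"`.
#' @return The corrupted series; `$provenance$corruption` holds the frame
#'   indices, mode and the applied shift.
#' @export
inject_artifacts <- function(series, n_shifted, shift = c(0, 0), seed = 1,
                             mode = c("shift", "noise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "dwi_series"), length(shift) == 2)
  nf <- n_frames(series)
  if (n_shifted >= nf) stop("n_shifted must be smaller than the frame count")
  if (any(abs(shift) >= dim(series$frames)[1]))
    stop("shift exceeds the image extent")
  if (n_shifted == 0) return(series)
  set.seed(as.integer(seed))
  which_frames <- sort(sample.int(nf, n_shifted))
  for (i in which_frames) {
    if (mode == "shift")
      series$frames[, , i] <- translate_image(series$frames[, , i],
                                              shift[1], shift[2])
    else {
      sc <- stats::sd(series$frames[, , i])
      series$frames[, , i] <- matrix(
        abs(stats::rnorm(length(series$frames[, , i]), 0, max(sc, 1))),
        dim(series$frames)[1], dim(series$frames)[2])
    }
  }
  series$corrupted[which_frames] <- TRUE
  series$provenance$corruption <- list(frames = which_frames,
                                       shift = shift, mode = mode)
  series
}
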