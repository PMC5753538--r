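#' Diffusion-weighted image series
#'
#' Container for an ordered stack of 2D magnitude frames with per-frame
#' acquisition metadata: nominal b-value, unit encoding direction, RR
#' interval of the encoding beat, sequence tag and a corruption flag.
#' Synthetic series additionally carry their ground truth (tensor field,
#' coordinates, generating spec) in `$truth` and a corruption ledger in
#' `$provenance`.
#'
#' @param frames 3D array `[rows, cols, n_frames]` of magnitude images.
#' @param b Numeric vector of per-frame b-values (s/mm^2).
#' @param dirs `n_frames x 3` matrix of unit encoding directions.
#' @param rr_ms Per-frame RR interval of the encoding beat (ms).
#' @param tag Sequence tag, `"STEAM"` or `"M2SE"` (scalar).
#' @param corrupted Logical per-frame corruption flags.
#' @param masks List of logical matrices: `myocardium`, `blood`,
#'   `exclusion`.
#' @param pixdim Pixel spacing (mm).
#' @param truth,provenance Optional ground truth / provenance lists.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(frames, b, dirs, rr_ms, tag,
                       corrupted = rep(FALSE, length(b)),
                       masks = NULL, pixdim = 1,
                       truth = NULL, provenance = list()) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3) stop("frames must be a 3D array")
  nf <- dim(frames)[3]
  dirs <- as.matrix(dirs)
  if (length(b) != nf || nrow(dirs) != nf || length(rr_ms) != nf ||
      length(corrupted) != nf)
    stop("per-frame metadata length must equal the frame count")
  if (!tag %in% c("STEAM", "M2SE")) stop("tag must be STEAM or M2SE")
  if (!is.null(masks)) {
    for (m in masks)
      if (!identical(dim(m), dim(frames)[1:2]))
        stop("masks must share the frame grid")
  }
  structure(list(frames = frames, b = as.numeric(b), dirs = dirs,
                 rr_ms = as.numeric(rr_ms), tag = tag,
                 corrupted = as.logical(corrupted), masks = masks,
                 pixdim = pixdim, truth = truth, provenance = provenance),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dwi_series> %s, %d frames of %d x %d, b in [%g, %g] s/mm^2\n",
              x$tag, d[3], d[1], d[2], min(x$b), max(x$b)))
  invisible(x)
}

n_frames <- function(series) dim(series$frames)[3]

#' Write / read a diffusion series as NIfTI + JSON sidecar
#'
#' Frames are stored as a single 3D NIfTI volume (rows x cols x frames),
#' masks as separate NIfTI volumes, and per-frame metadata in a JSON
#' sidecar `{"tag": ..., "pixdim": ..., "frames": [{"b", "dir", "rr_ms",
#' "corrupted"}, ...]}`. Ground truth is not serialised.
#'
#' @param series A [dwi_series()].
#' @param dir Output directory (created if missing).
#' @return `write_dwi_series` returns `dir` invisibly; `read_dwi_series`
#'   returns a [dwi_series()].
#' @export
write_dwi_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(series$frames),
                     file.path(dir, "frames.nii.gz"))
  if (!is.null(series$masks)) {
    for (nm in names(series$masks))
      RNifti::writeNifti(RNifti::asNifti(series$masks[[nm]] * 1L),
                         file.path(dir, paste0("mask_", nm, ".nii.gz")))
  }
  meta <- list(tag = series$tag, pixdim = series$pixdim,
               frames = lapply(seq_along(series$b), function(i) {
                 list(b = series$b[i], dir = series$dirs[i, ],
                      rr_ms = series$rr_ms[i],
                      corrupted = series$corrupted[i])
               }))
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dwi_series
#' @export
read_dwi_series <- function(dir) {
  frames <- as.array(RNifti::readNifti(file.path(dir, "frames.nii.gz")))
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  masks <- NULL
  mask_files <- list.files(dir, pattern = "^mask_.*\\.nii\\.gz$",
                           full.names = TRUE)
  if (length(mask_files) > 0) {
    masks <- lapply(mask_files, function(f)
      as.array(RNifti::readNifti(f)) > 0.5)
    names(masks) <- sub("^mask_(.*)\\.nii\\.gz$", "\\1", basename(mask_files))
  }
  fr <- meta$frames
  dwi_series(frames, b = fr$b, dirs = do.call(rbind, fr$dir),
             rr_ms = fr$rr_ms, tag = meta$tag, corrupted = fr$corrupted,
             masks = masks, pixdim = meta$pixdim)
}
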