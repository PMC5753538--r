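#' Transmural helix-angle profiles
#'
#' Samples the HA map along `n_spokes` equally spaced angular rays from
#' the LV centre. Along each spoke the transmural depth field is inverted
#' to locate the radii of fixed depth fractions, and HA is sampled there
#' by bilinear interpolation (samples touching flagged/NA pixels are
#' skipped). Depth is expressed in percent from the epicardium (0%) to the
#' endocardium (100%).
#'
#' @param ha HA map (matrix, degrees).
#' @param coords A `cardiac_coords` field (supplies depth, mask, centre).
#' @param n_spokes Number of angular spokes (default 72, i.e. 5 degree
#'   steps).
#' @param depths Depth fractions sampled on each spoke.
#' @param exclude Optional logical exclusion mask (papillary muscle /
#'   right-ventricular septum surrogate); excluded pixels are skipped.
#' @return List of per-spoke data frames with columns `depth_pct`, `ha`;
#'   spokes with fewer than 3 valid samples are dropped with a warning.
#' @export
extract_profiles <- function(ha, coords, n_spokes = 72,
                             depths = seq(0.1, 0.9, by = 0.1),
                             exclude = NULL) {
  if (n_spokes < 1) stop("n_spokes must be positive")
  if (!is.null(exclude)) ha[exclude] <- NA_real_
  n <- nrow(ha)
  cx <- coords$centre[1]; cy <- coords$centre[2]
  rmax <- n / sqrt(2)
  step <- 0.25
  rs <- seq(step, rmax, by = step)
  mask_num <- coords$mask * 1
  profiles <- list()
  dropped <- 0
  for (k in seq_len(n_spokes)) {
    th <- 2 * pi * (k - 1) / n_spokes
    xs <- cx + rs * cos(th); ys <- cy + rs * sin(th)
    dvals <- bilinear_interp(coords$depth, xs, ys)
    mvals <- bilinear_interp(mask_num, xs, ys)
    inwall <- which(!is.na(mvals) & mvals > 0.99 &
                      dvals >= 0 & dvals <= 1)
    samp <- data.frame(depth_pct = numeric(0), ha = numeric(0))
    if (length(inwall) >= 2) {
      rw <- rs[inwall]; dw <- dvals[inwall]
      for (d in depths) {
        # depth decreases with radius; find bracketing pair
        j <- which(dw[-length(dw)] >= d & dw[-1] <= d)
        if (length(j) == 0) next
        j <- j[1]
        f <- (d - dw[j]) / (dw[j + 1] - dw[j])
        rq <- rw[j] + f * (rw[j + 1] - rw[j])
        hv <- bilinear_interp(ha, cx + rq * cos(th), cy + rq * sin(th))
        if (!is.na(hv))
          samp <- rbind(samp, data.frame(depth_pct = 100 * d, ha = hv))
      }
    }
    if (nrow(samp) >= 3) profiles[[length(profiles) + 1]] <- samp
    else dropped <- dropped + 1
  }
  if (dropped > 0)
    warning(sprintf("%d spokes dropped (< 3 valid samples)", dropped))
  profiles
}

#' Transmural HA gradient and linear-fit quality statistics
#'
#' Fits an ordinary least-squares line of HA against transmural depth (%)
#' on each spoke. The wall-thickness-normalised helix-angle gradient (HAG,
#' degrees per % depth) is the mean per-spoke slope; HA R-squared and HA
#' RMSE are the mean per-spoke regression R^2 and root-mean-square
#' residual. R^2 of a zero-variance (constant HA) regression is defined as
#' 0. With depth running epicardium (0%) to endocardium (100%), the
#' default phantom convention gives a positive HAG.
#'
#' An alternative pooled estimate (single regression over all samples of
#' all spokes) is available via `method = "pooled"`.
#'
#' @param profiles Output of [extract_profiles()].
#' @param method `"mean_of_spokes"` (default) or `"pooled"`.
#' @return List with `hag` (deg/%), `r2`, `rmse` (deg), `slopes`
#'   (per-spoke), `n_spokes`.
#' @export
hag_fit_stats <- function(profiles, method = c("mean_of_spokes", "pooled")) {
  method <- match.arg(method)
  if (length(profiles) == 0) stop("no valid transmural profiles")
  fit_one <- function(p) {
    fit <- stats::lm(ha ~ depth_pct, data = p)
    ss_tot <- sum((p$ha - mean(p$ha))^2)
    ss_res <- sum(stats::residuals(fit)^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
    c(slope = unname(stats::coef(fit)[2]), r2 = r2,
      rmse = sqrt(mean(stats::residuals(fit)^2)))
  }
  if (method == "pooled") {
    pooled <- do.call(rbind, profiles)
    s <- fit_one(pooled)
    return(list(hag = s[["slope"]], r2 = s[["r2"]], rmse = s[["rmse"]],
                slopes = s[["slope"]], n_spokes = length(profiles)))
  }
  stats_mat <- vapply(profiles, fit_one, numeric(3))
  list(hag = mean(stats_mat["slope", ]), r2 = mean(stats_mat["r2", ]),
       rmse = mean(stats_mat["rmse", ]), slopes = stats_mat["slope", ],
       n_spokes = length(profiles))
}

#' Transverse-angle standard deviation
#'
#' Quality measure built on the assumption that the transverse angle is
#' constant within a slice: the standard deviation of TA over the LV mask
#' (flagged pixels excluded). Shift-invariant by construction.
#'
#' @param ta TA map (degrees).
#' @param mask Logical LV mask.
#' @return Standard deviation (degrees).
#' @export
ta_std <- function(ta, mask) {
  v <- ta[mask]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 valid pixels for TA std")
  stats::sd(v)
}

#' Score an HA map from its transmural profiles
#'
#' Automated surrogate for visual HA-map scoring. A spoke is "normal" if
#' its transmural linear fit has R^2 of at least `r2_threshold` and a
#' slope of the expected sign. The fraction f of normal spokes maps to the
#' rubric: f > 0.95 scores 3, f > 0.75 scores 2, f >= 0.5 scores 1,
#' otherwise 0; a score of 0 marks the acquisition as failed. The R^2
#' threshold and slope-sign convention are configurable surrogates for the
#' visual criterion.
#'
#' @param profiles Output of [extract_profiles()].
#' @param r2_threshold Per-spoke linearity threshold (default 0.3).
#' @param slope_sign Expected slope sign (+1 for the default epi-0 to
#'   endo-100 convention with HA rising towards the endocardium).
#' @param normal_fraction Directly supply the normal fraction instead of
#'   profiles (profiles may then be NULL).
#' @return List with `score` (0-3), `normal_fraction`, `failed`.
#' @export
score_ha_map <- function(profiles = NULL, r2_threshold = 0.3,
                         slope_sign = 1, normal_fraction = NULL) {
  if (is.null(normal_fraction)) {
    if (length(profiles) == 0) stop("no profiles to score")
    normal <- vapply(profiles, function(p) {
      fit <- stats::lm(ha ~ depth_pct, data = p)
      ss_tot <- sum((p$ha - mean(p$ha))^2)
      r2 <- if (ss_tot > 0)
        1 - sum(stats::residuals(fit)^2) / ss_tot else 0
      r2 >= r2_threshold && sign(stats::coef(fit)[2]) == sign(slope_sign)
    }, logical(1))
    normal_fraction <- mean(normal)
  }
  score <- if (normal_fraction > 0.95) 3L
  else if (normal_fraction > 0.75) 2L
  else if (normal_fraction >= 0.5) 1L
  else 0L
  list(score = score, normal_fraction = normal_fraction,
       failed = score == 0L)
}

#' SNR per image from repeated measurements
#'
#' For repeats of the same (b, direction) condition, the per-pixel SNR is
#' the ratio of the temporal mean to the temporal standard deviation of
#' the signal; the reported SNR per image is the mean of that ratio over a
#' region of interest. Zero-SD pixels are excluded with a warning rather
#' than returned as infinite SNR. The estimator is invariant to a global
#' intensity scale.
#'
#' @param frames 3D array `[rows, cols, repeats]` of the same condition,
#'   at least 3 repeats.
#' @param roi Logical ROI mask.
#' @return Mean ROI SNR (dimensionless).
#' @export
snr_repeated_measures <- function(frames, roi) {
  if (dim(frames)[3] < 3) stop("need at least 3 repeats of the condition")
  mu <- apply(frames, c(1, 2), mean)
  sdv <- apply(frames, c(1, 2), stats::sd)
  ratio <- ifelse(sdv > 0, mu / sdv, NA_real_)
  v <- ratio[roi]
  if (anyNA(v)) {
    warning("zero-SD pixels excluded from the SNR ROI")
    v <- v[!is.na(v)]
  }
  if (length(v) == 0) stop("no usable pixels in the SNR ROI")
  mean(v)
}

#' Mean-signal ratio between two series
#'
#' Ratio of mean ROI intensities, used as a surrogate for the SNR ratio
#' when the noise level is matched between acquisitions.
#'
#' @param frames_a,frames_b 3D frame arrays (or matrices).
#' @param roi Logical ROI mask, shared by both.
#' @return `mean(A[roi]) / mean(B[roi])`.
#' @export
mean_signal_ratio <- function(frames_a, frames_b, roi) {
  ma <- mean(apply_roi_mean(frames_a, roi))
  mb <- mean(apply_roi_mean(frames_b, roi))
  if (mb == 0) stop("zero denominator in mean signal ratio")
  ma / mb
}

apply_roi_mean <- function(frames, roi) {
  if (length(dim(frames)) == 2) return(mean(frames[roi]))
  apply(frames, 3, function(f) mean(f[roi]))
}

#' Summarise one acquisition into a study-table row
#'
#' Mean LV values of MD, FA and mode (E2A summarised by its median, since
#' it is not expected to be normally distributed), merged with the
#' HA-profile quality statistics, after removing pixels in the exclusion
#' mask (papillary muscles / right-ventricular septum surrogate). Invalid
#' (flagged) pixels are excluded. The input maps are never modified.
#'
#' @param maps Output of [compute_scalar_maps()].
#' @param mask Logical LV myocardial mask.
#' @param exclude Optional logical exclusion mask.
#' @param quality Optional named list merged into the row (e.g. `hag`,
#'   `ha_r2`, `ha_rmse`, `ta_std`, `score`, `snr`).
#' @return One-row `data.frame`.
#' @export
summarize_lv <- function(maps, mask, exclude = NULL, quality = list()) {
  keep <- mask
  if (!is.null(exclude)) keep <- keep & !exclude
  if (!any(keep)) stop("empty mask after exclusions")
  mstat <- function(m, f) f(m[keep], na.rm = TRUE)
  row <- data.frame(
    md = mstat(maps$md, mean),
    fa = mstat(maps$fa, mean),
    mode = mstat(maps$mode, mean),
    e2a = mstat(maps$e2a, stats::median),
    e1 = mean(maps$evals[, , 1][keep], na.rm = TRUE),
    e2 = mean(maps$evals[, , 2][keep], na.rm = TRUE),
    e3 = mean(maps$evals[, , 3][keep], na.rm = TRUE),
    n_pixels = sum(keep))
  for (nm in names(quality)) row[[nm]] <- quality[[nm]]
  row
}
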