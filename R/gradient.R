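#' Piecewise-linear diffusion gradient waveform
#'
#' A waveform is a sequence of `(time ms, amplitude mT/m)` breakpoints
#' joined linearly, plus the times of refocusing pulses, each of which
#' flips the effective polarity of all subsequent gradient lobes (the spin
#' phase accrued before a 180-degree pulse is negated, so moments and
#' b-values must be computed on the polarity-corrected waveform). Optional
#' hardware limits are validated: `|amplitude| <= gmax` at breakpoints and
#' `|slope| <= slew` between them.
#'
#' @param breakpoints 2-column matrix or data frame `(t_ms, g_mT_m)`,
#'   times non-decreasing.
#' @param refocus Numeric vector of refocusing-pulse times (ms).
#' @param gmax Optional amplitude limit (mT/m).
#' @param slew Optional slew limit (T/m/s, numerically mT/m/ms).
#' @return An object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(breakpoints, refocus = numeric(0),
                              gmax = NULL, slew = NULL) {
  bp <- as.matrix(breakpoints)
  if (ncol(bp) != 2 || nrow(bp) < 2) stop("need >= 2 (t, g) breakpoints")
  if (is.unsorted(bp[, 1])) stop("breakpoints must be time-sorted")
  if (!is.null(gmax) && any(abs(bp[, 2]) > gmax + 1e-9))
    stop("waveform exceeds the amplitude limit")
  if (!is.null(slew)) {
    dt <- diff(bp[, 1]); dg <- diff(bp[, 2])
    rate <- abs(dg[dt > 0] / dt[dt > 0])
    if (any(dt == 0 & dg != 0) || any(rate > slew * (1 + 1e-9)))
      stop("waveform exceeds the slew limit")
  }
  structure(list(breakpoints = bp, refocus = sort(refocus),
                 gmax = gmax, slew = slew),
            class = "gradient_waveform")
}

# Split the waveform into linear segments (t0, t1, g0, g1, polarity),
# with extra nodes at refocusing times.
waveform_segments <- function(w) {
  bp <- w$breakpoints
  tt <- sort(unique(c(bp[, 1], w$refocus[w$refocus > bp[1, 1] &
                                           w$refocus < bp[nrow(bp), 1]])))
  gval <- stats::approx(bp[, 1], bp[, 2], xout = tt, ties = "ordered")$y
  t0 <- tt[-length(tt)]; t1 <- tt[-1]
  mid <- (t0 + t1) / 2
  pol <- (-1)^vapply(mid, function(m) sum(w$refocus <= m), numeric(1))
  keep <- t1 > t0
  data.frame(t0 = t0[keep], t1 = t1[keep],
             g0 = gval[-length(gval)][keep], g1 = gval[-1][keep],
             pol = pol[keep])
}

#' Gradient moments at the echo
#'
#' Exact closed-form moments `Mn = integral of G_eff(t) t^n dt`
#' (n = 0, 1, 2) of the polarity-corrected waveform, evaluated over the
#' full waveform (i.e. at the echo), about t = 0 at the waveform start.
#' Once M0 = 0, M1 is independent of the time reference, and once
#' M0 = M1 = 0 so is M2, so the nulling conditions do not depend on this
#' choice. Units: mT/m times ms^(n+1). The b-value is included when the
#' waveform is refocused (M0 nulled), otherwise `NA`.
#'
#' @param w A [gradient_waveform()].
#' @param gamma Gyromagnetic ratio (rad/s/T), proton by default.
#' @return List `m0`, `m1`, `m2`, `b` (s/mm^2 or NA).
#' @export
compute_moments <- function(w, gamma = 2.675e8) {
  seg <- waveform_segments(w)
  mom <- c(0, 0, 0)
  area_abs <- 0
  for (i in seq_len(nrow(seg))) {
    t0 <- seg$t0[i]; t1 <- seg$t1[i]
    slope <- (seg$g1[i] - seg$g0[i]) / (t1 - t0)
    A <- seg$pol[i] * (seg$g0[i] - slope * t0)
    B <- seg$pol[i] * slope
    for (n in 0:2) {
      mom[n + 1] <- mom[n + 1] +
        A * (t1^(n + 1) - t0^(n + 1)) / (n + 1) +
        B * (t1^(n + 2) - t0^(n + 2)) / (n + 2)
    }
    area_abs <- area_abs + (abs(seg$g0[i]) + abs(seg$g1[i])) / 2 * (t1 - t0)
  }
  b <- NA_real_
  if (area_abs == 0 || abs(mom[1]) <= 1e-6 * max(area_abs, 1e-12))
    b <- compute_b_value(w, gamma = gamma, force = TRUE, quiet = TRUE)
  list(m0 = mom[1], m1 = mom[2], m2 = mom[3], b = b)
}

#' b-value of a gradient waveform
#'
#' `b = gamma^2 integral q(t)^2 dt` with
#' `q(t) = gamma integral_0^t G_eff(tau) dtau`, integrated exactly per
#' linear segment (q is piecewise quadratic, q^2 piecewise quartic).
#' A waveform whose zeroth moment is not nulled at the echo has no
#' well-defined imaging b-value and raises an error unless `force = TRUE`.
#'
#' @param w A [gradient_waveform()].
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @param force Compute anyway for a non-refocused waveform.
#' @param quiet Suppress the non-refocused warning when forcing.
#' @return b-value (s/mm^2).
#' @export
compute_b_value <- function(w, gamma = 2.675e8, force = FALSE,
                            quiet = FALSE) {
  seg <- waveform_segments(w)
  # SI conversion: ms -> s, mT/m -> T/m
  t0s <- seg$t0 * 1e-3; t1s <- seg$t1 * 1e-3
  g0s <- seg$pol * seg$g0 * 1e-3; g1s <- seg$pol * seg$g1 * 1e-3
  q <- 0; b_si <- 0; m0 <- 0; area <- 0
  for (i in seq_len(nrow(seg))) {
    h <- t1s[i] - t0s[i]
    a <- g0s[i]; slope <- (g1s[i] - g0s[i]) / h
    # q(u) = q + gamma*(a u + slope u^2 / 2), u in [0, h]
    c0 <- q; c1 <- gamma * a; c2 <- gamma * slope / 2
    b_si <- b_si + c0^2 * h + c0 * c1 * h^2 +
      (c1^2 + 2 * c0 * c2) * h^3 / 3 + c1 * c2 * h^4 / 2 + c2^2 * h^5 / 5
    q <- c0 + c1 * h + c2 * h^2
    m0 <- m0 + (a + (g1s[i] - g0s[i]) / 2) * h
    area <- area + (abs(g0s[i]) + abs(g1s[i])) / 2 * h
  }
  if (area > 0 && abs(m0) > 1e-6 * area) {
    if (!force) stop("waveform is not refocused (M0 != 0 at echo); ",
                     "b-value ill-defined - use force = TRUE to override")
    if (!quiet) warning("computing b for a non-refocused waveform")
  }
  b_si * 1e-6  # s/m^2 -> s/mm^2
}

# One trapezoidal lobe: returns breakpoints of a lobe starting at t0 with
# signed flat-top amplitude, total duration dur and ramp time ramp
# (triangle when dur == 2 * ramp).
trapezoid_lobe <- function(t0, amplitude, dur, ramp) {
  if (dur < 2 * ramp - 1e-12) stop("lobe shorter than twice the ramp time")
  if (dur <= 2 * ramp + 1e-12)
    rbind(c(t0, 0), c(t0 + dur / 2, amplitude), c(t0 + dur, 0))
  else
    rbind(c(t0, 0), c(t0 + ramp, amplitude),
          c(t0 + dur - ramp, amplitude), c(t0 + dur, 0))
}

#' Stejskal-Tanner gradient pair
#'
#' Two identical lobes of duration `delta` separated by `Delta` (leading
#' edge to leading edge) straddling a refocusing pulse, the classical
#' monopolar diffusion encoding with
#' `b = gamma^2 G^2 delta^2 (Delta - delta/3)` for rectangular lobes.
#' Near-rectangular lobes are generated with ramp time `ramp` (default
#' 1e-3 ms).
#'
#' @param g_amp Amplitude (mT/m).
#' @param delta_ms Lobe duration (ms).
#' @param Delta_ms Lobe separation (ms).
#' @param ramp Ramp time (ms).
#' @return A [gradient_waveform()] with the refocusing marker between the
#'   lobes.
#' @export
stejskal_tanner_waveform <- function(g_amp, delta_ms, Delta_ms,
                                     ramp = 1e-3) {
  l1 <- trapezoid_lobe(0, g_amp, delta_ms, ramp)
  l2 <- trapezoid_lobe(Delta_ms, g_amp, delta_ms, ramp)
  gradient_waveform(rbind(l1, l2),
                    refocus = (delta_ms + Delta_ms) / 2)
}

# Build the 4-lobe motion-compensated waveform: physical pattern
# [+d1, -d2] gap [-d2, +d1]; the refocusing pulse at the gap centre makes
# the effective waveform [+d1, -d2, +d2, -d1], antisymmetric about its
# midpoint, which nulls M0 exactly and leaves a single M1 = 0 condition.
m2_waveform_build <- function(d1, d2, amp, ramp, gap, gmax = NULL,
                              slew = NULL) {
  t <- 0
  l1 <- trapezoid_lobe(t, amp, d1, ramp); t <- t + d1
  l2 <- trapezoid_lobe(t, -amp, d2, ramp); t <- t + d2
  refocus_t <- t + gap / 2
  t <- t + gap
  l3 <- trapezoid_lobe(t, -amp, d2, ramp); t <- t + d2
  l4 <- trapezoid_lobe(t, amp, d1, ramp)
  bp <- rbind(l1, l2, c(t - d2, 0), l3, l4)
  bp <- bp[!duplicated(bp), , drop = FALSE]
  bp <- bp[order(bp[, 1]), , drop = FALSE]
  gradient_waveform(bp, refocus = refocus_t, gmax = gmax, slew = slew)
}

#' Design a first- and second-order moment-nulled diffusion waveform
#'
#' Designs the asymmetric paired-lobe (short + long lobe before the
#' refocusing pulse, mirrored after it) velocity- and
#' acceleration-compensated encoding used by motion-compensated spin-echo
#' sequences. The effective waveform is antisymmetric about its midpoint,
#' which nulls M0 and M2 identically; the long/short duration ratio is
#' solved so M1 vanishes, and the short-lobe duration (or, below the
#' minimum slew-limited duration, the amplitude) is solved so the b-value
#' hits the target. Lobes are slew-limited trapezoids at the maximum
#' amplitude.
#'
#' @param target_b Target b-value (s/mm^2).
#' @param gmax Amplitude limit (mT/m).
#' @param slew Slew limit (T/m/s).
#' @param refocus_gap_ms Gradient-free gap bracketing the refocusing pulse
#'   (ms).
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @param max_duration_ms Optional cap on the total encoding duration;
#'   exceeding it raises an infeasibility error naming the limiting
#'   constraint.
#' @return A [gradient_waveform()]; attribute `"design"` holds the lobe
#'   durations, amplitude, achieved b, residual moments and the
#'   single-lobe moment magnitudes used as the nulling reference.
#' @export
design_m2_waveform <- function(target_b, gmax = 43, slew = 180,
                               refocus_gap_ms = 8, gamma = 2.675e8,
                               max_duration_ms = Inf) {
  if (target_b < 0) stop("target_b must be non-negative")
  if (gmax <= 0 || slew <= 0) stop("gmax and slew must be positive")
  if (target_b == 0)
    return(gradient_waveform(rbind(c(0, 0), c(1, 0)), gmax = gmax,
                             slew = slew))
  ramp <- gmax / slew
  gap <- refocus_gap_ms
  solve_d2 <- function(d1, amp) {
    f <- function(d2) {
      w <- m2_waveform_build(d1, d2, amp, ramp, gap)
      compute_moments(w, gamma)$m1
    }
    stats::uniroot(f, lower = d1, upper = 6 * d1 + 3 * gap + 10,
                   tol = 1e-12)$root
  }
  b_of <- function(d1, amp) {
    d2 <- solve_d2(d1, amp)
    w <- m2_waveform_build(d1, d2, amp, ramp, gap)
    list(b = compute_b_value(w, gamma), d2 = d2, w = w)
  }
  d1_min <- 2 * ramp
  amp <- gmax
  bmin <- b_of(d1_min, amp)
  if (bmin$b >= target_b) {
    # below the minimum slew-limited duration: scale the amplitude
    amp <- gmax * sqrt(target_b / bmin$b)
    d1 <- d1_min
  } else {
    f <- function(d1) b_of(d1, amp)$b - target_b
    upper <- d1_min * 2
    while (f(upper) < 0) {
      upper <- upper * 2
      if (upper > 1e4) stop("infeasible target b under the given limits")
    }
    d1 <- stats::uniroot(f, lower = d1_min, upper = upper, tol = 1e-10)$root
  }
  sol <- b_of(d1, amp)
  total <- max(sol$w$breakpoints[, 1])
  if (total > max_duration_ms)
    stop(sprintf(paste0("infeasible: total encoding duration %.2f ms ",
                        "exceeds max_duration_ms = %g (limiting ",
                        "constraint: gmax/slew)"), total, max_duration_ms))
  w <- m2_waveform_build(d1, sol$d2, amp, ramp, gap, gmax = gmax,
                         slew = slew)
  lobe <- gradient_waveform(trapezoid_lobe(0, amp, sol$d2, ramp))
  lm <- compute_moments(lobe, gamma)
  m <- compute_moments(w, gamma)
  attr(w, "design") <- list(d1 = d1, d2 = sol$d2, amplitude = amp,
                            ramp = ramp, gap = gap, total_ms = total,
                            b = m$b, m0 = m$m0, m1 = m$m1, m2 = m$m2,
                            lobe_m1 = abs(lm$m1), lobe_m2 = abs(lm$m2))
  w
}
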