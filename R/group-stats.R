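#' Paired Wilcoxon comparison of two sequences
#'
#' Paired Wilcoxon signed-rank test of a metric between the two sequences
#' at one cardiac phase. Zero differences are dropped (Wilcoxon
#' convention); the exact distribution is used for up to 25 informative
#' pairs without ties, the normal approximation with continuity correction
#' otherwise.
#'
#' @param summary Study table with columns `subject`, `sequence`, `phase`
#'   and the metric.
#' @param metric Column name to compare.
#' @param phase Cardiac phase to subset.
#' @param sequences The two sequence labels (default STEAM vs M2SE).
#' @param alpha Significance level (default 0.05).
#' @return A `comparison_result` list: `test`, `metric`, `phase`, `n`,
#'   `statistic`, `p_value`, `significant`.
#' @export
compare_sequences <- function(summary, metric, phase,
                              sequences = c("STEAM", "M2SE"),
                              alpha = 0.05) {
  sub <- summary[summary$phase == phase &
                   summary$sequence %in% sequences, ]
  wide <- merge(sub[sub$sequence == sequences[1], c("subject", metric)],
                sub[sub$sequence == sequences[2], c("subject", metric)],
                by = "subject", suffixes = c("_a", "_b"))
  wide <- wide[stats::complete.cases(wide), ]
  if (nrow(wide) < 2) stop("fewer than 2 complete pairs")
  x <- wide[[paste0(metric, "_a")]]
  y <- wide[[paste0(metric, "_b")]]
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    res <- list(statistic = 0, p.value = 1)
  } else {
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    res <- suppressWarnings(
      stats::wilcox.test(d, exact = exact, correct = TRUE))
  }
  structure(list(test = "wilcoxon_signed_rank", metric = metric,
                 phase = phase, n = nrow(wide),
                 statistic = unname(res$statistic),
                 p_value = res$p.value,
                 significant = res$p.value < alpha),
            class = "comparison_result")
}

#' Friedman test across cardiac phases with Bonferroni-corrected pairwise
#' Wilcoxon follow-up
#'
#' Compares a metric across the three cardiac phases within one sequence.
#' Subjects missing any phase are dropped with a warning. If the Friedman
#' test is significant at `alpha`, all pairwise phase comparisons are run
#' as paired Wilcoxon tests against the Bonferroni-corrected threshold
#' `alpha / n_pairs` (0.0167 for three phases).
#'
#' @param summary Study table (see [compare_sequences()]).
#' @param metric Column name.
#' @param sequence Sequence label to subset.
#' @param phases Phase labels (default the study's three phases).
#' @param alpha Significance level for the Friedman test.
#' @return List with `friedman` (`statistic`, `p_value`, `significant`),
#'   `bonferroni_alpha` and `pairwise` (list of `comparison_result`, empty
#'   when the Friedman test is not significant).
#' @export
compare_phases <- function(summary, metric, sequence,
                           phases = c("systole", "sweetspot", "diastole"),
                           alpha = 0.05) {
  sub <- summary[summary$sequence == sequence & summary$phase %in% phases, ]
  wide <- stats::reshape(sub[, c("subject", "phase", metric)],
                         idvar = "subject", timevar = "phase",
                         direction = "wide")
  complete <- stats::complete.cases(wide)
  if (any(!complete))
    warning(sprintf("%d subjects dropped (missing phase)", sum(!complete)))
  wide <- wide[complete, ]
  mat <- as.matrix(wide[, -1])
  if (nrow(mat) < 2) stop("fewer than 2 complete subjects")
  fr <- stats::friedman.test(mat)
  # fully tied data yields an undefined statistic; no evidence of an effect
  if (!is.finite(fr$p.value)) {
    fr$p.value <- 1
    fr$statistic[] <- 0
  }
  bon <- alpha / choose(length(phases), 2)
  pairwise <- list()
  if (is.finite(fr$p.value) && fr$p.value < alpha) {
    combos <- utils::combn(phases, 2, simplify = FALSE)
    for (cmb in combos) {
      a <- wide[[paste(metric, cmb[1], sep = ".")]]
      b <- wide[[paste(metric, cmb[2], sep = ".")]]
      d <- (a - b)[a != b]
      res <- if (length(d) == 0) list(statistic = 0, p.value = 1)
      else suppressWarnings(
        stats::wilcox.test(d, exact = length(d) <= 25 &&
                             !any(duplicated(abs(d)))))
      pairwise[[paste(cmb, collapse = "_vs_")]] <-
        structure(list(test = "wilcoxon_signed_rank", metric = metric,
                       phase = paste(cmb, collapse = " vs "),
                       n = length(a),
                       statistic = unname(res$statistic),
                       p_value = res$p.value,
                       significant = res$p.value < bon),
                  class = "comparison_result")
    }
  }
  list(friedman = list(statistic = unname(fr$statistic),
                       p_value = fr$p.value,
                       significant = fr$p.value < alpha),
       bonferroni_alpha = bon, pairwise = pairwise)
}

#' Correlate diffusion-parameter differences with peak strain
#'
#' Pearson correlation between a per-subject difference in a DT-CMR metric
#' (between systole and diastole within a sequence, or between the
#' sequences at one phase) and a peak strain, with the linear regression
#' line and non-simultaneous 95% confidence-band parameters for plotting.
#' Signed (not absolute) differences are used.
#'
#' @param summary Study table.
#' @param strain Data frame with columns `subject` and the strain column.
#' @param metric DT-CMR metric column.
#' @param delta `"phases"` (systole minus diastole within `sequence`) or
#'   `"sequences"` (first minus second of `sequences` at `phase`).
#' @param sequence,phase Selectors for the chosen delta.
#' @param sequences Sequence pair for `delta = "sequences"`.
#' @param strain_col Strain column name (default `"peak_radial"`).
#' @param conf_level Confidence level of the band (default 0.95).
#' @return A `comparison_result` with `r`, `p_value`, `slope`,
#'   `intercept`, `conf_level`, `band` (function of x giving fit, lwr,
#'   upr) and `n`.
#' @export
correlate_with_strain <- function(summary, strain, metric,
                                  delta = c("phases", "sequences"),
                                  sequence = "STEAM", phase = "systole",
                                  sequences = c("STEAM", "M2SE"),
                                  strain_col = "peak_radial",
                                  conf_level = 0.95) {
  delta <- match.arg(delta)
  if (delta == "phases") {
    a <- summary[summary$sequence == sequence &
                   summary$phase == "systole", c("subject", metric)]
    b <- summary[summary$sequence == sequence &
                   summary$phase == "diastole", c("subject", metric)]
  } else {
    a <- summary[summary$sequence == sequences[1] &
                   summary$phase == phase, c("subject", metric)]
    b <- summary[summary$sequence == sequences[2] &
                   summary$phase == phase, c("subject", metric)]
  }
  m <- merge(merge(a, b, by = "subject", suffixes = c("_a", "_b")),
             strain[, c("subject", strain_col)], by = "subject")
  m <- m[stats::complete.cases(m), ]
  dmet <- m[[paste0(metric, "_a")]] - m[[paste0(metric, "_b")]]
  s <- m[[strain_col]]
  if (stats::sd(dmet) == 0 || stats::sd(s) == 0)
    stop("zero variance in one of the correlated variables")
  ct <- stats::cor.test(s, dmet, method = "pearson")
  fit <- stats::lm(dmet ~ s)
  band <- function(x) {
    p <- stats::predict(fit, newdata = data.frame(s = x),
                        interval = "confidence", level = conf_level)
    data.frame(x = x, fit = p[, "fit"], lwr = p[, "lwr"], upr = p[, "upr"])
  }
  structure(list(test = "pearson_correlation", metric = metric,
                 delta = delta, n = nrow(m),
                 r = unname(ct$estimate), p_value = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 conf_level = conf_level, band = band,
                 significant = ct$p.value < 0.05),
            class = "comparison_result")
}

#' Spearman correlation of image-quality score with RR interval
#'
#' Rank correlation (midrank ties convention) between per-acquisition
#' HA-map scores and the mean RR interval.
#'
#' @param scores Integer scores (0-3).
#' @param rr_ms Mean RR interval per acquisition (ms).
#' @return A `comparison_result` with `rho` and `p_value`.
#' @export
correlate_score_rr <- function(scores, rr_ms) {
  if (length(scores) < 5) stop("need at least 5 paired observations")
  if (stats::sd(scores) == 0) stop("constant scores: correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(scores, rr_ms, method = "spearman", exact = FALSE))
  structure(list(test = "spearman_correlation", n = length(scores),
                 rho = unname(ct$estimate), p_value = ct$p.value,
                 significant = ct$p.value < 0.05),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> n = %d, p = %.4g%s\n", x$test, x$n, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}
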