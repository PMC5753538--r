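make_summary <- function(values_a, values_b, metric = "md",
                         phase = "systole") {
  n <- length(values_a)
  out <- rbind(
    data.frame(subject = 1:n, sequence = "STEAM", phase = phase,
               v = values_a),
    data.frame(subject = 1:n, sequence = "M2SE", phase = phase,
               v = values_b))
  names(out)[names(out) == "v"] <- metric
  out
}

test_that("paired Wilcoxon matches exact sign-pattern enumeration", {
  set.seed(17)
  for (i in 1:5) {
    n <- sample(6:10, 1)
    a <- round(rnorm(n, 1, 0.3), 6)
    b <- round(a - rnorm(n, 0.15, 0.25), 6)
    res <- compare_sequences(make_summary(a, b), "md", "systole")
    expect_equal(res$p_value, wilcoxon_exact_p(a - b), tolerance = 1e-12)
  }
  # all (distinct) differences positive at n = 8: p = 2 / 2^8
  a <- 1:8 + (1:8) / 10; b <- (1:8) * 1.0
  res <- compare_sequences(make_summary(a, b), "md", "systole")
  expect_equal(res$p_value, 2 / 256, tolerance = 1e-12)
})

test_that("Wilcoxon handles identical samples and is symmetric", {
  a <- c(1, 2, 3, 4, 5)
  res <- compare_sequences(make_summary(a, a), "md", "systole")
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
  set.seed(3)
  x <- rnorm(9); y <- rnorm(9)
  p1 <- compare_sequences(make_summary(x, y), "md", "systole")$p_value
  p2 <- compare_sequences(make_summary(y, x), "md", "systole")$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(compare_sequences(make_summary(1, 2), "md", "systole"),
               "pairs")
})

test_that("statistics are invariant to the row order of the study table", {
  set.seed(23)
  tab <- make_summary(rnorm(10, 1), rnorm(10, 1.3))
  p1 <- compare_sequences(tab, "md", "systole")$p_value
  p2 <- compare_sequences(tab[sample(nrow(tab)), ], "md", "systole")$p_value
  expect_identical(p1, p2)
})

test_that("Friedman with Bonferroni follow-up isolates the shifted phase", {
  set.seed(11)
  n <- 10
  base <- rnorm(n, 1, 0.1)
  tab <- rbind(
    data.frame(subject = 1:n, sequence = "STEAM", phase = "systole",
               md = base + rnorm(n, 0, 0.01)),
    data.frame(subject = 1:n, sequence = "STEAM", phase = "sweetspot",
               md = base + rnorm(n, 0, 0.01)),
    data.frame(subject = 1:n, sequence = "STEAM", phase = "diastole",
               md = base + 5 + rnorm(n, 0, 0.01)))
  res <- compare_phases(tab, "md", "STEAM")
  expect_true(res$friedman$significant)
  expect_equal(round(res$bonferroni_alpha, 4), 0.0167)
  sig <- vapply(res$pairwise, function(p) p$significant, logical(1))
  involves_dia <- grepl("diastole", names(res$pairwise))
  expect_true(all(sig[involves_dia]))
  expect_false(any(sig[!involves_dia]))
})

test_that("Friedman on identical phase values is not significant", {
  n <- 8
  v <- rnorm(n)
  tab <- do.call(rbind, lapply(c("systole", "sweetspot", "diastole"),
                               function(ph)
                                 data.frame(subject = 1:n,
                                            sequence = "STEAM", phase = ph,
                                            md = v)))
  res <- suppressWarnings(compare_phases(tab, "md", "STEAM"))
  expect_false(res$friedman$significant)
  expect_length(res$pairwise, 0)
})

test_that("strain correlation recovers linear relations and slopes", {
  # perfectly linear: r = 1
  n <- 12
  strain <- data.frame(subject = 1:n, peak_radial = seq(0.3, 0.7,
                                                        length.out = n))
  tab <- rbind(
    data.frame(subject = 1:n, sequence = "STEAM", phase = "systole",
               e2a = 20 + 80 * strain$peak_radial),
    data.frame(subject = 1:n, sequence = "STEAM", phase = "diastole",
               e2a = 20))
  res <- correlate_with_strain(tab, strain, "e2a", delta = "phases")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$slope, 80, tolerance = 1e-9)
  # simulated cohort: unbiased slope recovery over 100 seeds
  set.seed(7)
  slopes <- vapply(1:100, function(i) {
    s <- data.frame(subject = 1:15, peak_radial = runif(15, 0.3, 0.7))
    tab <- rbind(
      data.frame(subject = 1:15, sequence = "STEAM", phase = "systole",
                 e2a = 10 + 60 * s$peak_radial + rnorm(15, 0, 4)),
      data.frame(subject = 1:15, sequence = "STEAM", phase = "diastole",
                 e2a = 10))
    correlate_with_strain(tab, s, "e2a", delta = "phases")$slope
  }, numeric(1))
  # noise sd 4 over x-range ~0.4 gives a per-fit slope SE of ~9; the mean
  # of 100 replicates should sit within ~2 SE/sqrt(100) of the truth
  expect_lt(abs(mean(slopes) - 60), 2.5)
  # confidence band brackets the fitted line
  bd <- res$band(c(0.4, 0.6))
  expect_true(all(bd$lwr <= bd$fit & bd$fit <= bd$upr))
  # zero variance errors out
  tab0 <- rbind(
    data.frame(subject = 1:5, sequence = "STEAM", phase = "systole",
               e2a = 1),
    data.frame(subject = 1:5, sequence = "STEAM", phase = "diastole",
               e2a = 1))
  expect_error(correlate_with_strain(tab0, strain[1:5, ], "e2a"),
               "variance")
})

test_that("permuting one variable destroys the strain correlation", {
  set.seed(19)
  n <- 15
  s <- data.frame(subject = 1:n, peak_radial = runif(n, 0.3, 0.7))
  tab <- rbind(
    data.frame(subject = 1:n, sequence = "STEAM", phase = "systole",
               e2a = 10 + 70 * s$peak_radial + rnorm(n, 0, 2)),
    data.frame(subject = 1:n, sequence = "STEAM", phase = "diastole",
               e2a = 10))
  obs <- correlate_with_strain(tab, s, "e2a", delta = "phases")
  expect_lt(obs$p_value, 0.01)
  sig <- vapply(1:1000, function(i) {
    sp <- s; sp$peak_radial <- sample(sp$peak_radial)
    correlate_with_strain(tab, sp, "e2a", delta = "phases")$p_value < 0.05
  }, logical(1))
  expect_lt(mean(sig), 0.1)  # ~5% false positives expected
})

test_that("score-RR Spearman correlation uses midranks and hits the bounds", {
  # tie-matched monotone and anti-monotone relations hit the bounds
  rr <- c(800, 800, 900, 900, 1000, 1000, 1100, 1100)
  expect_equal(correlate_score_rr(c(0, 0, 1, 1, 2, 2, 3, 3), rr)$rho, 1,
               tolerance = 1e-12)
  expect_equal(correlate_score_rr(c(3, 3, 2, 2, 1, 1, 0, 0), rr)$rho, -1,
               tolerance = 1e-12)
  # tie-heavy case matches the hand midrank computation
  scores <- c(0, 1, 1, 2, 2, 2, 3, 3)
  rrs <- c(900, 950, 950, 1000, 1000, 1100, 1150, 1150)
  res <- correlate_score_rr(scores, rrs)
  expect_equal(res$rho, cor(rank(scores), rank(rrs)), tolerance = 1e-12)
  expect_error(correlate_score_rr(c(1, 1, 1, 1, 1), rr[1:5]), "constant")
  expect_error(correlate_score_rr(c(1, 2), c(1, 2)), "at least 5")
})
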