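make_series <- function(sigma = 0, blood_mult = 3, protocol = tiny_steam(),
                        phase = "systole", seed = 7, ...) {
  spec <- small_spec(sigma = sigma, blood_mult = blood_mult, ...)
  tf <- build_tensor_field(spec, phase)
  simulate_dwis(tf, protocol, seed = seed, spec = spec, phase = phase)
}

test_that("blood nulling hits exactly the injected blood pool and restores", {
  series <- make_series(blood_mult = 3)
  nb <- null_blood_pixels(series, threshold_factor = 2)
  blood_idx <- sort(which(series$masks$blood))
  for (i in seq_along(nb$ledger))
    expect_identical(sort(nb$ledger[[i]]$idx), blood_idx)
  # null -> register (clean series: zero integer shifts) -> restore is the
  # identity
  reg <- register_frames(nb$series, max_shift = 3, subpixel = FALSE)
  expect_true(all(reg$shifts == 0))
  back <- restore_blood_pixels(reg$series, nb$ledger, reg$shifts)
  expect_equal(back$frames, series$frames, tolerance = 1e-14)
  # identical frames: zero shifts even with subpixel refinement
  same <- series
  for (i in seq_len(dim(same$frames)[3])) same$frames[, , i] <-
    series$frames[, , 1]
  reg2 <- register_frames(same, max_shift = 3)
  expect_true(all(reg2$shifts == 0))
})

test_that("nulling below threshold leaves the series unchanged", {
  series <- make_series(blood_mult = 1)  # blood at myocardial S0
  nb <- null_blood_pixels(series, threshold_factor = 2)
  expect_identical(nb$series$frames, series$frames)
  expect_true(all(vapply(nb$ledger, function(e) length(e$idx) == 0,
                         logical(1))))
  series$masks$myocardium[] <- FALSE
  expect_error(null_blood_pixels(series), "empty")
})

test_that("registration recovers injected integer shifts exactly", {
  series <- make_series(sigma = 0.5)
  bad <- inject_artifacts(series, 4, c(3, -2), seed = 2)
  reg <- register_frames(bad, max_shift = 5, subpixel = FALSE)
  led <- bad$provenance$corruption$frames
  expect_true(all(reg$shifts[led, 1] == -3))
  expect_true(all(reg$shifts[led, 2] == 2))
  expect_true(all(reg$shifts[-led, ] == 0))
})

test_that("subpixel shifts are recovered within half a pixel", {
  series <- make_series(sigma = 0.5)
  bad <- inject_artifacts(series, 3, c(0.5, -0.5), seed = 4)
  reg <- register_frames(bad, max_shift = 4)
  led <- bad$provenance$corruption$frames
  expect_true(all(abs(reg$shifts[led, 1] + 0.5) <= 0.5))
  expect_true(all(abs(reg$shifts[led, 2] - 0.5) <= 0.5))
})

test_that("registration and restoration preserve blood intensity", {
  series <- make_series(blood_mult = 3, sigma = 0)
  bad <- inject_artifacts(series, 3, c(2, -1), seed = 5)
  blood <- series$masks$blood
  total_before <- 3 * 100 * sum(blood)
  nb <- null_blood_pixels(bad, threshold_factor = 2)
  reg <- register_frames(nb$series, max_shift = 4, subpixel = FALSE)
  back <- restore_blood_pixels(reg$series, nb$ledger, reg$shifts)
  for (i in bad$provenance$corruption$frames) {
    vals <- back$frames[, , i]
    # the corrective integer translation relocates the restored blood
    # values exactly onto the original blood pool
    expect_equal(sum(vals[blood]), total_before)
    expect_equal(sum(vals == 3 * 100), sum(blood))
  }
})

test_that("frame rejection isolates noise-replaced frames", {
  series <- make_series(sigma = 1, protocol = steam_protocol())
  bad <- inject_artifacts(series, 4, seed = 6, mode = "noise")
  rej <- reject_frames(bad, min_correlation = 0.8)
  expect_identical(rej$rejected, bad$provenance$corruption$frames)
  clean <- reject_frames(series, min_correlation = 0.8)
  expect_length(clean$rejected, 0)
  # an impossible threshold surfaces rank deficiency
  expect_error(reject_frames(series, min_correlation = 1 + 1e-9), "rank")
})

test_that("beat-to-beat b correction follows the Stejskal-Tanner scaling", {
  spec <- small_spec()
  tf <- build_tensor_field(spec, "systole")
  series <- simulate_dwis(tf, tiny_steam(rr_jitter_ms = 0), seed = 1,
                          spec = spec, phase = "systole")
  # RR equal to nominal: identity
  same <- correct_b_values(series, nominal_rr = 1000, delta = 2.4)
  expect_equal(same$b, series$b)
  # hand evaluation: b' = 450 * (1100 - 0.8) / (1000 - 0.8)
  series$rr_ms[] <- 1100
  corr <- correct_b_values(series, nominal_rr = 1000, delta = 2.4)
  expect_equal(corr$b[series$b == 450][1], 450 * 1099.2 / 999.2,
               tolerance = 1e-12)
  expect_equal(corr$b[series$b == 450][1], 495.04, tolerance = 1e-4)
  # M2-SE passes through unchanged
  m2 <- series; m2$tag <- "M2SE"
  expect_identical(correct_b_values(m2, 1000, 2.4)$b, m2$b)
  # degenerate RR errors out
  series$rr_ms[1] <- 0.5
  expect_error(correct_b_values(series, 1000, 2.4), "RR")
})

test_that("corrected b-values strictly improve recovery under RR jitter", {
  spec <- small_spec()
  tf <- build_tensor_field(spec, "systole")
  series <- simulate_dwis(tf, steam_protocol(rr_jitter_ms = 50), seed = 8,
                          spec = spec, phase = "systole")
  fit_nominal <- fit_tensor_lls(series)
  fit_corrected <- fit_tensor_lls(correct_b_values(series, 1000, 2.4))
  err_nom <- max_map_diff(fit_nominal$D, tf$tensors$D)
  err_cor <- max_map_diff(fit_corrected$D, tf$tensors$D)
  expect_lt(err_cor, 1e-12)
  expect_lt(err_cor, err_nom)
})

test_that("tensor fit is scale-invariant and treats duplicates as weights", {
  spec <- small_spec()
  tf <- build_tensor_field(spec, "systole")
  series <- simulate_dwis(tf, tiny_steam(rr_jitter_ms = 0), seed = 3,
                          spec = spec, phase = "systole")
  fit1 <- fit_tensor_lls(series)
  scaled <- series; scaled$frames <- scaled$frames * 7.3
  fit2 <- fit_tensor_lls(scaled)
  expect_lt(max_map_diff(fit1$D, fit2$D), 1e-12)
  expect_equal(max(fit2$lnS0 - fit1$lnS0, na.rm = TRUE), log(7.3),
               tolerance = 1e-10)
  # duplicating frame k equals giving it weight 2 in the normal equations
  noisy <- simulate_dwis(tf, tiny_steam(), seed = 4,
                         spec = small_spec(sigma = 1), phase = "systole")
  dup <- noisy
  dup$frames <- array(c(dup$frames, dup$frames[, , 1]),
                      dim = dim(dup$frames) + c(0, 0, 1))
  dup$b <- c(dup$b, dup$b[1]); dup$dirs <- rbind(dup$dirs, dup$dirs[1, ])
  dup$rr_ms <- c(dup$rr_ms, dup$rr_ms[1])
  dup$corrupted <- c(dup$corrupted, FALSE)
  fit_dup <- fit_tensor_lls(dup)
  nf <- dim(noisy$frames)[3]
  X <- cbind(1, -t(vapply(seq_len(nf), function(i)
    b_matrix_row(noisy$b[i], noisy$dirs[i, ]), numeric(6))))
  W <- diag(c(2, rep(1, nf - 1)))
  px <- which(noisy$masks$myocardium)[1]
  y <- log(apply(noisy$frames, 3, function(f) f[px]))
  beta_w <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_equal(unname(fit_dup$D[, , 1][px]), beta_w[2], tolerance = 1e-10)
  expect_equal(unname(fit_dup$lnS0[px]), beta_w[1], tolerance = 1e-10)
})

test_that("non-positive signals flag pixels instead of log-clipping", {
  spec <- small_spec()
  tf <- build_tensor_field(spec, "systole")
  series <- simulate_dwis(tf, tiny_steam(rr_jitter_ms = 0), seed = 2,
                          spec = spec, phase = "systole")
  px <- which(series$masks$myocardium)[1]
  series$frames[, , 1][px] <- 0
  fit <- fit_tensor_lls(series)
  expect_false(fit$valid[px])
  expect_true(is.na(fit$D[, , 1][px]))
  expect_true(all(fit$valid[which(series$masks$myocardium)[-1]]))
})
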