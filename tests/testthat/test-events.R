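test_that("TC refinement finds the filtered minimum within the clipped window", {
  fs <- 204.8
  n <- 800
  t <- (0:(n - 1)) / fs
  # clean parabolic dip centred at sample 400
  g <- 50 - 80 * exp(-((t - t[401]) / 0.05)^2)
  seq <- imu_sequence(matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                      cbind(g, 0, 0), fs = fs, frame = "body")
  expect_equal(refine_tc(seq, 385), 400)

  # 30 Hz ripple displaces the raw minimum; the filtered minimum stays at
  # the vertex and matches a brute-force argmin of an independently
  # filtered copy
  g2 <- g + 15 * sin(2 * pi * 30 * t)
  seq2 <- imu_sequence(seq$acc, cbind(g2, 0, 0), fs = fs, frame = "body")
  tc <- refine_tc(seq2, 385)
  filt <- signal::filtfilt(signal::butter(5, 10 / (fs / 2)), g2)
  half <- round(0.15 * fs)
  lo <- 385 - half
  oracle <- lo + which.min(filt[(lo + 1):(385 + half + 1)]) - 1
  expect_equal(tc, oracle)
  expect_lte(abs(tc - 400), 3)

  # border close to the sequence start: window clipped, no error
  expect_silent(refine_tc(seq, 10))
})

test_that("swing maximum is the first prominent filtered peak", {
  fs <- 204.8
  n <- 600
  t <- (0:(n - 1)) / fs
  # two peaks: first lower (80 dps) but prominent, second higher (120 dps)
  g <- 80 * exp(-((t - 0.8) / 0.08)^2) + 120 * exp(-((t - 1.6) / 0.08)^2)
  seq <- imu_sequence(matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                      cbind(g, 0, 0), fs = fs, frame = "body")
  sm <- detect_swing_max(seq, 10, n - 10)
  expect_lt(abs(sm - round(0.8 * fs)), 5)

  # single half-sine crest
  g1 <- pmax(0, 100 * sin(pi * (t - 0.5) / 0.6)) * (t > 0.5 & t < 1.1)
  seq1 <- imu_sequence(seq$acc, cbind(g1, 0, 0), fs = fs, frame = "body")
  sm1 <- detect_swing_max(seq1, 10, n - 10)
  expect_lt(abs(sm1 - round(0.8 * fs)), 5)

  # monotone signal: no interior peak -> NA (invalid stride)
  g2 <- seq(0, 100, length.out = n)
  seq2 <- imu_sequence(seq$acc, cbind(g2, 0, 0), fs = fs, frame = "body")
  expect_true(is.na(detect_swing_max(seq2, 10, n - 10)))
})

test_that("mid-stance equals the brute-force minimum-energy window centre", {
  fs <- 204.8
  set.seed(13)
  n <- 3000
  gyr <- matrix(stats::rnorm(3 * n, sd = 40), n)
  quiet <- 1501:1800
  gyr[quiet, ] <- gyr[quiet, ] * 0.001
  seq <- imu_sequence(matrix(c(0, 0, 1), n, 3, byrow = TRUE), gyr, fs = fs,
                      frame = "body")
  res <- detect_ms(seq, 100, n - 100)
  expect_false(res$flagged)
  expect_true(res$ms >= 1500 && res$ms <= 1800)
  # brute force over every window position
  w <- round(0.2 * fs)
  e <- rowSums(gyr[101:(n - 99), ]^2)
  oracle <- 100 + which.min(vapply(1:(length(e) - w + 1), function(s)
    sum(e[s:(s + w - 1)]), numeric(1))) - 1 + w %/% 2
  expect_equal(res$ms, oracle)

  # all-equal energy: earliest window centre
  seq2 <- imu_sequence(seq$acc, matrix(1, n, 3), fs = fs, frame = "body")
  expect_equal(detect_ms(seq2, 500, 1500)$ms, 500 + w %/% 2)

  # interval shorter than the window: centre of interval, flagged
  short <- detect_ms(seq, 100, 120)
  expect_true(short$flagged)
  expect_equal(short$ms, 110L)
})

test_that("IC detection uses the squared-signal peak with a derivative fallback", {
  fs <- 204.8
  n <- 800
  acc <- matrix(0, n, 3); acc[, 3] <- 1
  # dominant 3 g spike at sample 300 (9 g^2 >= 4 g^2) in region (200, 500)
  acc[301, 2] <- 3
  seq <- imu_sequence(acc, matrix(0, n, 3), fs = fs, frame = "body")
  res <- detect_ic(seq, 200, 500)
  expect_false(res$fallback)
  expect_equal(res$ic, 300)

  # sub-threshold region: fallback equals the brute-force argmax of the
  # central difference of the filtered signal
  t <- (0:(n - 1)) / fs
  acc2 <- matrix(0, n, 3); acc2[, 3] <- 1
  acc2[, 2] <- 1.2 * sin(2 * pi * 1.5 * t)   # max 1.44 g^2 < 4
  seq2 <- imu_sequence(acc2, matrix(0, n, 3), fs = fs, frame = "body")
  res2 <- detect_ic(seq2, 200, 500)
  expect_true(res2$fallback)
  low <- lowpass(acc2[, 2], 5, fs, order = 5)
  idx <- 201:(200 + floor(0.6 * 300))
  d <- (low[idx + 2] - low[idx]) / 2
  expect_equal(res2$ic, idx[which.max(d)])

  # spike at 70% of the window is outside the 60% region -> fallback
  acc3 <- acc2
  acc3[201 + 210, 2] <- 5
  seq3 <- imu_sequence(acc3, matrix(0, n, 3), fs = fs, frame = "body")
  expect_true(detect_ic(seq3, 200, 500)$fallback)
})

test_that("temporal parameters satisfy the swing + stance = stride identity", {
  fs <- 1000  # 1 ms samples for readable numbers
  ev <- data.frame(tc = c(600, 1600), swing_max = c(700, 1700),
                   facc_max = c(800, 1800), ic = c(1000, 2000),
                   ms = c(1100, 2100), valid = c(TRUE, TRUE))
  class(ev) <- c("gait_event_set", "data.frame")
  p <- compute_temporal_params(ev, fs)
  expect_equal(p$stride_time_s[2], 1.0)
  expect_equal(p$swing_time_s[2], 0.4)
  expect_equal(p$stance_time_s[2], 0.6)
  expect_identical(p$swing_time_s[2] + p$stance_time_s[2], p$stride_time_s[2])
  # first stride: no preceding IC
  expect_true(is.na(p$stride_time_s[1]))

  # equal consecutive ICs invalidate the stride
  ev2 <- ev; ev2$ic[2] <- ev2$ic[1]
  expect_false(compute_temporal_params(ev2, fs)$valid[2])
})

test_that("the identity holds exactly for every generated stride", {
  w <- generate_walk(walk_specs(rep("level", 8)), noise = noise_params(0, 0),
                     seed = 3)
  body <- w$truth$left$body
  ev <- detect_gait_events(body, truth_borders(w, "left"))
  p <- compute_temporal_params(ev, body$fs)
  ok <- !is.na(p$stride_time_s)
  expect_identical(p$swing_time_s[ok] + p$stance_time_s[ok],
                   p$stride_time_s[ok])
})

test_that("biomechanical outlier rules flag implausible strides", {
  p <- data.frame(stride_time_s = c(1.0, 1.0, 1.0, NA),
                  swing_time_s = c(0.15, 0.4, 0.7, 0.4),
                  stance_time_s = c(0.85, 0.6, 0.3, NA),
                  swing_ratio = c(0.15, 0.4, 0.7, NA),
                  valid = TRUE)
  out <- flag_outliers(p)
  expect_equal(out$valid, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("event detection recovers generator truth on noise-free strides", {
  for (ty in c("level", "ascending", "descending")) {
    w <- generate_walk(walk_specs(c("level", rep(ty, 6), "level"),
                                  staircase = "B"),
                       noise = noise_params(0, 0), seed = 5)
    body <- w$truth$left$body
    ev <- detect_gait_events(body, truth_borders(w, "left"))
    tr <- w$truth$left$events
    expect_true(all(ev$valid))
    for (col in c("tc", "swing_max", "facc_max", "ic", "ms"))
      expect_lte(max(abs(ev[[col]] - tr[[col]])), 2)
  }
})
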