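test_that("ZUPT components and their OR behave as specified", {
  fs <- 204.8
  n <- 1024
  # perfectly static: everything true
  seq <- imu_sequence(matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                      matrix(0, n, 3), fs = fs, frame = "body")
  z <- detect_zupt(seq)
  expect_true(all(z$acc) && all(z$gyr) && all(z$combined))

  # continuous 100 dps rotation with 0.5 g acceleration deviation:
  # only the enforced 50 ms MS windows are stationary
  seq2 <- imu_sequence(matrix(c(0, 0, 1.5), n, 3, byrow = TRUE),
                       matrix(c(100, 0, 0), n, 3, byrow = TRUE),
                       fs = fs, frame = "body")
  ev <- data.frame(ms = c(300L, 700L))
  z2 <- detect_zupt(seq2, ev)
  expect_false(any(z2$acc) || any(z2$gyr))
  half <- round(0.05 * fs / 2)
  expected <- logical(n)
  for (m in ev$ms) expected[(m - half + 1):(m + half + 1)] <- TRUE
  expect_equal(z2$ms_event, expected)
  expect_equal(z2$combined, expected)
})

test_that("the combined mask is the OR of its components on arbitrary signals", {
  set.seed(21)
  n <- 5000
  acc <- matrix(stats::rnorm(3 * n, sd = 0.2), n); acc[, 3] <- acc[, 3] + 1
  gyr <- matrix(stats::rnorm(3 * n, sd = 15), n)
  quiet <- 2000:2600
  acc[quiet, ] <- matrix(c(0, 0, 1), length(quiet), 3, byrow = TRUE)
  gyr[quiet, ] <- 0
  seq <- imu_sequence(acc, gyr, fs = 204.8, frame = "body")
  ev <- data.frame(ms = 4000L)
  z <- detect_zupt(seq, ev)
  expect_identical(z$combined, z$acc | z$gyr | z$ms_event)

  # brute-force per-sample centred-window oracle
  w <- round(0.15 * 204.8)
  h <- w %/% 2
  dev <- abs(sqrt(rowSums(acc^2)) - 1)
  sq <- rowSums(gyr^2)
  acc_oracle <- gyr_oracle <- logical(n)
  for (i in 1:n) {
    win <- max(1, i - h):min(n, i + (w - 1 - h))
    acc_oracle[i] <- max(dev[win]) < 0.1
    gyr_oracle[i] <- mean(sq[win]) < 100
  }
  expect_identical(z$acc, acc_oracle)
  expect_identical(z$gyr, gyr_oracle)
})

test_that("orientation windows are maximal variance-bounded runs with forced endpoints", {
  fs <- 204.8
  # fully static 10 s record: one window spanning it
  seq <- static_body_seq(2048, wiggle = 0)
  up <- find_orientation_windows(seq)
  expect_equal(nrow(up), 1L)
  expect_equal(up$start, 0L)
  expect_equal(up$end, 2048L)

  # one 400 ms quiet mid-segment inside motion: that window plus two
  # forced endpoint updates
  set.seed(6)
  n <- 2048
  acc <- matrix(stats::rnorm(3 * n, sd = 1), n); acc[, 3] <- acc[, 3] + 1
  quiet <- 1000:1082
  acc[quiet, ] <- matrix(c(0, 0, 1), length(quiet), 3, byrow = TRUE)
  seq2 <- imu_sequence(acc, matrix(0, n, 3), fs = fs, frame = "body")
  wmsg <- capture_warnings(up2 <- find_orientation_windows(seq2))
  expect_true(all(grepl("forced", wmsg)) && length(wmsg) == 2L)
  expect_equal(sum(up2$forced), 2L)
  interior <- up2[!up2$forced, ]
  expect_equal(nrow(interior), 1L)
  expect_true(interior$start >= 999 && interior$end <= 1083)

  # no quiet segment at all: exactly the two forced endpoint updates
  acc3 <- matrix(stats::rnorm(3 * n, sd = 1), n); acc3[, 3] <- acc3[, 3] + 1
  seq3 <- imu_sequence(acc3, matrix(0, n, 3), fs = fs, frame = "body")
  wmsg3 <- capture_warnings(up3 <- find_orientation_windows(seq3))
  expect_true(all(grepl("forced", wmsg3)) && length(wmsg3) == 2L)
  expect_equal(nrow(up3), 2L)
  expect_true(all(up3$forced))
})

test_that("a static noise-free record reconstructs to sub-millimetre displacement", {
  seq <- static_body_seq(2048, wiggle = 0)
  z <- detect_zupt(seq)
  up <- find_orientation_windows(seq)
  traj <- reconstruct_trajectory(seq, z, up)
  expect_lt(max(abs(traj$position)), 1e-3)
  qn <- sqrt(rowSums(traj$quaternion^2))
  expect_lt(max(abs(qn - 1)), 1e-9)
})

test_that("level and stair strides recover ground-truth elevation changes", {
  # level walking: per-stride vertical change within 2 cm of zero
  w <- generate_walk(walk_specs(rep("level", 8)), noise = noise_params(0, 0),
                     seed = 17)
  body <- w$truth$left$body
  ev <- detect_gait_events(body, truth_borders(w, "left"))
  z <- detect_zupt(body, ev)
  up <- find_orientation_windows(body)
  traj <- reconstruct_trajectory(body, z, up)
  sp <- compute_spatial_params(traj, ev)
  expect_lt(max(abs(sp$stride_height_m)), 0.02)

  # double-step ascent on staircase A: per-stride rise = 2 x 17.5 cm
  w2 <- generate_walk(walk_specs(c("level", rep("ascending", 6), "level"),
                                 staircase = "A"),
                      noise = noise_params(0, 0), seed = 18)
  body2 <- w2$truth$left$body
  ev2 <- detect_gait_events(body2, truth_borders(w2, "left"))
  z2 <- detect_zupt(body2, ev2)
  up2 <- find_orientation_windows(body2)
  traj2 <- reconstruct_trajectory(body2, z2, up2)
  sp2 <- compute_spatial_params(traj2, ev2)
  asc <- w2$truth$left$strides$stride_type == "ascending"
  expect_lt(max(abs(sp2$stride_height_m[asc[-1]] - 0.35)), 0.02)

  # smoothing suppresses discontinuities: every position step is explained
  # by the estimated velocity (no correction jumps), and the sub-sequence
  # stitch points (static stance centres) move by well under 1 cm
  dp <- diff(traj2$position)
  vbar <- (traj2$velocity[-1, ] + traj2$velocity[-nrow(traj2$velocity), ]) / 2
  expect_lt(max(abs(dp - vbar / body2$fs)), 1e-3)
  stitches <- traj2$segments[-1, 1]
  expect_lt(max(sqrt(rowSums(dp[stitches, , drop = FALSE]^2))), 0.01)
  runs <- rle(z2$combined)
  ends <- cumsum(runs$lengths)
  centres <- ends - runs$lengths %/% 2
  centres <- centres[runs$values]
  speeds <- sqrt(rowSums(traj2$velocity[centres, ]^2))
  expect_lt(max(speeds), 0.05)
  qn <- sqrt(rowSums(traj2$quaternion^2))
  expect_lt(max(abs(qn - 1)), 1e-9)
})

test_that("spatial stride parameters follow the height/length/inclination identities", {
  traj <- list(position = rbind(c(0, 0, 0), c(0.4, 0.3, 0.35)))
  class(traj) <- "trajectory_estimate"
  sp <- compute_spatial_params(traj, c(0L, 1L))
  expect_equal(sp$stride_length_m, 0.5)
  expect_equal(sp$stride_height_m, 0.35)
  expect_equal(sp$stride_inclination_deg, atan(0.7) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(round(sp$stride_inclination_deg, 2), 34.99)

  # staircase A double step geometry (2 x 17.5 over 2 x 26.5 cm)
  expect_equal(round(stride_inclination(0.35, 0.53), 1), 33.4)
  # zero height is level
  expect_equal(stride_inclination(0, 1.3), 0)
  # degenerate zero-length stride flags +/- 90 degrees
  traj2 <- list(position = rbind(c(0, 0, 0), c(0, 0, 0.2)))
  class(traj2) <- "trajectory_estimate"
  sp2 <- compute_spatial_params(traj2, c(0L, 1L))
  expect_true(sp2$flagged)
  expect_equal(sp2$stride_inclination_deg, 90)
})
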