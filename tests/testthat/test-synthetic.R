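test_that("a stride-free recording is pure gravity plus noise-free rest", {
  w <- generate_walk(list(), noise = noise_params(0, 0), duration_s = 1)
  for (f in c("left", "right")) {
    expect_equal(sqrt(rowSums(w[[f]]$acc^2)), rep(1, n_samples(w[[f]])),
                 tolerance = 1e-9)
    expect_equal(max(abs(w[[f]]$gyr)), 0)
  }
})

test_that("generation is deterministic under a fixed seed", {
  s <- walk_specs(c("level", "ascending", "level", "descending"))
  w1 <- generate_walk(s, seed = 123)
  w2 <- generate_walk(s, seed = 123)
  expect_identical(w1$left$acc, w2$left$acc)
  expect_identical(w1$right$gyr, w2$right$gyr)
  expect_identical(w1$truth$left$events, w2$truth$left$events)
  w3 <- generate_walk(s, seed = 124)
  expect_false(identical(w1$left$acc, w3$left$acc))
})

test_that("specs that do not alternate feet are refused", {
  bad <- list(stride_spec("level", "left"), stride_spec("level", "left"))
  expect_error(generate_walk(bad), "alternate")
})

test_that("ground-truth elevation follows the stride specs", {
  # noise-free level stride: no height change between mid-stances
  w <- generate_walk(walk_specs(rep("level", 4)), noise = noise_params(0, 0))
  tr <- w$truth$left
  dz <- diff(tr$position[tr$events$ms + 1, 3])
  expect_equal(dz, rep(0, length(dz)), tolerance = 1e-9)

  # double stair step on staircase A: rise exactly 2 x 17.5 cm
  w2 <- generate_walk(walk_specs(rep("ascending", 4), staircase = "A"),
                      noise = noise_params(0, 0))
  tr2 <- w2$truth$left
  dz2 <- diff(tr2$position[tr2$events$ms + 1, 3])
  expect_equal(dz2, rep(0.35, length(dz2)), tolerance = 1e-9)
})

test_that("stride morphology satisfies the annotation rules", {
  for (ty in c("level", "ascending", "descending")) {
    w <- generate_walk(walk_specs(rep(ty, 6), staircase = "B"),
                       noise = noise_params(0, 0), seed = 2)
    tb <- w$truth$left$body
    tr <- w$truth$left
    b <- tr$borders
    # TC dip at every border at most -20 dps; swing peak at least +50 dps
    expect_true(all(tb$gyr[b + 1, 1] <= -20))
    for (i in seq_len(nrow(tr$events))) {
      seg <- tb$gyr[(b[i] + 1):(b[i + 1] + 1), 1]
      expect_gte(max(seg), 50)
    }
  }
})

test_that("emitted signals are self-consistent with the ground-truth trajectory", {
  w <- generate_walk(walk_specs(rep("level", 4)), noise = noise_params(0, 0),
                     seed = 4)
  tb <- w$truth$left$body
  tr <- w$truth$left
  fs <- w$fs
  b <- tr$borders
  i0 <- b[2]; i1 <- b[3]
  idx <- (i0 + 1):(i1 + 1)
  # rebuild world acceleration from the emitted body-frame specific force
  # via the ground-truth orientation, then integrate with Simpson's rule
  th <- tr$theta_deg * pi / 180
  f_pa <- tb$acc[, 2] * 9.81; f_si <- tb$acc[, 3] * 9.81
  aw_x <- cos(th) * f_pa - sin(th) * f_si
  aw_z <- sin(th) * f_pa + cos(th) * f_si - 9.81
  # cumulative quadrature through a cubic-spline reconstruction of the
  # sampled signal (the samples are instantaneous readings of a smooth
  # signal; plain trapezoid quadrature would be limited by its own
  # truncation error, not by the generator's consistency)
  spline_cum <- function(x, dt, fine = 8) {
    n <- length(x)
    sf <- stats::splinefun((0:(n - 1)) * dt, x, method = "natural")
    ts <- seq(0, (n - 1) * dt, by = dt / fine)
    xv <- sf(ts)
    cum <- cumsum((xv + c(xv[1], xv[-length(xv)])) / 2) * (dt / fine) -
      xv[1] * dt / fine
    cum[seq(1, length(ts), by = fine)]
  }
  dt <- 1 / fs
  vx <- spline_cum(aw_x[idx], dt); vz <- spline_cum(aw_z[idx], dt)
  px <- spline_cum(vx, dt); pz <- spline_cum(vz, dt)
  expect_lt(abs(px[length(px)] -
                  (tr$position[i1 + 1, 1] - tr$position[i0 + 1, 1])), 1e-3)
  expect_lt(abs(pz[length(pz)] -
                  (tr$position[i1 + 1, 3] - tr$position[i0 + 1, 3])), 1e-3)
})

test_that("insole contact intervals coincide with the IC-TC ground truth", {
  w <- generate_walk(walk_specs(rep("level", 6)), noise = noise_params(0, 0),
                     seed = 6)
  tr <- w$truth$left
  tw <- w$fsr$left$toe_kg + w$fsr$left$mth_kg + w$fsr$left$heel_kg - 1.5
  for (i in seq_len(nrow(tr$contacts))) {
    ic <- tr$contacts[i, "ic"]; tc <- tr$contacts[i, "tc"]
    mid <- round((ic + tc) / 2)
    expect_gt(tw[mid + 1], 0.9 * w$body_weight_kg)   # loaded mid-stance
    if (i < nrow(tr$contacts)) {
      swing_mid <- round((tc + tr$contacts[i + 1, "ic"]) / 2)
      expect_lt(tw[swing_mid + 1], 1e-6)             # unloaded mid-swing
    }
  }
})

test_that("the evaluation collection mirrors the 21-task protocol", {
  es <- generate_evaluation_set(n_participants = 1, seed = 5,
                                noise = noise_params(0, 0),
                                n_stair_strides = 4)
  expect_equal(nrow(es$manifest), 21L)
  expect_equal(length(es$walks), 21L)
  expect_equal(sum(es$manifest$direction == "combined"), 3L)
  # staircase C tasks use single-step strides interleaved with level strides
  c_task <- es$manifest$task[es$manifest$staircase == "C" &
                               es$manifest$direction == "ascending"][1]
  st <- es$walks[[c_task]]$strides
  stair <- st[st$stride_type == "ascending", ]
  expect_equal(unique(stair$height_m), 0.13)
  expect_true(any(st$stride_type == "level"))
  # deterministic regeneration
  es2 <- generate_evaluation_set(n_participants = 1, seed = 5,
                                 noise = noise_params(0, 0),
                                 n_stair_strides = 4)
  expect_identical(es$walks[[3]]$left$acc, es2$walks[[3]]$left$acc)
})
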