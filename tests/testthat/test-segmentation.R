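test_that("feature extraction downsamples by 4 and yields 4 standardized columns", {
  seq <- static_body_seq(2048, wiggle = 0.3)
  f <- extract_features(seq)
  expect_equal(nrow(f$X), 512L)
  expect_equal(ncol(f$X), 4L)
  expect_equal(f$rate, 51.2)
  expect_equal(unname(colMeans(f$X)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(f$X, 2, stats::sd)), rep(1, 4), tolerance = 1e-9)
})

test_that("a linear gyr_ml ramp gives a constant gradient column equal to its slope", {
  fs <- 204.8
  n <- 2048
  t <- (0:(n - 1)) / fs
  gyr <- cbind(12 * t, 0, 0)                       # 12 dps/s ramp
  acc <- cbind(0, 0, 1 + 0.1 * sin(2 * pi * 1.1 * t))
  seq <- imu_sequence(acc, gyr, fs = fs, frame = "body")
  f <- extract_features(seq)
  grad_raw <- f$X[, 3] * f$scale[3] + f$center[3]  # undo standardization
  interior <- 10:(nrow(f$X) - 10)
  expect_equal(grad_raw[interior], rep(12, length(interior)), tolerance = 0.05)
})

test_that("constant feature columns raise a degenerate-standardization error", {
  seq <- static_body_seq(1024, wiggle = 0)
  expect_error(extract_features(seq), "gyr_ml")
})

test_that("the combined segmentation model has the documented block structure", {
  mk <- function(cls, K) {
    spec <- submodel_spec(cls, n_states = K, n_components = 1,
                          n_iterations = 1)
    mask <- stairgait:::topology_mask(spec$topology, K)
    A <- matrix(0, K, K); A[mask] <- 1; A <- A / rowSums(A)
    init <- if (spec$topology == "left_right") c(1, rep(0, K - 1)) else
      rep(1 / K, K)
    ghmm(A, init, array(stats::rnorm(K), c(K, 1, 1)),
         array(1, c(K, 1, 1)), matrix(1, K, 1))
  }
  sm <- build_segmentation_model(mk("transition", 5), mk("level", 20),
                                 mk("ascending", 20), mk("descending", 20))
  S <- sm$model$A
  expect_equal(dim(S), c(65L, 65L))
  expect_equal(rowSums(S), rep(1, 65), tolerance = 1e-9)
  # every border edge present with positive probability
  expect_true(all(S[sm$border_edges] > 0))
  # structural zeros: everything outside the diagonal blocks and the border
  # edges must be exactly zero
  allowed <- matrix(FALSE, 65, 65)
  off <- c(0, 5, 25, 45)
  Ks <- c(5, 20, 20, 20)
  topo <- c("transition_topology", "left_right", "left_right", "left_right")
  for (b in 1:4) {
    r <- off[b] + seq_len(Ks[b])
    allowed[r, r] <- stairgait:::topology_mask(topo[b], Ks[b])
  }
  allowed[sm$border_edges] <- TRUE
  expect_true(all(S[!allowed] == 0))
  # the documented inter-model edges exist: any transition state -> stride
  # starts; stride ends -> transition states; self restarts; level switches
  expect_true(all(S[cbind(1:5, 6)] > 0))    # sT -> sL0
  expect_true(S[25, 6] > 0 && S[25, 26] > 0 && S[25, 46] > 0)  # sLn -> starts
  expect_true(S[45, 6] > 0 && S[45, 26] > 0)  # sAn -> sL0, sA0
  expect_true(S[65, 6] > 0 && S[65, 46] > 0)  # sDn -> sL0, sD0
  expect_true(all(S[cbind(c(25, 45, 65), 1)] > 0))  # stride ends -> sT
  # forbidden direct stair switches: ascending end never jumps to descending
  expect_equal(S[45, 46], 0)
  expect_equal(S[65, 26], 0)
})

test_that("model persistence round-trips through JSON", {
  model <- sg_trained_model()
  path <- tempfile(fileext = ".json")
  save_segmentation_model(model, path)
  back <- load_segmentation_model(path)
  expect_equal(back$model$A, model$model$A, tolerance = 1e-12)
  expect_equal(back$model$means, model$model$means, tolerance = 1e-12)
  expect_equal(back$state_class, model$state_class)
  expect_equal(sort(back$border_edges[, 1] * 1e3 + back$border_edges[, 2]),
               sort(model$border_edges[, 1] * 1e3 + model$border_edges[, 2]))
  unlink(path)
})

test_that("a gait-free wiggle signal yields an empty border set", {
  model <- sg_trained_model()
  seq <- static_body_seq(4096, wiggle = 0.05)
  f <- extract_features(seq)
  out <- predict_stride_borders(model, f, seq)
  expect_equal(nrow(out), 0L)
})

test_that("post-processing enforces dip, swing and duration rules", {
  fs <- 204.8
  n <- 2200
  gyr <- matrix(0, n, 3)
  mk_stride <- function(gyr, s, e, dip, swing) {
    gyr[s + 1, 1] <- dip
    gyr[round((s + e) / 2) + 1, 1] <- swing
    gyr
  }
  # stride 1: weak dip (-15), fine otherwise -> removed
  gyr <- mk_stride(gyr, 100, 305, -15, 60)
  # stride 2: 0.3 s duration -> removed
  gyr <- mk_stride(gyr, 400, 461, -30, 60)
  # stride 3: 1.0 s, dip -30, swing 60 -> kept
  gyr <- mk_stride(gyr, 600, 805, -30, 60)
  # stride 4: weak swing (40) -> removed
  gyr <- mk_stride(gyr, 900, 1105, -30, 40)
  seq <- imu_sequence(matrix(c(0, 0, 1), n, 3, byrow = TRUE), gyr, fs = fs,
                      frame = "body")
  borders <- stride_border_set(c(100, 400, 600, 900), c(305, 461, 805, 1105),
                               stage = "refined")
  out <- postprocess_strides(borders, seq)
  expect_equal(out$start, 600L)
  expect_identical(attr(out, "stage"), "filtered")
  # empty input passes through
  empty <- postprocess_strides(stride_border_set(integer(), integer()), seq)
  expect_equal(nrow(empty), 0L)
})

test_that("border refinement snaps each border by at most the window width", {
  model <- sg_trained_model()
  w <- generate_walk(walk_specs(rep("level", 6)), noise = noise_params(),
                     seed = 77)
  body <- auto_align(w$left)
  f <- extract_features(body)
  refined <- predict_stride_borders(model, f, body)
  filt <- postprocess_strides(refined, body)
  # filtered borders are a subset of refined borders
  key_r <- paste(refined$start, refined$end)
  key_f <- paste(filt$start, filt$end)
  expect_true(all(key_f %in% key_r))
  # each refined border lies within 150 ms + one feature step of an HMM
  # border multiple of 4
  expect_true(all((refined$end - refined$start) / body$fs > 0.3))
})
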