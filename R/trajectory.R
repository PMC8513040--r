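# ZUPT-aided trajectory reconstruction: zero-velocity detection, static
# orientation updates, open-loop error-state Kalman filtering of a strapdown
# integration with RTS smoothing, and spatial stride features.
#
# Units: the IMU interface stays in g and dps; this module converts to SI
# (m/s^2, rad/s) at its boundary. World frame: z points up (opposite
# gravity); stride height is positive for ascent.

GRAVITY_MS2 <- 9.81

#' Detect zero-velocity (ZUPT) samples
#'
#' Combines three boolean detectors by logical OR: (1) acceleration
#' magnitude: a sliding 150 ms window where the deviation of the
#' acceleration norm from 1 g stays below 0.1 g; (2) gyroscope energy: a
#' 150 ms window whose RMS angular rate is below 10 dps; (3) an enforced
#' 50 ms window centred on each detected mid-stance event, guaranteeing at
#' least one ZUPT period per segmented stride.
#'
#' @param seq body-frame `imu_sequence`.
#' @param events optional `gait_event_set` providing MS indices.
#' @param window_ms detector window (default 150 ms).
#' @param acc_threshold_g acceleration-deviation threshold (default 0.1 g).
#' @param gyr_threshold_dps RMS angular-rate threshold (default 10 dps).
#' @param ms_window_ms MS enforcement window (default 50 ms, centred).
#' @return A `zupt_mask`: list of logical vectors `acc`, `gyr`, `ms_event`
#'   and their OR `combined`, plus the parameters used.
#' @export
detect_zupt <- function(seq, events = NULL, window_ms = 150,
                        acc_threshold_g = 0.1, gyr_threshold_dps = 10,
                        ms_window_ms = 50) {
  n <- n_samples(seq)
  w <- max(1L, round(window_ms / 1000 * seq$fs))
  acc_dev <- abs(vec_norms(seq$acc) - 1)
  gyr_sq <- rowSums(seq$gyr^2)
  acc_mask <- window_all_below(acc_dev, w, acc_threshold_g)
  # RMS over window < threshold  <=>  windowed mean square < threshold^2
  gyr_mask <- window_mean_below(gyr_sq, w, gyr_threshold_dps^2)
  ms_mask <- logical(n)
  if (!is.null(events) && nrow(events) > 0) {
    half <- round(ms_window_ms / 1000 * seq$fs / 2)
    for (m in events$ms[!is.na(events$ms)]) {
      lo <- max(0L, m - half); hi <- min(n - 1L, m + half)
      ms_mask[(lo + 1):(hi + 1)] <- TRUE
    }
  }
  structure(list(acc = acc_mask, gyr = gyr_mask, ms_event = ms_mask,
                 combined = acc_mask | gyr_mask | ms_mask,
                 window_ms = window_ms, acc_threshold_g = acc_threshold_g,
                 gyr_threshold_dps = gyr_threshold_dps,
                 ms_window_ms = ms_window_ms),
            class = "zupt_mask")
}

# per-sample centred-window statistics (windows clipped at the edges):
# a sample passes when the maximum of x over its centred window is < thr
window_all_below <- function(x, w, thr) {
  n <- length(x)
  h <- w %/% 2L
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + (w - 1L - h))
  bad <- cumsum(c(0, x >= thr))
  (bad[hi + 1L] - bad[lo]) == 0
}

# a sample passes when the mean of x over its centred window is < thr
window_mean_below <- function(x, w, thr) {
  n <- length(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + (w - 1L - h))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L) < thr
}

#' Find static orientation-update windows
#'
#' Maximal windows of at least 300 ms where the per-axis accelerometer
#' variance stays below 0.015 g^2, each providing a gravity-referenced
#' orientation at its centre. An update is additionally forced at the
#' beginning and at the end of the sequence; if those samples are not
#' static, the forced update uses best-effort local statistics and a
#' warning is issued.
#'
#' @param seq body-frame `imu_sequence`.
#' @param min_duration_s minimum window length (default 0.3 s).
#' @param var_threshold_g2 per-axis variance bound (default 0.015 g^2).
#' @return data.frame with 0-based `start`, `end` (half-open), `centre` and
#'   logical `forced`.
#' @export
find_orientation_windows <- function(seq, min_duration_s = 0.3,
                                     var_threshold_g2 = 0.015) {
  n <- n_samples(seq)
  w <- max(2L, round(min_duration_s * seq$fs))
  ok <- rep(FALSE, n)
  if (n >= w) {
    # per-axis moving variance over the minimum window length
    below <- rep(TRUE, n - w + 1L)
    for (j in 1:3) {
      x <- seq$acc[, j]
      cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
      s1 <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
      s2 <- cs2[(w + 1):(n + 1)] - cs2[1:(n - w + 1)]
      v <- (s2 - s1^2 / w) / (w - 1)
      below <- below & (v < var_threshold_g2)
    }
    for (s in which(below)) ok[s:(s + w - 1L)] <- TRUE
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values
  res <- data.frame(start = starts[keep], end = ends[keep],
                    forced = rep(FALSE, sum(keep)))
  # forced updates at sequence start and end
  if (nrow(res) == 0L || res$start[1] > 0) {
    warning("sequence start is not static; forced orientation update uses ",
            "local statistics")
    res <- rbind(data.frame(start = 0L, end = min(n, w), forced = TRUE), res)
  }
  if (res$end[nrow(res)] < n) {
    warning("sequence end is not static; forced orientation update uses ",
            "local statistics")
    res <- rbind(res, data.frame(start = max(0L, n - w), end = n,
                                 forced = TRUE))
  }
  res$centre <- as.integer(floor((res$start + res$end - 1) / 2))
  res[order(res$start), c("start", "end", "centre", "forced")]
}

# gravity-referenced orientation (yaw-free) at a window centre:
# quaternion q with R(q)^T e_z = normalized low-pass acceleration
orientation_from_acc <- function(seq, centre, win = NULL) {
  n <- n_samples(seq)
  half <- round(0.15 * seq$fs)
  lo <- max(0L, centre - half); hi <- min(n - 1L, centre + half)
  a <- colMeans(seq$acc[(lo + 1):(hi + 1), , drop = FALSE])
  al <- estimate_gravity_rotation(matrix(a, 1))
  # al$R maps the measured body-frame gravity direction onto e_z, which is
  # exactly the body-to-world rotation (up to unobservable yaw)
  quat_from_matrix(al$R)
}

#' Reconstruct the foot trajectory with an error-state Kalman filter
#'
#' Splits the sequence at the orientation-update windows into subsequences.
#' Within each, the nominal state (position, velocity, orientation) is
#' propagated open-loop by strapdown integration; a 9-dimensional error
#' state (position, velocity and small-angle orientation errors) is tracked
#' by a Kalman filter receiving zero-velocity measurements on ZUPT samples.
#' The error state is smoothed backwards (Rauch-Tung-Striebel) over the
#' subsequence and applied once to correct the nominal trajectory, avoiding
#' update discontinuities. Subsequences are stitched with positional
#' continuity; no level-ground (zero-z) assumption and no heading correction
#' are applied.
#'
#' @param seq body-frame `imu_sequence`.
#' @param zupt a `zupt_mask` from [detect_zupt()].
#' @param updates orientation-update windows from
#'   [find_orientation_windows()].
#' @param gyro_noise_dps gyroscope noise density surrogate in dps/sqrt(Hz)
#'   (default 0.02).
#' @param acc_noise_g accelerometer noise density surrogate in g/sqrt(Hz)
#'   (default 0.002).
#' @param zupt_sd_ms zero-velocity measurement SD in m/s (default 0.01).
#' @return A `trajectory_estimate`: list with per-sample `position` (m),
#'   `velocity` (m/s), `quaternion` (n x 4, unit), the `zupt` mask used and
#'   the subsequence `segments`.
#' @export
reconstruct_trajectory <- function(seq, zupt, updates,
                                   gyro_noise_dps = 0.02,
                                   acc_noise_g = 0.002,
                                   zupt_sd_ms = 0.01) {
  if (nrow(updates) < 1L) stop("at least one orientation update is required")
  n <- n_samples(seq)
  dt <- 1 / seq$fs
  acc <- seq$acc * GRAVITY_MS2              # specific force, m/s^2
  gyr <- seq$gyr * pi / 180                 # rad/s
  g_w <- c(0, 0, -GRAVITY_MS2)
  sigma_a <- acc_noise_g * GRAVITY_MS2
  sigma_g <- gyro_noise_dps * pi / 180
  pos <- matrix(0, n, 3); vel <- matrix(0, n, 3); quat <- matrix(0, n, 4)
  centres <- sort(unique(pmin(pmax(updates$centre, 0L), n - 1L)))
  bounds <- c(centres, n - 1L)
  p_offset <- c(0, 0, 0)
  for (si in seq_along(centres)) {
    s0 <- centres[si]
    s1 <- if (si < length(centres)) centres[si + 1] else n - 1L
    idx <- s0:s1                       # 0-based inclusive
    Tn <- length(idx)
    q <- orientation_from_acc(seq, s0)
    # nominal strapdown
    p_nom <- matrix(0, Tn, 3); v_nom <- matrix(0, Tn, 3)
    q_nom <- matrix(0, Tn, 4)
    q_nom[1, ] <- q
    a_w_prev <- quat_rotate(q, acc[s0 + 1, ]) + g_w
    Rf <- vector("list", Tn)
    Rf[[1]] <- quat_to_matrix(q) %*% acc[s0 + 1, ]
    for (t in 2:max(Tn, 2)) {
      if (Tn < 2) break
      k <- idx[t]
      om <- 0.5 * (gyr[k, ] + gyr[k + 1, ])  # midpoint body rate
      q <- quat_normalize(quat_multiply(q, quat_from_rotvec(om * dt)))
      q_nom[t, ] <- q
      a_w <- quat_rotate(q, acc[k + 1, ]) + g_w
      v_nom[t, ] <- v_nom[t - 1, ] + 0.5 * (a_w_prev + a_w) * dt
      p_nom[t, ] <- p_nom[t - 1, ] + 0.5 * (v_nom[t - 1, ] + v_nom[t, ]) * dt
      a_w_prev <- a_w
      Rf[[t]] <- quat_to_matrix(q) %*% acc[k + 1, ]
    }
    # error-state Kalman filter (open loop) + RTS smoothing
    est <- eskf_rts(Tn, dt, Rf, v_nom, zupt$combined[idx + 1],
                    sigma_a, sigma_g, zupt_sd_ms)
    # apply smoothed corrections once
    rows <- idx + 1
    pos[rows, ] <- p_nom + est$dp
    vel[rows, ] <- v_nom + est$dv
    for (t in seq_len(Tn)) {
      dth <- est$dth[t, ]
      qc <- quat_multiply(quat_from_rotvec(dth), q_nom[t, ])
      quat[rows[t], ] <- quat_normalize(qc)
    }
    # stitch with positional continuity
    pos[rows, ] <- sweep(pos[rows, , drop = FALSE], 2,
                         p_offset - pos[rows[1], ], "+")
    p_offset <- pos[rows[Tn], ]
    if (si == 1 && s0 > 0) {
      # samples before the first update: hold the first state
      pre <- 1:s0
      pos[pre, ] <- matrix(pos[rows[1], ], length(pre), 3, byrow = TRUE)
      vel[pre, ] <- 0
      quat[pre, ] <- matrix(quat[rows[1], ], length(pre), 4, byrow = TRUE)
    }
  }
  if (!any(zupt$combined))
    warning("no ZUPT sample available; trajectory drift is unbounded")
  structure(list(position = pos, velocity = vel, quaternion = quat,
                 zupt = zupt$combined, segments = cbind(start = centres,
                                                        end = bounds[-1])),
            class = "trajectory_estimate")
}

# Kalman forward pass + RTS smoother for the 9-state error model
# state x = (dp, dv, dtheta); dp' = dv; dv' = -[R f]_x dtheta; dtheta' = 0
eskf_rts <- function(Tn, dt, Rf, v_nom, zupt_mask, sigma_a, sigma_g,
                     zupt_sd) {
  I9 <- diag(9)
  H <- matrix(0, 3, 9); H[, 4:6] <- diag(3)
  Rm <- diag(zupt_sd^2, 3)
  Qbase <- diag(c(rep(1e-12, 3), rep(sigma_a^2 * dt, 3), rep(sigma_g^2 * dt, 3)))
  x_f <- matrix(0, Tn, 9)      # filtered means
  P_f <- vector("list", Tn)
  x_p <- matrix(0, Tn, 9)      # predicted means
  P_p <- vector("list", Tn)
  Phi <- vector("list", Tn)
  x <- rep(0, 9)
  P <- diag(c(rep(1e-8, 3), rep(1e-8, 3), rep(1e-6, 3)))
  x_f[1, ] <- x; P_f[[1]] <- P; x_p[1, ] <- x; P_p[[1]] <- P
  Phi[[1]] <- I9
  for (t in 2:max(Tn, 2)) {
    if (Tn < 2) break
    f <- Rf[[t - 1]]
    S <- matrix(c(0, f[3], -f[2],
                  -f[3], 0, f[1],
                  f[2], -f[1], 0), nrow = 3)   # [f]_x (column-major)
    F_t <- I9
    F_t[1:3, 4:6] <- diag(3) * dt
    F_t[4:6, 7:9] <- -S * dt
    Phi[[t]] <- F_t
    x <- as.numeric(F_t %*% x)
    P <- F_t %*% P %*% t(F_t) + Qbase
    x_p[t, ] <- x; P_p[[t]] <- P
    if (zupt_mask[t]) {
      z <- -v_nom[t, ]                      # measured 0 minus nominal
      y <- z - as.numeric(H %*% x)
      Sm <- H %*% P %*% t(H) + Rm
      K <- P %*% t(H) %*% solve(Sm)
      x <- x + as.numeric(K %*% y)
      P <- (I9 - K %*% H) %*% P
      P <- (P + t(P)) / 2
    }
    x_f[t, ] <- x; P_f[[t]] <- P
  }
  # RTS backward pass
  x_s <- x_f
  if (Tn >= 2) {
    P_s <- P_f[[Tn]]
    for (t in (Tn - 1):1) {
      C <- P_f[[t]] %*% t(Phi[[t + 1]]) %*% solve(P_p[[t + 1]])
      x_s[t, ] <- x_f[t, ] + as.numeric(C %*% (x_s[t + 1, ] - x_p[t + 1, ]))
      P_s <- P_f[[t]] + C %*% (P_s - P_p[[t + 1]]) %*% t(C)
    }
  }
  list(dp = x_s[, 1:3, drop = FALSE], dv = x_s[, 4:6, drop = FALSE],
       dth = x_s[, 7:9, drop = FALSE])
}

#' Spatial stride parameters from a reconstructed trajectory
#'
#' For each pair of consecutive mid-stance events the displacement along the
#' world axes gives the stride height (vertical component, positive for
#' ascent), stride length (norm of the horizontal components) and stride
#' inclination (arctangent of height over length, degrees).
#'
#' @param traj a `trajectory_estimate`.
#' @param events a `gait_event_set` (needs >= 2 MS events) or an integer
#'   vector of 0-based MS sample indices.
#' @param fs sampling rate (only used for bookkeeping).
#' @return A `spatial_stride_params` data.frame with `ms_prev`, `ms`, `s_x`,
#'   `s_y`, `s_z`, `stride_height_m`, `stride_length_m`,
#'   `stride_inclination_deg` and `flagged` (vertical displacement with zero
#'   horizontal displacement).
#' @export
compute_spatial_params <- function(traj, events, fs = NULL) {
  ms <- if (is.data.frame(events)) events$ms[!is.na(events$ms)] else
    as.integer(events)
  if (length(ms) < 2L) stop("need at least two MS events")
  ms <- sort(ms)
  d <- data.frame(ms_prev = ms[-length(ms)], ms = ms[-1])
  P <- traj$position
  S <- P[d$ms + 1, , drop = FALSE] - P[d$ms_prev + 1, , drop = FALSE]
  d$s_x <- S[, 1]; d$s_y <- S[, 2]; d$s_z <- S[, 3]
  d$stride_height_m <- d$s_z
  d$stride_length_m <- sqrt(d$s_x^2 + d$s_y^2)
  d$stride_inclination_deg <- stride_inclination(d$stride_height_m,
                                                 d$stride_length_m)
  d$flagged <- d$stride_length_m < 1e-9 & abs(d$stride_height_m) > 1e-9
  class(d) <- c("spatial_stride_params", "data.frame")
  d
}

#' Stride inclination
#'
#' Inclination angle in degrees of a stride with the given vertical height
#' and horizontal length: `atan(height / length)`. A zero-length stride with
#' non-zero height maps to +/- 90 degrees.
#'
#' @param height_m stride height in m (positive up).
#' @param length_m stride length in m (non-negative).
#' @return Inclination in degrees.
#' @export
stride_inclination <- function(height_m, length_m) {
  atan2(height_m, length_m) * 180 / pi
}
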