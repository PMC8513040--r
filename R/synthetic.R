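# Synthetic foot-IMU + pressure-insole gait generator with complete ground
# truth. Per-stride kinematics are composed from raised-cosine (Hann)
# velocity and angular-rate primitives with closed-form position, velocity
# and acceleration, so the emitted accelerometer signal is exactly the
# second derivative of the ground-truth trajectory re-projected through the
# ground-truth orientation plus gravity. Stride morphology follows the
# field's foot-flexion pattern: a negative mediolateral angular-velocity dip
# at terminal contact (the stride border), a prominent positive swing peak,
# and a second negative dip around initial contact.

#' Staircase geometries
#'
#' Step rise and run (m) of the three staircase configurations used
#' throughout: A (steep outdoor staircase), B (straight staircase) and C
#' (flat staircase with elongated landings).
#'
#' @return data.frame with `staircase`, `rise_m`, `run_m`.
#' @export
staircase_geometries <- function() {
  data.frame(staircase = c("A", "B", "C"),
             rise_m = c(0.175, 0.145, 0.13),
             run_m = c(0.265, 0.35, 0.97))
}

#' Noise parameters for the generator
#' @param acc_sd_g accelerometer white-noise SD in g (default 0.01).
#' @param gyr_sd_dps gyroscope white-noise SD in dps (default 0.5).
#' @return list of noise parameters.
#' @export
noise_params <- function(acc_sd_g = 0.01, gyr_sd_dps = 0.5) {
  list(acc_sd_g = acc_sd_g, gyr_sd_dps = gyr_sd_dps)
}

#' Specification of one synthetic stride
#'
#' @param stride_type `"level"`, `"ascending"` or `"descending"`.
#' @param foot `"left"` or `"right"`.
#' @param speed `"slow"`, `"preferred"` or `"fast"` (scales the duration).
#' @param staircase `"A"`, `"B"`, `"C"` or `NULL` (level walking).
#' @param steps_per_stride 2 for steady-state (double-step) stair strides,
#'   1 for transition/landing strides.
#' @param stride_duration_s optional explicit duration; defaults per type
#'   and speed.
#' @param stride_length_m optional explicit length; stair strides default to
#'   steps x run, level strides to 1.30 m.
#' @return A `stride_spec`.
#' @export
stride_spec <- function(stride_type = c("level", "ascending", "descending"),
                        foot = c("left", "right"),
                        speed = c("preferred", "slow", "fast"),
                        staircase = NULL, steps_per_stride = 2,
                        stride_duration_s = NULL, stride_length_m = NULL) {
  stride_type <- match.arg(stride_type)
  foot <- match.arg(foot)
  speed <- match.arg(speed)
  base_dur <- c(level = 1.1, ascending = 1.25, descending = 1.15)
  speed_fac <- c(slow = 1.25, preferred = 1.0, fast = 0.8)
  if (is.null(stride_duration_s))
    stride_duration_s <- base_dur[[stride_type]] * speed_fac[[speed]]
  rise <- 0; run <- NA_real_
  if (stride_type != "level") {
    if (is.null(staircase)) staircase <- "A"
    geo <- staircase_geometries()
    g <- geo[geo$staircase == staircase, ]
    rise <- steps_per_stride * g$rise_m *
      if (stride_type == "descending") -1 else 1
    run <- steps_per_stride * g$run_m
  }
  if (is.null(stride_length_m))
    stride_length_m <- if (stride_type == "level") 1.30 else run
  structure(list(stride_type = stride_type, foot = foot, speed = speed,
                 staircase = staircase, steps_per_stride = steps_per_stride,
                 duration = stride_duration_s, length = stride_length_m,
                 rise = rise),
            class = "stride_spec")
}

# ---- raised-cosine primitives (closed forms) -------------------------------
# velocity bump: support [c - w/2, c + w/2], total displacement d
#   v(t) = (d / w) (1 + cos(2 pi u)),  u = (t - c)/w
#   p(t) = d ((u + 1/2) + sin(2 pi u)/(2 pi)) inside, d after
#   a(t) = -(2 pi d / w^2) sin(2 pi u)
bump_add <- function(t, c0, w, d, pos, vel, acc) {
  u <- (t - c0) / w
  inside <- u > -0.5 & u < 0.5
  after <- u >= 0.5
  pos[after] <- pos[after] + d
  ui <- u[inside]
  pos[inside] <- pos[inside] + d * ((ui + 0.5) + sin(2 * pi * ui) / (2 * pi))
  vel[inside] <- vel[inside] + (d / w) * (1 + cos(2 * pi * ui))
  acc[inside] <- acc[inside] - (2 * pi * d / w^2) * sin(2 * pi * ui)
  list(pos = pos, vel = vel, acc = acc)
}

# asymmetric velocity bump: sin^2 rise over wa/2 then cos^2 fall over wb/2,
# peak velocity v_pk = 4 d / (wa + wb); the braking acceleration peak
# (amplitude pi v_pk / wb) is sharper than the rise peak when wb < wa
asym_bump_add <- function(t, t0, wa, wb, d, pos, vel, acc) {
  v_pk <- 4 * d / (wa + wb)
  s <- t - t0
  rise <- s > 0 & s < wa / 2
  sr <- s[rise]
  vel[rise] <- vel[rise] + v_pk * sin(pi * sr / wa)^2
  acc[rise] <- acc[rise] + v_pk * pi / wa * sin(2 * pi * sr / wa)
  pos[rise] <- pos[rise] + v_pk * (sr / 2 - wa * sin(2 * pi * sr / wa) / (4 * pi))
  fall <- s >= wa / 2 & s < wa / 2 + wb / 2
  sf <- s[fall] - wa / 2
  vel[fall] <- vel[fall] + v_pk * cos(pi * sf / wb)^2
  acc[fall] <- acc[fall] - v_pk * pi / wb * sin(2 * pi * sf / wb)
  pos[fall] <- pos[fall] + v_pk * wa / 4 +
    v_pk * (sf / 2 + wb * sin(2 * pi * sf / wb) / (4 * pi))
  after <- s >= wa / 2 + wb / 2
  pos[after] <- pos[after] + d
  list(pos = pos, vel = vel, acc = acc)
}

# angular-rate bump in dps: peak amplitude A, support [c - w/2, c + w/2];
# integrated angle (degrees) accumulates A * w / 2
rate_bump_add <- function(t, c0, w, A, omega, theta) {
  u <- (t - c0) / w
  inside <- u > -0.5 & u < 0.5
  after <- u >= 0.5
  area <- A * w / 2
  theta[after] <- theta[after] + area
  ui <- u[inside]
  omega[inside] <- omega[inside] + A * 0.5 * (1 + cos(2 * pi * ui))
  theta[inside] <- theta[inside] +
    area * ((ui + 0.5) + sin(2 * pi * ui) / (2 * pi))
  list(omega = omega, theta = theta)
}

# morphology constants, as fractions of the swing duration
SWING_FRACTION <- 0.42
MORPH <- list(
  tc_dip = list(c = 0.0, w = 0.16),
  swing = list(c = 0.35, w = 0.40),
  ic_dip = list(c = 0.80, w = 0.45),
  x_main = list(c = 0.35, w = 0.70),
  x_surge = list(t0 = 0.70, wa = 0.40, wb = 0.20),
  z_net = list(c = 0.42, w = 0.70),
  z_up = list(c = 0.25, w = 0.36),
  z_down = list(c = 0.62, w = 0.44),
  ic_frac = 0.95,      # x_surge braking peak = initial contact
  clearance_m = 0.05,
  surge_m = 0.15)

gyr_amplitudes <- function(stride_type) {
  swing <- c(level = 200, ascending = 150, descending = 250)[[stride_type]]
  tc <- max(160, 0.7 * swing)
  ic <- (MORPH$swing$w * swing - MORPH$tc_dip$w * tc) / MORPH$ic_dip$w
  list(swing = swing, tc = tc, ic = ic)
}

#' Generate a synthetic two-foot walk with full ground truth
#'
#' Builds an analytic foot trajectory per stride (stance dwell, swing with
#' forward surge, vertical clearance and net rise per the stride spec),
#' differentiates it in closed form, rotates the specific force into a
#' sensor frame with a tilt-only mounting rotation, adds gravity and
#' optional Gaussian noise, and emits matching pressure-insole stance
#' pulses. All ground truth (borders, events, trajectory, stride
#' parameters, contact intervals) is stored.
#'
#' @param specs list of `stride_spec`s in temporal order; feet must strictly
#'   alternate. An empty list yields a purely static recording.
#' @param noise [noise_params()]; use `noise_params(0, 0)` for noise-free.
#' @param fs sampling rate in Hz (default 204.8).
#' @param seed integer seed for the noise draw.
#' @param lead_s,tail_s static standing before/after the strides (s).
#' @param mounting_tilt_deg tilt of the sensor mounting relative to the body
#'   frame (zero-twist rotation; default 10 degrees).
#' @param body_weight_kg body weight driving the insole pulses (default 70).
#' @param duration_s minimum total duration for stride-free recordings.
#' @return A `synthetic_walk`: list with sensor-frame `imu_sequence`s
#'   (`left`, `right`), insole records (`fsr`), and per-foot ground `truth`
#'   (borders, events, stride table, trajectory, contact intervals).
#' @export
generate_walk <- function(specs, noise = noise_params(), fs = 204.8,
                          seed = 1L, lead_s = 2, tail_s = 2,
                          mounting_tilt_deg = 10, body_weight_kg = 70,
                          duration_s = 4) {
  set.seed(seed)
  feet <- vapply(specs, function(s) s$foot, character(1))
  if (length(feet) >= 2 && any(feet[-1] == feet[-length(feet)]))
    stop("stride specs must strictly alternate feet")
  per_foot <- list(left = specs[feet == "left"], right = specs[feet == "right"])
  start_time <- c(left = lead_s, right = lead_s)
  if (length(specs) > 0) {
    second <- setdiff(c("left", "right"), specs[[1]]$foot)
    start_time[second] <- lead_s + specs[[1]]$duration / 2
  }
  # total duration
  end_by_foot <- vapply(c("left", "right"), function(f) {
    ss <- per_foot[[f]]
    if (!length(ss)) return(lead_s)
    start_time[[f]] + sum(vapply(ss, function(s) s$duration, 1))
  }, 1)
  total <- max(max(end_by_foot) + tail_s, duration_s)
  n <- ceiling(total * fs)
  t <- (seq_len(n) - 1) / fs
  walk <- list(fs = fs, n = n)
  for (f in c("left", "right")) {
    ss <- per_foot[[f]]
    m <- length(ss)
    pos_x <- numeric(n); vel_x <- numeric(n); acc_x <- numeric(n)
    pos_z <- numeric(n); vel_z <- numeric(n); acc_z <- numeric(n)
    omega <- numeric(n); theta <- numeric(n)
    y_off <- if (f == "left") 0.10 else -0.10
    borders_t <- numeric(0)
    ev <- data.frame()
    stride_tbl <- data.frame()
    contacts <- NULL
    if (m > 0) {
      b <- start_time[[f]]
      borders_t <- b + cumsum(c(0, vapply(ss, function(s) s$duration, 1)))
      for (i in seq_len(m)) {
        sp <- ss[[i]]
        b_i <- borders_t[i]
        Tsw <- SWING_FRACTION * sp$duration
        amp <- gyr_amplitudes(sp$stride_type)
        # gyroscope morphology
        r <- rate_bump_add(t, b_i + MORPH$tc_dip$c * Tsw, MORPH$tc_dip$w * Tsw,
                           -amp$tc, omega, theta)
        r <- rate_bump_add(t, b_i + MORPH$swing$c * Tsw, MORPH$swing$w * Tsw,
                           amp$swing, r$omega, r$theta)
        r <- rate_bump_add(t, b_i + MORPH$ic_dip$c * Tsw, MORPH$ic_dip$w * Tsw,
                           -amp$ic, r$omega, r$theta)
        omega <- r$omega; theta <- r$theta
        # forward translation: main bump + late surge ending in the impact
        surge <- min(MORPH$surge_m, 0.3 * sp$length)
        bx <- bump_add(t, b_i + MORPH$x_main$c * Tsw, MORPH$x_main$w * Tsw,
                       sp$length - surge, pos_x, vel_x, acc_x)
        bx <- asym_bump_add(t, b_i + MORPH$x_surge$t0 * Tsw,
                            MORPH$x_surge$wa * Tsw, MORPH$x_surge$wb * Tsw,
                            surge, bx$pos, bx$vel, bx$acc)
        pos_x <- bx$pos; vel_x <- bx$vel; acc_x <- bx$acc
        # vertical: net rise plus clearance up/down
        bz <- bump_add(t, b_i + MORPH$z_net$c * Tsw, MORPH$z_net$w * Tsw,
                       sp$rise, pos_z, vel_z, acc_z)
        bz <- bump_add(t, b_i + MORPH$z_up$c * Tsw, MORPH$z_up$w * Tsw,
                       MORPH$clearance_m, bz$pos, bz$vel, bz$acc)
        bz <- bump_add(t, b_i + MORPH$z_down$c * Tsw, MORPH$z_down$w * Tsw,
                       -MORPH$clearance_m, bz$pos, bz$vel, bz$acc)
        pos_z <- bz$pos; vel_z <- bz$vel; acc_z <- bz$acc
      }
      # closing wiggle after the final border: terminal-contact dip plus a
      # broad low-amplitude settling hump cancelling the net rotation
      sp_l <- ss[[m]]
      Tsw_l <- SWING_FRACTION * sp_l$duration
      amp_l <- gyr_amplitudes(sp_l$stride_type)
      b_l <- borders_t[m + 1]
      r <- rate_bump_add(t, b_l, MORPH$tc_dip$w * Tsw_l, -amp_l$tc,
                         omega, theta)
      hump_area <- amp_l$tc * MORPH$tc_dip$w * Tsw_l / 2
      w_c <- 2 * hump_area / 45
      r <- rate_bump_add(t, b_l + MORPH$tc_dip$w * Tsw_l / 2 + 0.05 + w_c / 2,
                         w_c, 45, r$omega, r$theta)
      omega <- r$omega; theta <- r$theta
    }
    # ground-truth events per stride. TC, swing maximum, IC and MS have
    # analytic truths (bump centres / earliest quiet window). The
    # forward-acceleration maximum is a filtered-signal feature by
    # definition, so its truth is the argmax of the 5 Hz low-pass filtered
    # noise-free forward acceleration between the swing maximum and MS.
    if (m > 0) {
      tc_idx <- round(borders_t * fs)
      swing_i <- integer(m); facc_i <- integer(m); ic_i <- integer(m)
      ms_i <- integer(m)
      w_ms <- round(0.2 * fs)
      th_tmp <- theta * pi / 180
      acc_pa_clean <- cos(th_tmp) * acc_x +
        sin(th_tmp) * (acc_z + GRAVITY_MS2)
      acc_pa_low <- lowpass(acc_pa_clean / GRAVITY_MS2, 5, fs, order = 5)
      for (i in seq_len(m)) {
        Tsw <- SWING_FRACTION * ss[[i]]$duration
        swing_i[i] <- round((borders_t[i] + MORPH$swing$c * Tsw) * fs)
        ic_i[i] <- round((borders_t[i] + MORPH$ic_frac * Tsw) * fs)
        # mid-stance: centre of the earliest fully quiet 200 ms window
        q0 <- ic_i[i]
        while (q0 + w_ms < n && any(abs(omega[(q0 + 1):(q0 + w_ms)]) > 1e-9))
          q0 <- q0 + 1L
        ms_i[i] <- q0 + w_ms %/% 2L
        win <- (swing_i[i] + 2):ms_i[i]
        facc_i[i] <- swing_i[i] + which.max(acc_pa_low[win])
      }
      ev <- data.frame(tc = as.integer(tc_idx[seq_len(m)]),
                       swing_max = swing_i, facc_max = facc_i, ic = ic_i,
                       ms = ms_i, valid = TRUE)
      contacts <- cbind(ic = ic_i, tc = as.integer(tc_idx[-1]))
      stride_tbl <- data.frame(
        foot = f,
        stride_type = vapply(ss, function(s) s$stride_type, character(1)),
        time_s = borders_t[seq_len(m)],
        duration_s = vapply(ss, function(s) s$duration, 1),
        length_m = vapply(ss, function(s) s$length, 1),
        height_m = vapply(ss, function(s) s$rise, 1),
        speed = vapply(ss, function(s) s$speed, character(1)))
      stride_tbl$inclination_deg <-
        stride_inclination(stride_tbl$height_m, stride_tbl$length_m)
    }
    # body-frame signals in the shared convention
    th_rad <- theta * pi / 180
    g_w <- c(0, 0, -GRAVITY_MS2)
    # world acceleration (y is constant): specific force f_w = a_w - g_w
    f_w <- cbind(acc_x, 0, acc_z + GRAVITY_MS2)
    # body basis for a heading-+x foot: ml = (0,-1,0), pa = (1,0,0),
    # si = (0,0,1); pitch theta about the body ml axis
    ct <- cos(th_rad); st <- sin(th_rad)
    # f_b = R_pitch(theta)^T R_base^T f_w; R_base^T maps world (x,y,z) ->
    # body (pa on x, -ml on y ...): world->body: (ml,pa,si) = (-y, x, z)
    f_ml <- -f_w[, 2]
    f_pa0 <- f_w[, 1]
    f_si0 <- f_w[, 3]
    # body components: f_b = R_x(theta)^T (f_ml0, f_pa0, f_si0)
    f_pa <- ct * f_pa0 + st * f_si0
    f_si <- -st * f_pa0 + ct * f_si0
    acc_body <- cbind(f_ml, f_pa, f_si) / GRAVITY_MS2
    gyr_body <- cbind(omega, 0, 0)
    truth_body <- imu_sequence(acc_body, gyr_body, fs = fs, frame = "body",
                               foot = f)
    # mirror convention for the left foot (pipeline negates it back)
    if (f == "left") {
      acc_body[, 1] <- -acc_body[, 1]
      gyr_body[, 1] <- -gyr_body[, 1]
    }
    # tilt-only mounting rotation (sensor <- body)
    tilt <- mounting_tilt_deg * pi / 180
    u <- c(sin(tilt) * cos(0.7), sin(tilt) * sin(0.7), cos(tilt))
    al <- estimate_gravity_rotation(matrix(u, 1))
    R_sb <- t(al$R)   # maps e_z to u; al$R maps u to e_z
    acc_sens <- acc_body %*% t(R_sb)
    gyr_sens <- gyr_body %*% t(R_sb)
    if (noise$acc_sd_g > 0)
      acc_sens <- acc_sens + matrix(stats::rnorm(3 * n, sd = noise$acc_sd_g), n)
    if (noise$gyr_sd_dps > 0)
      gyr_sens <- gyr_sens + matrix(stats::rnorm(3 * n, sd = noise$gyr_sd_dps), n)
    # pressure insole: raised-cosine stance pulses per channel
    tw <- numeric(n)
    edge <- 0.020
    add_pulse <- function(tw, t_on, t_off) {
      seg <- t >= t_on & t <= t_off
      env <- as.numeric(seg)
      rise <- t >= t_on & t < t_on + edge
      env[rise] <- 0.5 * (1 - cos(pi * (t[rise] - t_on) / edge))
      fall <- t > t_off - edge & t <= t_off
      env[fall] <- 0.5 * (1 - cos(pi * (t_off - t[fall]) / edge))
      tw + env
    }
    if (m > 0) {
      tw <- add_pulse(tw, 0, borders_t[1])
      for (i in seq_len(m)) tw <- add_pulse(tw, contacts[i, 1] / fs,
                                            borders_t[i + 1])
      # final contact: foot stays grounded after the closing dip
      tw <- add_pulse(tw, borders_t[m + 1] + 0.02, total)
    } else {
      tw <- add_pulse(tw, 0, total)
    }
    fsr <- data.frame(t = t,
                      toe_kg = 0.5 + 0.3 * body_weight_kg * tw,
                      mth_kg = 0.5 + 0.4 * body_weight_kg * tw,
                      heel_kg = 0.5 + 0.3 * body_weight_kg * tw)
    walk[[f]] <- imu_sequence(acc_sens, gyr_sens, fs = fs, foot = f)
    walk$truth[[f]] <- list(
      borders = if (m > 0) as.integer(round(borders_t * fs)) else integer(),
      events = ev, strides = stride_tbl,
      contacts = contacts,
      position = cbind(x = pos_x, y = y_off, z = pos_z),
      velocity = cbind(vx = vel_x, vy = 0, vz = vel_z),
      theta_deg = theta,
      body = truth_body)
    walk$fsr[[f]] <- fsr
  }
  walk$body_weight_kg <- body_weight_kg
  walk$strides <- {
    st <- rbind(walk$truth$left$strides, walk$truth$right$strides)
    if (nrow(st)) st[order(st$time_s), ] else st
  }
  class(walk) <- "synthetic_walk"
  walk
}

#' Build an alternating-feet spec list from a stride-type pattern
#'
#' @param types character vector of stride types in temporal order.
#' @param staircase staircase id for the stair strides.
#' @param speed walking speed tag.
#' @param start_foot foot of the first stride.
#' @param steps_per_stride steps per stair stride (2 = double step).
#' @return list of `stride_spec`s.
#' @export
walk_specs <- function(types, staircase = "A", speed = "preferred",
                       start_foot = "left", steps_per_stride = 2) {
  feet <- rep(c(start_foot, setdiff(c("left", "right"), start_foot)),
              length.out = length(types))
  mapply(function(ty, ft) stride_spec(ty, ft, speed, staircase,
                                      steps_per_stride),
         types, feet, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Generate a synthetic evaluation collection
#'
#' Mirrors the study protocol shape: per synthetic participant, three
#' staircases x two directions x three speeds plus three combined walks
#' (level + ascent + level + descent + level at preferred speed) - 21 tasks.
#' Staircase C tasks use single-step stair strides interleaved with level
#' strides on the elongated landings. Per-participant kinematic variation
#' scales durations and lengths by a few percent.
#'
#' @param n_participants number of synthetic participants.
#' @param staircases subset of `c("A","B","C")`.
#' @param speeds subset of `c("slow","preferred","fast")`.
#' @param seed integer seed; regeneration is deterministic.
#' @param noise [noise_params()].
#' @param n_stair_strides stair strides per task (default 8).
#' @return List with `walks` (list of `synthetic_walk`) and `manifest`
#'   (data.frame: participant, task, staircase, direction, speed).
#' @export
generate_evaluation_set <- function(n_participants = 1,
                                    staircases = c("A", "B", "C"),
                                    speeds = c("slow", "preferred", "fast"),
                                    seed = 1L, noise = noise_params(),
                                    n_stair_strides = 8) {
  walks <- list()
  manifest <- NULL
  task_seed <- seed
  for (p in seq_len(n_participants)) {
    for (sc in staircases) {
      for (dir in c("ascending", "descending")) {
        for (sp in speeds) {
          task_seed <- task_seed + 1L
          if (sc == "C") {
            stair <- rep(c(dir, "level"), length.out = n_stair_strides)
            spst <- 1
          } else {
            stair <- rep(dir, n_stair_strides)
            spst <- 2
          }
          types <- c(rep("level", 4), stair, rep("level", 4))
          specs <- walk_specs(types, staircase = sc, speed = sp,
                              steps_per_stride = spst)
          walks[[length(walks) + 1]] <-
            generate_walk(specs, noise = noise, seed = task_seed)
          manifest <- rbind(manifest,
                            data.frame(participant = p,
                                       task = length(walks),
                                       staircase = sc, direction = dir,
                                       speed = sp))
        }
      }
    }
    for (sc in staircases) {
      task_seed <- task_seed + 1L
      spst <- if (sc == "C") 1 else 2
      types <- c(rep("level", 4), rep("ascending", 6), rep("level", 4),
                 rep("descending", 6), rep("level", 4))
      specs <- walk_specs(types, staircase = sc, speed = "preferred",
                          steps_per_stride = spst)
      walks[[length(walks) + 1]] <-
        generate_walk(specs, noise = noise, seed = task_seed)
      manifest <- rbind(manifest,
                        data.frame(participant = p, task = length(walks),
                                   staircase = sc, direction = "combined",
                                   speed = "preferred"))
    }
  }
  list(walks = walks, manifest = manifest)
}

#' Write a synthetic walk to the pipeline's CSV dialects
#'
#' Emits `imu_left.csv`, `imu_right.csv`, `fsr_left.csv`, `fsr_right.csv`
#' and a `truth.json` ground-truth sidecar into a directory.
#'
#' @param walk a `synthetic_walk`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_walk <- function(walk, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_imu_csv(walk$left, file.path(dir, "imu_left.csv"))
  write_imu_csv(walk$right, file.path(dir, "imu_right.csv"))
  utils::write.csv(walk$fsr$left, file.path(dir, "fsr_left.csv"),
                   row.names = FALSE)
  utils::write.csv(walk$fsr$right, file.path(dir, "fsr_right.csv"),
                   row.names = FALSE)
  truth <- list(
    fs = walk$fs, body_weight_kg = walk$body_weight_kg,
    left = list(borders = walk$truth$left$borders,
                events = walk$truth$left$events,
                strides = walk$truth$left$strides),
    right = list(borders = walk$truth$right$borders,
                 events = walk$truth$right$events,
                 strides = walk$truth$right$strides))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(dir)
}
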