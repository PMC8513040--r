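# Gait-event detection within segmented strides: terminal contact (TC),
# swing maximum, forward-acceleration maximum, initial contact (IC) and
# mid-stance (MS), plus temporal parameters and biomechanical outlier flags.
# A strict event order is assumed per stride:
#   TC < swing_max < facc_max < IC < MS < next TC.
# All indices are 0-based samples at the original rate.

#' Refine a terminal-contact index
#'
#' TC is the minimum of the zero-phase 10 Hz low-pass filtered (order 5)
#' mediolateral angular velocity within +/- 150 ms of the initial border;
#' the window is clipped at the sequence edges.
#'
#' @param seq body-frame `imu_sequence`.
#' @param border initial 0-based border sample (HMM stride border).
#' @param half_window_ms half-window in ms (default 150).
#' @param gyr_ml_filt optional precomputed filtered gyr_ml signal.
#' @return Refined 0-based TC sample index.
#' @export
refine_tc <- function(seq, border, half_window_ms = 150, gyr_ml_filt = NULL) {
  n <- n_samples(seq)
  if (border < 0 || border >= n) stop("border outside sequence")
  if (is.null(gyr_ml_filt))
    gyr_ml_filt <- lowpass(seq$gyr[, 1], 10, seq$fs, order = 5,
                           zero_phase = TRUE)
  half <- round(half_window_ms / 1000 * seq$fs)
  lo <- max(0L, border - half); hi <- min(n - 1L, border + half)
  lo + which.min(gyr_ml_filt[(lo + 1):(hi + 1)]) - 1L
}

#' Detect the swing maximum
#'
#' First prominent peak (prominence >= 20 dps) of the 5 Hz low-pass filtered
#' (order 5) mediolateral angular velocity strictly between two consecutive
#' TC events.
#'
#' @param seq body-frame `imu_sequence`.
#' @param tc_i,tc_next 0-based TC indices bounding the stride.
#' @param min_prominence_dps peak prominence threshold (default 20).
#' @param gyr_ml_low optional precomputed 5 Hz filtered gyr_ml.
#' @return 0-based swing-maximum index, or `NA` when no prominent peak exists
#'   (invalid stride).
#' @export
detect_swing_max <- function(seq, tc_i, tc_next, min_prominence_dps = 20,
                             gyr_ml_low = NULL) {
  if (tc_i >= tc_next) stop("tc_i must precede tc_next")
  if (is.null(gyr_ml_low))
    gyr_ml_low <- lowpass(seq$gyr[, 1], 5, seq$fs, order = 5)
  win <- gyr_ml_low[(tc_i + 2):(tc_next)]  # strictly inside (tc_i, tc_next)
  pk <- find_peaks(win)
  pk <- pk[pk$prominence >= min_prominence_dps, , drop = FALSE]
  if (nrow(pk) == 0L) return(NA_integer_)
  tc_i + pk$index[1]
}

#' Detect the mid-stance event
#'
#' Centre of the sliding 200 ms window with minimum total 3D angular-rate
#' energy, searched between the raw mediolateral angular-velocity maximum of
#' the stride and the next TC. Ties resolve to the earliest centre.
#'
#' @param seq body-frame `imu_sequence`.
#' @param raw_max_i 0-based index of the raw gyr_ml maximum (search start).
#' @param tc_next 0-based next TC index (search end).
#' @param window_ms energy window in ms (default 200).
#' @return List with `ms` (0-based index) and `flagged` (TRUE when the
#'   search interval was shorter than the window and the interval centre was
#'   used).
#' @export
detect_ms <- function(seq, raw_max_i, tc_next, window_ms = 200) {
  w <- round(window_ms / 1000 * seq$fs)
  lo <- raw_max_i; hi <- tc_next
  if (hi - lo < w) {
    return(list(ms = as.integer(floor((lo + hi) / 2)), flagged = TRUE))
  }
  e <- rowSums(seq$gyr[(lo + 1):(hi + 1), , drop = FALSE]^2)
  cs <- cumsum(c(0, e))
  n_win <- length(e) - w + 1L
  energies <- cs[(w + 1):(w + n_win)] - cs[1:n_win]
  best <- which.min(energies)  # earliest on ties
  list(ms = as.integer(lo + (best - 1L) + w %/% 2L), flagged = FALSE)
}

#' Detect the forward-acceleration maximum
#'
#' Maximum of the 5 Hz low-pass filtered posterior-anterior acceleration
#' between the swing maximum and the MS event.
#'
#' @param seq body-frame `imu_sequence`.
#' @param swing_max,ms 0-based bounding indices.
#' @param acc_pa_low optional precomputed 5 Hz filtered acc_pa.
#' @return 0-based index of the forward-acceleration maximum.
#' @export
detect_facc_max <- function(seq, swing_max, ms, acc_pa_low = NULL) {
  if (swing_max >= ms) return(NA_integer_)
  if (is.null(acc_pa_low))
    acc_pa_low <- lowpass(seq$acc[, 2], 5, seq$fs, order = 5)
  win <- acc_pa_low[(swing_max + 2):ms]
  if (!length(win)) return(NA_integer_)
  swing_max + which.max(win)
}

#' Detect the initial contact
#'
#' Searches the first 60% of the window between the forward-acceleration
#' maximum and MS. IC is the maximum of the squared posterior-anterior
#' acceleration if that peak reaches at least 4 g^2; otherwise a fallback
#' uses the maximum central first difference of the 5 Hz filtered acc_pa in
#' the same region.
#'
#' @param seq body-frame `imu_sequence`.
#' @param facc_max,ms 0-based bounding indices.
#' @param min_peak_g2 squared-acceleration threshold (default 4).
#' @param acc_pa_low optional precomputed 5 Hz filtered acc_pa.
#' @return List with `ic` (0-based index, `NA` for an empty region) and
#'   `fallback` (TRUE when the derivative fallback was used).
#' @export
detect_ic <- function(seq, facc_max, ms, min_peak_g2 = 4, acc_pa_low = NULL) {
  region_end <- facc_max + floor(0.6 * (ms - facc_max))
  if (region_end <= facc_max) return(list(ic = NA_integer_, fallback = FALSE))
  idx <- (facc_max + 1):region_end  # 0-based samples facc_max+1 .. region_end
  sq <- seq$acc[idx + 1, 2]^2
  if (max(sq) >= min_peak_g2) {
    return(list(ic = idx[which.max(sq)], fallback = FALSE))
  }
  if (is.null(acc_pa_low))
    acc_pa_low <- lowpass(seq$acc[, 2], 5, seq$fs, order = 5)
  n <- n_samples(seq)
  d <- (acc_pa_low[pmin(idx + 2, n)] - acc_pa_low[pmax(idx, 1)]) / 2
  list(ic = idx[which.max(d)], fallback = TRUE)
}

#' Detect all gait events for a set of segmented strides
#'
#' Runs the per-stride detectors in their pipeline order (TC refinement,
#' swing maximum, MS, forward-acceleration maximum, IC) over consecutive
#' stride borders. A trailing TC (the end border of the last stride) closes
#' the last stride's search interval.
#'
#' @param seq body-frame `imu_sequence`.
#' @param borders a `stride_border_set`.
#' @return A `gait_event_set` data.frame with 0-based columns `tc`,
#'   `swing_max`, `facc_max`, `ic`, `ms` and logical `valid`; one row per
#'   stride.
#' @export
detect_gait_events <- function(seq, borders) {
  n_str <- nrow(borders)
  out <- data.frame(tc = rep(NA_integer_, n_str),
                    swing_max = rep(NA_integer_, n_str),
                    facc_max = rep(NA_integer_, n_str),
                    ic = rep(NA_integer_, n_str),
                    ms = rep(NA_integer_, n_str),
                    valid = rep(FALSE, n_str))
  class(out) <- c("gait_event_set", "data.frame")
  if (n_str == 0L) return(out)
  gyr10 <- lowpass(seq$gyr[, 1], 10, seq$fs, order = 5)
  gyr5 <- lowpass(seq$gyr[, 1], 5, seq$fs, order = 5)
  acc5 <- lowpass(seq$acc[, 2], 5, seq$fs, order = 5)
  tc <- vapply(seq_len(n_str), function(i)
    refine_tc(seq, borders$start[i], gyr_ml_filt = gyr10), numeric(1))
  tc_end <- refine_tc(seq, borders$end[n_str], gyr_ml_filt = gyr10)
  tc_next <- c(tc[-1], tc_end)
  for (i in seq_len(n_str)) {
    out$tc[i] <- tc[i]
    if (tc_next[i] <= tc[i] + 2) next
    sm <- detect_swing_max(seq, tc[i], tc_next[i], gyr_ml_low = gyr5)
    if (is.na(sm)) next
    out$swing_max[i] <- sm
    raw_seg <- seq$gyr[(tc[i] + 2):tc_next[i], 1]
    raw_max <- tc[i] + which.max(raw_seg)
    msr <- detect_ms(seq, raw_max, tc_next[i])
    out$ms[i] <- msr$ms
    fm <- detect_facc_max(seq, sm, msr$ms, acc_pa_low = acc5)
    if (is.na(fm)) next
    out$facc_max[i] <- fm
    icr <- detect_ic(seq, fm, msr$ms, acc_pa_low = acc5)
    if (is.na(icr$ic)) next
    out$ic[i] <- icr$ic
    out$valid[i] <- out$tc[i] < out$swing_max[i] &&
      out$swing_max[i] < out$facc_max[i] && out$facc_max[i] < out$ic[i] &&
      out$ic[i] < out$ms[i] && out$ms[i] < tc_next[i]
  }
  out
}

#' Temporal stride parameters from gait events
#'
#' Stride time is the interval between consecutive initial contacts, swing
#' time spans TC to the same stride's IC, and stance time spans the previous
#' IC to the current TC, so swing + stance = stride exactly. The first
#' stride has no preceding IC and therefore undefined stride and stance
#' times.
#'
#' @param events a `gait_event_set`.
#' @param fs sampling rate in Hz.
#' @return A `temporal_params` data.frame with `stride_time_s`,
#'   `swing_time_s`, `stance_time_s`, `swing_ratio` and `valid`.
#' @export
compute_temporal_params <- function(events, fs) {
  n <- nrow(events)
  out <- data.frame(stride_time_s = rep(NA_real_, n),
                    swing_time_s = rep(NA_real_, n),
                    stance_time_s = rep(NA_real_, n),
                    swing_ratio = rep(NA_real_, n),
                    valid = events$valid)
  class(out) <- c("temporal_params", "data.frame")
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    if (!events$valid[i]) next
    if (!is.na(events$ic[i]) && !is.na(events$tc[i]))
      out$swing_time_s[i] <- (events$ic[i] - events$tc[i]) / fs
    if (i > 1 && events$valid[i - 1]) {
      if (events$ic[i] <= events$ic[i - 1] || events$tc[i] <= events$ic[i - 1]) {
        out$valid[i] <- FALSE
        next
      }
      out$stride_time_s[i] <- (events$ic[i] - events$ic[i - 1]) / fs
      out$stance_time_s[i] <- (events$tc[i] - events$ic[i - 1]) / fs
    }
    if (!is.na(out$stride_time_s[i]) && out$stride_time_s[i] > 0)
      out$swing_ratio[i] <- out$swing_time_s[i] / out$stride_time_s[i]
  }
  out
}

#' Flag biomechanically implausible strides
#'
#' A stride is kept valid only when its swing time lies in `[0.2, 1.0]` s,
#' its stance time in `[0.2, 1.5]` s and its swing ratio (swing/stride) in
#' `[25, 60]`%. Strides with undefined stride/stance times (first of a bout)
#' are judged on swing time alone.
#'
#' @param params a `temporal_params` data.frame.
#' @return The same data.frame with updated `valid` flags.
#' @export
flag_outliers <- function(params) {
  for (i in seq_len(nrow(params))) {
    if (!isTRUE(params$valid[i])) next
    sw <- params$swing_time_s[i]
    ok <- !is.na(sw) && sw >= 0.2 && sw <= 1.0
    st <- params$stance_time_s[i]
    if (ok && !is.na(st)) ok <- st >= 0.2 && st <= 1.5
    r <- params$swing_ratio[i]
    if (ok && !is.na(r)) ok <- r >= 0.25 && r <= 0.60
    params$valid[i] <- ok
  }
  params
}
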