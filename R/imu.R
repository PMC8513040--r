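#' Construct an IMU sequence
#'
#' An `imu_sequence` holds time-synchronous 3-axis accelerometer (in g) and
#' 3-axis gyroscope (in degrees per second, dps) data sampled at a fixed rate.
#' Data may be in the raw `"sensor"` frame or in the shared `"body"` frame.
#' In the body frame the axes are ordered ml (medial-to-lateral),
#' pa (posterior-to-anterior) and si (superior-to-inferior); while the foot is
#' flat and static the si axis reads approximately +1 g.
#'
#' @param acc numeric matrix, n x 3, acceleration in g.
#' @param gyr numeric matrix, n x 3, angular velocity in dps.
#' @param fs sampling rate in Hz (default 204.8).
#' @param frame `"sensor"` or `"body"`.
#' @param foot `"left"`, `"right"` or `"unknown"`.
#' @return An object of class `imu_sequence`.
#' @export
imu_sequence <- function(acc, gyr, fs = 204.8, frame = c("sensor", "body"),
                         foot = c("unknown", "left", "right")) {
  frame <- match.arg(frame)
  foot <- match.arg(foot)
  acc <- as.matrix(acc)
  gyr <- as.matrix(gyr)
  if (ncol(acc) != 3L || ncol(gyr) != 3L)
    stop("acc and gyr must have 3 columns")
  if (nrow(acc) != nrow(gyr))
    stop("acc and gyr must have the same number of samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  dimnames(acc) <- NULL
  dimnames(gyr) <- NULL
  structure(list(acc = acc, gyr = gyr, fs = fs, frame = frame, foot = foot),
            class = "imu_sequence")
}

#' @export
print.imu_sequence <- function(x, ...) {
  cat(sprintf("<imu_sequence> %d samples @ %.1f Hz (%.2f s), frame=%s, foot=%s\n",
              n_samples(x), x$fs, n_samples(x) / x$fs, x$frame, x$foot))
  invisible(x)
}

#' Number of samples in an IMU sequence
#' @param seq an `imu_sequence`.
#' @return integer sample count.
#' @export
n_samples <- function(seq) nrow(seq$acc)

#' Extract a sample range from an IMU sequence
#' @param seq an `imu_sequence`.
#' @param start,end half-open 0-based sample interval `[start, end)`.
#' @return An `imu_sequence` with the selected samples.
#' @export
imu_slice <- function(seq, start, end) {
  idx <- seq_len(end - start) + start  # rows start+1 .. end (1-based)
  imu_sequence(seq$acc[idx, , drop = FALSE], seq$gyr[idx, , drop = FALSE],
               fs = seq$fs, frame = seq$frame, foot = seq$foot)
}

#' Read an IMU recording from CSV
#'
#' Expects columns `t, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z` with
#' acceleration in g and angular velocity in dps. The sampling rate is taken
#' from `fs` if given, otherwise inferred from the median spacing of `t`.
#'
#' @param path CSV file path.
#' @param fs optional sampling rate in Hz.
#' @param foot foot side label.
#' @return An `imu_sequence` in the sensor frame.
#' @export
read_imu_csv <- function(path, fs = NULL, foot = "unknown") {
  d <- utils::read.csv(path)
  need <- c("t", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  if (!all(need %in% names(d)))
    stop("IMU CSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(fs)) {
    dt <- stats::median(diff(d$t))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from t")
    fs <- 1 / dt
  }
  imu_sequence(as.matrix(d[, c("acc_x", "acc_y", "acc_z")]),
               as.matrix(d[, c("gyr_x", "gyr_y", "gyr_z")]),
               fs = fs, foot = foot)
}

#' Write an IMU sequence to CSV
#' @param seq an `imu_sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(seq, path) {
  n <- n_samples(seq)
  d <- data.frame(t = (seq_len(n) - 1) / seq$fs,
                  acc_x = seq$acc[, 1], acc_y = seq$acc[, 2], acc_z = seq$acc[, 3],
                  gyr_x = seq$gyr[, 1], gyr_y = seq$gyr[, 2], gyr_z = seq$gyr[, 3])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Resample an IMU sequence to a target rate
#'
#' Linear interpolation per channel; used to bring recordings onto the
#' 204.8 Hz grid all window lengths are defined against.
#'
#' @param seq an `imu_sequence`.
#' @param fs_target target rate in Hz.
#' @return An `imu_sequence` at `fs_target`.
#' @export
imu_resample <- function(seq, fs_target = 204.8) {
  if (isTRUE(all.equal(seq$fs, fs_target))) return(seq)
  n <- n_samples(seq)
  t_old <- (seq_len(n) - 1) / seq$fs
  t_new <- seq(0, t_old[n], by = 1 / fs_target)
  interp <- function(m) vapply(1:3, function(j)
    stats::approx(t_old, m[, j], xout = t_new)$y, numeric(length(t_new)))
  imu_sequence(interp(seq$acc), interp(seq$gyr), fs = fs_target,
               frame = seq$frame, foot = seq$foot)
}
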