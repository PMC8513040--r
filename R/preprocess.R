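#' Detect static windows
#'
#' Finds the maximal runs of samples where the Euclidean norm of the 3-axis
#' angular velocity stays below a threshold, keeping only runs of at least a
#' minimum duration. These quiet standing periods (before the first and after
#' the last stride of a walking sequence) anchor the gravity alignment.
#'
#' @param seq an `imu_sequence`.
#' @param min_duration_s minimum window duration in seconds (default 1).
#' @param gyr_threshold_dps angular-rate threshold in dps (default 2.5).
#' @return A `static_window_set`: list with `windows` (two-column matrix of
#'   half-open 0-based `[start, end)` sample intervals), `min_duration`,
#'   `gyr_threshold`.
#' @export
detect_static_windows <- function(seq, min_duration_s = 1.0,
                                  gyr_threshold_dps = 2.5) {
  n <- n_samples(seq)
  if (n == 0L) stop("empty IMU sequence")
  quiet <- vec_norms(seq$gyr) < gyr_threshold_dps
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based start of each run
  keep <- r$values & r$lengths >= min_duration_s * seq$fs
  windows <- cbind(start = starts[keep], end = ends[keep])
  structure(list(windows = windows, min_duration = min_duration_s,
                 gyr_threshold = gyr_threshold_dps),
            class = "static_window_set")
}

#' Estimate the sensor-to-gravity rotation
#'
#' Averages acceleration vectors over static periods and computes the
#' rotation that maps the normalized mean acceleration onto the gravity
#' target (0, 0, 1): axis = a_s x e_g, angle = arccos of their normalized dot
#' product, rotation vector = unit axis times angle.
#'
#' @param static_acc matrix of static acceleration samples (n x 3, in g).
#' @return A `gravity_alignment`: list with `mean_acc`, `axis`, `angle`
#'   (radians), `rotation_vector` and the 3 x 3 rotation matrix `R` (applied
#'   as `R %*% v`, it maps the mean acceleration direction onto (0,0,1)).
#' @export
estimate_gravity_rotation <- function(static_acc) {
  static_acc <- matrix(as.numeric(static_acc), ncol = 3)
  if (nrow(static_acc) < 1L) stop("need at least one static sample")
  a <- colMeans(static_acc)
  na <- sqrt(sum(a^2))
  if (na < 1e-12) stop("degenerate input: zero-norm mean acceleration")
  e_g <- c(0, 0, 1)
  a_hat <- a / na
  axis <- c(a_hat[2] * e_g[3] - a_hat[3] * e_g[2],
            a_hat[3] * e_g[1] - a_hat[1] * e_g[3],
            a_hat[1] * e_g[2] - a_hat[2] * e_g[1])
  angle <- acos(max(-1, min(1, sum(a_hat * e_g))))
  n_axis <- sqrt(sum(axis^2))
  if (n_axis < 1e-12) {
    # parallel (angle 0) or anti-parallel (angle pi): cross product vanishes;
    # any axis orthogonal to e_g works for the anti-parallel case, fix (1,0,0)
    axis_hat <- c(1, 0, 0)
  } else {
    axis_hat <- axis / n_axis
  }
  structure(list(mean_acc = a, axis = axis_hat, angle = angle,
                 rotation_vector = axis_hat * angle,
                 R = rotation_matrix(axis_hat, angle)),
            class = "gravity_alignment")
}

# Rodrigues rotation matrix for unit axis u and angle a
rotation_matrix <- function(u, a) {
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), nrow = 3)  # column-major: K = [u]_x
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Align a sensor-frame sequence to the body frame
#'
#' Rotates accelerometer and gyroscope data by the gravity alignment so the
#' third axis points along gravity (static si acceleration about +1 g, ml/pa
#' about 0 g) and relabels the axes (ml, pa, si). Left-foot data additionally
#' has its ml axis negated so foot flexion carries the same sign on both
#' feet (terminal-contact dip negative).
#'
#' @param seq an `imu_sequence` in the sensor frame.
#' @param alignment a `gravity_alignment` from [estimate_gravity_rotation()].
#' @param foot `"left"` or `"right"`; defaults to the sequence's own label.
#' @return A body-frame `imu_sequence`.
#' @export
align_to_body_frame <- function(seq, alignment, foot = NULL) {
  if (seq$frame == "body")
    stop("sequence is already in the body frame")
  foot <- if (is.null(foot)) seq$foot else foot
  R <- alignment$R
  acc <- seq$acc %*% t(R)
  gyr <- seq$gyr %*% t(R)
  if (identical(foot, "left")) {
    acc[, 1] <- -acc[, 1]
    gyr[, 1] <- -gyr[, 1]
  }
  out <- imu_sequence(acc, gyr, fs = seq$fs, frame = "body", foot = foot)
  out
}

#' Gravity-align a recording in one call
#'
#' Convenience wrapper: detect static windows, estimate the gravity rotation
#' from the pooled static samples of the whole recording, and rotate into the
#' body frame.
#'
#' @param seq a sensor-frame `imu_sequence`.
#' @param min_duration_s,gyr_threshold_dps static-window parameters.
#' @return A body-frame `imu_sequence`.
#' @export
auto_align <- function(seq, min_duration_s = 1.0, gyr_threshold_dps = 2.5) {
  sw <- detect_static_windows(seq, min_duration_s, gyr_threshold_dps)
  if (nrow(sw$windows) == 0L)
    stop("no static window found for gravity alignment")
  idx <- unlist(apply(sw$windows, 1, function(w) (w[1] + 1):w[2],
                      simplify = FALSE))
  al <- estimate_gravity_rotation(seq$acc[idx, , drop = FALSE])
  align_to_body_frame(seq, al)
}
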