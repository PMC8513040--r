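#' Butterworth low-pass filter
#'
#' Shared filtering utility for the feature extraction, event detection and
#' orientation-update stages. Wraps [signal::butter()]; `zero_phase = TRUE`
#' applies forward-backward filtering ([signal::filtfilt()]) so filtered
#' extrema keep their timing.
#'
#' @param x numeric vector.
#' @param cutoff_hz cut-off frequency in Hz; must be below the Nyquist rate.
#' @param fs sampling rate in Hz.
#' @param order filter order.
#' @param zero_phase apply forward-backward (zero-phase) filtering.
#' @return Filtered vector, same length as `x`.
#' @export
lowpass <- function(x, cutoff_hz, fs, order = 4, zero_phase = TRUE) {
  if (cutoff_hz >= fs / 2)
    stop("cutoff_hz (", cutoff_hz, ") must be below the Nyquist rate ", fs / 2)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  x <- as.numeric(x)
  if (length(x) < 4L) return(x)
  if (zero_phase) {
    # pad by odd reflection to suppress filtfilt edge transients; the pad
    # must outlast the filter's settling time (a few cutoff periods)
    np <- min(length(x) - 1L, 3L * order * ceiling(fs / cutoff_hz))
    head_pad <- 2 * x[1] - x[(np + 1):2]
    tail_pad <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[(np + 1):(np + length(x))]
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

# Euclidean norm per row of an n x 3 matrix
vec_norms <- function(m) sqrt(rowSums(m * m))

# Centred moving sum of length w (same length as x, edges NA)
moving_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  out <- rep(NA_real_, n)
  if (w > n) return(out)
  starts <- 1:(n - w + 1)
  out[starts + (w %/% 2)] <- cs[starts + w] - cs[starts]
  out
}

#' Local peak prominence
#'
#' For each local maximum of `x`, the prominence is the height of the peak
#' above the higher of the two lowest valleys separating it from higher
#' terrain (or the signal edge) on either side.
#'
#' @param x numeric vector.
#' @return data.frame with columns `index`, `height`, `prominence`,
#'   one row per interior local maximum (plateaus use their first sample).
#' @export
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(), height = numeric(),
                                prominence = numeric()))
  dx <- diff(x)
  # rising-to-falling sign changes; plateaus collapse to their first sample
  s <- sign(dx)
  s_nz <- s
  for (i in seq_along(s_nz)) if (s_nz[i] == 0 && i > 1) s_nz[i] <- s_nz[i - 1]
  idx <- which(s_nz[-1] < 0 & s_nz[-length(s_nz)] > 0) + 1L
  prom <- vapply(idx, function(i) {
    h <- x[i]
    left_min <- h
    j <- i
    while (j > 1 && x[j] <= h) { j <- j - 1; left_min <- min(left_min, x[j]) }
    right_min <- h
    j <- i
    while (j < n && x[j] <= h) { j <- j + 1; right_min <- min(right_min, x[j]) }
    h - max(left_min, right_min)
  }, numeric(1))
  data.frame(index = idx, height = x[idx], prominence = prom)
}
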