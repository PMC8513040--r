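# Pressure-insole (force-sensitive resistor) reference processing: the
# non-inverting amplifier conditioning model, total-weight signal with
# per-stride baseline removal, and threshold-based reference IC/TC events.

#' FSR calibration description
#'
#' @param r_ref reference resistance in ohms.
#' @param v_ref reference voltage in volts (default 0.1 V).
#' @param coef optional 6th-order polynomial coefficients (intercept first)
#'   mapping conditioned voltage to load in kg.
#' @param max_load_kg saturation load (default 20 kg).
#' @return An `fsr_calibration` object.
#' @export
fsr_calibration <- function(r_ref, v_ref = 0.1, coef = NULL,
                            max_load_kg = 20) {
  structure(list(r_ref = r_ref, v_ref = v_ref, coef = coef,
                 max_load_kg = max_load_kg),
            class = "fsr_calibration")
}

#' Conditioned FSR output voltage
#'
#' Non-inverting amplifier model: `V_out = V_ref * (1 + R_ref / R_fsr)`.
#'
#' @param r_fsr FSR resistance in ohms (vectorized, must be positive).
#' @param cal an `fsr_calibration` (supplies `r_ref` and `v_ref`).
#' @return Output voltage in volts.
#' @export
conditioned_voltage <- function(r_fsr, cal) {
  if (any(r_fsr <= 0)) stop("FSR resistance must be positive")
  cal$v_ref * (1 + cal$r_ref / r_fsr)
}

#' Total-weight signal from a three-channel insole record
#'
#' Sums the toe, metatarsal-head and heel channel loads per sample, then
#' subtracts per-stride minimum baselines (between consecutive stride
#' borders) to remove offsets such as shoe-lacing pressure. Without borders
#' the global minimum of the bout is subtracted.
#'
#' @param record data.frame with columns `toe_kg`, `mth_kg`, `heel_kg`.
#' @param stride_borders optional `stride_border_set` (0-based half-open
#'   sample intervals).
#' @return Numeric total-weight series in kg (non-negative).
#' @export
total_weight <- function(record, stride_borders = NULL) {
  tw <- record$toe_kg + record$mth_kg + record$heel_kg
  n <- length(tw)
  if (is.null(stride_borders) || nrow(stride_borders) == 0L) {
    base <- rep(min(tw), n)
  } else {
    base <- rep(NA_real_, n)
    edges <- sort(unique(c(0L, stride_borders$start, stride_borders$end, n)))
    for (i in seq_len(length(edges) - 1L)) {
      idx <- (edges[i] + 1):edges[i + 1]
      base[idx] <- min(tw[idx])
    }
  }
  pmax(tw - base, 0)
}

#' Reference gait events from the total-weight signal
#'
#' Thresholds the total-weight signal at a fraction of body weight
#' (default 7.5%); an initial contact is registered at each upward crossing
#' (first sample at or above the threshold) and a terminal contact at each
#' downward crossing (first sample below it). IC and TC strictly alternate.
#'
#' @param total_weight_kg numeric total-weight series.
#' @param body_weight_kg participant body weight in kg (> 0).
#' @param threshold_fraction fraction of body weight (default 0.075).
#' @return data.frame with columns `event` ("ic"/"tc") and 0-based `sample`.
#' @export
detect_reference_events <- function(total_weight_kg, body_weight_kg,
                                    threshold_fraction = 0.075) {
  if (body_weight_kg <= 0) stop("body weight must be positive")
  thr <- threshold_fraction * body_weight_kg
  above <- total_weight_kg >= thr
  d <- diff(as.integer(above))
  ic <- which(d == 1)       # first 0-based sample >= thr is index `which`
  tc <- which(d == -1)
  ev <- rbind(data.frame(event = rep("ic", length(ic)), sample = ic),
              data.frame(event = rep("tc", length(tc)), sample = tc))
  if (above[1]) ev <- rbind(data.frame(event = "ic", sample = 0L), ev)
  ev <- ev[order(ev$sample), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
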