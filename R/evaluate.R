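# Segmentation scoring against reference stride borders (true/false
# positives, precision/recall/F1 with a +/- 100 ms border tolerance) and
# event-timing error statistics.

#' Match predicted strides to reference strides
#'
#' A predicted stride is a true positive when both of its borders lie
#' within the tolerance of the matched reference stride's borders; each
#' reference stride is matched at most once (greedy in time order).
#' Unmatched predictions are false positives, unmatched references false
#' negatives.
#'
#' @param predicted,reference `stride_border_set` data.frames (0-based
#'   `start`/`end` samples), ordered by start.
#' @param fs sampling rate in Hz.
#' @param tol_ms matching tolerance (default 100 ms).
#' @return List with `tp`, `fp`, `fn` counts and `pairing` (two-column
#'   matrix of matched predicted/reference row indices).
#' @export
match_strides <- function(predicted, reference, fs, tol_ms = 100) {
  tol <- tol_ms / 1000 * fs
  np <- nrow(predicted); nr <- nrow(reference)
  used <- logical(nr)
  pairs <- NULL
  for (i in seq_len(np)) {
    ok <- which(!used &
                  abs(reference$start - predicted$start[i]) <= tol &
                  abs(reference$end - predicted$end[i]) <= tol)
    if (length(ok)) {
      j <- ok[which.min(abs(reference$start[ok] - predicted$start[i]))]
      used[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  list(tp = tp, fp = np - tp, fn = nr - tp,
       pairing = if (is.null(pairs)) matrix(integer(), ncol = 2) else pairs)
}

#' Segmentation scores
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN) and their harmonic mean F1 =
#' 2PR/(P+R); degenerate zero denominators yield 0 with a notice.
#'
#' @param tp,fp,fn non-negative counts.
#' @return A `segmentation_score` list with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
seg_scores <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    message("no predicted strides: precision set to 0"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    message("no reference strides: recall set to 0"); 0
  }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "segmentation_score")
}

#' Event timing error statistics
#'
#' Signed per-stride timing errors (predicted minus reference, ms) for
#' paired strides, summarized as mean, SD and mean absolute error.
#'
#' @param predicted,reference numeric vectors of event sample indices (or
#'   parameter values in seconds when `fs = 1000`).
#' @param pairing two-column matrix pairing predicted/reference entries;
#'   defaults to positional pairing.
#' @param fs sampling rate in Hz used to convert samples to ms.
#' @return A `timing_error_stats` list with `errors_ms`, `mean_ms`, `sd_ms`,
#'   `mae_ms`, `n`.
#' @export
timing_errors <- function(predicted, reference, pairing = NULL, fs = 204.8) {
  if (is.null(pairing))
    pairing <- cbind(seq_along(predicted), seq_along(reference))
  if (nrow(pairing) == 0L)
    return(structure(list(errors_ms = numeric(), mean_ms = NA_real_,
                          sd_ms = NA_real_, mae_ms = NA_real_, n = 0L),
                     class = "timing_error_stats"))
  err <- (predicted[pairing[, 1]] - reference[pairing[, 2]]) / fs * 1000
  keep <- !is.na(err)
  err <- err[keep]
  structure(list(errors_ms = err, mean_ms = mean(err),
                 sd_ms = if (length(err) > 1) stats::sd(err) else 0,
                 mae_ms = mean(abs(err)), n = length(err)),
            class = "timing_error_stats")
}
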