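# Stride-type classification from spatial features, implausible-stride
# rejection, walking-bout assembly and digital mobility outcome summaries.

#' Reject biomechanically implausible strides
#'
#' A stride is rejected when its length falls below 0.25 m or above 2.0 m,
#' or when its temporal validity flag is FALSE.
#'
#' @param stride_length_m stride length in m.
#' @param temporal_valid logical temporal validity (default TRUE).
#' @param min_length_m,max_length_m bounds (defaults 0.25 and 2.0 m).
#' @return Logical: TRUE when the stride is rejected.
#' @export
reject_implausible <- function(stride_length_m, temporal_valid = TRUE,
                               min_length_m = 0.25, max_length_m = 2.0) {
  !temporal_valid | stride_length_m < min_length_m |
    stride_length_m > max_length_m
}

#' Classify a stride by its spatial features
#'
#' Ascending requires both a stride height of at least +10 cm and an
#' inclination of at least +6 degrees; descending requires at most -10 cm
#' and at most -6 degrees (thresholds inclusive). Everything else is level
#' walking.
#'
#' @param stride_height_m stride height in m (vectorized).
#' @param stride_inclination_deg stride inclination in degrees.
#' @param min_height_m,min_inclination_deg magnitude thresholds
#'   (defaults 0.10 m and 6 degrees).
#' @return Character vector: `"level"`, `"ascending"` or `"descending"`.
#' @export
classify_stride <- function(stride_height_m, stride_inclination_deg,
                            min_height_m = 0.10, min_inclination_deg = 6) {
  out <- rep("level", length(stride_height_m))
  out[stride_height_m >= min_height_m &
        stride_inclination_deg >= min_inclination_deg] <- "ascending"
  out[stride_height_m <= -min_height_m &
        stride_inclination_deg <= -min_inclination_deg] <- "descending"
  out
}

#' Assemble walking bouts from classified strides
#'
#' Strides from both feet, time-ordered, are grouped into bouts separated by
#' gaps longer than `max_gap_s`. Within a bout, runs of same-type stair
#' strides shorter than `min_stair_count` are re-labelled level walking;
#' brief level interruptions inside the gap bound do not split a stair run
#' when `merge_interrupted` is TRUE. Level bouts require at least two
#' strides per foot with alternating feet.
#'
#' @param strides data.frame with columns `time_s` (stride start time),
#'   `foot` ("left"/"right"), `stride_type` ("level"/"ascending"/
#'   "descending"/"rejected") and any parameter columns to carry through.
#' @param min_stair_count minimum consecutive same-type stair strides
#'   (default 5).
#' @param max_gap_s maximum inter-stride gap in seconds (default 2.5).
#' @param merge_interrupted allow level interruptions within a stair run
#'   (default TRUE).
#' @return List of `walking_bout` objects: each a list with `activity`,
#'   `strides` (data.frame of members) and `start_time`/`end_time`.
#' @export
assemble_bouts <- function(strides, min_stair_count = 5, max_gap_s = 2.5,
                           merge_interrupted = TRUE) {
  if (nrow(strides) == 0L) return(list())
  strides <- strides[order(strides$time_s), , drop = FALSE]
  for (ft in c("left", "right")) {
    tf <- strides$time_s[strides$foot == ft]
    if (any(diff(tf) <= 0)) stop("overlapping strides from one foot")
  }
  strides <- strides[strides$stride_type != "rejected", , drop = FALSE]
  if (nrow(strides) == 0L) return(list())
  # split at gaps
  gap_grp <- cumsum(c(0, diff(strides$time_s) > max_gap_s))
  bouts <- list()
  for (g in unique(gap_grp)) {
    grp <- strides[gap_grp == g, , drop = FALSE]
    ty <- grp$stride_type
    # demote stair runs that are too short; with merging enabled, level
    # interruptions inside the gap bound do not split a stair run, so the
    # minimum count applies to all same-type strides of the group
    for (stair in c("ascending", "descending")) {
      n_same <- sum(ty == stair)
      if (n_same > 0 && n_same < min_stair_count) ty[ty == stair] <- "level"
      if (!merge_interrupted) {
        # strictly consecutive runs must individually reach the minimum
        r <- rle(ty)
        pos <- cumsum(r$lengths)
        for (j in seq_along(r$values)) {
          if (r$values[j] == stair && r$lengths[j] < min_stair_count) {
            ty[(pos[j] - r$lengths[j] + 1):pos[j]] <- "level"
          }
        }
      }
    }
    grp$stride_type <- ty
    # emit stair bouts per type, then level bout from the rest
    for (stair in c("ascending", "descending")) {
      members <- grp[ty == stair, , drop = FALSE]
      if (nrow(members) >= min_stair_count &&
          feet_alternate(members$foot)) {
        bouts[[length(bouts) + 1]] <- walking_bout(stair, members)
      } else if (nrow(members) > 0) {
        grp$stride_type[grp$stride_type == stair] <- "level"
      }
    }
    members <- grp[grp$stride_type == "level", , drop = FALSE]
    if (nrow(members) >= 4 && sum(members$foot == "left") >= 2 &&
        sum(members$foot == "right") >= 2 && feet_alternate(members$foot)) {
      bouts[[length(bouts) + 1]] <- walking_bout("level", members)
    }
  }
  bouts
}

# feet strictly alternate L-R
feet_alternate <- function(feet) {
  length(feet) < 2L || all(feet[-1] != feet[-length(feet)])
}

walking_bout <- function(activity, members) {
  structure(list(activity = activity, strides = members,
                 start_time = min(members$time_s),
                 end_time = max(members$time_s)),
            class = "walking_bout")
}

#' Digital mobility outcomes per gait activity
#'
#' Pools member strides of all bouts per activity and reports the stride
#' count and the mean and standard deviation of stride, swing and stance
#' times. The SD uses the population formula (divide by n) so a single
#' stride yields SD 0.
#'
#' @param bouts list of `walking_bout` objects.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A `dmo_summary` data.frame, one row per activity present.
#' @export
compute_dmos <- function(bouts, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  sdf <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    if (sd_type == "population")
      sqrt(mean((x - mean(x))^2))
    else if (length(x) > 1L) stats::sd(x) else 0
  }
  acts <- c("level", "ascending", "descending")
  rows <- list()
  for (a in acts) {
    mem <- do.call(rbind, lapply(bouts, function(b)
      if (b$activity == a) b$strides else NULL))
    if (is.null(mem) || nrow(mem) == 0L) {
      message("no strides for activity '", a, "'; omitted from the summary")
      next
    }
    rows[[a]] <- data.frame(
      activity = a, n_strides = nrow(mem),
      stride_time_mean_s = mean(mem$stride_time_s, na.rm = TRUE),
      stride_time_sd_s = sdf(mem$stride_time_s),
      swing_time_mean_s = mean(mem$swing_time_s, na.rm = TRUE),
      swing_time_sd_s = sdf(mem$swing_time_s),
      stance_time_mean_s = mean(mem$stance_time_s, na.rm = TRUE),
      stance_time_sd_s = sdf(mem$stance_time_s))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  class(out) <- c("dmo_summary", "data.frame")
  out
}
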