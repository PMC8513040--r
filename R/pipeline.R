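# End-to-end orchestration: model fitting helpers, configuration, and the
# align -> segment -> events -> trajectory -> classify -> bouts -> DMO flow.

#' Per-class HMM training segments from labelled borders
#'
#' Slices a bout's feature matrix into per-class training segments using
#' ground-truth (or annotated) stride borders: each stride (border to
#' border) becomes one training sequence for its class sub-model, so the
#' left-right chain learns the phase progression of a single stride;
#' everything before the first and after the last border feeds the
#' transition model.
#'
#' @param features an `hmm_features` object for the whole bout.
#' @param borders integer vector of 0-based stride borders at the original
#'   rate (m + 1 borders for m strides).
#' @param classes character vector (length m) of stride classes.
#' @param min_rows segments shorter than this many feature rows are dropped.
#' @return Named list of lists of feature matrices: `transition`, `level`,
#'   `ascending`, `descending`.
#' @export
segmentation_training_data <- function(features, borders, classes,
                                       min_rows = 8L) {
  fac <- features$factor
  X <- features$X
  Tn <- nrow(X)
  out <- list(transition = list(), level = list(), ascending = list(),
              descending = list())
  add <- function(cls, lo, hi) {  # feature-row range, 1-based inclusive
    lo <- max(1L, lo); hi <- min(Tn, hi)
    if (hi - lo + 1L >= min_rows)
      out[[cls]][[length(out[[cls]]) + 1L]] <<- X[lo:hi, , drop = FALSE]
  }
  if (length(borders) < 2L) {
    add("transition", 1L, Tn)
    return(out)
  }
  f_b <- round(borders / fac)
  add("transition", 1L, f_b[1])
  add("transition", f_b[length(f_b)] + 1L, Tn)
  for (j in seq_along(classes)) {
    add(classes[j], f_b[j] + 1L, f_b[j + 1L])
  }
  out
}

#' Fit the multiclass segmentation model on labelled walks
#'
#' Aligns each walk's sensor data to the body frame, extracts features,
#' slices per-class training segments from the ground-truth borders, trains
#' the four sub-models and assembles the combined segmentation model.
#'
#' @param walks list of `synthetic_walk` objects (or any list with per-foot
#'   `imu_sequence`s and `truth` borders/strides of the same shape).
#' @param seed seed for emission initialization.
#' @param n_iterations Baum-Welch iterations per sub-model (default 10).
#' @param n_components mixture components per state (default 8).
#' @return A `segmentation_model`.
#' @export
fit_segmentation_model <- function(walks, seed = 1L, n_iterations = 10,
                                   n_components = 8) {
  pools <- list(transition = list(), level = list(), ascending = list(),
                descending = list())
  for (w in walks) {
    for (f in c("left", "right")) {
      tr <- w$truth[[f]]
      if (is.null(tr)) next
      body <- auto_align(w[[f]])
      feats <- extract_features(body)
      segs <- segmentation_training_data(feats, tr$borders,
                                         tr$strides$stride_type)
      for (cls in names(pools))
        pools[[cls]] <- c(pools[[cls]], segs[[cls]])
    }
  }
  models <- list()
  for (cls in names(pools)) {
    if (!length(pools[[cls]]))
      stop("no training data for class '", cls, "'")
    spec <- submodel_spec(cls, n_components = n_components,
                          n_iterations = n_iterations)
    keep <- vapply(pools[[cls]], nrow, 1L) > spec$n_states
    models[[cls]] <- train_submodel(pools[[cls]][keep], spec, seed = seed)
  }
  build_segmentation_model(models$transition, models$level,
                           models$ascending, models$descending)
}

#' Pipeline configuration
#'
#' Collects all module parameters with their standard defaults plus I/O
#' paths. Any parameter can be overridden.
#'
#' @param imu_left,imu_right per-foot IMU CSV paths or `imu_sequence`s.
#' @param model a `segmentation_model` or path to a saved model JSON.
#' @param fs sampling rate in Hz.
#' @param out_dir optional directory for per-stage artifacts.
#' @param ... overrides for the defaults (see the returned list).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(imu_left = NULL, imu_right = NULL, model = NULL,
                            fs = 204.8, out_dir = NULL, ...) {
  cfg <- list(
    imu_left = imu_left, imu_right = imu_right, model = model, fs = fs,
    out_dir = out_dir,
    static_min_duration_s = 1.0, static_gyr_threshold_dps = 2.5,
    border_refine_window_s = 0.15,
    min_dip_dps = -20, min_swing_dps = 50,
    min_stride_duration_s = 0.4, max_stride_duration_s = 2.5,
    zupt_window_ms = 150, zupt_acc_threshold_g = 0.1,
    zupt_gyr_threshold_dps = 10, zupt_ms_window_ms = 50,
    orient_min_duration_s = 0.3, orient_var_threshold_g2 = 0.015,
    gyro_noise_dps = 0.02, acc_noise_g = 0.002, zupt_sd_ms = 0.01,
    class_min_height_m = 0.10, class_min_inclination_deg = 6,
    min_length_m = 0.25, max_length_m = 2.0,
    min_stair_count = 5, max_gap_s = 2.5, merge_interrupted = TRUE,
    sd_type = "population")
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

# full single-foot processing chain; returns per-stage artifacts
process_foot <- function(seq, seg_model, cfg, foot) {
  body <- auto_align(seq, cfg$static_min_duration_s,
                     cfg$static_gyr_threshold_dps)
  feats <- extract_features(body)
  refined <- predict_stride_borders(seg_model, feats, body,
                                    cfg$border_refine_window_s)
  borders <- postprocess_strides(refined, body, cfg$min_dip_dps,
                                 cfg$min_swing_dps, cfg$min_stride_duration_s,
                                 cfg$max_stride_duration_s)
  events <- detect_gait_events(body, borders)
  params <- flag_outliers(compute_temporal_params(events, body$fs))
  zupt <- detect_zupt(body, events, cfg$zupt_window_ms,
                      cfg$zupt_acc_threshold_g, cfg$zupt_gyr_threshold_dps,
                      cfg$zupt_ms_window_ms)
  updates <- find_orientation_windows(body, cfg$orient_min_duration_s,
                                      cfg$orient_var_threshold_g2)
  traj <- reconstruct_trajectory(body, zupt, updates, cfg$gyro_noise_dps,
                                 cfg$acc_noise_g, cfg$zupt_sd_ms)
  ms <- events$ms[!is.na(events$ms)]
  spatial <- if (length(ms) >= 2) compute_spatial_params(traj, events) else
    NULL
  # one stride row per stride with spatial params (stride i spans MS_i-1..MS_i;
  # spatial features attach to the stride ending at that MS)
  strides <- NULL
  if (!is.null(spatial) && nrow(borders) >= 1) {
    ms_all <- events$ms
    rows <- match(spatial$ms, ms_all)
    strides <- data.frame(
      foot = foot,
      time_s = borders$start[rows] / body$fs,
      stride_time_s = params$stride_time_s[rows],
      swing_time_s = params$swing_time_s[rows],
      stance_time_s = params$stance_time_s[rows],
      temporal_valid = params$valid[rows],
      stride_height_m = spatial$stride_height_m,
      stride_length_m = spatial$stride_length_m,
      stride_inclination_deg = spatial$stride_inclination_deg)
  }
  list(body = body, features = feats, refined = refined, borders = borders,
       events = events, params = params, zupt = zupt, updates = updates,
       trajectory = traj, spatial = spatial, strides = strides)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments and defaults of [pipeline_config()]; unknown
#' keys are rejected to catch typos in threshold names.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- pipeline_config()
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full gait-analysis pipeline
#'
#' Executes alignment, HMM segmentation, event detection, ZUPT-aided
#' trajectory reconstruction, spatial-feature stride classification,
#' walking-bout assembly and DMO computation for a two-foot recording.
#'
#' @param config a `pipeline_config`.
#' @return List with per-foot stage artifacts (`left`, `right`), the merged
#'   classified stride table (`strides`), `bouts` and the `dmos` summary.
#' @export
run_pipeline <- function(config) {
  seg_model <- config$model
  if (is.character(seg_model)) seg_model <- load_segmentation_model(seg_model)
  if (is.null(seg_model)) stop("a segmentation model is required")
  feet <- list()
  all_strides <- NULL
  for (f in c("left", "right")) {
    src <- config[[paste0("imu_", f)]]
    if (is.null(src)) next
    seq <- if (is.character(src)) read_imu_csv(src, fs = config$fs, foot = f)
      else src
    res <- tryCatch(process_foot(seq, seg_model, config, f),
                    error = function(e)
                      stop("pipeline stage failure (foot ", f, "): ",
                           conditionMessage(e), call. = FALSE))
    feet[[f]] <- res
    all_strides <- rbind(all_strides, res$strides)
  }
  bouts <- list()
  dmos <- data.frame()
  if (!is.null(all_strides) && nrow(all_strides) > 0) {
    all_strides$rejected <- reject_implausible(
      all_strides$stride_length_m,
      !is.na(all_strides$temporal_valid) & all_strides$temporal_valid,
      config$min_length_m, config$max_length_m)
    all_strides$stride_type <- ifelse(
      all_strides$rejected, "rejected",
      classify_stride(all_strides$stride_height_m,
                      all_strides$stride_inclination_deg,
                      config$class_min_height_m,
                      config$class_min_inclination_deg))
    all_strides <- all_strides[order(all_strides$time_s), ]
    rownames(all_strides) <- NULL
    bouts <- assemble_bouts(all_strides, config$min_stair_count,
                            config$max_gap_s, config$merge_interrupted)
    dmos <- suppressMessages(compute_dmos(bouts, config$sd_type))
  } else {
    warning("no strides detected; empty DMO report")
  }
  out <- list(left = feet$left, right = feet$right, strides = all_strides,
              bouts = bouts, dmos = dmos)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config)
  out
}

# persist per-stage artifacts as CSV plus a JSON DMO report
write_pipeline_artifacts <- function(result, config) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in c("left", "right")) {
    r <- result[[f]]
    if (is.null(r)) next
    utils::write.csv(as.data.frame(r$borders),
                     file.path(dir, paste0("strides_", f, ".csv")),
                     row.names = FALSE)
    ev <- cbind(r$events, r$params)
    utils::write.csv(ev, file.path(dir, paste0("events_", f, ".csv")),
                     row.names = FALSE)
    if (!is.null(r$spatial))
      utils::write.csv(as.data.frame(r$spatial),
                       file.path(dir, paste0("spatial_", f, ".csv")),
                       row.names = FALSE)
    traj <- data.frame(t = (seq_len(nrow(r$trajectory$position)) - 1) /
                         r$body$fs,
                       x = r$trajectory$position[, 1],
                       y = r$trajectory$position[, 2],
                       z = r$trajectory$position[, 3],
                       vx = r$trajectory$velocity[, 1],
                       vy = r$trajectory$velocity[, 2],
                       vz = r$trajectory$velocity[, 3],
                       qw = r$trajectory$quaternion[, 1],
                       qx = r$trajectory$quaternion[, 2],
                       qy = r$trajectory$quaternion[, 3],
                       qz = r$trajectory$quaternion[, 4],
                       zupt = r$trajectory$zupt)
    utils::write.csv(traj, file.path(dir, paste0("trajectory_", f, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(result$strides))
    utils::write.csv(result$strides, file.path(dir, "strides_typed.csv"),
                     row.names = FALSE)
  report <- list(schema = "stairgait-dmos/1",
                 n_bouts = length(result$bouts),
                 activities = result$dmos)
  jsonlite::write_json(report, file.path(dir, "dmos.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(dir)
}
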