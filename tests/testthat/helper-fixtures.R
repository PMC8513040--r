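# Shared fixtures: all synthetic, generated in code at test time.

sg_cache <- new.env()

# a small static body-frame sequence with an optional wiggle so feature
# standardization stays well defined
static_body_seq <- function(n = 1024, fs = 204.8, wiggle = 0) {
  t <- (seq_len(n) - 1) / fs
  acc <- cbind(0, 0, 1 + wiggle * sin(2 * pi * 1.3 * t))
  gyr <- cbind(wiggle * 100 * sin(2 * pi * 0.9 * t), 0, 0)
  imu_sequence(acc, gyr, fs = fs, frame = "body")
}

# mixed-class training walks (fixed seeds) and a cached trained model
sg_training_walks <- function() {
  if (!is.null(sg_cache$train_walks)) return(sg_cache$train_walks)
  walks <- list()
  k <- 0
  for (sp in c("slow", "preferred", "fast")) for (sc in c("A", "B")) {
    k <- k + 1
    types <- c(rep("level", 3), rep("ascending", 6), rep("level", 3),
               rep("descending", 6), rep("level", 3))
    walks[[k]] <- generate_walk(walk_specs(types, staircase = sc, speed = sp),
                                noise = noise_params(), seed = 100 + k)
  }
  sg_cache$train_walks <- walks
  walks
}

sg_trained_model <- function() {
  if (!is.null(sg_cache$model)) return(sg_cache$model)
  sg_cache$model <- fit_segmentation_model(sg_training_walks(), seed = 1)
  sg_cache$model
}

# reference border set from a walk's ground truth
truth_borders <- function(walk, foot) {
  b <- walk$truth[[foot]]$borders
  stride_border_set(b[-length(b)], b[-1], stage = "refined")
}

# brute-force maximal sub-threshold runs (static-window oracle)
brute_static_windows <- function(gyr_norm, fs, min_s, thr) {
  below <- gyr_norm < thr
  out <- NULL
  i <- 1
  n <- length(below)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      if (j - i + 1 >= min_s * fs) out <- rbind(out, c(i - 1, j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# independent Rodrigues rotation evaluation
rodrigues_rotate <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  cx <- c(axis[2] * v[3] - axis[3] * v[2],
          axis[3] * v[1] - axis[1] * v[3],
          axis[1] * v[2] - axis[2] * v[1])
  v * cos(angle) + cx * sin(angle) + axis * sum(axis * v) * (1 - cos(angle))
}

# brute-force Viterbi: enumerate every state path
brute_viterbi <- function(model, X) {
  em <- stairgait:::ghmm_log_emissions(model, X)
  logB <- em$logB
  K <- model$K
  Tn <- nrow(X)
  logA <- log(model$A)
  best <- -Inf
  best_path <- NULL
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- log(model$init[p[1]]) + logB[1, p[1]]
    if (Tn > 1) for (t in 2:Tn) lp <- lp + logA[p[t - 1], p[t]] + logB[t, p[t]]
    if (lp > best + 1e-12) { best <- lp; best_path <- p }
  }
  list(path = unname(best_path), logp = best)
}

# brute-force optimal one-to-one stride matching (maximum TP)
brute_match_count <- function(predicted, reference, fs, tol_ms = 100) {
  tol <- tol_ms / 1000 * fs
  np <- nrow(predicted); nr <- nrow(reference)
  compat <- outer(seq_len(np), seq_len(nr), function(i, j)
    abs(predicted$start[i] - reference$start[j]) <= tol &
      abs(predicted$end[i] - reference$end[j]) <= tol)
  rec <- function(i, used) {
    if (i > np) return(0L)
    best <- rec(i + 1L, used)
    for (j in which(compat[i, ] & !used)) {
      used[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  rec(1L, rep(FALSE, nr))
}
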