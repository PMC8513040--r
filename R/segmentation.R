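# Multiclass HMM stride segmentation: feature extraction at 51.2 Hz,
# per-class sub-model training, combined segmentation model with
# stride-border edges, Viterbi prediction and border post-processing.

SEG_RATE_FACTOR <- 4L
SEG_LOWPASS_HZ <- 10
SEG_LOWPASS_ORDER <- 4
SEG_GRAD_WINDOW_S <- 0.2

#' Least-squares sliding gradient
#'
#' Slope of the least-squares line in a centred window around each sample,
#' in signal units per second. Edge samples use symmetrically shrunken
#' windows; the first and last sample fall back to the adjacent difference.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 0.2).
#' @return Numeric vector of slopes, same length as `x`.
#' @export
ls_gradient <- function(x, fs, window_s = SEG_GRAD_WINDOW_S) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  w <- round(window_s * fs)
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  out <- numeric(n)
  k_full <- (-h):h
  w_full <- k_full / sum(k_full^2)
  # interior: convolution with the exact LS slope weights
  if (n >= w) {
    interior <- (h + 1):(n - h)
    conv <- stats::filter(x, rev(w_full), sides = 2)
    out[interior] <- conv[interior] * fs
  }
  # edges: shrunken symmetric windows
  for (i in seq_len(min(h, n))) {
    m <- min(i - 1L, n - i)
    if (m < 1L) {
      out[i] <- (x[min(i + 1L, n)] - x[i]) * fs
    } else {
      k <- (-m):m
      out[i] <- sum(k * x[i + k]) / sum(k^2) * fs
    }
  }
  for (i in (n - min(h, n) + 1L):n) {
    m <- min(i - 1L, n - i)
    if (m < 1L) {
      out[i] <- (x[i] - x[max(i - 1L, 1L)]) * fs
    } else {
      k <- (-m):m
      out[i] <- sum(k * x[i + k]) / sum(k^2) * fs
    }
  }
  out
}

#' Extract HMM features from a body-frame sequence
#'
#' Takes the mediolateral angular velocity and superior-inferior acceleration,
#' downsamples by a factor of 4 (to 51.2 Hz for 204.8 Hz input), low-pass
#' filters (4th-order Butterworth, 10 Hz), adds a centred 200 ms
#' least-squares gradient per axis, and z-score standardizes each of the four
#' columns over the bout.
#'
#' @param seq a body-frame `imu_sequence`; input not on the 204.8 Hz grid is
#'   resampled first.
#' @param bout_id identifier carried through for bookkeeping.
#' @return An `hmm_features` object: list with matrix `X`
#'   (columns gyr_ml, acc_si, grad_gyr_ml, grad_acc_si), `rate`, `factor`,
#'   standardization `center`/`scale`, and `bout_id`.
#' @export
extract_features <- function(seq, bout_id = "bout") {
  if (seq$frame != "body") stop("extract_features needs a body-frame sequence")
  if (!isTRUE(all.equal(seq$fs, 204.8))) seq <- imu_resample(seq, 204.8)
  idx <- seq(1L, n_samples(seq), by = SEG_RATE_FACTOR)
  rate <- seq$fs / SEG_RATE_FACTOR
  gyr_ml <- lowpass(seq$gyr[idx, 1], SEG_LOWPASS_HZ, rate, SEG_LOWPASS_ORDER)
  acc_si <- lowpass(seq$acc[idx, 3], SEG_LOWPASS_HZ, rate, SEG_LOWPASS_ORDER)
  X <- cbind(gyr_ml = gyr_ml,
             acc_si = acc_si,
             grad_gyr_ml = ls_gradient(gyr_ml, rate),
             grad_acc_si = ls_gradient(acc_si, rate))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  bad <- which(!is.finite(scl) | scl < 1e-12)
  if (length(bad))
    stop("degenerate standardization: constant feature column(s) ",
         paste(colnames(X)[bad], collapse = ", "))
  X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  structure(list(X = X, rate = rate, factor = SEG_RATE_FACTOR,
                 center = ctr, scale = scl, bout_id = bout_id),
            class = "hmm_features")
}

#' Sub-model specification
#'
#' @param stride_class one of `"transition"`, `"level"`, `"ascending"`,
#'   `"descending"`.
#' @param n_states number of hidden states; defaults to 5 for the transition
#'   model and 20 for the stride models.
#' @param n_components Gaussian mixture components per state (default 8).
#' @param n_iterations Baum-Welch iterations (default 10).
#' @return A `submodel_spec`.
#' @export
submodel_spec <- function(stride_class = c("transition", "level", "ascending",
                                           "descending"),
                          n_states = NULL, n_components = 8,
                          n_iterations = 10) {
  stride_class <- match.arg(stride_class)
  if (is.null(n_states)) n_states <- if (stride_class == "transition") 5L else 20L
  topology <- if (stride_class == "transition") "transition_topology" else "left_right"
  structure(list(stride_class = stride_class, n_states = as.integer(n_states),
                 topology = topology, n_components = as.integer(n_components),
                 n_iterations = as.integer(n_iterations)),
            class = "submodel_spec")
}

# structural transition matrix (allowed-entry mask) for a topology
topology_mask <- function(topology, K) {
  A <- matrix(FALSE, K, K)
  if (topology == "left_right") {
    # self + next state only; last state self-loops
    for (i in seq_len(K)) {
      A[i, i] <- TRUE
      if (i < K) A[i, i + 1] <- TRUE
    }
  } else {
    # dense first row and first column, chain with self-loops,
    # last-state self-loop
    A[1, ] <- TRUE
    A[, 1] <- TRUE
    for (i in seq_len(K)) {
      A[i, i] <- TRUE
      if (i < K) A[i, i + 1] <- TRUE
    }
  }
  A
}

#' Train one HMM sub-model on the data of a single stride class
#'
#' Initializes a Gaussian-mixture HMM with the class topology (left-right
#' chain for strides; chain plus dense first row/column for the transition
#' model), an equal-length state partition of each sequence for the mixture
#' initialization (k-means within each state), then runs Baum-Welch.
#'
#' @param feature_seqs list of feature matrices (T x 4) or `hmm_features`
#'   objects restricted to the class.
#' @param spec a `submodel_spec`.
#' @param seed integer seed controlling the k-means initialization.
#' @return A trained `ghmm` with the spec stored as attribute `spec` and the
#'   Baum-Welch log-likelihood trace as attribute `loglik`.
#' @export
train_submodel <- function(feature_seqs, spec, seed = 1L) {
  seqs <- lapply(feature_seqs, function(f)
    if (inherits(f, "hmm_features")) f$X else as.matrix(f))
  if (length(seqs) < 1L) stop("need at least one training sequence")
  K <- spec$n_states
  if (any(vapply(seqs, nrow, 1L) < K))
    stop("each training sequence must be longer than the number of states")
  M <- spec$n_components
  D <- ncol(seqs[[1]])
  mask <- topology_mask(spec$topology, K)
  A <- matrix(0, K, K)
  if (spec$topology == "left_right") {
    # dwell-matched: expected frames per state from the mean sequence length
    dwell <- max(1.5, mean(vapply(seqs, nrow, 1L)) / K)
    p_stay <- 1 - 1 / dwell
    for (i in seq_len(K - 1)) { A[i, i] <- p_stay; A[i, i + 1] <- 1 - p_stay }
    A[K, K] <- 1
    init <- c(1, rep(0, K - 1))
  } else {
    A[mask] <- 1
    A <- A / rowSums(A)
    init <- rep(1 / K, K)
  }
  # pool per-state data from an equal-length partition of every sequence
  state_data <- vector("list", K)
  for (X in seqs) {
    Tn <- nrow(X)
    cut <- floor(seq(0, Tn, length.out = K + 1))
    for (k in seq_len(K)) {
      rows <- (cut[k] + 1):cut[k + 1]
      state_data[[k]] <- rbind(state_data[[k]], X[rows, , drop = FALSE])
    }
  }
  means <- array(0, c(K, M, D))
  vars <- array(1, c(K, M, D))
  weights <- matrix(1 / M, K, M)
  set.seed(seed)
  for (k in seq_len(K)) {
    Z <- state_data[[k]]
    if (nrow(Z) <= M + 1) {
      # too few samples: replicate with jitter
      Z <- Z[rep(seq_len(nrow(Z)), length.out = M * 3), , drop = FALSE]
      Z <- Z + matrix(stats::rnorm(length(Z), sd = 1e-3), nrow(Z))
    }
    km <- suppressWarnings(stats::kmeans(Z, centers = M, iter.max = 20,
                                         nstart = 1))
    means[k, , ] <- km$centers
    for (m in seq_len(M)) {
      pts <- Z[km$cluster == m, , drop = FALSE]
      v <- if (nrow(pts) > 1) apply(pts, 2, stats::var) else rep(0.05, D)
      vars[k, m, ] <- pmax(v, 1e-3)
      weights[k, m] <- max(nrow(pts) / nrow(Z), 1e-6)
    }
    weights[k, ] <- weights[k, ] / sum(weights[k, ])
  }
  model <- ghmm(A, init, means, vars, weights)
  model <- ghmm_train(model, seqs, n_iter = spec$n_iterations)
  attr(model, "spec") <- spec
  model
}

#' Build the combined multiclass segmentation model
#'
#' Joins the transition, level, ascending and descending sub-models into one
#' block-diagonal transition matrix and inserts the inter-sub-model edges
#' that mark stride borders: from any transition state into each stride
#' model's first state, from each stride model's last state back into every
#' transition state, stride-model self-restarts (last to first state), and
#' the direct stride-type switches (level end to ascending/descending start
#' and vice versa). Each inserted edge receives the mean outgoing probability
#' of its source row before row renormalization.
#'
#' @param transition_m,level_m,ascending_m,descending_m trained `ghmm`
#'   sub-models.
#' @return A `segmentation_model`: list with the combined `ghmm` (`model`),
#'   `state_class` (per-state class labels), `border_edges` (two-column
#'   matrix of 1-based from/to state indices), and per-class state offsets.
#' @export
build_segmentation_model <- function(transition_m, level_m, ascending_m,
                                     descending_m) {
  subs <- list(transition = transition_m, level = level_m,
               ascending = ascending_m, descending = descending_m)
  if (any(vapply(subs, is.null, TRUE))) stop("all four sub-models are required")
  Ks <- vapply(subs, function(m) m$K, 1L)
  off <- cumsum(c(0, Ks))[1:4]
  names(off) <- names(subs)
  N <- sum(Ks)
  M <- subs[[1]]$M; D <- subs[[1]]$D
  A <- matrix(0, N, N)
  means <- array(0, c(N, M, D)); vars <- array(1, c(N, M, D))
  weights <- matrix(1 / M, N, M)
  state_class <- character(N)
  for (nm in names(subs)) {
    m <- subs[[nm]]
    r <- off[[nm]] + seq_len(m$K)
    A[r, r] <- m$A
    means[r, , ] <- m$means
    vars[r, , ] <- m$vars
    weights[r, ] <- m$weights
    state_class[r] <- nm
  }
  t_states <- off[["transition"]] + seq_len(Ks[["transition"]])
  firsts <- c(level = off[["level"]] + 1L,
              ascending = off[["ascending"]] + 1L,
              descending = off[["descending"]] + 1L)
  lasts <- c(level = off[["level"]] + Ks[["level"]],
             ascending = off[["ascending"]] + Ks[["ascending"]],
             descending = off[["descending"]] + Ks[["descending"]])
  edges <- NULL
  add_edge <- function(from, to) {
    for (f in from) for (tt in to) edges <<- rbind(edges, c(f, tt))
  }
  # transition states -> stride starts
  add_edge(t_states, unname(firsts))
  # stride ends -> transition states
  add_edge(unname(lasts), t_states)
  # self restarts and type switches involving level walking
  add_edge(lasts[["level"]], unname(firsts))          # sLn -> sL0/sA0/sD0
  add_edge(lasts[["ascending"]], firsts[c("ascending", "level")])
  add_edge(lasts[["descending"]], firsts[c("descending", "level")])
  edges <- unique(edges)
  for (i in seq_len(nrow(edges))) {
    f <- edges[i, 1]; tt <- edges[i, 2]
    nz <- A[f, ] > 0
    A[f, tt] <- A[f, tt] + mean(A[f, nz])
  }
  A <- A / rowSums(A)
  # initial distribution: uniform over transition states and stride starts
  init <- rep(0, N)
  init[c(t_states, unname(firsts))] <- 1
  init <- init / sum(init)
  model <- ghmm(A, init, means, vars, weights)
  structure(list(model = model, state_class = state_class,
                 border_edges = edges, offsets = off, n_states = Ks),
            class = "segmentation_model")
}

#' Predict stride borders from continuous body-frame data
#'
#' Viterbi-decodes the feature sequence under the combined segmentation
#' model, extracts border-edge transitions of the hidden-state path, scales
#' them back to the original sampling rate (factor 4), and snaps each border
#' to the minimum of the raw mediolateral angular velocity within a
#' +/- 150 ms window.
#'
#' @param seg_model a `segmentation_model`.
#' @param features an `hmm_features` object from [extract_features()].
#' @param seq the body-frame `imu_sequence` the features came from.
#' @param refine_window_s half-width of the border refinement window in
#'   seconds (default 0.15).
#' @return A `stride_border_set`: data.frame with 0-based `start`/`end`
#'   sample columns, predicted `class`, and attribute `stage` = "refined".
#' @export
predict_stride_borders <- function(seg_model, features, seq,
                                   refine_window_s = 0.15) {
  path <- ghmm_viterbi(seg_model$model, features$X)
  Tn <- length(path)
  key <- seg_model$border_edges[, 1] * 1e6 + seg_model$border_edges[, 2]
  trans_key <- path[-Tn] * 1e6 + path[-1]
  b_feat <- which(trans_key %in% key)  # border between t and t+1 -> index t+1
  empty <- stride_border_set(integer(), integer(), character(), "refined")
  if (length(b_feat) < 2L) return(empty)
  borders <- b_feat * features$factor  # 0-based original-rate sample
  half <- round(refine_window_s * seq$fs)
  n <- n_samples(seq)
  gml <- seq$gyr[, 1]
  snapped <- vapply(borders, function(b) {
    lo <- max(0L, b - half); hi <- min(n - 1L, b + half)
    win <- gml[(lo + 1):(hi + 1)]
    lo + which.min(win) - 1L
  }, numeric(1))
  # stride class: modal state class between consecutive borders
  starts <- integer(); ends <- integer(); cls <- character()
  for (i in seq_len(length(b_feat) - 1L)) {
    seg_states <- path[(b_feat[i] + 1):b_feat[i + 1]]
    seg_cls <- seg_model$state_class[seg_states]
    cl <- names(sort(table(seg_cls), decreasing = TRUE))[1]
    if (cl == "transition") next
    starts <- c(starts, snapped[i]); ends <- c(ends, snapped[i + 1])
    cls <- c(cls, cl)
  }
  keep <- ends > starts
  stride_border_set(starts[keep], ends[keep], cls[keep], "refined")
}

#' Construct a stride border set
#' @param start,end 0-based sample indices (half-open strides; the end border
#'   of one stride may be the start border of the next).
#' @param class per-stride predicted class (optional).
#' @param stage provenance tag: `"raw_hmm"`, `"refined"` or `"filtered"`.
#' @return A `stride_border_set` data.frame.
#' @export
stride_border_set <- function(start, end, class = NULL, stage = "raw_hmm") {
  d <- data.frame(start = as.integer(start), end = as.integer(end),
                  class = if (is.null(class) || !length(class))
                    rep(NA_character_, length(start)) else as.character(class))
  attr(d, "stage") <- stage
  class(d) <- c("stride_border_set", "data.frame")
  d
}

#' Post-process predicted strides
#'
#' Applies the validity rules used for manual annotation plus the duration
#' bound: the mediolateral angular velocity at the stride's start border
#' (terminal-contact dip) must reach at most -20 dps, the in-stride swing
#' maximum must reach at least +50 dps, and the stride duration must lie in
#' `[0.4, 2.5]` seconds.
#'
#' @param borders a `stride_border_set` (stage "refined").
#' @param seq the body-frame `imu_sequence`.
#' @param min_dip_dps,min_swing_dps,min_duration_s,max_duration_s rule
#'   parameters.
#' @return A filtered `stride_border_set` (stage "filtered").
#' @export
postprocess_strides <- function(borders, seq, min_dip_dps = -20,
                                min_swing_dps = 50, min_duration_s = 0.4,
                                max_duration_s = 2.5) {
  if (nrow(borders) == 0L) {
    attr(borders, "stage") <- "filtered"
    return(borders)
  }
  gml <- seq$gyr[, 1]
  dur <- (borders$end - borders$start) / seq$fs
  keep <- logical(nrow(borders))
  for (i in seq_len(nrow(borders))) {
    s <- borders$start[i]; e <- borders$end[i]
    dip_ok <- gml[s + 1] <= min_dip_dps
    swing_ok <- max(gml[(s + 1):(e + 1)]) >= min_swing_dps
    keep[i] <- dip_ok && swing_ok &&
      dur[i] >= min_duration_s && dur[i] <= max_duration_s
  }
  out <- borders[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- "filtered"
  class(out) <- c("stride_border_set", "data.frame")
  out
}

#' Save / load a segmentation model as JSON
#'
#' @param seg_model a `segmentation_model`.
#' @param path file path.
#' @return `path` (save) or the restored `segmentation_model` (load).
#' @export
save_segmentation_model <- function(seg_model, path) {
  m <- seg_model$model
  obj <- list(schema = "stairgait-segmentation-model/1",
              A = as.numeric(m$A), init = m$init,
              means = as.numeric(m$means), vars = as.numeric(m$vars),
              weights = as.numeric(m$weights), dims = c(m$K, m$M, m$D),
              state_class = seg_model$state_class,
              border_edges = seg_model$border_edges,
              offsets = as.list(seg_model$offsets),
              n_states = as.list(seg_model$n_states))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_segmentation_model
#' @export
load_segmentation_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "stairgait-segmentation-model/1"))
    stop("unrecognized model schema")
  K <- obj$dims[1]; M <- obj$dims[2]; D <- obj$dims[3]
  model <- ghmm(matrix(unlist(obj$A), K, K), obj$init,
                array(unlist(obj$means), c(K, M, D)),
                array(unlist(obj$vars), c(K, M, D)),
                matrix(unlist(obj$weights), K, M))
  be <- obj$border_edges
  if (!is.matrix(be)) be <- matrix(unlist(be), ncol = 2, byrow = TRUE)
  structure(list(model = model, state_class = obj$state_class,
                 border_edges = be,
                 offsets = unlist(obj$offsets),
                 n_states = unlist(obj$n_states)),
            class = "segmentation_model")
}
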