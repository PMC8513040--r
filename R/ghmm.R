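# Gaussian-mixture hidden Markov model core: diagonal-covariance GMM
# emissions, scaled forward-backward, Baum-Welch with topology-preserving
# (structural-zero) transition updates, and log-space Viterbi decoding.

#' Create a Gaussian-mixture HMM
#'
#' @param A K x K row-stochastic transition matrix; zero entries are
#'   structural and stay zero under training.
#' @param init length-K initial state distribution.
#' @param means,vars,weights emission parameters: `means` and `vars` are
#'   K x M x D arrays (M mixture components, D feature dimensions),
#'   `weights` a K x M matrix of mixture weights.
#' @return A `ghmm` object.
#' @export
ghmm <- function(A, init, means, vars, weights) {
  K <- nrow(A)
  stopifnot(ncol(A) == K, length(init) == K, dim(means)[1] == K,
            all(dim(means) == dim(vars)), nrow(weights) == K,
            ncol(weights) == dim(means)[2])
  structure(list(A = A, init = init, means = means, vars = vars,
                 weights = weights, K = K, M = dim(means)[2],
                 D = dim(means)[3]),
            class = "ghmm")
}

# per-component log densities: returns T x (K*M) matrix, column-major in
# (component within state), plus the T x K state log-likelihood matrix
ghmm_log_emissions <- function(model, X) {
  Tn <- nrow(X); K <- model$K; M <- model$M; D <- model$D
  logc <- matrix(0, Tn, K * M)
  for (k in seq_len(K)) {
    for (m in seq_len(M)) {
      mu <- model$means[k, m, ]
      v <- model$vars[k, m, ]
      q <- 0
      for (d in seq_len(D)) q <- q + (X[, d] - mu[d])^2 / v[d]
      logc[, (k - 1) * M + m] <- -0.5 * (q + sum(log(2 * pi * v))) +
        log(model$weights[k, m])
    }
  }
  logB <- matrix(0, Tn, K)
  for (k in seq_len(K)) {
    block <- logc[, (k - 1) * M + seq_len(M), drop = FALSE]
    mx <- apply(block, 1, max)
    logB[, k] <- mx + log(rowSums(exp(block - mx)))
  }
  list(logc = logc, logB = logB)
}

# scaled forward-backward; returns gamma (T x K), summed xi (K x K),
# log-likelihood, and the scaled emission matrix used
ghmm_forward_backward <- function(model, logB) {
  Tn <- nrow(logB); K <- model$K
  bmax <- apply(logB, 1, max)
  B <- exp(logB - bmax)  # per-row rescale; constants absorbed by scaling
  A <- model$A
  alpha <- matrix(0, Tn, K)
  cvec <- numeric(Tn)
  a <- model$init * B[1, ]
  cvec[1] <- sum(a)
  if (cvec[1] <= 0) stop("zero forward probability at t = 1")
  alpha[1, ] <- a / cvec[1]
  for (t in 2:Tn) {
    a <- as.numeric(crossprod(A, alpha[t - 1, ])) * B[t, ]
    cvec[t] <- sum(a)
    if (cvec[t] <= 0) stop("zero forward probability at t = ", t)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  for (t in (Tn - 1):1) {
    beta[t, ] <- as.numeric(A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, K, K)
  for (t in 1:(Tn - 1)) {
    x <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A
    xi <- xi + x / sum(x)
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)) + sum(bmax))
}

#' Baum-Welch training of a Gaussian-mixture HMM
#'
#' Runs expectation-maximization over one or more observation sequences.
#' Structural zeros of the transition matrix and of the initial distribution
#' are preserved exactly; mixture variances are floored to keep the
#' likelihood bounded.
#'
#' @param model a `ghmm`.
#' @param seqs list of T x D observation matrices.
#' @param n_iter number of iterations (default 10).
#' @param var_floor minimum per-dimension mixture variance.
#' @return The trained `ghmm` with a `loglik` attribute: the per-iteration
#'   total log-likelihood (non-decreasing).
#' @export
ghmm_train <- function(model, seqs, n_iter = 10, var_floor = 1e-3) {
  if (!is.list(seqs)) seqs <- list(seqs)
  K <- model$K; M <- model$M; D <- model$D
  ll_trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    xi_acc <- matrix(0, K, K)
    init_acc <- numeric(K)
    r_acc <- matrix(0, K * M, 1)          # sum of component responsibilities
    mu_acc <- matrix(0, K * M, D)
    m2_acc <- matrix(0, K * M, D)
    ll <- 0
    for (X in seqs) {
      em <- ghmm_log_emissions(model, X)
      fb <- ghmm_forward_backward(model, em$logB)
      ll <- ll + fb$loglik
      xi_acc <- xi_acc + fb$xi
      init_acc <- init_acc + fb$gamma[1, ]
      # component responsibilities: gamma_t(k) * c_km(t) / b_k(t)
      for (k in seq_len(K)) {
        cols <- (k - 1) * M + seq_len(M)
        w <- exp(em$logc[, cols, drop = FALSE] - em$logB[, k])
        w <- w * fb$gamma[, k]
        r_acc[cols, 1] <- r_acc[cols, 1] + colSums(w)
        mu_acc[cols, ] <- mu_acc[cols, ] + t(w) %*% X
        m2_acc[cols, ] <- m2_acc[cols, ] + t(w) %*% (X * X)
      }
    }
    ll_trace[it] <- ll
    # M-step: transitions (structural zeros preserved: xi is zero wherever A is)
    rs <- rowSums(xi_acc)
    A_new <- model$A
    upd <- rs > 0
    A_new[upd, ] <- xi_acc[upd, , drop = FALSE] / rs[upd]
    model$A <- A_new
    si <- sum(init_acc)
    if (si > 0) model$init <- init_acc / si
    # emissions
    for (k in seq_len(K)) {
      cols <- (k - 1) * M + seq_len(M)
      rk <- r_acc[cols, 1]
      tot <- sum(rk)
      if (tot <= 0) next
      model$weights[k, ] <- pmax(rk / tot, 1e-8)
      model$weights[k, ] <- model$weights[k, ] / sum(model$weights[k, ])
      for (m in seq_len(M)) {
        if (rk[m] <= 1e-10) next
        mu <- mu_acc[cols[m], ] / rk[m]
        v <- m2_acc[cols[m], ] / rk[m] - mu^2
        model$means[k, m, ] <- mu
        model$vars[k, m, ] <- pmax(v, var_floor)
      }
    }
  }
  attr(model, "loglik") <- ll_trace
  model
}

#' Viterbi decoding
#'
#' Most likely hidden-state path, computed in log space; ties are broken
#' toward the lower state index.
#'
#' @param model a `ghmm`.
#' @param X T x D observation matrix.
#' @return Integer vector of length T with 1-based state indices.
#' @export
ghmm_viterbi <- function(model, X) {
  em <- ghmm_log_emissions(model, X)
  logB <- em$logB
  Tn <- nrow(X); K <- model$K
  logA <- log(model$A)
  delta <- log(model$init) + logB[1, ]
  psi <- matrix(0L, Tn, K)
  for (t in 2:Tn) {
    cand <- delta + logA  # K x K: cand[i, j] = delta_i + log a_ij
    best <- apply(cand, 2, which.max)  # which.max returns first (lowest) max
    delta <- cand[cbind(best, seq_len(K))] + logB[t, ]
    psi[t, ] <- best
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}
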