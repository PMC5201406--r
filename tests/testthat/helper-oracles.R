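# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's scaled/compiled code paths.

rdirichlet_mat <- function(n, m, conc = 1) {
  x <- matrix(rgamma(n * m, conc), n, m)
  x / rowSums(x)
}

# A random discrete HMM drawn from the current RNG stream.
random_model <- function(N = 4, M = 6, conc = 1) {
  list(pi = as.numeric(rdirichlet_mat(1, N, conc)),
       A = rdirichlet_mat(N, N, conc),
       B = rdirichlet_mat(N, M, conc))
}

# All N^T state paths as a T-column matrix.
all_paths <- function(N, T) {
  as.matrix(expand.grid(rep(list(seq_len(N)), T)))
}

# Log-probability of every state path for a given observation sequence.
path_logprobs <- function(pi, A, B, obs) {
  Tn <- length(obs)
  P <- all_paths(length(pi), Tn)
  lp <- log(pi[P[, 1]]) + log(B[cbind(P[, 1], obs[1])])
  if (Tn >= 2) for (t in 2:Tn) {
    lp <- lp + log(A[cbind(P[, t - 1], P[, t])]) +
      log(B[cbind(P[, t], obs[t])])
  }
  list(paths = P, logprob = lp)
}

# Brute-force log P(O | lambda) by summing over every path.
brute_force_loglik <- function(pi, A, B, obs) {
  lp <- path_logprobs(pi, A, B, obs)$logprob
  m <- max(lp)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lp - m)))
}

# Brute-force Viterbi: the highest-probability path and its log-probability.
brute_force_viterbi <- function(pi, A, B, obs) {
  pp <- path_logprobs(pi, A, B, obs)
  k <- which.max(pp$logprob)
  list(path = as.integer(pp$paths[k, ]) - 1L, log_prob = pp$logprob[k])
}

# Naive (unscaled) forward/backward recursions, usable for short sequences.
naive_forward <- function(pi, A, B, obs) {
  Tn <- length(obs); N <- length(pi)
  alpha <- matrix(0, Tn, N)
  alpha[1, ] <- pi * B[, obs[1]]
  if (Tn >= 2) for (t in 2:Tn)
    alpha[t, ] <- (alpha[t - 1, ] %*% A) * B[, obs[t]]
  alpha
}

naive_backward <- function(pi, A, B, obs) {
  Tn <- length(obs); N <- length(pi)
  beta <- matrix(0, Tn, N)
  beta[Tn, ] <- 1
  if (Tn >= 2) for (t in (Tn - 1):1)
    beta[t, ] <- A %*% (B[, obs[t + 1]] * beta[t + 1, ])
  beta
}

# Naive posteriors from unscaled quantities.
naive_posteriors <- function(pi, A, B, obs) {
  alpha <- naive_forward(pi, A, B, obs)
  beta <- naive_backward(pi, A, B, obs)
  Tn <- length(obs); N <- length(pi)
  p_obs <- sum(alpha[Tn, ])
  gamma <- (alpha * beta) / p_obs
  xi <- array(0, dim = c(max(Tn - 1, 0), N, N))
  if (Tn >= 2) for (t in seq_len(Tn - 1)) {
    xi[t, , ] <- (alpha[t, ] %o% (B[, obs[t + 1]] * beta[t + 1, ])) * A / p_obs
  }
  list(gamma = gamma, xi = xi, loglik = log(p_obs))
}

# One naive multi-sequence EM update (no smoothing), pooled numerators and
# denominators, for checking baum_welch_step.
naive_em_step <- function(pi, A, B, seqs) {
  N <- length(pi); M <- ncol(B)
  A_num <- matrix(0, N, N); A_den <- numeric(N)
  B_num <- matrix(0, N, M); B_den <- numeric(N)
  g1 <- numeric(N)
  for (o in seqs) {
    po <- naive_posteriors(pi, A, B, o)
    Tn <- length(o)
    g1 <- g1 + po$gamma[1, ]
    A_num <- A_num + apply(po$xi, c(2, 3), sum)
    A_den <- A_den + colSums(po$gamma[-Tn, , drop = FALSE])
    for (t in seq_len(Tn)) B_num[, o[t]] <- B_num[, o[t]] + po$gamma[t, ]
    B_den <- B_den + colSums(po$gamma)
  }
  list(pi = g1 / sum(g1), A = A_num / A_den, B = B_num / B_den)
}

# Power-iteration estimate of the largest singular value of B.
power_norm2 <- function(B, iters = 500, tol = 1e-14) {
  M <- crossprod(B)  # t(B) %*% B; largest eigenvalue = sigma_max^2
  v <- rep(1 / sqrt(ncol(M)), ncol(M))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- M %*% v
    lam_new <- sqrt(sum(w^2))
    v <- as.numeric(w) / lam_new
    if (abs(lam_new - lam) < tol * max(1, lam_new)) break
    lam <- lam_new
  }
  sqrt(lam_new)
}

# Wrap explicit matrices as a ground truth shared by every zone.
make_truth <- function(pi, A, B) {
  zs <- c("1", "2", "3", "whole")
  structure(list(pi = pi,
                 A_by_zone = setNames(rep(list(A), 4), zs),
                 B_by_zone = setNames(rep(list(B), 4), zs),
                 state_names = hmdm_states()),
            class = "hmdm_truth")
}

# A well-separated 4-state/81-symbol truth for parameter-recovery
# experiments: sticky transitions, near-orthogonal emission rows.
separated_truth <- function(seed = 101) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  A <- 0.6 * diag(4) + 0.4 * rdirichlet_mat(4, 4, 1)
  A <- A / rowSums(A)
  B <- rdirichlet_mat(4, 81, 0.2)
  make_truth(rep(0.25, 4), A, B)
}

# Multiplicative perturbation of a stochastic matrix (rows renormalized).
perturb_rows <- function(M, eps = 0.05) {
  M2 <- M * (1 + matrix(runif(length(M), -eps, eps), nrow(M)))
  M2 / rowSums(M2)
}
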