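test_that("forward collapses to closed forms in degenerate models", {
  # single-state model: log P(O) is the sum of log emissions
  B1 <- matrix(c(0.2, 0.3, 0.5), 1, 3)
  m1 <- list(pi = 1, A = matrix(1, 1, 1), B = B1)
  o <- c(1L, 3L, 3L, 2L)
  expect_equal(forward(m1, o)$loglik, sum(log(B1[1, o])), tolerance = 1e-12)
  # uniform pi and A with deterministic one-hot emissions: P = (1/N)^T
  N <- 4
  m2 <- list(pi = rep(1 / N, N), A = matrix(1 / N, N, N), B = diag(N))
  o2 <- c(2L, 4L, 1L, 1L, 3L)
  expect_equal(forward(m2, o2)$loglik, length(o2) * log(1 / N),
               tolerance = 1e-12)
})

test_that("scaled forward matches brute-force path enumeration", {
  set.seed(42)
  for (i in 1:25) {
    N <- sample(2:4, 1)
    M <- sample(2:6, 1)
    Tn <- sample(1:6, 1)
    m <- random_model(N, M)
    o <- sample.int(M, Tn, replace = TRUE)
    expect_equal(forward(m, o)$loglik, brute_force_loglik(m$pi, m$A, m$B, o),
                 tolerance = 1e-10)
  }
})

test_that("an impossible symbol yields -Inf log-likelihood, not an error", {
  B <- rbind(c(0.5, 0.5, 0), c(0.7, 0.3, 0))  # symbol 3 unemittable
  m <- list(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2), B = B)
  expect_identical(forward(m, c(1L, 3L, 2L))$loglik, -Inf)
  expect_identical(forward(m, 3L)$loglik, -Inf)
})

test_that("backward pass is consistent with the forward scaling", {
  set.seed(7)
  m <- random_model(4, 5)
  o <- sample.int(5, 12, replace = TRUE)
  fw <- forward(m, o)
  bw <- backward(m, o)
  # T = 1 remainder: beta is identically 1
  expect_equal(backward(m, o[1])$beta[1, ], rep(1, 4))
  # sum_i alpha_hat_t(i) beta_hat_t(i) = 1 at every t
  expect_equal(rowSums(fw$alpha * bw$beta), rep(1, 12), tolerance = 1e-12)
  # single-state model: unscaled beta_t is the product of remaining emissions
  B1 <- matrix(c(0.4, 0.6), 1, 2)
  o1 <- c(1L, 2L, 2L)
  nb <- naive_backward(1, matrix(1, 1, 1), B1, o1)
  expect_equal(nb[, 1], c(0.6 * 0.6, 0.6, 1))
})

test_that("scaled forward/backward/posteriors agree with naive unscaled code", {
  set.seed(11)
  for (i in 1:10) {
    N <- sample(2:4, 1); M <- sample(3:6, 1)
    Tn <- sample(2:20, 1)
    m <- random_model(N, M)
    o <- sample.int(M, Tn, replace = TRUE)
    fw <- forward(m, o)
    na <- naive_forward(m$pi, m$A, m$B, o)
    # scaled alpha is the row-normalized naive alpha
    expect_equal(fw$alpha, na / rowSums(na), tolerance = 1e-9)
    expect_equal(fw$loglik, log(sum(na[Tn, ])), tolerance = 1e-9)
    po <- posteriors(m, o)
    np <- naive_posteriors(m$pi, m$A, m$B, o)
    expect_equal(po$gamma, np$gamma, tolerance = 1e-9)
    expect_equal(po$xi, np$xi, tolerance = 1e-9)
  }
})

test_that("posterior identities hold", {
  set.seed(3)
  m <- random_model(4, 6)
  o <- sample.int(6, 15, replace = TRUE)
  po <- posteriors(m, o)
  expect_equal(rowSums(po$gamma), rep(1, 15), tolerance = 1e-12)
  # gamma_t(i) = sum_j xi_t(i, j) for t < T
  marg <- t(apply(po$xi, 1, rowSums))
  expect_equal(po$gamma[-15, ], marg, tolerance = 1e-12)
  # single-state model: gamma is identically 1
  m1 <- list(pi = 1, A = matrix(1, 1, 1), B = matrix(c(0.3, 0.7), 1, 2))
  expect_equal(posteriors(m1, c(1L, 2L, 1L))$gamma[, 1], rep(1, 3))
})

test_that("viterbi matches brute-force maximization and its invariants", {
  set.seed(99)
  for (i in 1:25) {
    N <- sample(2:4, 1); M <- sample(2:5, 1)
    Tn <- sample(1:6, 1)
    m <- random_model(N, M)
    o <- sample.int(M, Tn, replace = TRUE)
    v <- viterbi(m, o)
    bf <- brute_force_viterbi(m$pi, m$A, m$B, o)
    expect_identical(v$path, bf$path)
    expect_equal(v$log_prob, bf$log_prob, tolerance = 1e-10)
    # best single path can never beat the total likelihood
    expect_lte(v$log_prob, forward(m, o)$loglik + 1e-12)
    # replaying the decoded path reproduces its log-probability
    lp <- log(m$pi[v$path[1] + 1]) + log(m$B[v$path[1] + 1, o[1]])
    if (Tn >= 2) for (t in 2:Tn) {
      lp <- lp + log(m$A[v$path[t - 1] + 1, v$path[t] + 1]) +
        log(m$B[v$path[t] + 1, o[t]])
    }
    expect_equal(lp, v$log_prob, tolerance = 1e-10)
  }
})

test_that("viterbi edge cases: T = 1 argmax, deterministic chain, ties", {
  m <- random_model(4, 5)
  o1 <- 3L
  v <- viterbi(m, o1)
  expect_identical(v$path, which.max(m$pi * m$B[, 3]) - 1L)
  # absorbing deterministic chain stays in its start state
  md <- list(pi = c(0, 0, 1, 0), A = diag(4),
             B = matrix(1 / 5, 4, 5))
  vd <- viterbi(md, rep(2L, 6))
  expect_identical(vd$path, rep(2L, 6))
  # full symmetry: ties break toward the lowest state index
  mu <- list(pi = rep(0.25, 4), A = matrix(0.25, 4, 4),
             B = matrix(1 / 5, 4, 5))
  expect_identical(viterbi(mu, c(1L, 2L))$path, c(0L, 0L))
})
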