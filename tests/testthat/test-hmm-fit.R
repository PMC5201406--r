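test_that("a fixed point of the EM update is left unchanged", {
  # single-state model already matching the data exactly
  m <- list(pi = 1, A = matrix(1, 1, 1), B = matrix(c(0, 1, 0), 1, 3))
  step <- baum_welch_step(m, list(rep(2L, 5)), epsilon = 0)
  expect_equal(step$params$pi, c(S1 = 1), tolerance = 1e-12)
  expect_equal(unname(step$params$A), matrix(1, 1, 1), tolerance = 1e-12)
  expect_equal(unname(step$params$B), matrix(c(0, 1, 0), 1, 3),
               tolerance = 1e-12)
  # two exchangeable states with matching emissions are also stationary
  m2 <- list(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
             B = rbind(c(0.5, 0.5), c(0.5, 0.5)))
  s2 <- baum_welch_step(m2, list(c(1L, 2L, 2L, 1L)), epsilon = 0)
  expect_equal(unname(s2$params$A), matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_equal(unname(s2$params$B), m2$B, tolerance = 1e-12)
})

test_that("one EM update matches the naive pooled-count oracle", {
  set.seed(5)
  for (i in 1:5) {
    m <- random_model(3, 4)
    seqs <- lapply(1:3, function(j) sample.int(4, sample(2:6, 1),
                                               replace = TRUE))
    step <- baum_welch_step(m, seqs, epsilon = 0)
    ref <- naive_em_step(m$pi, m$A, m$B, seqs)
    expect_equal(unname(step$params$pi), ref$pi, tolerance = 1e-10)
    expect_equal(unname(step$params$A), ref$A, tolerance = 1e-10)
    expect_equal(unname(step$params$B), ref$B, tolerance = 1e-10)
    # reported log-likelihood is that of the input parameters
    expect_equal(step$loglik,
                 sum(sapply(seqs, function(o) forward(m, o)$loglik)),
                 tolerance = 1e-10)
  }
})

test_that("EM updates never decrease the training log-likelihood", {
  set.seed(21)
  truth <- separated_truth()
  seqs <- sample_hmm_sequences(truth, 1, 30, 25, seed = 8)
  fit <- hmdm(seqs, supervised = FALSE,
              control = hmdm_control(n_restarts = 2, max_iterations = 60,
                                     seed = 4))
  expect_true(all(diff(fit$trace) >= -1e-9))
  # and again on a second data set with a different shape
  m <- random_model(4, 81)
  seqs2 <- lapply(1:10, function(i) sample.int(81, 20, replace = TRUE))
  fit2 <- hmdm(seqs2, supervised = FALSE,
               control = hmdm_control(n_restarts = 1, max_iterations = 40,
                                      seed = 9))
  expect_true(all(diff(fit2$trace) >= -1e-9))
})

test_that("EM preserves row-stochasticity exactly after every update", {
  set.seed(13)
  m <- random_model(4, 6)
  seqs <- lapply(1:4, function(i) sample.int(6, 10, replace = TRUE))
  for (i in 1:5) {
    m <- coef(baum_welch_step(m, seqs)$params)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    expect_equal(rowSums(m$A), setNames(rep(1, 4), hmdm_states()),
                 tolerance = 1e-12)
    expect_equal(rowSums(m$B), setNames(rep(1, 4), hmdm_states()),
                 tolerance = 1e-12)
  }
})

test_that("constant-symbol data concentrates the fitted emissions", {
  seqs <- lapply(1:5, function(i) rep(7L, 12))
  fit <- hmdm(seqs, n_states = 4, n_symbols = 10, supervised = FALSE,
              control = hmdm_control(n_restarts = 1, max_iterations = 10,
                                     seed = 2, epsilon = 1e-10))
  expect_true(all(fit$B[, 7] >= 1 - 10 * 1e-10))
})

test_that("supervised MLE equals exact count ratios on a labeled toy", {
  fit <- hmdm(list(c(5L, 5L, 7L)), states = list(c(0L, 0L, 1L)),
              n_states = 4, n_symbols = 10) |>
    suppressWarnings()  # states 2 and 3 unobserved
  expect_equal(unname(fit$A[1, 1:2]), c(0.5, 0.5))
  expect_equal(unname(fit$B[1, 5]), 1)
  expect_equal(unname(fit$B[2, 7]), 1)
  expect_equal(unname(fit$pi), c(1, 0, 0, 0))
  expect_equal(unname(fit$A[3, ]), rep(0.25, 4))  # unvisited row -> uniform
})

test_that("supervised MLE is invariant to sequence order and handles
           single-state data", {
  seqs <- list(c(1L, 2L), c(2L, 2L, 1L), c(1L, 1L, 1L, 2L))
  states <- list(c(0L, 1L), c(1L, 1L, 0L), c(0L, 0L, 1L, 1L))
  f1 <- suppressWarnings(hmdm(seqs, states, n_states = 2, n_symbols = 2))
  f2 <- suppressWarnings(hmdm(rev(seqs), rev(states), n_states = 2,
                              n_symbols = 2))
  expect_equal(coef(f1), coef(f2))
  # all labels in state 0: its transition row is the point mass at 0
  f3 <- suppressWarnings(hmdm(list(c(1L, 1L, 2L)), list(c(0L, 0L, 0L)),
                              n_states = 2, n_symbols = 2))
  expect_equal(unname(f3$A[1, ]), c(1, 0))
  expect_error(hmdm(list(), states = list()), "non-empty")
})

test_that("supervised MLE converges to the truth with sample size", {
  truth <- separated_truth()
  # one long chain: ~1e5 transitions
  seqs <- sample_hmm_sequences(truth, 1, n_sequences = 20, length = 5000,
                               seed = 31)
  fit <- hmdm(seqs)
  expect_identical(fit$method, "mle")
  expect_lt(mean(abs(fit$A - truth$A_by_zone[["1"]])), 0.02)
})

test_that("baum_welch_fit recovers parameters from a near-truth start", {
  truth <- separated_truth()
  tm <- list(pi = unname(truth$pi), A = unname(truth$A_by_zone[["1"]]),
             B = unname(truth$B_by_zone[["1"]]))
  seqs <- sample_hmm_sequences(truth, 1, 60, 40, seed = 11)
  set.seed(12)
  init <- list(pi = as.numeric(perturb_rows(matrix(tm$pi, 1))),
               A = perturb_rows(tm$A), B = perturb_rows(tm$B))
  fit <- hmdm(seqs, supervised = FALSE, init = init,
              control = hmdm_control(n_restarts = 1, max_iterations = 300,
                                     seed = 3))
  expect_lt(mean(abs(fit$A - tm$A)), 0.05)
  expect_true(all(diff(fit$trace) >= -1e-9))
})

test_that("fitting validates inputs and seeds determinately", {
  seqs <- lapply(1:3, function(i) sample.int(5, 8, replace = TRUE))
  expect_error(hmdm(seqs, n_symbols = 3, supervised = FALSE), "exceeds")
  ctrl <- hmdm_control(n_restarts = 2, max_iterations = 10, seed = 77)
  f1 <- hmdm(seqs, n_states = 2, n_symbols = 5, supervised = FALSE,
             control = ctrl)
  f2 <- hmdm(seqs, n_states = 2, n_symbols = 5, supervised = FALSE,
             control = ctrl)
  expect_identical(coef(f1), coef(f2))
  expect_error(hmdm_control(tolerance = 0), "positive")
  expect_error(hmdm_control(n_restarts = 0), "restarts")
})
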