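test_that("stability 2-norm matches closed forms", {
  # orthonormal one-hot rows: largest singular value is exactly 1
  B <- matrix(0, 4, 81)
  B[cbind(1:4, c(3, 20, 50, 81))] <- 1
  expect_equal(stability_2norm(B), 1.0, tolerance = 1e-12)
  # uniform rows: rank one, sigma = sqrt(N * M) / M = 2/9
  expect_equal(stability_2norm(matrix(1 / 81, 4, 81)), 2 / 9,
               tolerance = 1e-12)
  expect_error(stability_2norm(matrix(1, 4, 81)), "sum to 1")
})

test_that("stability 2-norm agrees with a power-iteration oracle and its
           bounds", {
  set.seed(17)
  for (i in 1:30) {
    N <- sample(2:6, 1)
    M <- sample(c(10, 27, 81), 1)
    B <- rdirichlet_mat(N, M, conc = runif(1, 0.2, 3))
    s <- stability_2norm(B)
    expect_equal(s, power_norm2(B), tolerance = 1e-8)
    expect_gte(s, 1 / sqrt(M) - 1e-12)
    expect_lte(s, sqrt(N) + 1e-12)
  }
  # frobenius variant
  B <- rdirichlet_mat(4, 81)
  expect_equal(stability_2norm(B, "frobenius"), sqrt(sum(B^2)))
})

# helper: a stochastic B whose per-dangerous-symbol maxima are prescribed
b_with_maxima <- function(maxima) {
  dang <- dangerous_symbols()
  B <- matrix(0, 4, 81)
  B[1, dang[1:3]] <- maxima[1:3]
  B[2, dang[4:6]] <- maxima[4:6]
  other <- setdiff(1:81, dang)
  B[1, other] <- (1 - sum(maxima[1:3])) / length(other)
  B[2, other] <- (1 - sum(maxima[4:6])) / length(other)
  B[3, other] <- 1 / length(other)
  B[4, other] <- 1 / length(other)
  B
}

test_that("risk index sums base-10 logs of the dangerous-symbol maxima", {
  expect_equal(risk_index(b_with_maxima(rep(0.1, 6))), -6.0,
               tolerance = 1e-12)
  mx <- c(0.5, 0.2, 0.1, 0.05, 0.3, 0.25)
  expect_equal(risk_index(b_with_maxima(mx)), sum(log10(mx)),
               tolerance = 1e-12)
  # degenerate case: every referenced maximum at 1 gives risk 0
  dang <- dangerous_symbols()
  B1 <- matrix(0, 4, 81)
  B1[cbind(1:4, dang[1:4])] <- 1  # one-hot rows on four dangerous symbols
  expect_equal(risk_index(B1, dangerous = dang[1:4]), 0, tolerance = 1e-12)
})

test_that("risk index is monotone in any referenced probability", {
  mx <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  base <- risk_index(b_with_maxima(mx))
  for (k in 1:6) {
    mx2 <- mx
    mx2[k] <- 0.2
    expect_gt(risk_index(b_with_maxima(mx2)), base)
  }
  expect_error(risk_index(b_with_maxima(mx), dangerous = integer(0)),
               "non-empty")
})

test_that("the all-states risk variant is systematically more negative", {
  set.seed(23)
  B <- rdirichlet_mat(4, 81)
  expect_lt(risk_index(B, variant = "all"), risk_index(B, variant = "max"))
})

test_that("mape measures mean relative error on thresholded entries", {
  truth <- separated_truth()
  m <- list(pi = unname(truth$pi), A = unname(truth$A_by_zone[["1"]]),
            B = unname(truth$B_by_zone[["1"]]))
  expect_equal(mape(m, m), 0)
  # uniform 10% inflation on the compared entries
  expect_equal(mape(c(0.55, 0.11), c(0.5, 0.1)), 10, tolerance = 1e-9)
  expect_equal(mape(c(0.45, 0.25), c(0.5, 0.2)), 17.5, tolerance = 1e-9)
  expect_gte(mape(list(pi = c(0.4, 0.6), A = matrix(0.5, 2, 2),
                       B = rdirichlet_mat(2, 4)),
                  list(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
                       B = rdirichlet_mat(2, 4))), 0)
  expect_error(mape(c(0.5), c(0.001)), "min_reference")
})

test_that("state alignment undoes a label permutation", {
  truth <- separated_truth()
  ref <- list(pi = unname(truth$pi), A = unname(truth$A_by_zone[["1"]]),
              B = unname(truth$B_by_zone[["1"]]))
  p <- c(3, 1, 4, 2)
  shuffled <- list(pi = ref$pi[p], A = ref$A[p, p], B = ref$B[p, ])
  aligned <- align_states(shuffled, ref)
  expect_equal(unname(aligned$B), ref$B, tolerance = 1e-12)
  expect_equal(unname(aligned$A), ref$A, tolerance = 1e-12)
  expect_equal(mape(aligned, ref), 0, tolerance = 1e-9)
})
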