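#' Stability of driver behavior: matrix 2-norm of the emission matrix
#'
#' The decisiveness of the decision process in a zone is summarized by the
#' 2-norm of its fitted emission matrix `B`: a larger value means more
#' concentrated (more decisive, hence more stable) state-conditional
#' observation distributions.  The default `"spectral"` norm is the largest
#' singular value — the standard meaning of a matrix 2-norm; for a
#' row-stochastic N x M matrix it lies in `[1/sqrt(M), sqrt(N)]` — with a
#' Frobenius variant available for comparison.
#'
#' @param B A row-stochastic emission matrix.
#' @param type `"spectral"` (largest singular value) or `"frobenius"`.
#' @return A single numeric norm value.
#' @export
#' @examples
#' stability_2norm(matrix(1 / 81, 4, 81))  # 2/9
stability_2norm <- function(B, type = c("spectral", "frobenius")) {
  type <- match.arg(type)
  B <- as.matrix(B)
  check_stochastic_matrix(B, nrow(B), ncol(B), "B")
  if (type == "spectral") norm(B, type = "2") else norm(B, type = "F")
}

#' Default dangerous observation symbols
#'
#' The six observation combinations flagged as dangerous driving contexts:
#' medium or high speed, a short headway, and a queue context with a
#' stopped vehicle ahead, under any signal phase — the tuples
#' (2,2,3,1), (2,2,3,2), (2,2,3,3), (3,2,3,1), (3,2,3,2), (3,2,3,3),
#' which encode to symbols 43, 44, 45, 70, 71, 72.
#'
#' @return Integer vector of six symbol indices.
#' @export
dangerous_symbols <- function() {
  tuples <- rbind(c(2, 2, 3, 1), c(2, 2, 3, 2), c(2, 2, 3, 3),
                  c(3, 2, 3, 1), c(3, 2, 3, 2), c(3, 2, 3, 3))
  encode_observation(tuples[, 1], tuples[, 2], tuples[, 3], tuples[, 4])
}

#' Risk index of driver behavior
#'
#' Summarizes how much emission probability a fitted model places on the
#' dangerous observation symbols: `alpha = sum over dangerous symbols k of
#' log10(x_k)`, where under the default `"max"` variant `x_k` is the
#' emission probability of the most likely state for symbol `k`
#' (`max_j B[j, k]`).  Larger (less negative) values indicate riskier
#' behavior.  The `"all"` variant sums `log10 B[j, k]` over every state and
#' dangerous symbol and is systematically more negative.  Probabilities are
#' floored at `floor_prob` before taking logs so unobserved symbols do not
#' produce `-Inf`.
#'
#' @param B A row-stochastic emission matrix.
#' @param dangerous Non-empty set of symbol indices in `1..ncol(B)`.
#' @param variant `"max"` (default) or `"all"`.
#' @param floor_prob Lower floor applied to probabilities before `log10`.
#' @return A single numeric risk index (<= 0 whenever all probabilities
#'   are <= 1).
#' @export
#' @examples
#' B <- matrix(1 / 81, 4, 81)
#' risk_index(B, dangerous_symbols())
risk_index <- function(B, dangerous = dangerous_symbols(),
                       variant = c("max", "all"), floor_prob = 1e-10) {
  variant <- match.arg(variant)
  B <- as.matrix(B)
  check_stochastic_matrix(B, nrow(B), ncol(B), "B")
  if (!length(dangerous)) stopf("dangerous symbol set must be non-empty")
  if (any(dangerous < 1) || any(dangerous > ncol(B)))
    stopf("dangerous symbols must be in 1..%d", ncol(B))
  cols <- B[, dangerous, drop = FALSE]
  if (variant == "max") {
    x <- apply(cols, 2, max)
  } else {
    x <- as.numeric(cols)
  }
  sum(log10(pmax(x, floor_prob)))
}

#' Align the state order of an unsupervised fit to a reference
#'
#' Hidden states of an unsupervised fit are identified only up to
#' permutation (label switching).  Before comparing a Baum-Welch fit
#' against a supervised reference, this relabels the fitted states by the
#' permutation minimizing the total absolute difference between the two
#' emission matrices.
#'
#' @param fit An [hmdm] object (or `pi`/`A`/`B` list) to relabel.
#' @param reference The reference parameter set defining the state order.
#' @return `fit` with `pi`, `A`, `B` permuted; the chosen permutation is
#'   attached as attribute `"permutation"`.
#' @export
align_states <- function(fit, reference) {
  fit <- as_hmdm_params(fit)
  ref <- as_hmdm_params(reference)
  N <- fit$n_states
  if (N != ref$n_states || fit$n_symbols != ref$n_symbols)
    stopf("parameter sets have different dimensions")
  perms <- permutations_of(N)
  cost <- vapply(perms, function(p)
    sum(abs(fit$B[p, , drop = FALSE] - ref$B)), numeric(1))
  p <- perms[[which.min(cost)]]
  fit$pi <- setNames(fit$pi[p], names(ref$pi))
  fit$A <- fit$A[p, p, drop = FALSE]
  fit$B <- fit$B[p, , drop = FALSE]
  dimnames(fit$A) <- dimnames(ref$A)
  rownames(fit$B) <- rownames(ref$B)
  attr(fit, "permutation") <- p
  fit
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(permutations_of(n - 1L), function(p)
      c(i, setdiff(seq_len(n), i)[p]))
  }))
}

#' Mean absolute percentage error between two parameter sets
#'
#' Validation statistic comparing an unsupervised (Baum-Welch) fit against
#' a supervised maximum-likelihood reference: the mean, over all entries of
#' `pi`, `A` and `B` whose reference value is at least `min_reference`, of
#' `|estimate - reference| / reference`, expressed in percent.  Masking
#' near-zero reference entries keeps the ratio well defined.
#'
#' @param estimated,reference [hmdm] objects (or `pi`/`A`/`B` lists) of the
#'   same dimensions; plain numeric vectors of equal length are also
#'   accepted and compared entrywise.
#' @param min_reference Reference-probability threshold below which entries
#'   are excluded from the mean.
#' @return MAPE in percent.
#' @export
#' @examples
#' mape(c(0.45, 0.25), c(0.5, 0.2))  # mean(10%, 25%) = 17.5
mape <- function(estimated, reference, min_reference = 0.01) {
  if (is.numeric(estimated) && is.numeric(reference)) {
    if (length(estimated) != length(reference))
      stopf("estimated and reference must have equal length")
    e <- estimated
    r <- reference
  } else {
    est <- as_hmdm_params(estimated)
    ref <- as_hmdm_params(reference)
    if (est$n_states != ref$n_states || est$n_symbols != ref$n_symbols)
      stopf("parameter sets have different dimensions")
    e <- c(est$pi, as.numeric(est$A), as.numeric(est$B))
    r <- c(ref$pi, as.numeric(ref$A), as.numeric(ref$B))
  }
  keep <- r >= min_reference
  if (!any(keep)) stopf("no reference entry reaches min_reference = %g",
                        min_reference)
  mean(abs(e[keep] - r[keep]) / r[keep]) * 100
}
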