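#' Control parameters for Baum-Welch fitting
#'
#' @param max_iterations Maximum EM iterations per restart.
#' @param tolerance Relative log-likelihood improvement below which a
#'   restart is declared converged.
#' @param n_restarts Number of random restarts; the restart with the
#'   highest final log-likelihood is kept.
#' @param epsilon Additive smoothing applied to every row of `A`, `B` and
#'   `pi` after each update (rows are renormalized), so a held-out sequence
#'   containing a symbol unseen in training never has exactly zero
#'   probability.
#' @param seed Integer seed controlling the random initializations; `NULL`
#'   uses the current RNG stream.
#' @return A list of class `hmdm_control`.
#' @export
hmdm_control <- function(max_iterations = 500L, tolerance = 1e-6,
                         n_restarts = 5L, epsilon = 1e-10, seed = NULL) {
  if (tolerance <= 0) stopf("tolerance must be positive")
  if (n_restarts < 1) stopf("n_restarts must be >= 1")
  if (max_iterations < 1) stopf("max_iterations must be >= 1")
  if (epsilon < 0) stopf("epsilon must be non-negative")
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, n_restarts = as.integer(n_restarts),
                 epsilon = epsilon, seed = seed), class = "hmdm_control")
}

# ---- sequence coercion ----------------------------------------------------

# Accepts: a list of integer symbol vectors, a single integer vector, or a
# data frame with vehicle_id/symbol (and optionally state) columns.
# Returns list(symbols = list of int vectors, states = list of 0-based int
# vectors or NULL).
as_hmdm_sequences <- function(x, states = NULL) {
  if (is.data.frame(x)) {
    need <- c("vehicle_id", "symbol")
    if (!all(need %in% names(x)))
      stopf("sequence data frame needs vehicle_id and symbol columns")
    if ("t" %in% names(x)) x <- x[order(x$vehicle_id, x$t), , drop = FALSE]
    symbols <- lapply(split(x$symbol, x$vehicle_id), as.integer)
    st <- if ("state" %in% names(x) && !all(is.na(x$state)))
      lapply(split(x$state, x$vehicle_id), as.integer) else NULL
    return(list(symbols = unname(symbols),
                states = if (is.null(st)) NULL else unname(st)))
  }
  if (is.numeric(x)) x <- list(x)
  if (!is.list(x) || !length(x)) stopf("sequences must be a non-empty list")
  symbols <- lapply(x, function(s) {
    s <- as.integer(s)
    if (!length(s)) stopf("empty observation sequence")
    if (any(is.na(s)) || any(s < 1)) stopf("symbols must be positive integers")
    s
  })
  if (!is.null(states)) {
    if (is.numeric(states)) states <- list(states)
    if (length(states) != length(symbols))
      stopf("states must align with sequences")
    states <- Map(function(s, q) {
      q <- as.integer(q)
      if (length(q) != length(s)) stopf("state labels must align with symbols")
      q
    }, symbols, states)
  }
  list(symbols = symbols, states = states)
}

new_hmdm <- function(pi, A, B, method, state_names, ...) {
  N <- length(pi); M <- ncol(B)
  names(pi) <- state_names
  dimnames(A) <- list(from = state_names, to = state_names)
  rownames(B) <- state_names
  structure(c(list(pi = pi, A = A, B = B, n_states = N, n_symbols = M,
                   state_names = state_names, method = method),
              list(...)),
            class = "hmdm")
}

check_hmdm_params <- function(object) {
  check_prob_vector(object$pi, object$n_states, "pi")
  check_stochastic_matrix(object$A, object$n_states, object$n_states, "A")
  check_stochastic_matrix(object$B, object$n_states, object$n_symbols, "B")
  invisible(object)
}

as_hmdm_params <- function(params, n_states = NULL, n_symbols = NULL,
                           state_names = NULL) {
  if (inherits(params, "hmdm")) return(check_hmdm_params(params))
  if (!is.list(params) || !all(c("pi", "A", "B") %in% names(params)))
    stopf("params must be an hmdm object or a list with pi, A, B")
  A <- as.matrix(params$A); B <- as.matrix(params$B)
  N <- length(params$pi); M <- ncol(B)
  if (is.null(state_names))
    state_names <- if (N == 4) HMDM_STATES else paste0("S", seq_len(N))
  obj <- new_hmdm(as.numeric(params$pi), A, B, method = "given",
                  state_names = state_names)
  check_hmdm_params(obj)
}

# ---- forward / backward / posteriors --------------------------------------

#' Forward algorithm with per-step scaling
#'
#' Computes the scaled forward variables and the log-likelihood
#' `log P(O | lambda)` of an observation sequence under a fitted or
#' hand-specified model.  The forward variables are renormalized at every
#' step; the per-step normalizers are returned as `scale` and the
#' log-likelihood is their summed logarithm.  A sequence containing a
#' symbol that no state can emit has probability zero: the log-likelihood
#' is reported as `-Inf` rather than raising an error.
#'
#' @param params An [hmdm] object or a list with elements `pi`, `A`, `B`.
#' @param sequence Integer vector of observation symbols in `1..n_symbols`.
#' @return A list with `alpha` (T x N scaled forward matrix, rows sum to 1),
#'   `scale` (length-T normalizers), `loglik`, and `T`.
#' @export
forward <- function(params, sequence) {
  params <- as_hmdm_params(params)
  sequence <- as_hmdm_sequences(sequence)$symbols[[1]]
  if (max(sequence) > params$n_symbols)
    stopf("symbol %d exceeds the model alphabet (%d)", max(sequence),
          params$n_symbols)
  res <- .forward_cpp(unname(params$pi), unname(params$A), unname(params$B),
                      sequence)
  list(alpha = res$alpha, scale = res$scale, loglik = res$loglik,
       T = length(sequence))
}

#' Backward algorithm under the forward scaling
#'
#' Scaled backward variables, using the same per-step normalizers as
#' [forward()] so that `rowSums(alpha * beta) = 1` at every step.
#'
#' @inheritParams forward
#' @return A list with `beta` (T x N matrix), `scale` and `loglik` from the
#'   forward pass.
#' @export
backward <- function(params, sequence) {
  params <- as_hmdm_params(params)
  fw <- forward(params, sequence)
  sequence <- as_hmdm_sequences(sequence)$symbols[[1]]
  beta <- .backward_cpp(unname(params$A), unname(params$B), sequence,
                        fw$scale)
  list(beta = beta, scale = fw$scale, loglik = fw$loglik)
}

#' State-occupancy and transition posteriors
#'
#' Computes `gamma` (the posterior probability of each state at each step)
#' and `xi` (the posterior probability of each state pair at consecutive
#' steps), the expected-count building blocks of the Baum-Welch update.
#'
#' @inheritParams forward
#' @return A list with `gamma` (T x N, rows sum to 1), `xi`
#'   ((T-1) x N x N array), and `loglik`.
#' @export
posteriors <- function(params, sequence) {
  params <- as_hmdm_params(params)
  seqv <- as_hmdm_sequences(sequence)$symbols[[1]]
  fw <- forward(params, seqv)
  if (!is.finite(fw$loglik))
    stopf("sequence has zero probability under the model")
  beta <- .backward_cpp(unname(params$A), unname(params$B), seqv, fw$scale)
  Tn <- length(seqv); N <- params$n_states
  gamma <- fw$alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- array(0, dim = c(max(Tn - 1, 0), N, N))
  if (Tn >= 2) {
    A <- unname(params$A); B <- unname(params$B)
    for (t in seq_len(Tn - 1)) {
      m <- (fw$alpha[t, ] %o% (B[, seqv[t + 1]] * beta[t + 1, ])) * A /
        fw$scale[t + 1]
      xi[t, , ] <- m / sum(m)
    }
  }
  list(gamma = gamma, xi = xi, loglik = fw$loglik)
}

# ---- Baum-Welch -----------------------------------------------------------

#' One Baum-Welch update over a set of sequences
#'
#' Performs a single EM iteration: expected transition and emission counts
#' are accumulated over all sequences (numerators and denominators pooled
#' before dividing), the initial distribution is the mean of the first-step
#' state posteriors, and every row is epsilon-smoothed and renormalized.
#' A state never visited in the expected counts would leave a zero
#' denominator; its row is reset to uniform with a warning.
#'
#' @param params An [hmdm] object or `pi`/`A`/`B` list.
#' @param sequences List of integer symbol vectors (each of length >= 2), or
#'   a sequence data frame (see [hmdm()]).
#' @param epsilon Additive smoothing constant.
#' @return A list with the updated `params` (an `hmdm` object) and `loglik`,
#'   the total log-likelihood of the data under the *input* parameters.
#' @export
baum_welch_step <- function(params, sequences, epsilon = 1e-10) {
  params <- as_hmdm_params(params)
  seqs <- as_hmdm_sequences(sequences)$symbols
  if (any(lengths(seqs) < 2)) stopf("each sequence needs length >= 2")
  if (max(unlist(seqs)) > params$n_symbols)
    stopf("observed symbol exceeds the model alphabet")
  N <- params$n_states; M <- params$n_symbols
  A_num <- matrix(0, N, N); B_num <- matrix(0, N, M)
  A_den <- numeric(N); B_den <- numeric(N); g1 <- numeric(N)
  ll <- 0
  for (s in seqs) {
    acc <- .bw_accumulate_cpp(unname(params$pi), unname(params$A),
                              unname(params$B), s)
    if (!acc$ok)
      stopf("a training sequence has zero probability under the current parameters")
    ll <- ll + acc$loglik
    A_num <- A_num + acc$A_num; A_den <- A_den + acc$A_den
    B_num <- B_num + acc$B_num; B_den <- B_den + acc$B_den
    g1 <- g1 + acc$gamma1
  }
  dead <- A_den <= 0 | B_den <= 0
  if (any(dead)) {
    warning(sprintf("state(s) %s never visited; row(s) reset to uniform",
                    paste(which(dead) - 1L, collapse = ", ")), call. = FALSE)
    A_num[dead, ] <- 1; A_den[dead] <- N
    B_num[dead, ] <- 1; B_den[dead] <- M
  }
  A <- normalize_rows((A_num / A_den) + epsilon)
  B <- normalize_rows((B_num / B_den) + epsilon)
  pi <- g1 / sum(g1)
  pi <- (pi + epsilon) / sum(pi + epsilon)
  upd <- new_hmdm(pi, A, B, method = "baum-welch",
                  state_names = params$state_names)
  list(params = upd, loglik = ll)
}

random_params <- function(n_states, n_symbols) {
  draw <- function(n, m) normalize_rows(matrix(rgamma(n * m, 1), n, m))
  list(pi = as.numeric(draw(1, n_states)),
       A = draw(n_states, n_states),
       B = draw(n_states, n_symbols))
}

bw_one_restart <- function(init, seqs, n_states, n_symbols, control,
                           state_names) {
  params <- as_hmdm_params(init, state_names = state_names)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(control$max_iterations)) {
    step <- baum_welch_step(params, seqs, epsilon = control$epsilon)
    params <- step$params
    trace <- c(trace, step$loglik)
    if (is.finite(ll_prev)) {
      rel <- (step$loglik - ll_prev) / abs(ll_prev)
      if (rel < control$tolerance) { converged <- TRUE; break }
    }
    ll_prev <- step$loglik
  }
  final_ll <- total_loglik(params, seqs)
  list(params = params, trace = trace, loglik = final_ll,
       converged = converged, iterations = length(trace))
}

total_loglik <- function(params, seqs) {
  sum(vapply(seqs, function(s) forward(params, s)$loglik, numeric(1)))
}

#' Fit a hidden Markov driving model
#'
#' The main fitting function.  Given per-vehicle observation sequences over
#' the 81-symbol discretized alphabet, estimates the initial distribution
#' `pi`, the state transition matrix `A` and the emission matrix `B` of a
#' discrete HMM over the four driver decision states (accelerate,
#' decelerate, maintain, stop).
#'
#' Without state labels the model is trained by multi-sequence Baum-Welch
#' (EM): each restart starts from seeded random row-stochastic parameters
#' (or from `init`, for the first restart) and iterates until the relative
#' log-likelihood improvement falls below the tolerance; the restart with
#' the highest final log-likelihood is returned.  With `states` supplied
#' (integer codes 0..3 aligned with the symbols), the closed-form supervised
#' maximum-likelihood estimates are used instead: `A` and `B` are
#' row-normalized transition/emission counts and `pi` the normalized
#' initial-state frequencies; rows for states never observed are set to
#' uniform with a warning.
#'
#' @param sequences List of integer symbol vectors, or a data frame with
#'   columns `vehicle_id`, `symbol` and optionally `t` and `state` (a
#'   `state` column is used as supervision unless `supervised = FALSE`).
#' @param states Optional list of integer state-label vectors (codes 0..3)
#'   aligned with `sequences`.
#' @param n_states,n_symbols Model dimensions; defaults 4 states over the
#'   81-symbol alphabet.
#' @param init Optional starting parameters (an `hmdm` object or a
#'   `pi`/`A`/`B` list) used for the first Baum-Welch restart.
#' @param control A [hmdm_control()] object.
#' @param supervised Set `FALSE` to ignore a `state` column in a data frame
#'   and run Baum-Welch.
#' @param state_names State labels; defaults to the canonical four.
#' @return An object of class `hmdm` with elements `pi`, `A`, `B`,
#'   `n_states`, `n_symbols`, `method` (`"baum-welch"` or `"mle"`),
#'   `logLik`, `trace` (per-iteration training log-likelihood of the kept
#'   restart), `restart_logliks`, `converged`, `iterations`,
#'   `n_sequences`, `n_obs` and `call`.  Supports [coef()], [logLik()],
#'   [predict()], [simulate()], [summary()] and [plot()].
#' @seealso [viterbi()], [stability_2norm()], [risk_index()],
#'   [warning_report()]
#' @export
#' @examples
#' truth <- default_ground_truth()
#' seqs <- sample_hmm_sequences(truth, zone = 2, n_sequences = 20,
#'                              length = 30, seed = 1)
#' fit <- hmdm(seqs, supervised = FALSE,
#'             control = hmdm_control(n_restarts = 1, max_iterations = 20,
#'                                    seed = 1))
#' fit
hmdm <- function(sequences, states = NULL, n_states = 4L, n_symbols = 81L,
                 init = NULL, control = hmdm_control(), supervised = NA,
                 state_names = NULL) {
  cl <- match.call()
  parsed <- as_hmdm_sequences(sequences, states)
  seqs <- parsed$symbols
  if (is.null(states)) states <- parsed$states
  use_supervised <- if (is.na(supervised)) !is.null(states) else supervised
  if (use_supervised && is.null(states))
    stopf("supervised fitting requires state labels")
  if (max(unlist(seqs)) > n_symbols)
    stopf("observed symbol %d exceeds n_symbols = %d", max(unlist(seqs)),
          n_symbols)
  if (is.null(state_names))
    state_names <- if (n_states == 4) HMDM_STATES else
      paste0("S", seq_len(n_states))

  if (use_supervised) {
    fit <- supervised_mle_impl(seqs, states, n_states, n_symbols, state_names)
  } else {
    keep <- lengths(seqs) >= 2
    if (!all(keep)) {
      warning(sprintf("dropping %d sequence(s) of length < 2 for Baum-Welch",
                      sum(!keep)), call. = FALSE)
      seqs <- seqs[keep]
    }
    if (!length(seqs)) stopf("no sequences of length >= 2 to train on")
    restarts <- with_local_seed(control$seed, {
      lapply(seq_len(control$n_restarts), function(r) {
        start <- if (r == 1 && !is.null(init)) init else
          random_params(n_states, n_symbols)
        bw_one_restart(start, seqs, n_states, n_symbols, control, state_names)
      })
    })
    lls <- vapply(restarts, `[[`, numeric(1), "loglik")
    best <- restarts[[which.max(lls)]]
    fit <- best$params
    fit$trace <- best$trace
    fit$restart_logliks <- lls
    fit$converged <- best$converged
    fit$iterations <- best$iterations
    fit$logLik <- best$loglik
  }
  fit$n_sequences <- length(seqs)
  fit$n_obs <- sum(lengths(seqs))
  if (is.null(fit$logLik)) fit$logLik <- total_loglik(fit, seqs)
  fit$control <- control
  fit$call <- cl
  fit
}

supervised_mle_impl <- function(seqs, states, n_states, n_symbols,
                                state_names) {
  if (is.null(states)) stopf("state labels required for supervised MLE")
  allq <- unlist(states)
  if (any(allq < 0) || any(allq >= n_states))
    stopf("state labels must be integer codes in 0..%d", n_states - 1)
  N <- n_states; M <- n_symbols
  q_all <- unlist(lapply(states, function(q) q + 1L))
  o_all <- unlist(seqs)
  from <- unlist(lapply(states, function(q) q[-length(q)] + 1L))
  to <- unlist(lapply(states, function(q) q[-1] + 1L))
  first <- vapply(states, function(q) q[1] + 1L, integer(1))
  A_counts <- unclass(table(factor(from, levels = seq_len(N)),
                            factor(to, levels = seq_len(N))))
  B_counts <- unclass(table(factor(q_all, levels = seq_len(N)),
                            factor(o_all, levels = seq_len(M))))
  init_counts <- tabulate(first, nbins = N)
  storage.mode(A_counts) <- "double"
  storage.mode(B_counts) <- "double"
  dimnames(A_counts) <- dimnames(B_counts) <- NULL
  A_unv <- rowSums(A_counts) == 0
  B_unv <- rowSums(B_counts) == 0
  if (any(A_unv | B_unv))
    warning(sprintf("state(s) %s unobserved; rows set to uniform",
                    paste(which(A_unv | B_unv) - 1L, collapse = ", ")),
            call. = FALSE)
  A_counts[A_unv, ] <- 1
  B_counts[B_unv, ] <- 1
  pi <- if (sum(init_counts) > 0) init_counts / sum(init_counts) else
    rep(1 / N, N)
  fit <- new_hmdm(pi, normalize_rows(A_counts), normalize_rows(B_counts),
                  method = "mle", state_names = state_names,
                  counts = list(A = A_counts, B = B_counts,
                                initial = init_counts))
  fit
}

# ---- Viterbi --------------------------------------------------------------

#' Viterbi decoding of the most likely state path
#'
#' Log-space dynamic program returning the single most probable hidden
#' state sequence for an observation sequence.  Ties are broken toward the
#' lowest state index.
#'
#' @inheritParams forward
#' @return A list with `path` (integer state codes 0..3, length T),
#'   `states` (the corresponding labels), `log_prob` (log probability of
#'   the best path), `delta` (T x N log trellis) and `psi` (T x N
#'   backpointers).
#' @export
viterbi <- function(params, sequence) {
  params <- as_hmdm_params(params)
  o <- as_hmdm_sequences(sequence)$symbols[[1]]
  if (max(o) > params$n_symbols) stopf("symbol exceeds the model alphabet")
  N <- params$n_states; Tn <- length(o)
  logpi <- log(unname(params$pi)); logA <- log(unname(params$A))
  logB <- log(unname(params$B))
  delta <- matrix(-Inf, Tn, N)
  psi <- matrix(0L, Tn, N)
  delta[1, ] <- logpi + logB[, o[1]]
  if (Tn >= 2) for (t in 2:Tn) {
    for (j in seq_len(N)) {
      cand <- delta[t - 1, ] + logA[, j]
      psi[t, j] <- which.max(cand)  # first max = lowest state index
      delta[t, j] <- cand[psi[t, j]] + logB[j, o[t]]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn >= 2) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  list(path = path - 1L,
       states = params$state_names[path],
       log_prob = max(delta[Tn, ]),
       delta = delta, psi = psi)
}
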