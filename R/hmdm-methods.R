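#' @export
print.hmdm <- function(x, digits = 3, ...) {
  cat("Hidden Markov driving model (", x$method, ")\n", sep = "")
  cat(sprintf("  %d states over %d observation symbols\n",
              x$n_states, x$n_symbols))
  if (!is.null(x$n_sequences))
    cat(sprintf("  trained on %d sequence(s), %d observations\n",
                x$n_sequences, x$n_obs))
  if (!is.null(x$logLik))
    cat(sprintf("  log-likelihood: %.4f\n", x$logLik))
  if (identical(x$method, "baum-welch"))
    cat(sprintf("  EM: %d iteration(s), %sconverged, %d restart(s)\n",
                x$iterations, if (isTRUE(x$converged)) "" else "not ",
                length(x$restart_logliks)))
  cat("\nInitial distribution:\n")
  print(round(x$pi, digits))
  cat("\nTransition matrix A:\n")
  print(round(x$A, digits))
  invisible(x)
}

#' @export
coef.hmdm <- function(object, ...) {
  list(pi = object$pi, A = object$A, B = object$B)
}

#' @export
logLik.hmdm <- function(object, ...) {
  N <- object$n_states; M <- object$n_symbols
  ll <- if (is.null(object$logLik)) NA_real_ else object$logLik
  structure(ll, df = (N - 1) + N * (N - 1) + N * (M - 1),
            nobs = object$n_obs, class = "logLik")
}

#' Summary of a fitted driving model
#'
#' Augments the parameter estimates with the two behavioral summaries used
#' for dilemma-zone analysis: the stability of the decision process
#' (spectral 2-norm of the emission matrix `B`; larger = more decisive) and
#' the risk index over the six dangerous observation symbols (base-10 log
#' scale; larger, i.e. less negative, = riskier).
#'
#' @param object A fitted [hmdm] object.
#' @param dangerous Symbol set used for the risk index.
#' @param ... Unused.
#' @export
summary.hmdm <- function(object, dangerous = dangerous_symbols(), ...) {
  out <- list(fit = object,
              stability = stability_2norm(object$B),
              risk = risk_index(object$B, dangerous),
              dangerous = dangerous)
  class(out) <- "summary.hmdm"
  out
}

#' @export
print.summary.hmdm <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("\nStability (2-norm of B): %.4f\n", x$stability))
  cat(sprintf("Risk index over symbols {%s}: %.4f\n",
              paste(x$dangerous, collapse = ", "), x$risk))
  invisible(x)
}

#' Predict hidden states or next actions from a fitted model
#'
#' `type = "states"` runs Viterbi decoding on each new observation sequence
#' and returns the most probable hidden state path.  `type = "next"`
#' treats `newdata` as current state codes (0..3) and returns the most
#' probable next state under the transition matrix.
#'
#' @param object A fitted [hmdm] object.
#' @param newdata For `"states"`: a list of symbol vectors or a sequence
#'   data frame; for `"next"`: integer current-state codes 0..3.
#' @param type `"states"` or `"next"`.
#' @param ... Unused.
#' @return For `"states"`: a list of integer state-code vectors (0..3), one
#'   per sequence, with the Viterbi log path probability as attribute
#'   `"log_prob"`.  For `"next"`: a data frame with the predicted state
#'   code, label and transition probability.
#' @export
predict.hmdm <- function(object, newdata, type = c("states", "next"), ...) {
  type <- match.arg(type)
  if (type == "next") {
    pred <- predict_next_state(object$A, newdata)
    return(pred)
  }
  seqs <- as_hmdm_sequences(newdata)$symbols
  lapply(seqs, function(s) {
    v <- viterbi(object, s)
    structure(v$path, log_prob = v$log_prob)
  })
}

#' Simulate observation sequences from a fitted model
#'
#' Draws `nsim` sequences of the given length from the generative process:
#' the initial state from `pi`, subsequent states from the rows of `A`, and
#' one symbol per step from the rows of `B`.
#'
#' @param object A fitted [hmdm] object.
#' @param nsim Number of sequences.
#' @param seed Integer seed (the caller's RNG state is restored).
#' @param length Sequence length.
#' @param ... Unused.
#' @return A data frame with columns `vehicle_id`, `t`, `symbol`, `state`
#'   (true state codes 0..3).
#' @export
simulate.hmdm <- function(object, nsim = 1, seed = NULL, length = 44, ...) {
  if (nsim < 1 || length < 1) stopf("nsim and length must be >= 1")
  N <- object$n_states; M <- object$n_symbols
  with_local_seed(seed, {
    res <- lapply(seq_len(nsim), function(v) {
      q <- integer(length); o <- integer(length)
      q[1] <- sample.int(N, 1, prob = object$pi)
      o[1] <- sample.int(M, 1, prob = object$B[q[1], ])
      if (length >= 2) for (t in 2:length) {
        q[t] <- sample.int(N, 1, prob = object$A[q[t - 1], ])
        o[t] <- sample.int(M, 1, prob = object$B[q[t], ])
      }
      data.frame(vehicle_id = v, t = seq_len(length), symbol = o,
                 state = q - 1L)
    })
    do.call(rbind, res)
  })
}

#' Plot a fitted driving model
#'
#' `type = "trace"` draws the Baum-Welch log-likelihood trace;
#' `type = "emissions"` draws the emission matrix `B` as an image with the
#' dangerous symbols marked.
#'
#' @param x A fitted [hmdm] object.
#' @param type `"trace"` or `"emissions"`.
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.hmdm <- function(x, type = c("trace", "emissions"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    if (is.null(x$trace) || !length(x$trace))
      stopf("no EM trace available (supervised fit?)")
    plot(seq_along(x$trace), x$trace, type = "b", pch = 16,
         xlab = "EM iteration", ylab = "log-likelihood", ...)
  } else {
    image(x = seq_len(x$n_symbols), y = seq_len(x$n_states), z = t(x$B),
          xlab = "observation symbol", ylab = "", yaxt = "n",
          main = "Emission matrix B", ...)
    axis(2, at = seq_len(x$n_states), labels = x$state_names, las = 1)
    abline(v = dangerous_symbols(), lty = 3)
  }
  invisible(x)
}
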