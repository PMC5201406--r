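#' Is an observation symbol dangerous?
#'
#' @param symbol Integer symbol(s) in 1..81.
#' @param dangerous Dangerous symbol set.
#' @return Logical vector.
#' @export
#' @examples
#' is_dangerous(c(1, 43, 72))
is_dangerous <- function(symbol, dangerous = dangerous_symbols()) {
  if (any(symbol < 1) || any(symbol > 81))
    stopf("symbol index must be in 1..81")
  symbol %in% dangerous
}

#' Most likely hidden state for an observed symbol
#'
#' Given the emission matrix, the driver's current decision state for a
#' single observed symbol is inferred as the state with the largest
#' emission probability for that symbol (ties broken toward the lowest
#' state index).  All states compete; in practice the stop state carries
#' negligible emission mass at the high-speed symbols where this inference
#' matters.
#'
#' @param B Emission matrix (rows = states, in canonical order).
#' @param symbol A single symbol index.
#' @return A list with `state` (code 0..3), `label` and `probability`.
#' @export
most_likely_state <- function(B, symbol) {
  B <- as.matrix(B)
  if (length(symbol) != 1 || symbol < 1 || symbol > ncol(B))
    stopf("symbol must be a single index in 1..%d", ncol(B))
  col <- B[, symbol]
  j <- which.max(col)  # first max = lowest state index
  label <- if (!is.null(rownames(B))) rownames(B)[j] else HMDM_STATES[j]
  list(state = j - 1L, label = label, probability = unname(col[j]))
}

#' Most likely next state from the transition matrix
#'
#' The predicted next decision is the argmax of the current state's row of
#' the transition matrix (ties toward the lowest state index).
#'
#' @param A Transition matrix (rows/cols = states, canonical order).
#' @param current_state Integer current-state code(s) 0..3.
#' @return A data frame with one row per input: `current_state`,
#'   `next_state` (code), `next_label`, `probability`.
#' @export
#' @examples
#' A <- matrix(0.25, 4, 4)
#' predict_next_state(A, 1)
predict_next_state <- function(A, current_state) {
  A <- as.matrix(A)
  N <- nrow(A)
  if (any(current_state < 0) || any(current_state >= N))
    stopf("current_state codes must be in 0..%d", N - 1)
  labels <- if (!is.null(rownames(A))) rownames(A) else HMDM_STATES[seq_len(N)]
  rows <- as.integer(current_state) + 1L
  nxt <- vapply(rows, function(i) which.max(A[i, ]), integer(1))
  data.frame(current_state = as.integer(current_state),
             next_state = nxt - 1L,
             next_label = labels[nxt],
             probability = A[cbind(rows, nxt)])
}

#' Dangerous-action warning report
#'
#' Implements the danger-prediction procedure: every occurrence of a
#' dangerous observation symbol in the input sequences is flagged; the
#' driver's current state is inferred from the emission matrix
#' ([most_likely_state()]), the next state is predicted from the transition
#' matrix ([predict_next_state()]), and a warning is marked severe when the
#' predicted next action is not a slow-down (neither decelerate nor stop)
#' while the context is dangerous.
#'
#' @param params A fitted [hmdm] object (or `pi`/`A`/`B` list).
#' @param sequences List of symbol vectors or a sequence data frame with
#'   `vehicle_id`, `t`, `symbol`.
#' @param dangerous Dangerous symbol set.
#' @return A data frame with one row per dangerous-symbol occurrence:
#'   `vehicle_id`, `t`, `symbol`, the decoded tuple columns
#'   (`speed_bin`, `headway_bin`, `queue_bin`, `signal_bin`),
#'   `current_state`, `current_label`, `emission_prob`, `next_state`,
#'   `next_label`, `transition_prob`, `severe`.
#' @export
warning_report <- function(params, sequences,
                           dangerous = dangerous_symbols()) {
  params <- as_hmdm_params(params)
  if (is.data.frame(sequences)) {
    df <- sequences
    if (!all(c("vehicle_id", "symbol") %in% names(df)))
      stopf("sequence data frame needs vehicle_id and symbol columns")
    if (!"t" %in% names(df))
      df$t <- stats::ave(seq_len(nrow(df)), df$vehicle_id, FUN = seq_along)
  } else {
    seqs <- as_hmdm_sequences(sequences)$symbols
    df <- do.call(rbind, lapply(seq_along(seqs), function(i)
      data.frame(vehicle_id = i, t = seq_along(seqs[[i]]),
                 symbol = seqs[[i]])))
  }
  hit <- df[is_dangerous(df$symbol, dangerous), , drop = FALSE]
  slowdown <- which(params$state_names %in% c("decelerate", "stop")) - 1L
  rows <- lapply(seq_len(nrow(hit)), function(i) {
    sym <- hit$symbol[i]
    cur <- most_likely_state(params$B, sym)
    nxt <- predict_next_state(params$A, cur$state)
    tup <- decode_observation(sym)
    data.frame(vehicle_id = hit$vehicle_id[i], t = hit$t[i], symbol = sym,
               speed_bin = tup[1, "speed"], headway_bin = tup[1, "headway"],
               queue_bin = tup[1, "queue"], signal_bin = tup[1, "signal"],
               current_state = cur$state, current_label = cur$label,
               emission_prob = cur$probability,
               next_state = nxt$next_state, next_label = nxt$next_label,
               transition_prob = nxt$probability,
               severe = !(nxt$next_state %in% slowdown))
  })
  if (!length(rows)) {
    return(data.frame(vehicle_id = integer(), t = integer(),
                      symbol = integer(), speed_bin = integer(),
                      headway_bin = integer(), queue_bin = integer(),
                      signal_bin = integer(), current_state = integer(),
                      current_label = character(),
                      emission_prob = numeric(), next_state = integer(),
                      next_label = character(), transition_prob = numeric(),
                      severe = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
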