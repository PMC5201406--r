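#' Discretization rules for the observation alphabet
#'
#' The observation alphabet codes each detection-line record as a tuple of
#' four three-level factors: speed, headway, queue context and signal phase.
#' The default breakpoints are the ones used throughout the package: speed
#' bins split at 8 and 16 m/s (8 m/s falls in bin 1, 16 m/s in bin 3), a
#' headway of 6 s or more is "long", and the categorical queue/signal codes
#' are fixed bijections onto 1..3.
#'
#' @param speed_breaks Two increasing positive speeds (m/s) splitting the
#'   three speed bins.
#' @param headway_break Headway (s) at and above which the gap is "long".
#' @param signal_codes Named integer vector mapping phase names to codes.
#' @param queue_codes Named integer vector mapping queue categories to codes.
#'   `head_car`: first vehicle, no leader; `no_stopped`: a leader exists but
#'   is not stopped; `other`: remaining situations (typically a stopped
#'   leader / standing queue ahead).
#' @return An object of class `discretization_rules`.
#' @export
#' @examples
#' r <- discretization_rules()
#' bin_speed(12, r)
discretization_rules <- function(speed_breaks = c(8, 16),
                                 headway_break = 6,
                                 signal_codes = c(green = 1L, red = 2L,
                                                  yellow = 3L),
                                 queue_codes = c(head_car = 1L,
                                                 no_stopped = 2L,
                                                 other = 3L)) {
  if (length(speed_breaks) != 2 || any(speed_breaks <= 0) ||
      diff(speed_breaks) <= 0)
    stopf("speed_breaks must be two increasing positive values")
  if (headway_break <= 0) stopf("headway_break must be positive")
  for (codes in list(signal_codes, queue_codes))
    if (length(codes) != 3 || !setequal(codes, 1:3))
      stopf("signal/queue codes must be bijections onto 1..3")
  structure(list(speed_breaks = speed_breaks,
                 headway_break = headway_break,
                 signal_codes = signal_codes,
                 queue_codes = queue_codes),
            class = "discretization_rules")
}

#' Discretize speed, headway, queue and signal observations
#'
#' `bin_speed()` maps a speed in m/s to bins 1 (slow, `<= 8`), 2 (medium) or
#' 3 (fast, `>= 16`); `bin_headway()` maps a time gap to 1 (head car, no
#' predecessor), 2 (short gap) or 3 (`>= 6` s); `bin_queue()` and
#' `bin_signal()` look up the categorical codes.  All are vectorized.
#'
#' @param v Speed(s), m/s, non-negative.
#' @param gap Headway(s) in seconds (positive), or `NA` for a head car.
#'   `head_car = TRUE` forces the head-car bin regardless of `gap`.
#' @param head_car Logical, recycled: is this vehicle the first in its lane
#'   (no predecessor at this line)?
#' @param queue Character vector of queue categories (names of
#'   `rules$queue_codes`).
#' @param phase Character vector of signal phases (names of
#'   `rules$signal_codes`).
#' @param rules A [discretization_rules()] object.
#' @return Integer bin(s) in 1..3.
#' @export
bin_speed <- function(v, rules = discretization_rules()) {
  if (any(is.na(v)) || any(v < 0)) stopf("speeds must be non-negative")
  ifelse(v <= rules$speed_breaks[1], 1L,
         ifelse(v < rules$speed_breaks[2], 2L, 3L))
}

#' @rdname bin_speed
#' @export
bin_headway <- function(gap, head_car = is.na(gap),
                        rules = discretization_rules()) {
  head_car <- rep_len(head_car, length(gap))
  if (any(!head_car & (is.na(gap) | gap <= 0)))
    stopf("numeric headways must be positive")
  ifelse(head_car, 1L, ifelse(gap < rules$headway_break, 2L, 3L))
}

#' @rdname bin_speed
#' @export
bin_queue <- function(queue, rules = discretization_rules()) {
  code <- rules$queue_codes[as.character(queue)]
  if (any(is.na(code))) stopf("unknown queue category: %s",
                              paste(unique(queue[is.na(code)]), collapse = ", "))
  as.integer(unname(code))
}

#' @rdname bin_speed
#' @export
bin_signal <- function(phase, rules = discretization_rules()) {
  code <- rules$signal_codes[as.character(phase)]
  if (any(is.na(code))) stopf("unknown signal phase: %s",
                              paste(unique(phase[is.na(code)]), collapse = ", "))
  as.integer(unname(code))
}

#' Encode and decode observation symbols
#'
#' The 81-symbol observation alphabet enumerates the discretized
#' (speed, headway, queue, signal) tuples with the signal varying fastest,
#' then queue, then headway, then speed, starting at 1 for (1,1,1,1):
#' `index = 27 (speed - 1) + 9 (headway - 1) + 3 (queue - 1) + signal`.
#' Under this enumeration the six dangerous combinations (2,2,3,*) and
#' (3,2,3,*) receive indices 43, 44, 45 and 70, 71, 72.
#'
#' @param speed,headway,queue,signal Integer bins in 1..3 (vectorized).
#'   `encode_observation(c(2, 2, 3, 1))` is also accepted for a single tuple.
#' @param index Integer symbol(s) in 1..81.
#' @return `encode_observation()`: integer index in 1..81.
#'   `decode_observation()`: a matrix with columns speed, headway, queue,
#'   signal (one row per index).
#' @export
#' @examples
#' encode_observation(2, 2, 3, 1)  # 43
#' decode_observation(72)
encode_observation <- function(speed, headway = NULL, queue = NULL,
                               signal = NULL) {
  if (is.null(headway) && length(speed) == 4) {
    headway <- speed[2]; queue <- speed[3]; signal <- speed[4]
    speed <- speed[1]
  }
  comp <- cbind(speed, headway, queue, signal)
  if (any(is.na(comp)) || any(comp < 1) || any(comp > 3) ||
      any(comp != round(comp)))
    stopf("all tuple components must be integers in 1..3")
  as.integer(27 * (comp[, 1] - 1) + 9 * (comp[, 2] - 1) +
               3 * (comp[, 3] - 1) + comp[, 4])
}

#' @rdname encode_observation
#' @export
decode_observation <- function(index) {
  if (any(is.na(index)) || any(index < 1) || any(index > 81) ||
      any(index != round(index)))
    stopf("symbol index must be in 1..81")
  i0 <- as.integer(index) - 1L
  cbind(speed = i0 %/% 27L + 1L,
        headway = (i0 %/% 9L) %% 3L + 1L,
        queue = (i0 %/% 3L) %% 3L + 1L,
        signal = i0 %% 3L + 1L)
}

#' Zone assignment on the intersection approach
#'
#' The approach is split into three zones by distance from the stop line:
#' zone 1 is `[0, 40)` m (beyond the dilemma zone, nearest the stop line),
#' zone 2 is the dilemma zone `[40, 100)` m, and zone 3 is `[100, 135]` m.
#' Intervals are half-open toward the stop line.
#'
#' @param distance Distance(s) to the stop line, metres, within the study
#'   area `[0, max(boundaries)]`.
#' @param boundaries Increasing zone boundaries in metres.
#' @return Integer zone(s) in 1..3.
#' @export
#' @examples
#' assign_zone(c(20, 70, 120))
assign_zone <- function(distance, boundaries = c(40, 100, 135)) {
  if (length(boundaries) != 3 || any(diff(boundaries) <= 0) ||
      boundaries[1] <= 0)
    stopf("boundaries must be three increasing positive distances")
  if (any(is.na(distance)) || any(distance < 0) ||
      any(distance > boundaries[3]))
    stopf("distance outside the study area [0, %g]", boundaries[3])
  ifelse(distance < boundaries[1], 1L,
         ifelse(distance < boundaries[2], 2L, 3L))
}

#' Turn kinematic tracks into per-zone observation sequences
#'
#' Each interior detection-line record of a track (one that carries a speed,
#' a headway/head-car flag, a queue category and a signal phase) is encoded
#' as one observation symbol and tagged with the zone of its detection line.
#' Rows without a speed (first/last line of each track) are skipped.
#'
#' @param tracks A track data frame from [build_tracks()], augmented with
#'   `queue` and `signal` columns (the simulator provides these; field data
#'   must supply them).  A `distance_m` column locates each line; if absent
#'   it is derived as `line_index * spacing`.
#' @param rules A [discretization_rules()] object.
#' @param boundaries Zone boundaries passed to [assign_zone()].
#' @param spacing Detection-line spacing in metres, used only when
#'   `distance_m` is missing.
#' @return A data frame with columns `vehicle_id`, `zone`, `t` (1-based
#'   position within the vehicle's sequence), `symbol`, and `state` if the
#'   tracks carry ground-truth or classified states.
#' @export
tracks_to_sequences <- function(tracks, rules = discretization_rules(),
                                boundaries = c(40, 100, 135),
                                spacing = 2.92) {
  need <- c("vehicle_id", "queue", "signal")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stopf("tracks are missing context columns: %s", paste(miss, collapse = ", "))
  if (!"speed_ms" %in% names(tracks))
    stopf("tracks carry no speeds; run build_tracks() first")
  if (!"distance_m" %in% names(tracks))
    tracks$distance_m <- tracks$line_index * spacing
  keep <- !is.na(tracks$speed_ms)
  tr <- tracks[keep, , drop = FALSE]
  if (!nrow(tr)) stopf("no rows with speeds to encode")
  symbol <- encode_observation(
    bin_speed(tr$speed_ms, rules),
    bin_headway(tr$headway_s, head_car = tr$head_car, rules = rules),
    bin_queue(tr$queue, rules),
    bin_signal(tr$signal, rules))
  out <- data.frame(vehicle_id = tr$vehicle_id,
                    zone = assign_zone(pmin(tr$distance_m, boundaries[3]),
                                       boundaries),
                    t = stats::ave(seq_len(nrow(tr)), tr$vehicle_id,
                                   FUN = seq_along),
                    symbol = symbol)
  if ("state" %in% names(tr)) out$state <- tr$state
  ord <- order(out$vehicle_id, out$t)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
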