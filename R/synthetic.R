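#' Simulation configuration for the intersection approach
#'
#' The study conditions emulated by the simulator: a 190 s signal cycle with
#' 35 s of green (yellow defaults to 3 s, an ordinary urban value; the
#' remainder is red), detection lines every 2.92 m timed at 30 frames/s,
#' zone boundaries 40/100/135 m from the stop line, a 60 km/h speed limit,
#' and a Poisson arrival process (default 600 veh/h, a per-lane share of a
#' busy urban through movement).  State-conditional accelerations default
#' to +1.5 m/s^2 (accelerate) and -2.5 m/s^2 (decelerate); the stop state
#' brakes at -4.5 m/s^2 until standstill.
#'
#' @param cycle_length,green_time,yellow_time Signal timing, seconds.
#' @param line_spacing Detection-line spacing, metres.
#' @param frames_per_second Video frame rate.
#' @param zone_boundaries Zone boundaries, metres from the stop line.
#' @param speed_limit Speed limit, km/h.
#' @param arrival_rate Vehicle arrivals per hour (single lane).
#' @param accel,decel,stop_decel State-conditional accelerations, m/s^2.
#' @param min_gap Minimum bumper-to-bumper spacing, metres (no-overtake
#'   car-following constraint).
#' @param entry_speed_range Range (m/s) from which entry speeds are drawn.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(cycle_length = 190, green_time = 35, yellow_time = 3,
                       line_spacing = 2.92, frames_per_second = 30L,
                       zone_boundaries = c(40, 100, 135), speed_limit = 60,
                       arrival_rate = 600, accel = 1.5, decel = -2.5,
                       stop_decel = -4.5, min_gap = 5,
                       entry_speed_range = c(8, 14)) {
  if (any(c(cycle_length, green_time, yellow_time, line_spacing,
            frames_per_second, speed_limit, arrival_rate, min_gap) <= 0))
    stopf("all durations, rates and distances must be strictly positive")
  if (green_time + yellow_time >= cycle_length)
    stopf("green_time + yellow_time must be less than cycle_length")
  if (any(diff(zone_boundaries) <= 0) || zone_boundaries[1] <= 0)
    stopf("zone_boundaries must be strictly increasing and positive")
  if (accel <= 0 || decel >= 0 || stop_decel >= 0)
    stopf("accel must be positive; decel and stop_decel negative")
  structure(list(cycle_length = cycle_length, green_time = green_time,
                 yellow_time = yellow_time, line_spacing = line_spacing,
                 frames_per_second = as.integer(frames_per_second),
                 zone_boundaries = zone_boundaries,
                 speed_limit = speed_limit, arrival_rate = arrival_rate,
                 accel = accel, decel = decel, stop_decel = stop_decel,
                 min_gap = min_gap, entry_speed_range = entry_speed_range),
            class = "sim_config")
}

#' Signal phase at a given time
#'
#' The cycle starts with green: `[0, green)` is green, then yellow, then
#' red until the cycle wraps.
#'
#' @param time Time(s) in seconds.
#' @param config A [sim_config()].
#' @return Character vector of phases (`"green"`, `"yellow"`, `"red"`).
#' @export
signal_phase <- function(time, config = sim_config()) {
  tc <- time %% config$cycle_length
  ifelse(tc < config$green_time, "green",
         ifelse(tc < config$green_time + config$yellow_time, "yellow", "red"))
}

# Build one emission row as the outer product of per-factor distributions
# (speed, headway, queue, signal), then pin the total mass on the dangerous
# symbols to d_mass, spread proportionally to the base pattern.
make_emission_row <- function(speed_d, headway_d, queue_d, signal_d,
                              d_mass, uniform_mix) {
  tup <- decode_observation(1:81)
  row <- speed_d[tup[, "speed"]] * headway_d[tup[, "headway"]] *
    queue_d[tup[, "queue"]] * signal_d[tup[, "signal"]]
  row <- row / sum(row)
  dang <- dangerous_symbols()
  w <- row[dang] + 1e-6
  row[dang] <- d_mass * w / sum(w)
  rest <- setdiff(1:81, dang)
  row[rest] <- (1 - d_mass) * row[rest] / sum(row[rest])
  row <- (1 - uniform_mix) * row + uniform_mix / 81
  row <- pmax(row, 1e-8)
  row / sum(row)
}

#' Ground-truth model parameters for the synthetic study
#'
#' A fixed, documented parameter set used as the generative truth in
#' simulations and estimator tests.  States are accelerate, decelerate,
#' maintain, stop; zones are 1 (nearest the stop line), 2 (the dilemma
#' zone) and 3 (furthest), plus `"whole"` (a zone-length-weighted mixture).
#'
#' The fixture is built to reflect the qualitative dilemma-zone findings:
#' the zone-2 transition matrix is volatile (decisions flip often), its
#' emission rows are more diffuse (lower 2-norm, less stable behavior) and
#' they carry substantially more mass on the six dangerous observation
#' symbols than zones 1 and 3 (higher risk index).  Zone 1 is
#' decelerate/stop-dominated at low speeds; zone 3 is a persistent
#' maintain-speed regime.
#'
#' @return A list of class `hmdm_truth` with elements `pi`, `A_by_zone` and
#'   `B_by_zone` (named lists over `"1"`, `"2"`, `"3"`, `"whole"`), and
#'   `state_names`.
#' @export
#' @examples
#' truth <- default_ground_truth()
#' sapply(truth$B_by_zone, function(B) risk_index(B))
default_ground_truth <- function() {
  pi <- c(accelerate = 0.15, decelerate = 0.15, maintain = 0.60, stop = 0.10)

  A <- list(
    "1" = rbind(c(0.30, 0.35, 0.25, 0.10),
                c(0.05, 0.55, 0.15, 0.25),
                c(0.05, 0.40, 0.45, 0.10),
                c(0.05, 0.10, 0.05, 0.80)),
    "2" = rbind(c(0.45, 0.25, 0.25, 0.05),
                c(0.40, 0.15, 0.35, 0.10),
                c(0.25, 0.30, 0.35, 0.10),
                c(0.15, 0.10, 0.15, 0.60)),
    "3" = rbind(c(0.55, 0.05, 0.38, 0.02),
                c(0.10, 0.50, 0.35, 0.05),
                c(0.10, 0.10, 0.78, 0.02),
                c(0.10, 0.05, 0.05, 0.80)))

  # per-zone, per-state factor distributions (speed, headway, queue, signal)
  spd <- list(
    "1" = rbind(c(0.60, 0.36, 0.04), c(0.70, 0.28, 0.02),
                c(0.55, 0.40, 0.05), c(0.97, 0.03, 0.00)),
    "2" = rbind(c(0.10, 0.55, 0.35), c(0.35, 0.55, 0.10),
                c(0.20, 0.55, 0.25), c(0.95, 0.05, 0.00)),
    "3" = rbind(c(0.10, 0.50, 0.40), c(0.30, 0.60, 0.10),
                c(0.15, 0.60, 0.25), c(0.95, 0.05, 0.00)))
  hwy <- list(
    "1" = rbind(c(0.25, 0.55, 0.20), c(0.20, 0.60, 0.20),
                c(0.25, 0.55, 0.20), c(0.20, 0.60, 0.20)),
    "2" = rbind(c(0.15, 0.60, 0.25), c(0.15, 0.65, 0.20),
                c(0.20, 0.55, 0.25), c(0.20, 0.60, 0.20)),
    "3" = rbind(c(0.30, 0.30, 0.40), c(0.20, 0.55, 0.25),
                c(0.30, 0.35, 0.35), c(0.25, 0.45, 0.30)))
  que <- list(
    "1" = rbind(c(0.25, 0.45, 0.30), c(0.25, 0.40, 0.35),
                c(0.25, 0.45, 0.30), c(0.15, 0.25, 0.60)),
    "2" = rbind(c(0.20, 0.50, 0.30), c(0.20, 0.50, 0.30),
                c(0.20, 0.50, 0.30), c(0.15, 0.35, 0.50)),
    "3" = rbind(c(0.35, 0.60, 0.05), c(0.30, 0.60, 0.10),
                c(0.35, 0.60, 0.05), c(0.30, 0.55, 0.15)))
  sig <- list(
    "1" = rbind(c(0.45, 0.50, 0.05), c(0.40, 0.55, 0.05),
                c(0.45, 0.50, 0.05), c(0.10, 0.88, 0.02)),
    "2" = rbind(c(0.40, 0.45, 0.15), c(0.35, 0.50, 0.15),
                c(0.40, 0.45, 0.15), c(0.15, 0.80, 0.05)),
    "3" = rbind(c(0.45, 0.45, 0.10), c(0.40, 0.50, 0.10),
                c(0.45, 0.45, 0.10), c(0.20, 0.75, 0.05)))

  # dangerous-symbol mass and diffuseness per zone x state
  d_mass <- list("1" = c(0.015, 0.010, 0.010, 0.002),
                 "2" = c(0.200, 0.060, 0.150, 0.002),
                 "3" = c(0.003, 0.003, 0.003, 0.001))
  u_mix <- list("1" = 0.08, "2" = 0.35, "3" = 0.12)

  B <- lapply(c("1", "2", "3"), function(z) {
    rows <- t(sapply(1:4, function(s)
      make_emission_row(spd[[z]][s, ], hwy[[z]][s, ], que[[z]][s, ],
                        sig[[z]][s, ], d_mass[[z]][s], u_mix[[z]])))
    dimnames(rows) <- list(HMDM_STATES, NULL)
    rows
  })
  names(B) <- c("1", "2", "3")
  A <- lapply(A, function(m) {
    dimnames(m) <- list(from = HMDM_STATES, to = HMDM_STATES)
    normalize_rows(m)
  })

  # whole-road: zone-length-weighted mixture (zones span 40, 60, 35 m)
  w <- c(40, 60, 35) / 135
  A$whole <- normalize_rows(w[1] * A[["1"]] + w[2] * A[["2"]] + w[3] * A[["3"]])
  B$whole <- normalize_rows(w[1] * B[["1"]] + w[2] * B[["2"]] + w[3] * B[["3"]])

  structure(list(pi = pi, A_by_zone = A, B_by_zone = B,
                 state_names = HMDM_STATES),
            class = "hmdm_truth")
}

truth_zone_model <- function(truth, zone) {
  zone <- as.character(zone)
  if (!zone %in% names(truth$A_by_zone))
    stopf("unknown zone '%s' (expected one of %s)", zone,
          paste(names(truth$A_by_zone), collapse = ", "))
  new_hmdm(truth$pi, truth$A_by_zone[[zone]], truth$B_by_zone[[zone]],
           method = "truth", state_names = truth$state_names)
}

#' Sample labeled sequences from a ground-truth model
#'
#' The exact-HMM sampling path: the initial state is drawn from `pi`,
#' states evolve by the zone's transition matrix, and one symbol per step
#' is emitted from the zone's emission matrix.  True state labels are
#' retained, making the output suitable for supervised estimation and
#' parameter-recovery experiments.
#'
#' @param truth A [default_ground_truth()]-shaped object.
#' @param zone Zone id: 1, 2, 3 or `"whole"`.
#' @param n_sequences,length Number and length of sequences (>= 1).
#' @param seed Integer seed; the caller's RNG state is restored.
#' @return A data frame with columns `vehicle_id`, `zone`, `t`, `symbol`,
#'   `state` (true codes 0..3).
#' @export
#' @examples
#' head(sample_hmm_sequences(default_ground_truth(), 2, 3, 10, seed = 1))
sample_hmm_sequences <- function(truth, zone, n_sequences, length,
                                 seed = NULL) {
  if (n_sequences < 1 || length < 1)
    stopf("n_sequences and length must be >= 1")
  model <- truth_zone_model(truth, zone)
  out <- simulate(model, nsim = n_sequences, seed = seed, length = length)
  out$zone <- if (identical(as.character(zone), "whole")) NA_integer_ else
    as.integer(zone)
  out[, c("vehicle_id", "zone", "t", "symbol", "state")]
}

#' Simulate vehicles approaching the intersection
#'
#' The physical generation path: vehicles arrive by a Poisson process,
#' enter 135 m upstream at a random speed, and carry a hidden decision
#' state that evolves once per second by the transition matrix of the zone
#' they currently occupy.  The state dictates acceleration (accelerate
#' +`accel`, decelerate `decel`, maintain 0, stop brakes to standstill);
#' position is integrated at frame resolution.  Vehicles never overtake:
#' a follower is held at least `min_gap` behind its leader at no more than
#' the leader's speed.  On red (and yellow) the stop line acts as a wall,
#' so queues form and dissipate with the signal.  A detection record is
#' emitted each time a vehicle crosses one of the lines spaced every
#' `line_spacing` metres, with the frame index rounded to the nearest
#' frame.
#'
#' Alongside the raw records, the function returns exact-kinematics labeled
#' sequences (symbols discretized from the true, un-rounded speed, headway,
#' queue context and signal at each crossing) for validation against the
#' frame-count reconstruction.
#'
#' @param truth A [default_ground_truth()]-shaped object supplying `pi` and
#'   the per-zone transition matrices.
#' @param config A [sim_config()].
#' @param n_vehicles Number of vehicles to release (>= 1).
#' @param seed Integer seed; the caller's RNG state is restored.
#' @param rules Discretization rules for the exact-kinematics sequences.
#' @param max_time Optional wall-clock cap (simulated seconds); by default
#'   the simulation runs until every vehicle has cleared the stop line,
#'   with a generous internal cap.
#' @return A list with `records` (data frame: `vehicle_id`, `lane`,
#'   `line_index`, `frame_index`), `sequences` (data frame: `vehicle_id`,
#'   `zone`, `t`, `symbol`, `state`) and `context` (per-crossing truth:
#'   speed, state, signal, queue, headway).
#' @export
simulate_approach <- function(truth, config = sim_config(), n_vehicles,
                              seed = NULL,
                              rules = discretization_rules(),
                              max_time = NULL) {
  if (n_vehicles < 1) stopf("n_vehicles must be >= 1")
  with_local_seed(seed, simulate_approach_impl(truth, config, n_vehicles,
                                               rules, max_time))
}

simulate_approach_impl <- function(truth, config, n_vehicles, rules,
                                   max_time = NULL) {
  fps <- config$frames_per_second
  dt <- 1 / fps
  entry <- config$zone_boundaries[3]
  n_lines <- floor(entry / config$line_spacing)  # line 0 at the stop line
  line_d <- (0:n_lines) * config$line_spacing
  vmax <- config$speed_limit / 3.6
  N <- length(truth$pi)

  arrivals <- cumsum(rexp(n_vehicles, rate = config$arrival_rate / 3600))
  entry_speed <- runif(n_vehicles, config$entry_speed_range[1],
                       config$entry_speed_range[2])
  init_state <- sample.int(N, n_vehicles, replace = TRUE, prob = truth$pi)

  # per-vehicle state vectors
  d <- rep(NA_real_, n_vehicles)      # distance to stop line, m
  v <- rep(NA_real_, n_vehicles)
  st <- rep(NA_integer_, n_vehicles)  # 1-based state
  active <- rep(FALSE, n_vehicles)
  done <- rep(FALSE, n_vehicles)
  next_line <- rep(NA_integer_, n_vehicles)  # index into line_d (1-based)

  cap <- (n_lines + 1) * n_vehicles
  rec <- list(vid = integer(cap), line = integer(cap), frame = integer(cap),
              tx = numeric(cap), speed = numeric(cap), state = integer(cap),
              signal = character(cap), queue = character(cap),
              headway = numeric(cap))
  nrec <- 0L
  last_cross <- rep(NA_real_, n_lines + 1)      # last crossing time per line
  last_veh <- rep(NA_integer_, n_lines + 1)

  t <- 0
  t_max <- if (is.null(max_time)) arrivals[n_vehicles] + 1200 else max_time
  next_state_tick <- 1
  while ((!all(done)) && t < t_max) {
    phase <- signal_phase(t, config)
    red_wall <- phase %in% c("red", "yellow")

    # spawn arrivals whose entry area is clear
    for (i in which(!active & !done & arrivals <= t)) {
      blockers <- which(active)
      clear <- !length(blockers) || min(entry - d[blockers]) >= config$min_gap
      if (clear) {
        active[i] <- TRUE
        d[i] <- entry
        v[i] <- entry_speed[i]
        if (length(blockers)) {
          lead <- blockers[which.max(d[blockers])]
          v[i] <- min(v[i], v[lead])
        }
        st[i] <- init_state[i]
        next_line[i] <- n_lines + 1L  # first line strictly below entry
      }
    }

    # state transitions once per second, zone-specific
    if (t >= next_state_tick) {
      for (i in which(active)) {
        z <- as.character(assign_zone(min(max(d[i], 0), entry)))
        st[i] <- sample.int(N, 1, prob = truth$A_by_zone[[z]][st[i], ])
      }
      next_state_tick <- next_state_tick + 1
    }

    # integrate motion, leaders (smallest d) first so followers see the
    # leader's updated position this step
    ord <- which(active)
    ord <- ord[order(d[ord])]
    prev_d <- NA_real_; prev_v <- NA_real_
    for (i in ord) {
      a <- c(config$accel, config$decel, 0, config$stop_decel)[st[i]]
      vi <- if (st[i] == 4L) max(0, v[i] + config$stop_decel * dt) else
        min(max(0, v[i] + a * dt), vmax)
      di <- d[i] - vi * dt
      if (red_wall && d[i] > 0 && di < 0) { di <- 0; vi <- 0 }
      if (!is.na(prev_d) && di < prev_d + config$min_gap) {
        di <- prev_d + config$min_gap
        vi <- min(vi, prev_v)
        if (di > d[i]) di <- d[i]  # never move backwards
      }
      # detection-line crossings between d[i] and di
      if (di < d[i]) {
        ks <- which(line_d < d[i] & line_d >= di)
        for (k in rev(ks)) {  # in travel order (decreasing distance)
          frac <- (d[i] - line_d[k]) / (d[i] - di)
          tx <- t + frac * dt
          nrec <- nrec + 1L
          rec$vid[nrec] <- i
          rec$line[nrec] <- k - 1L
          rec$frame[nrec] <- as.integer(round(tx * fps))
          rec$tx[nrec] <- tx
          rec$speed[nrec] <- vi
          rec$state[nrec] <- st[i]
          rec$signal[nrec] <- signal_phase(tx, config)
          has_lead <- !is.na(last_veh[k]) && active[last_veh[k]] &&
            last_veh[k] != i
          rec$queue[nrec] <- if (!has_lead) "head_car" else
            if (v[last_veh[k]] > 0.5) "no_stopped" else "other"
          rec$headway[nrec] <- if (is.na(last_cross[k])) NA_real_ else
            tx - last_cross[k]
          if (!has_lead) rec$headway[nrec] <- NA_real_
          last_cross[k] <- tx
          last_veh[k] <- i
        }
      }
      d[i] <- di; v[i] <- vi
      if (d[i] <= 0 && !red_wall) { active[i] <- FALSE; done[i] <- TRUE }
      if (d[i] > 0 || red_wall) { prev_d <- d[i]; prev_v <- v[i] }
    }
    t <- t + dt
  }

  idx <- seq_len(nrec)
  records <- data.frame(vehicle_id = rec$vid[idx], lane = 1L,
                        line_index = rec$line[idx],
                        frame_index = rec$frame[idx])
  context <- data.frame(vehicle_id = rec$vid[idx],
                        line_index = rec$line[idx],
                        time_s = rec$tx[idx],
                        distance_m = rec$line[idx] * config$line_spacing,
                        speed_ms = rec$speed[idx],
                        state = rec$state[idx] - 1L,
                        signal = rec$signal[idx],
                        queue = rec$queue[idx],
                        headway_s = rec$headway[idx])
  ok <- context$speed_ms > 0
  seqs <- context[ok, , drop = FALSE]
  if (nrow(seqs)) {
    symbol <- encode_observation(
      bin_speed(seqs$speed_ms, rules),
      bin_headway(seqs$headway_s, head_car = is.na(seqs$headway_s),
                  rules = rules),
      bin_queue(seqs$queue, rules),
      bin_signal(seqs$signal, rules))
    sequences <- data.frame(
      vehicle_id = seqs$vehicle_id,
      zone = assign_zone(pmin(seqs$distance_m, entry)),
      t = stats::ave(seq_len(nrow(seqs)), seqs$vehicle_id, FUN = seq_along),
      symbol = symbol,
      state = seqs$state)
  } else {
    sequences <- data.frame(vehicle_id = integer(), zone = integer(),
                            t = integer(), symbol = integer(),
                            state = integer())
  }
  list(records = records, sequences = sequences, context = context)
}
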