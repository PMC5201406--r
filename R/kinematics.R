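#' Kinematics configuration
#'
#' Parameters for recovering vehicle kinematics from detection-line crossing
#' records: the spacing of the virtual detection lines (2.92 m), the video
#' frame rate used to time crossings (30 frames/s), and the thresholds that
#' classify motion states.  A vehicle slower than `stop_speed_threshold` is
#' "stopped"; otherwise an acceleration beyond `accel_threshold` in
#' magnitude means accelerating/decelerating, and anything inside the band
#' is "maintain speed".
#'
#' @param line_spacing Metres between adjacent detection lines.
#' @param frames_per_second Video frame rate (frames representing 1 s).
#' @param stop_speed_threshold Speed (m/s) at or below which a vehicle is
#'   classified as stopped.
#' @param accel_threshold Acceleration band half-width (m/s^2) for the
#'   maintain-speed state.
#' @return An object of class `kinematics_config`.
#' @export
kinematics_config <- function(line_spacing = 2.92, frames_per_second = 30L,
                              stop_speed_threshold = 0.5,
                              accel_threshold = 0.3) {
  if (line_spacing <= 0) stopf("line_spacing must be positive")
  if (frames_per_second < 1) stopf("frames_per_second must be >= 1")
  if (stop_speed_threshold < 0 || accel_threshold < 0)
    stopf("thresholds must be non-negative")
  structure(list(line_spacing = line_spacing,
                 frames_per_second = as.integer(frames_per_second),
                 stop_speed_threshold = stop_speed_threshold,
                 accel_threshold = accel_threshold),
            class = "kinematics_config")
}

#' Travel time between two detection lines from a frame count
#'
#' A crossing pair `frame_count` frames apart at `frames_per_second` frames
#' per second took `frame_count / frames_per_second` seconds.
#'
#' @param frame_count Number of frames between the two crossings (>= 1).
#' @param frames_per_second Frame rate.
#' @return Travel time in seconds (vectorized).
#' @export
#' @examples
#' travel_time(45, 30)  # 1.5 s
travel_time <- function(frame_count, frames_per_second = 30L) {
  if (any(is.na(frame_count)) || any(frame_count < 1))
    stopf("frame_count must be >= 1 (a zero-frame crossing implies infinite speed)")
  frame_count / frames_per_second
}

#' Speed at a detection line from adjacent travel times
#'
#' With equally spaced lines a--b--c the speed at the middle line b is the
#' distance `2 * spacing` divided by the total time `t_ab + t_bc`.
#'
#' @param t_ab,t_bc Travel times (s) over the two adjacent line pairs.
#' @param spacing Line spacing in metres.
#' @return Speed in m/s (vectorized).
#' @export
#' @examples
#' speed_at_line(0.5, 0.5, 2.92)  # 5.84 m/s
speed_at_line <- function(t_ab, t_bc, spacing = 2.92) {
  tot <- t_ab + t_bc
  if (any(is.na(tot)) || any(tot <= 0))
    stopf("t_ab + t_bc must be positive")
  2 * spacing / tot
}

#' Headways at detection lines
#'
#' The headway of a vehicle at a line is the time since the previous vehicle
#' in the same lane crossed that line.  The first vehicle per lane (and per
#' signal cycle, when `cycle_length` is given) has no predecessor and is
#' flagged as the head car.
#'
#' @param crossings Data frame with columns `vehicle_id`, `lane`,
#'   `line_index` and `time_s` (or `frame_index` plus `frames_per_second`).
#' @param cycle_length Optional signal cycle length (s); when given, the
#'   head-car flag resets at each cycle boundary.
#' @param frames_per_second Frame rate used when only `frame_index` is
#'   present.
#' @return The input with `headway_s` (NA for head cars) and `head_car`
#'   columns appended.
#' @export
headways <- function(crossings, cycle_length = NULL,
                     frames_per_second = 30L) {
  if (!"time_s" %in% names(crossings)) {
    if (!"frame_index" %in% names(crossings))
      stopf("crossings need a time_s or frame_index column")
    crossings$time_s <- crossings$frame_index / frames_per_second
  }
  if (!"lane" %in% names(crossings)) crossings$lane <- 1L
  key <- paste(crossings$vehicle_id, crossings$line_index, crossings$lane)
  if (anyDuplicated(key))
    stopf("duplicate (vehicle, line) crossing records")
  cyc <- if (is.null(cycle_length)) 0L else
    as.integer(crossings$time_s %/% cycle_length)
  grp <- paste(crossings$lane, crossings$line_index, cyc)
  ord <- order(grp, crossings$time_s)
  gap <- rep(NA_real_, nrow(crossings))
  g <- grp[ord]
  tt <- crossings$time_s[ord]
  same <- c(FALSE, g[-1] == g[-length(g)])
  gap[ord] <- ifelse(same, tt - c(NA, tt[-length(tt)]), NA)
  crossings$headway_s <- gap
  crossings$head_car <- is.na(gap)
  crossings
}

#' Classify a motion state from speed and acceleration
#'
#' Returns the integer motion-state codes 0 = accelerate, 1 = decelerate,
#' 2 = maintain speed, 3 = stop.  The stop test (speed at or below the stop
#' threshold) takes precedence over the acceleration band.
#'
#' @param speed Speed(s), m/s, non-negative.
#' @param accel Acceleration(s), m/s^2; `NA` is treated as 0 (steady).
#' @param config A [kinematics_config()].
#' @return Integer state code(s) 0..3.
#' @export
#' @examples
#' classify_motion_state(c(0.2, 10, 10), c(-0.1, 1, 0.1))
classify_motion_state <- function(speed, accel,
                                  config = kinematics_config()) {
  if (any(is.na(speed)) || any(speed < 0))
    stopf("speed must be non-negative")
  accel[is.na(accel)] <- 0
  ifelse(speed <= config$stop_speed_threshold, 3L,
         ifelse(accel > config$accel_threshold, 0L,
                ifelse(accel < -config$accel_threshold, 1L, 2L)))
}

#' Build vehicle tracks from detection-line crossing records
#'
#' Converts raw crossing records (vehicle, lane, line, frame) into per-line
#' kinematics: crossing times, speeds at interior lines (from the travel
#' times over the two adjacent line pairs), accelerations by finite
#' differences of consecutive line speeds, headways, and motion-state
#' labels.  The first and last line of each track carry no speed (both
#' neighbors are needed); vehicles with fewer than three crossings cannot
#' yield any speed and are dropped with a warning.
#'
#' @param records Data frame with columns `vehicle_id`, `lane` (optional),
#'   `line_index`, `frame_index`.
#' @param config A [kinematics_config()].
#' @param cycle_length Optional cycle length (s) forwarded to [headways()].
#' @return A data frame with one row per retained crossing: `vehicle_id`,
#'   `lane`, `line_index`, `distance_m`, `time_s`, `speed_ms`, `accel_ms2`,
#'   `state`, `headway_s`, `head_car`, ordered by vehicle and time.
#' @export
build_tracks <- function(records, config = kinematics_config(),
                         cycle_length = NULL) {
  need <- c("vehicle_id", "line_index", "frame_index")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("records missing columns: %s",
                          paste(miss, collapse = ", "))
  if (!"lane" %in% names(records)) records$lane <- 1L
  records$time_s <- records$frame_index / config$frames_per_second
  records <- headways(records, cycle_length = cycle_length,
                      frames_per_second = config$frames_per_second)
  n_by_veh <- table(records$vehicle_id)
  short <- names(n_by_veh)[n_by_veh < 3]
  if (length(short)) {
    warning(sprintf(
      "dropping %d vehicle(s) with fewer than 3 crossings: %s",
      length(short), paste(head(short, 5), collapse = ", ")), call. = FALSE)
    records <- records[!records$vehicle_id %in% short, , drop = FALSE]
  }
  if (!nrow(records)) stopf("no vehicles with >= 3 crossings")
  pieces <- lapply(split(records, records$vehicle_id), function(df) {
    df <- df[order(df$time_s), , drop = FALSE]
    n <- nrow(df)
    dt <- diff(df$time_s)
    if (any(dt <= 0)) stopf("crossing times not strictly increasing for vehicle %s",
                            df$vehicle_id[1])
    v <- rep(NA_real_, n)
    # interior lines: Eq. of motion over the flanking pair, 2s / (t_ab + t_bc)
    v[2:(n - 1)] <- 2 * config$line_spacing /
      (df$time_s[3:n] - df$time_s[1:(n - 2)])
    a <- rep(NA_real_, n)
    if (n >= 4) {
      # backward difference of line speeds; first interior line uses the
      # forward difference so every speed-bearing row gets an acceleration
      idx <- 3:(n - 1)
      a[idx] <- (v[idx] - v[idx - 1]) / (df$time_s[idx] - df$time_s[idx - 1])
      a[2] <- (v[3] - v[2]) / (df$time_s[3] - df$time_s[2])
    } else {
      a[2] <- 0  # single interior speed: assume steady
    }
    df$speed_ms <- v
    df$accel_ms2 <- a
    df$state <- NA_integer_
    ok <- !is.na(v)
    df$state[ok] <- classify_motion_state(v[ok], a[ok], config)
    df
  })
  out <- do.call(rbind, pieces)
  out$distance_m <- out$line_index * config$line_spacing
  rownames(out) <- NULL
  out
}
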