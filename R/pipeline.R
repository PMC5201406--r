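#' Read and write model parameters as JSON
#'
#' Parameters are stored as `{"n_states", "n_symbols", "pi", "A", "B"}`
#' with matrices row-major.
#'
#' @param params An [hmdm] object or `pi`/`A`/`B` list.
#' @param path File path.
#' @return `read_hmdm_json()` returns an [hmdm] object.
#' @export
write_hmdm_json <- function(params, path) {
  params <- as_hmdm_params(params)
  obj <- list(n_states = params$n_states, n_symbols = params$n_symbols,
              pi = unname(params$pi),
              A = unname(params$A), B = unname(params$B))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_hmdm_json
#' @export
read_hmdm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_hmdm_params(list(pi = obj$pi, A = obj$A, B = obj$B))
}

#' Split sequences into training and validation sets by vehicle
#'
#' Whole vehicle sequences are assigned to one side or the other (a
#' sequence is never cut), with the number of training vehicles equal to
#' `round(train_fraction * n_vehicles)`, at least one vehicle on each side.
#'
#' @param sequences A sequence data frame with a `vehicle_id` column.
#' @param train_fraction Fraction of vehicles assigned to training; the
#'   default mirrors a 7480/11264 record split.
#' @param seed Integer seed; the caller's RNG state is restored.
#' @return A list with `train` and `validation` data frames and the
#'   realized record counts `n_train`, `n_validation`.
#' @export
split_train_validation <- function(sequences, train_fraction = 7480 / 11264,
                                   seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  ids <- unique(sequences$vehicle_id)
  if (length(ids) < 2) stopf("need at least 2 vehicles to split")
  n_train <- round(train_fraction * length(ids))
  if (n_train < 1 || n_train >= length(ids))
    stopf("train_fraction leaves an empty split for %d vehicles",
          length(ids))
  train_ids <- with_local_seed(seed, sample(ids, n_train))
  train <- sequences[sequences$vehicle_id %in% train_ids, , drop = FALSE]
  valid <- sequences[!sequences$vehicle_id %in% train_ids, , drop = FALSE]
  list(train = train, validation = valid,
       n_train = nrow(train), n_validation = nrow(valid))
}

#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()].
#'
#' @param out_dir Output run directory (created if missing).
#' @param truth Generative truth ([default_ground_truth()] by default).
#' @param sim A [sim_config()].
#' @param rules [discretization_rules()].
#' @param boundaries Zone boundaries (m).
#' @param fit A [hmdm_control()]; the pipeline default uses 2 restarts and
#'   up to 100 EM iterations per zone model.
#' @param train_fraction Vehicle-level training fraction.
#' @param n_vehicles Vehicles to generate.
#' @param observation_source `"hmm"` (exact per-zone HMM emissions; the
#'   controlled path for metric studies) or `"physical"` (kinematic
#'   simulation, frame-count records, full kinematics + discretization
#'   chain).
#' @param zone_lengths For the `"hmm"` source: observations per vehicle in
#'   zones 1, 2, 3 (defaults 13/19/12, roughly one per detection line, 44
#'   per vehicle in total).
#' @param norm_type,risk_variant,mape_min_reference Metric options.
#' @param dangerous Dangerous symbol set.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("hmdm_run_"),
                            truth = default_ground_truth(),
                            sim = sim_config(),
                            rules = discretization_rules(),
                            boundaries = c(40, 100, 135),
                            fit = hmdm_control(n_restarts = 2L,
                                               max_iterations = 100L),
                            train_fraction = 7480 / 11264,
                            n_vehicles = 256L,
                            observation_source = c("hmm", "physical"),
                            zone_lengths = c(13L, 19L, 12L),
                            norm_type = "spectral",
                            risk_variant = "max",
                            mape_min_reference = 0.01,
                            dangerous = dangerous_symbols(),
                            seed = 1L) {
  observation_source <- match.arg(observation_source)
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  structure(list(out_dir = out_dir, truth = truth, sim = sim, rules = rules,
                 boundaries = boundaries, fit = fit,
                 train_fraction = train_fraction,
                 n_vehicles = as.integer(n_vehicles),
                 observation_source = observation_source,
                 zone_lengths = as.integer(zone_lengths),
                 norm_type = norm_type, risk_variant = risk_variant,
                 mape_min_reference = mape_min_reference,
                 dangerous = dangerous, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Exact-HMM observation generation: each vehicle traverses zone 3, then 2,
# then 1, with a per-zone segment sampled from that zone's truth model.
generate_hmm_observations <- function(truth, n_vehicles, zone_lengths,
                                      seed) {
  segs <- lapply(c(3L, 2L, 1L), function(z) {
    s <- sample_hmm_sequences(truth, z, n_vehicles, zone_lengths[z],
                              seed = seed + z)
    s
  })
  out <- do.call(rbind, segs)
  out <- out[order(out$vehicle_id, -out$zone, out$t), , drop = FALSE]
  out$t <- stats::ave(seq_len(nrow(out)), out$vehicle_id, FUN = seq_along)
  rownames(out) <- NULL
  out
}

zone_sequence_lists <- function(df, zone) {
  sub <- if (identical(zone, "whole")) df else df[df$zone == zone, ,
                                                  drop = FALSE]
  if (!nrow(sub)) return(list(symbols = list(), states = NULL))
  as_hmdm_sequences(sub)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate, (for the physical source) kinematics and
#' discretization, vehicle-level train/validation split, per-zone and
#' whole-road Baum-Welch training, supervised-MLE validation with MAPE,
#' stability and risk metrics, and the dangerous-action warning report.
#' All outputs are written into the run directory: one parameter JSON per
#' zone, a per-zone summary CSV (stability 2-norm, risk index, MAPE), a
#' warning report CSV, a config snapshot and a stage log.  Every random
#' draw derives from the config seed, so a rerun with the same config is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `hmdm_run` with `summary` (data
#'   frame), `fits`, `mle_fits`, `warnings`, `sequences`, `split` and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("stage=start source=%s n_vehicles=%d seed=%d",
       config$observation_source, config$n_vehicles, config$seed)

  if (config$observation_source == "hmm") {
    seqdf <- generate_hmm_observations(config$truth, config$n_vehicles,
                                       config$zone_lengths,
                                       seed = config$seed * 13L)
    logf("stage=generate vehicles=%d records=%d",
         length(unique(seqdf$vehicle_id)), nrow(seqdf))
  } else {
    sim <- simulate_approach(config$truth, config$sim, config$n_vehicles,
                             seed = config$seed * 13L, rules = config$rules)
    logf("stage=simulate vehicles=%d crossings=%d",
         length(unique(sim$records$vehicle_id)), nrow(sim$records))
    kin <- kinematics_config(line_spacing = config$sim$line_spacing,
                             frames_per_second = config$sim$frames_per_second)
    tracks <- build_tracks(sim$records, kin,
                           cycle_length = config$sim$cycle_length)
    ctx <- sim$context[, c("vehicle_id", "line_index", "queue", "signal",
                           "state")]
    tracks$state <- NULL  # ground-truth labels come from the simulator
    tracks <- merge(tracks, ctx, by = c("vehicle_id", "line_index"),
                    sort = FALSE)
    tracks <- tracks[order(tracks$vehicle_id, tracks$time_s), , drop = FALSE]
    seqdf <- tracks_to_sequences(tracks, config$rules, config$boundaries,
                                 spacing = config$sim$line_spacing)
    logf("stage=kinematics vehicles=%d symbols=%d",
         length(unique(seqdf$vehicle_id)), nrow(seqdf))
  }

  split <- split_train_validation(seqdf, config$train_fraction,
                                  seed = config$seed * 17L)
  logf("stage=split train_records=%d validation_records=%d",
       split$n_train, split$n_validation)

  zones <- c("1", "2", "3", "whole")
  fits <- list(); mle_fits <- list()
  summary_rows <- list()
  for (zi in seq_along(zones)) {
    z <- zones[zi]
    ztrain <- zone_sequence_lists(split$train,
                                  if (z == "whole") "whole" else
                                    as.integer(z))
    zvalid <- zone_sequence_lists(split$validation,
                                  if (z == "whole") "whole" else
                                    as.integer(z))
    ctrl <- config$fit
    ctrl$seed <- config$seed * 101L + zi
    fit <- hmdm(ztrain$symbols, n_states = 4L, n_symbols = 81L,
                control = ctrl, supervised = FALSE)
    fits[[z]] <- fit
    mle <- hmdm(zvalid$symbols, states = zvalid$states, n_states = 4L,
                n_symbols = 81L)
    mle_fits[[z]] <- mle
    aligned <- align_states(fit, mle)
    m <- mape(aligned, mle, config$mape_min_reference)
    fits[[z]] <- fit <- aligned
    summary_rows[[z]] <- data.frame(
      zone = z,
      n_train = sum(lengths(ztrain$symbols)),
      n_validation = sum(lengths(zvalid$symbols)),
      loglik = fit$logLik,
      stability_2norm = stability_2norm(fit$B, config$norm_type),
      risk_index = risk_index(fit$B, config$dangerous,
                              config$risk_variant),
      mape_pct = m)
    write_hmdm_json(fit, file.path(config$out_dir,
                                   sprintf("params_zone_%s.json", z)))
    logf("stage=train zone=%s iters=%d loglik=%.4f mape=%.2f",
         z, fit$iterations, fit$logLik, m)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  warn <- do.call(rbind, lapply(c("1", "2", "3"), function(z) {
    sub <- split$validation[split$validation$zone == as.integer(z), ,
                            drop = FALSE]
    if (!nrow(sub)) return(NULL)
    w <- warning_report(fits[[z]], sub, config$dangerous)
    if (nrow(w)) w$zone <- as.integer(z)
    w
  }))
  if (is.null(warn)) warn <- warning_report(fits[["whole"]],
                                            split$validation[0, ],
                                            config$dangerous)
  logf("stage=predict warnings=%d severe=%d", nrow(warn), sum(warn$severe))

  write.csv(summary, file.path(config$out_dir, "summary.csv"),
            row.names = FALSE)
  write.csv(warn, file.path(config$out_dir, "warnings.csv"),
            row.names = FALSE)
  snapshot <- config
  snapshot$truth <- NULL
  jsonlite::write_json(
    lapply(snapshot[c("train_fraction", "n_vehicles", "observation_source",
                      "norm_type", "risk_variant", "mape_min_reference",
                      "seed")], identity),
    file.path(config$out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  logf("stage=done")

  invisible(structure(list(summary = summary, fits = fits,
                           mle_fits = mle_fits, warnings = warn,
                           sequences = seqdf, split = split,
                           out_dir = config$out_dir),
                      class = "hmdm_run"))
}

#' @export
print.hmdm_run <- function(x, ...) {
  cat("Hidden Markov driving model pipeline run\n")
  cat(sprintf("  output: %s\n", x$out_dir))
  cat(sprintf("  %d warnings (%d severe)\n\n", nrow(x$warnings),
              sum(x$warnings$severe)))
  print(x$summary, digits = 4)
  invisible(x)
}
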