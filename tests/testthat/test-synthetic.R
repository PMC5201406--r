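test_that("the ground-truth fixture is valid and risk-loaded in zone 2", {
  truth <- default_ground_truth()
  zones <- c("1", "2", "3", "whole")
  expect_identical(names(truth$A_by_zone), zones)
  expect_equal(sum(truth$pi), 1, tolerance = 1e-9)
  for (z in zones) {
    expect_equal(rowSums(truth$A_by_zone[[z]]), setNames(rep(1, 4),
                                                         hmdm_states()),
                 tolerance = 1e-9)
    expect_equal(unname(rowSums(truth$B_by_zone[[z]])), rep(1, 4),
                 tolerance = 1e-9)
    expect_true(all(truth$A_by_zone[[z]] >= 0) &&
                  all(truth$B_by_zone[[z]] >= 0))
  }
  risks <- sapply(c("1", "2", "3"), function(z)
    risk_index(truth$B_by_zone[[z]]))
  norms <- sapply(c("1", "2", "3"), function(z)
    stability_2norm(truth$B_by_zone[[z]]))
  # dilemma zone: riskiest and least stable; far zone: safest
  expect_identical(names(which.max(risks)), "2")
  expect_lt(risks[["3"]], risks[["1"]])
  expect_identical(names(which.min(norms)), "2")
  # fixture is a constant
  expect_identical(default_ground_truth(), truth)
})

test_that("hmm sampling is seed-deterministic and respects absorbing chains", {
  truth <- default_ground_truth()
  s1 <- sample_hmm_sequences(truth, 2, 5, 10, seed = 99)
  s2 <- sample_hmm_sequences(truth, 2, 5, 10, seed = 99)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 50L)
  expect_error(sample_hmm_sequences(truth, 5, 2, 2), "unknown zone")
  # absorbing chain pinned at state 0 emits only state-0 labels
  absorbing <- make_truth(c(1, 0, 0, 0),
                          diag(4),
                          rdirichlet_mat(4, 81))
  sa <- sample_hmm_sequences(absorbing, 1, 4, 25, seed = 1)
  expect_true(all(sa$state == 0L))
})

test_that("sampled transition frequencies converge to the truth matrix", {
  truth <- default_ground_truth()
  s <- sample_hmm_sequences(truth, 3, n_sequences = 2000, length = 50,
                            seed = 5)
  A <- truth$A_by_zone[["3"]]
  counts <- matrix(0, 4, 4)
  for (v in split(s$state, s$vehicle_id)) {
    from <- v[-length(v)] + 1L; to <- v[-1] + 1L
    counts <- counts + unclass(table(factor(from, 1:4), factor(to, 1:4)))
  }
  emp <- counts / rowSums(counts)
  expect_lt(max(abs(emp - A)), 0.02)
})

test_that("sampled symbol frequencies match the emission rows (chi-square)", {
  truth <- default_ground_truth()
  s <- sample_hmm_sequences(truth, 2, n_sequences = 250, length = 44,
                            seed = 12)
  B <- truth$B_by_zone[["2"]]
  st <- 2  # maintain; well populated under this chain
  sym <- s$symbol[s$state == st]
  expect_gt(length(sym), 1e3)
  p <- B[st + 1, ]
  # condition on the well-populated cells to keep the chi-square valid
  big <- which(p * length(sym) >= 5)
  obs <- tabulate(sym, 81)[big]
  pval <- stats::chisq.test(obs, p = p[big] / sum(p[big]))$p.value
  expect_gt(pval, 0.01)
})

test_that("a maintain-state vehicle crosses lines at the uniform-motion rate", {
  maintain_truth <- make_truth(
    c(0, 0, 1, 0),
    matrix(c(0, 0, 1, 0), 4, 4, byrow = TRUE),
    default_ground_truth()$B_by_zone[["3"]])
  cfg <- sim_config(arrival_rate = 36000, entry_speed_range = c(10, 10))
  sim <- simulate_approach(maintain_truth, cfg, n_vehicles = 1, seed = 4)
  f <- sim$records$frame_index
  gaps <- diff(f)
  # 2.92 m at 10 m/s = 0.292 s = 8.76 frames, rounded to 8 or 9
  expect_true(all(gaps %in% c(8L, 9L)))
  expect_lt(abs(mean(gaps) - 8.76), 0.15)
  expect_identical(nrow(sim$records), 47L)  # lines 46 down to 0
})

test_that("simulated trajectories satisfy the physical invariants", {
  truth <- default_ground_truth()
  sim <- simulate_approach(truth, sim_config(), n_vehicles = 12, seed = 21)
  # frame indices strictly increasing per vehicle
  for (v in split(sim$records$frame_index, sim$records$vehicle_id))
    expect_true(all(diff(v) > 0))
  # no negative speeds; distance travelled never increases
  expect_true(all(sim$context$speed_ms >= 0))
  for (v in split(sim$context$distance_m, sim$context$vehicle_id))
    expect_true(all(diff(v) < 0))
  # determinism
  sim2 <- simulate_approach(truth, sim_config(), n_vehicles = 12, seed = 21)
  expect_identical(sim, sim2)
})

test_that("followers never overtake a leader held at the stop line", {
  truth <- default_ground_truth()
  # signal is effectively always red after 2 s: leader must stop at the line
  cfg <- sim_config(cycle_length = 1000, green_time = 1, yellow_time = 1,
                    arrival_rate = 36000, entry_speed_range = c(12, 12))
  sim <- simulate_approach(truth, cfg, n_vehicles = 2, seed = 3,
                           max_time = 60)
  ctx <- sim$context
  lead <- ctx[ctx$vehicle_id == 1, ]
  foll <- ctx[ctx$vehicle_id == 2, ]
  expect_gt(nrow(lead), 0)
  expect_gt(nrow(foll), 0)
  # at every shared line the leader passes first
  shared <- intersect(lead$line_index, foll$line_index)
  lt <- lead$time_s[match(shared, lead$line_index)]
  ft <- foll$time_s[match(shared, foll$line_index)]
  expect_true(all(lt < ft))
  # the follower halts upstream of the leader's final position
  expect_gt(min(foll$distance_m), min(lead$distance_m))
})

test_that("exact-kinematics sequences carry consistent zones and symbols", {
  truth <- default_ground_truth()
  sim <- simulate_approach(truth, sim_config(), n_vehicles = 8, seed = 14)
  s <- sim$sequences
  expect_true(all(s$zone %in% 1:3))
  expect_true(all(s$symbol >= 1 & s$symbol <= 81))
  expect_true(all(s$state %in% 0:3))
  # per vehicle, t indexes contiguously from 1
  for (v in split(s$t, s$vehicle_id))
    expect_identical(v, seq_along(v))
})
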