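test_that("config validation enforces the stated invariants", {
  expect_error(synthetic_config(theta_open = 90, theta_closed = 90), "differ")
  expect_error(synthetic_config(noise_sigma = -1), "noise_sigma")
  expect_error(synthetic_config(n_runs = 0), "n_runs")
  expect_error(synthetic_config(n_residues = 100), "beyond n_residues")
  expect_error(synthetic_config(event_schedule = data.frame(
    run = 1L, time_ps = 60000, direction = "opening")), "inside the run")
  expect_error(synthetic_config(event_schedule = data.frame(
    run = 5L, time_ps = 100, direction = "opening")), "outside 1..n_runs")
  expect_error(generate_trajectory(synthetic_config(
    run_length_ns = 1, start_state = "open",
    event_schedule = data.frame(run = 1L, time_ps = 500,
                                direction = "opening"))),
    "already open")
})

test_that("toy references encode the open/closed geometry and omega isomer", {
  for (iso in c("cis", "trans")) {
    toy <- make_toy_protein(synthetic_config(omega16 = iso, seed = 30))
    part <- domain_partition()
    expect_gt(interdomain_distance(toy$open_ref, part),
              interdomain_distance(toy$closed_ref, part))
    for (ref in list(toy$open_ref, toy$closed_ref)) {
      rec <- suppressWarnings(omega_angles(ref))
      expect_equal(rec$isomer[rec$residue_index == 16L], iso)
    }
  }
  # chain spacing ~3.8 A between consecutive Calpha (outside the grafted bond)
  toy <- make_toy_protein(synthetic_config(seed = 30))
  ca <- flytrap:::ca_coords(toy$open_ref)
  gaps <- sqrt(rowSums(diff(ca$xyz)^2))
  expect_true(all(gaps[-(14:16)] > 3.7 & gaps[-(14:16)] < 3.9))
})

test_that("generation is deterministic and noise-free frames equal the reference", {
  cfg <- synthetic_config(n_runs = 2, run_length_ns = 0.2, seed = 31)
  a <- generate_trajectory(cfg)
  b <- generate_trajectory(cfg)
  expect_identical(a$trajectories[[2]]$coords, b$trajectories[[2]]$coords)
  quiet <- generate_trajectory(synthetic_config(
    run_length_ns = 0.2, noise_sigma = 0, start_state = "open", seed = 32))
  for (f in seq_len(n_frames(quiet$trajectories[[1]]))) {
    expect_equal(quiet$trajectories[[1]]$coords[, , f], quiet$open_ref$xyz,
                 tolerance = 1e-12)
  }
})

test_that("ground-truth hinge angle is recovered by the measured angle", {
  cfg <- synthetic_config(n_runs = 2, run_length_ns = 5, noise_sigma = 0.5,
                          seed = 33, event_schedule = data.frame(
                            run = 1:2, time_ps = c(2000, 3000),
                            direction = "opening"))
  res <- generate_trajectory(cfg)
  part <- domain_partition()
  for (r in 1:2) {
    measured <- vapply(seq_len(n_frames(res$trajectories[[r]])), function(f) {
      interdomain_angle(get_frame(res$trajectories[[r]], f), part)
    }, numeric(1))
    expect_gt(cor(measured, res$truth$true_angle[[r]]), 0.95)
  }
})

test_that("a scheduled closing produces the expected metric and score response", {
  cfg <- synthetic_config(run_length_ns = 4, start_state = "open", seed = 34,
                          event_schedule = data.frame(
                            run = 1L, time_ps = 2000, direction = "closing"))
  res <- generate_trajectory(cfg)
  tr <- res$trajectories[[1]]
  part <- domain_partition()
  d <- vapply(seq_len(n_frames(tr)), function(f) {
    interdomain_distance(get_frame(tr, f), part)
  }, numeric(1))
  sm <- flytrap:::smooth_series(d, 25)
  # monotone decrease across the transition window (frames 75..125)
  expect_true(all(diff(sm[75:125]) < 0))
  ss <- similarity_series(tr, res$open_ref, res$closed_ref)
  expect_true(all(ss$q_open[1:20] > ss$q_closed[1:20]))
  expect_true(all(ss$q_closed[181:200] > ss$q_open[181:200]))
})

test_that("benchmark_suite emits the eight conditions with consistent rosters", {
  suite <- benchmark_suite(seed = 35, n_runs = 1, run_length_ns = 2)
  expect_length(suite, 8L)
  expect_setequal(
    names(suite),
    c("open_empty_cis", "closed_empty_cis", "open_holo_cis", "closed_holo_cis",
      "open_empty_trans", "closed_empty_trans", "open_holo_trans",
      "closed_holo_trans"))
  for (fx in suite) {
    roster <- fx$trajectories[[1]]$atoms
    expect_identical(roster, fx$open_ref$atoms)
    expect_identical(roster, fx$closed_ref$atoms)
    is_holo <- grepl("holo", fx$name)
    expect_equal("LIG" %in% roster$residue_name, is_holo)
    n_events <- sum(vapply(fx$truth$events, nrow, 1L))
    if (grepl("trans", fx$name)) expect_gt(n_events, 0L) else expect_equal(n_events, 0L)
  }
  # trans fixtures: scheduled transitions are recovered end to end
  fx <- suite$closed_empty_trans
  ss <- similarity_series(fx$trajectories[[1]], fx$open_ref, fx$closed_ref)
  cx <- detect_crossovers(ss$q_open, ss$q_closed, min_sustain_frames = 25)
  expect_equal(nrow(cx), 1L)
  expect_equal(cx$new_dominant, "open")
})

test_that("evaluate_detection scores matches, misses and spurious calls", {
  truth <- structure(list(events = list(
    data.frame(frame = c(100L, 300L), direction = "opening"),
    data.frame(frame = integer(), direction = character())),
    true_angle = list(numeric(), numeric())), class = "GroundTruth")
  det <- data.frame(frame = c(105L, 680L), new_dominant = "open", run = c(1L, 2L))
  ev <- evaluate_detection(truth, det, run_lengths = c(500L, 500L), tol_frames = 25)
  expect_equal(ev$n_true, 2L)
  expect_equal(ev$n_matched, 1L)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$n_spurious, 1L)
  expect_equal(ev$frame_errors, 5)
})
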