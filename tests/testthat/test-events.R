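# Build a MetricSeries bundle from plain vectors (one or more runs).
vector_bundle <- function(..., interval = 20) {
  runs <- list(...)
  tables <- lapply(seq_along(runs), function(r) {
    cols <- runs[[r]]
    df <- data.frame(run_id = sprintf("run%02d", r),
                     frame = seq_along(cols[[1]]),
                     time_ps = seq_along(cols[[1]]) * interval,
                     stringsAsFactors = FALSE)
    for (nm in names(cols)) df[[nm]] <- cols[[nm]]
    df
  })
  bundle_runs(tables, interval)
}

test_that("endpoint summaries pool the stated sample counts", {
  one_run <- vector_bundle(list(distance = rep(30, 2500)))
  es <- endpoint_summary(one_run, "distance")
  expect_equal(es$initial$n_values, 250L)   # 5 ns / 20 ps per run
  expect_equal(es$final$n_values, 250L)
  expect_equal(unname(es$initial$quartiles), rep(30, 3))
  expect_equal(unname(es$final$whiskers), c(30, 30))

  ten <- do.call(vector_bundle, rep(list(list(distance = rnorm(2500, 30))), 10))
  es10 <- endpoint_summary(ten, "distance")
  expect_equal(es10$initial$n_values, 2500L)
  expect_equal(es10$final$n_values, 2500L)
  expect_true(all(diff(c(es10$initial$whiskers[["min"]],
                         es10$initial$quartiles,
                         es10$initial$whiskers[["max"]])) >= 0))
  short <- vector_bundle(list(distance = rep(1, 100)))
  expect_error(endpoint_summary(short, "distance"), "shorter than two")
  expect_error(endpoint_summary(one_run, "nope"), "unknown metric")
})

test_that("endpoint summaries are permutation-invariant within windows", {
  set.seed(20)
  v <- rnorm(2500)
  b1 <- vector_bundle(list(distance = v))
  v2 <- v
  v2[1:250] <- sample(v2[1:250])
  v2[2251:2500] <- sample(v2[2251:2500])
  b2 <- vector_bundle(list(distance = v2))
  expect_equal(endpoint_summary(b1, "distance"), endpoint_summary(b2, "distance"))
})

test_that("detect_crossovers finds sustained sign changes only", {
  expect_equal(nrow(detect_crossovers(rep(0.6, 500), rep(0.8, 500))), 0L)
  # constructed step: delta +0.2 then -0.2
  q_closed <- c(rep(0.8, 500), rep(0.6, 500))
  q_open <- c(rep(0.6, 500), rep(0.8, 500))
  cx <- detect_crossovers(q_open, q_closed)
  expect_equal(nrow(cx), 1L)
  expect_equal(cx$new_dominant, "open")
  expect_lte(abs(cx$frame - 501L), 13L)  # within half the smoothing window
  # a blip shorter than the sustain threshold is not a crossover
  blip <- rep(0.8, 500); blip[200:220] <- 0.55
  expect_equal(nrow(detect_crossovers(rep(0.6, 500), blip,
                                      smooth_window_frames = 1)), 0L)
  expect_error(detect_crossovers(1:5 / 10, 1:4 / 10), "length mismatch")
  expect_error(detect_crossovers(rep(0.5, 10), rep(0.6, 10),
                                 smooth_window_frames = 10), "shorter")
})

test_that("crossovers mirror under time reversal and respect run boundaries", {
  q_closed <- c(rep(0.8, 300), rep(0.6, 700))
  q_open <- c(rep(0.6, 300), rep(0.8, 700))
  f_fwd <- detect_crossovers(q_open, q_closed)$frame
  f_rev <- detect_crossovers(rev(q_open), rev(q_closed))$frame
  expect_equal(length(f_fwd), 1L)
  expect_equal(length(f_rev), 1L)
  expect_lte(abs((1000 - f_fwd + 2) - f_rev), 1L)
  # step exactly at a run boundary: each run is internally constant -> no call
  cx <- detect_crossovers(q_open, q_closed, run_boundaries = 301L)
  expect_equal(nrow(cx), 0L)
})

test_that("score_concurrency recognizes the peak/valley patterns", {
  set.seed(21)
  n <- 1000
  base <- function() rnorm(n, sd = 0.05)
  gauss <- function(center, amp, width = 20) amp * exp(-((seq_len(n) - center)^2) / (2 * width^2))
  # opening: peaks in all five metrics at the crossover
  opening <- vector_bundle(list(
    distance = 30 + base() + gauss(500, 5),
    angle = 100 + base() + gauss(500, 12),
    rmsd = 2 + base() + gauss(500, 3),
    rg = 17 + base() + gauss(500, 2),
    sas = 3000 + 10 * base() + gauss(500, 150)))
  call <- score_concurrency(list(frame = 500L, new_dominant = "open", run = 1L),
                            opening)
  expect_s3_class(call, "EventCall")
  expect_equal(call$direction, "opening")
  expect_setequal(call$supporting_metrics, c("distance", "angle", "rmsd", "rg", "sas"))
  expect_true(call$sustained)
  # closure: valleys in distance/angle/rg/sas, peak in rmsd
  closing <- vector_bundle(list(
    distance = 30 + base() - gauss(500, 5),
    angle = 100 + base() - gauss(500, 12),
    rmsd = 2 + base() + gauss(500, 3),
    rg = 17 + base() - gauss(500, 2),
    sas = 3000 + 10 * base() - gauss(500, 150)))
  call2 <- score_concurrency(list(frame = 500L, new_dominant = "closed", run = 1L),
                             closing)
  expect_equal(call2$direction, "closing")
  expect_setequal(call2$supporting_metrics, c("distance", "angle", "rmsd", "rg", "sas"))
  # flat metrics: unsupported call, never an error
  flat <- vector_bundle(list(distance = 30 + base(), angle = 100 + base(),
                             rmsd = 2 + base(), rg = 17 + base(),
                             sas = 3000 + base()))
  call3 <- score_concurrency(list(frame = 500L, new_dominant = "open", run = 1L),
                             flat)
  expect_equal(length(call3$supporting_metrics), 0L)
  expect_false(call3$sustained)
})

test_that("bundling records run boundaries and rejects mismatched runs", {
  b <- vector_bundle(list(distance = rep(1, 100)), list(distance = rep(2, 100)))
  expect_equal(b$run_boundaries, 101L)
  b1 <- vector_bundle(list(distance = rep(1, 100)))
  expect_equal(b1$run_boundaries, integer())
  expect_error(bundle_runs(list(data.frame(a = 1), data.frame(b = 2)), 20),
               "differing columns")
})

test_that("concatenate_runs computes per-run metrics with boundaries", {
  world <- tiny_world(seed = 22, n_runs = 2, run_length_ns = 0.4)
  bundle <- concatenate_runs(world$trajectories, open_ref = world$open_ref,
                             closed_ref = world$closed_ref,
                             metrics = c("distance", "q_sim_open", "q_sim_closed"),
                             sasa_points = 60)
  expect_equal(nrow(bundle$data), 40L)
  expect_equal(bundle$run_boundaries, 21L)
  expect_equal(unique(bundle$data$run_id), c("run01", "run02"))
  bad <- world$trajectories
  bad[[2]]$frame_interval_ps <- 10
  expect_error(concatenate_runs(bad, open_ref = world$open_ref,
                                closed_ref = world$closed_ref),
               "frame_interval_ps differs")
})

test_that("detect_events ties crossovers to concurrent metric changes", {
  # transient excursion: open at 1.6 ns, re-close at 2.4 ns of a 4 ns run,
  # so the geometric metrics show a plateau-peak against the closed baseline
  world <- tiny_world(seed = 23, run_length_ns = 4, schedule = data.frame(
    run = c(1L, 1L), time_ps = c(1600, 2400),
    direction = c("opening", "closing")))
  bundle <- concatenate_runs(world$trajectories, open_ref = world$open_ref,
                             closed_ref = world$closed_ref, sasa_points = 60)
  calls <- detect_events(bundle, min_sustain_frames = 25)
  expect_equal(length(calls), 2L)
  expect_equal(calls[[1]]$direction, "opening")
  expect_equal(calls[[2]]$direction, "closing")
  expect_lte(abs(calls[[1]]$crossover_frame - 80L), 25L)
  expect_true(all(c("distance", "angle") %in% calls[[1]]$supporting_metrics))
  expect_true(calls[[1]]$sustained)
})
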