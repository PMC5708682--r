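test_that("build_contacts honors cutoff boundary and separation", {
  s <- ca_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)))
  cs <- build_contacts(s, cutoff = 8, separation = 2)
  expect_equal(nrow(cs$pairs), 1L)
  expect_equal(unlist(cs$pairs[1, ]), c(i = 1, j = 3))
  expect_equal(cs$native_distances, 8)           # boundary inclusive
  expect_error(build_contacts(s, cutoff = 7.9), "no native contacts")
})

test_that("contact lists equal the exhaustive double-loop oracle", {
  set.seed(10)
  xyz <- matrix(rnorm(30, sd = 3), 10, 3)
  s <- ca_structure(xyz)
  cs <- build_contacts(s)
  orc <- oracle_contacts(xyz, 1:10)
  expect_equal(nrow(cs$pairs), nrow(orc))
  got <- cbind(cs$pairs$i, cs$pairs$j, cs$native_distances)
  got <- got[order(got[, 1], got[, 2]), ]
  orc <- orc[order(orc[, 1], orc[, 2]), ]
  expect_equal(unname(got), unname(orc), tolerance = 1e-12)
})

test_that("Q(NC) is 1 at identity, vanishes far away, and matches the oracle", {
  set.seed(11)
  for (n in c(5L, 12L, 20L)) {
    xyz <- matrix(rnorm(3 * n, sd = 3), n, 3)
    ref <- ca_structure(xyz)
    cs <- build_contacts(ref, cutoff = 12)
    expect_identical(q_nc(ref, cs), 1)
    frame <- ca_structure(xyz + matrix(rnorm(3 * n, sd = 1), n, 3))
    expect_equal(q_nc(frame, cs), oracle_qnc(frame$xyz, 1:n, cs),
                 tolerance = 1e-12)
    far <- ca_structure(xyz * 50)
    expect_lt(q_nc(far, cs), 1e-6)
    # printed prefactor mode: NC terms over (NC-1)(NC-2)
    nc <- nrow(cs$pairs)
    expect_equal(q_nc(ref, cs, normalization = "printed"),
                 nc / ((nc - 1) * (nc - 2)))
  }
})

test_that("q(similarity) is 1 at identity, symmetric, and matches the oracle", {
  set.seed(12)
  n <- 15L
  xyz <- matrix(rnorm(3 * n, sd = 3), n, 3)
  a <- ca_structure(xyz)
  b <- ca_structure(xyz + matrix(rnorm(3 * n, sd = 0.8), n, 3))
  expect_identical(q_similarity(a, a), 1)
  expect_equal(q_similarity(a, b), q_similarity(b, a), tolerance = 1e-12)
  expect_equal(q_similarity(b, a), oracle_qsim(b$xyz, a$xyz, 1:n),
               tolerance = 1e-12)
  mismatched <- ca_structure(xyz[-1, , drop = FALSE], residue_index = 2:n)
  expect_error(q_similarity(mismatched, a), "rosters differ")
})

test_that("both scores are rigid-motion invariant and decrease under dilation", {
  world <- tiny_world(seed = 13, run_length_ns = 0.2)
  ref <- world$open_ref
  cs <- build_contacts(ref)
  frame <- world$closed_ref
  q0 <- q_nc(frame, cs); qs0 <- q_similarity(frame, ref)
  set.seed(14)
  for (k in 1:3) {
    m <- rigid_move(frame)
    expect_equal(q_nc(m, cs), q0, tolerance = 1e-9)
    expect_equal(q_similarity(m, ref), qs0, tolerance = 1e-9)
  }
  scales <- c(1.02, 1.05, 1.1, 1.3)
  qv <- vapply(scales, function(sc) {
    scaled <- ref; scaled$xyz <- ref$xyz * sc
    q_nc(scaled, cs)
  }, numeric(1))
  expect_true(all(diff(c(1, qv)) < 0))
  qsv <- vapply(scales, function(sc) {
    scaled <- ref; scaled$xyz <- ref$xyz * sc
    q_similarity(scaled, ref)
  }, numeric(1))
  expect_true(all(diff(c(1, qsv)) < 0))
})

test_that("similarity_series scores frames against both references", {
  world <- tiny_world(seed = 15, run_length_ns = 0.2)
  ref_c <- world$closed_ref
  nfr <- 10L
  const <- new_trajectory(ref_c$atoms,
                          array(ref_c$xyz, c(nrow(ref_c$xyz), 3, nfr)), 20)
  ss <- similarity_series(const, world$open_ref, world$closed_ref)
  expect_equal(ss$q_closed, rep(1, nfr))
  expect_true(all(ss$q_open < 1))
  expect_equal(length(unique(round(ss$q_open, 12))), 1L)
  qn <- similarity_series(const, world$open_ref, world$closed_ref,
                          metric_kind = "Q_NC")
  expect_equal(qn$q_closed, rep(1, nfr))
  empty <- new_trajectory(ref_c$atoms,
                          array(0, c(nrow(ref_c$xyz), 3, 0)), 20)
  expect_error(similarity_series(empty, world$open_ref, world$closed_ref),
               "empty")
})

test_that("similarity series crosses over after a scheduled opening", {
  world <- tiny_world(seed = 16, run_length_ns = 2, schedule = data.frame(
    run = 1L, time_ps = 1000, direction = "opening"))
  ss <- similarity_series(world$trajectories[[1]], world$open_ref, world$closed_ref)
  expect_true(all(ss$q_closed[1:20] > ss$q_open[1:20]))
  expect_true(all(ss$q_open[81:100] > ss$q_closed[81:100]))
})

test_that("density_map bins, clips and conserves counts", {
  single <- density_map(0.7, 0.7)
  expect_equal(sum(single$counts), 1L)
  expect_equal(sum(single$counts > 0), 1L)
  expect_equal(single$log10[single$counts == 1L], log10(2))
  suppressMessages(clipped <- density_map(rep(0.2, 7), rep(0.2, 7)))
  expect_equal(sum(clipped$counts), 0L)
  expect_equal(clipped$n_dropped, 7L)
  set.seed(17)
  x <- runif(500, 0.3, 1.05); y <- runif(500, 0.3, 1.05)
  suppressMessages(dm <- density_map(x, y))
  kept <- sum(x >= 0.4 & x <= 1 & y >= 0.4 & y <= 1)
  expect_equal(sum(dm$counts), kept)
  expect_equal(dm$n_dropped, 500L - kept)
  expect_error(density_map(1:3 / 4, 1:2 / 4), "length mismatch")
})
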