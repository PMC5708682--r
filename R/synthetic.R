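# Synthetic two-domain hinge trajectories with ground-truth events.
#
# The generator emulates what the production MD supplies to the analysis: two
# rigid globular domains joined by a hinge, interconverting between an "open"
# and a "closed" reference geometry via scheduled logistic transitions, with
# isotropic Gaussian coordinate noise. It is a stand-in for physical
# simulation: metrics under test depend only on rigid-body geometry, so the
# domains are compact pseudo-Calpha random walks, not folded chains.

#' Configuration of the synthetic hinge-trajectory generator
#'
#' Defaults state the emulated world: a 238-residue PBP-like chain with the
#' canonical domain partition, 50-ns runs sampled every 20 ps, and 0.3 A
#' isotropic coordinate noise (a typical Calpha thermal fluctuation scale).
#'
#' @param n_residues chain length (default 238).
#' @param partition a [domain_partition()]; must fit within `n_residues`.
#' @param theta_open,theta_closed hinge angles of the two reference states,
#'   degrees (defaults 120 and 80: a 40-degree closure, the magnitude of a
#'   large PBP flytrap motion).
#' @param event_schedule data.frame with columns `run`, `time_ps`, `direction`
#'   (`"opening"`/`"closing"`); empty by default.
#' @param noise_sigma isotropic Gaussian noise per coordinate, Angstrom.
#' @param n_runs number of independent runs.
#' @param run_length_ns length of each run, ns.
#' @param frame_interval_ps frame spacing, ps (default 20).
#' @param seed RNG seed; every random choice derives from it.
#' @param omega16 isomer built into the residue 15-16 peptide bond
#'   (`"cis"` or `"trans"`).
#' @param start_state conformation each run starts in (`"closed"`/`"open"`).
#' @param transition_width_ps 10-90% width of the logistic transitions, ps.
#' @param ligand add a pseudo-atom ligand proxy (residue "LIG") in the cleft.
#' @return a validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_residues = 238, partition = domain_partition(),
                             theta_open = 120, theta_closed = 80,
                             event_schedule = NULL, noise_sigma = 0.3,
                             n_runs = 1, run_length_ns = 50,
                             frame_interval_ps = 20, seed = 42,
                             omega16 = c("cis", "trans"),
                             start_state = c("closed", "open"),
                             transition_width_ps = 500, ligand = FALSE) {
  omega16 <- match.arg(omega16)
  start_state <- match.arg(start_state)
  if (is.null(event_schedule)) {
    event_schedule <- data.frame(run = integer(), time_ps = numeric(),
                                 direction = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(event_schedule),
            all(c("run", "time_ps", "direction") %in% names(event_schedule)))
  if (theta_open == theta_closed) stop("theta_open and theta_closed must differ")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (max(unlist(partition)) > n_residues) {
    stop("partition references residues beyond n_residues")
  }
  if (nrow(event_schedule) > 0) {
    if (any(event_schedule$time_ps <= 0 |
            event_schedule$time_ps >= run_length_ns * 1000)) {
      stop("event times must fall strictly inside the run length")
    }
    if (any(event_schedule$run < 1 | event_schedule$run > n_runs)) {
      stop("event schedule references runs outside 1..n_runs")
    }
    if (!all(event_schedule$direction %in% c("opening", "closing"))) {
      stop("event direction must be 'opening' or 'closing'")
    }
  }
  structure(list(n_residues = as.integer(n_residues), partition = partition,
                 theta_open = theta_open, theta_closed = theta_closed,
                 event_schedule = event_schedule, noise_sigma = noise_sigma,
                 n_runs = as.integer(n_runs), run_length_ns = run_length_ns,
                 frame_interval_ps = frame_interval_ps, seed = as.integer(seed),
                 omega16 = omega16, start_state = start_state,
                 transition_width_ps = transition_width_ps, ligand = ligand),
            class = "SyntheticConfig")
}

.unit <- function(v) v / sqrt(sum(v^2))

.rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# NeRF-style placement: position of atom d given a-b-c, bond length |cd|,
# angle b-c-d (deg) and torsion a-b-c-d (deg).
.place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(c(
    (b - a)[2] * bc[3] - (b - a)[3] * bc[2],
    (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
    (b - a)[1] * bc[2] - (b - a)[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- c(-length * cos(ang),
               length * sin(ang) * cos(tor),
               length * sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Guided random walk: step 3.8 A toward a per-residue target with a seeded
# random component; keeps each domain a compact blob near its center.
.hinge_walk <- function(n_residues, targets) {
  pos <- matrix(0, n_residues, 3)
  pos[1, ] <- targets[1, ] + rnorm(3, sd = 2)
  for (i in 2:n_residues) {
    to_target <- targets[i, ] - pos[i - 1L, ]
    dist <- sqrt(sum(to_target^2))
    pull <- min(2.5, 0.3 + dist / 8)
    dir <- .unit(pull * .unit(to_target + 1e-9) + rnorm(3))
    pos[i, ] <- pos[i - 1L, ] + 3.8 * dir
  }
  pos
}

#' Build the open and closed toy reference structures
#'
#' A pseudo-Calpha chain (3.8 A spacing) folded into two compact domains joined
#' by hinge linkers near the origin; domain 1 sits along +x, domain 2 at the
#' open hinge angle in the xy-plane. The closed reference is the open one with
#' domain 2 rigidly rotated about the hinge (z) axis by
#' `theta_closed - theta_open`. Residues 15 and 16 carry N/CA/C backbone atoms
#' so the 15-16 peptide bond has the configured omega isomer. With
#' `ligand = TRUE` a pseudo-atom (residue "LIG") marks the inter-domain cleft.
#'
#' @param config a [synthetic_config()].
#' @return list with `open_ref` and `closed_ref` (`Structure`s) plus
#'   `domain2_atoms` (atom indices rotated by hinge motion).
#' @export
make_toy_protein <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  p <- config$partition
  n <- config$n_residues
  com_dist <- 22
  c1 <- c(com_dist, 0, 0)
  c2 <- com_dist * c(cos(config$theta_open * pi / 180),
                     sin(config$theta_open * pi / 180), 0)
  targets <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    targets[i, ] <- if (i %in% p$domain1) c1
    else if (i %in% p$domain2) c2
    else c(0, 0, 0)  # linkers hug the hinge
  }
  pos <- .hinge_walk(n, targets)

  # Graft an explicit peptide fragment for the 15-16 bond with the configured
  # omega, oriented along the walk direction at residue 15.
  omega <- if (config$omega16 == "cis") 0 else 180
  ca15 <- c(0, 0, 0)
  c15 <- c(1.52, 0, 0)
  n16 <- .place_atom(c(-0.5, 1.3, 0), ca15, c15, 1.33, 116, 180)
  ca16 <- .place_atom(ca15, c15, n16, 1.46, 122, omega)
  n15 <- c(-0.7, -1.2, 0)
  c16 <- .place_atom(c15, n16, ca16, 1.52, 111, if (omega == 0) -120 else 120)
  frag <- rbind(N15 = n15, CA15 = ca15, C15 = c15, N16 = n16, CA16 = ca16, C16 = c16)
  walk_dir <- .unit(pos[16, ] - pos[15, ])
  frag_dir <- .unit(ca16 - ca15)
  axis <- c(frag_dir[2] * walk_dir[3] - frag_dir[3] * walk_dir[2],
            frag_dir[3] * walk_dir[1] - frag_dir[1] * walk_dir[3],
            frag_dir[1] * walk_dir[2] - frag_dir[2] * walk_dir[1])
  sa <- sqrt(sum(axis^2)); caang <- sum(frag_dir * walk_dir)
  R <- if (sa < 1e-9) diag(3) * sign(caang) else {
    ax <- axis / sa
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    diag(3) + sa * K + (1 - caang) * (K %*% K)
  }
  frag <- sweep(frag %*% t(R), 2, -pos[15, ])  # rotate, then translate CA15 into place
  pos[16, ] <- frag["CA16", ]

  res_idx <- integer(); res_name <- character(); atom_name <- character()
  element <- character(); xyz <- NULL
  add <- function(ri, rn, an, el, p) {
    res_idx <<- c(res_idx, ri); res_name <<- c(res_name, rn)
    atom_name <<- c(atom_name, an); element <<- c(element, el)
    xyz <<- rbind(xyz, p)
  }
  for (i in seq_len(n)) {
    rn <- if (i == 16L) "PRO" else if (i == 15L) "ALA" else "GLY"
    if (i == 15L) {
      add(i, rn, "N", "N", frag["N15", ]); add(i, rn, "CA", "C", frag["CA15", ])
      add(i, rn, "C", "C", frag["C15", ])
    } else if (i == 16L) {
      add(i, rn, "N", "N", frag["N16", ]); add(i, rn, "CA", "C", frag["CA16", ])
      add(i, rn, "C", "C", frag["C16", ])
    } else {
      add(i, rn, "CA", "C", pos[i, ])
    }
  }
  if (config$ligand) add(n + 1L, "LIG", "C1", "C", (c1 + c2) / 2)
  atoms <- atom_table(res_idx, res_name, atom_name, element = element)
  open_ref <- new_structure(atoms, xyz, label = "toy_open")
  d2_atoms <- which(atoms$residue_index %in% config$partition$domain2)
  closed_xyz <- xyz
  closed_xyz[d2_atoms, ] <- xyz[d2_atoms, , drop = FALSE] %*%
    t(.rot_z(config$theta_closed - config$theta_open))
  closed_ref <- new_structure(atoms, closed_xyz, label = "toy_closed")
  list(open_ref = open_ref, closed_ref = closed_ref, domain2_atoms = d2_atoms)
}

# Per-frame hinge angle path for one run: start state plus logistic transitions.
.angle_path <- function(config, run, times_ps) {
  th <- c(open = config$theta_open, closed = config$theta_closed)
  state <- config$start_state
  angle <- rep(th[[state]], length(times_ps))
  sched <- config$event_schedule
  sched <- sched[sched$run == run, , drop = FALSE]
  if (nrow(sched) > 0) sched <- sched[order(sched$time_ps), , drop = FALSE]
  # logistic scale: 10-90% range of a logistic is ~4.394 scale units
  s <- config$transition_width_ps / 4.394
  events <- data.frame(frame = integer(), direction = character(),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(sched))) {
    target <- if (sched$direction[k] == "opening") "open" else "closed"
    if (target == state) {
      stop(sprintf("run %d: '%s' event scheduled while already %s",
                   run, sched$direction[k], target))
    }
    step <- th[[target]] - th[[state]]
    angle <- angle + step / (1 + exp(-(times_ps - sched$time_ps[k]) / s))
    state <- target
    events <- rbind(events, data.frame(
      frame = as.integer(round(sched$time_ps[k] / config$frame_interval_ps)),
      direction = sched$direction[k], stringsAsFactors = FALSE))
  }
  list(angle = angle, events = events)
}

#' Generate synthetic hinge trajectories with ground truth
#'
#' Per frame, the hinge angle follows the event schedule through logistic
#' transitions; domain 2 is rigidly rotated about the hinge axis accordingly and
#' isotropic Gaussian noise is added to every coordinate. Fully reproducible
#' from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `trajectories` (list of `Trajectory`, one per run),
#'   `truth` (a `GroundTruth` list: per-run `events` data.frame (frame,
#'   direction) and per-frame `true_angle`), `open_ref`, `closed_ref`.
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  toy <- make_toy_protein(config)  # seeds the RNG from config$seed
  tmpl <- toy$open_ref
  d2 <- toy$domain2_atoms
  n_atoms <- nrow(tmpl$atoms)
  n_fr <- as.integer(round(config$run_length_ns * 1000 / config$frame_interval_ps))
  if (n_fr < 1L) stop("run too short for the frame interval")
  times <- seq_len(n_fr) * config$frame_interval_ps
  trajectories <- vector("list", config$n_runs)
  truth <- list(events = vector("list", config$n_runs),
                true_angle = vector("list", config$n_runs))
  # Noise is applied per residue (one displacement per residue per frame), not
  # per atom: residues jitter as rigid units, so stiff internal geometry — in
  # particular the omega torsion of the grafted 15-16 peptide — is preserved.
  # Residues 15 and 16 share one noise group for the same reason.
  noise_group <- tmpl$atoms$residue_index
  noise_group[noise_group == 16L] <- 15L
  group_ids <- sort(unique(noise_group))
  group_of_atom <- match(noise_group, group_ids)
  n_grp <- length(group_ids)
  for (r in seq_len(config$n_runs)) {
    path <- .angle_path(config, r, times)
    coords <- array(0, dim = c(n_atoms, 3L, n_fr))
    noise <- if (config$noise_sigma > 0) {
      array(rnorm(n_grp * 3L * n_fr, sd = config$noise_sigma),
            dim = c(n_grp, 3L, n_fr))
    } else NULL
    for (f in seq_len(n_fr)) {
      xyz <- tmpl$xyz
      xyz[d2, ] <- xyz[d2, , drop = FALSE] %*%
        t(.rot_z(path$angle[f] - config$theta_open))
      if (!is.null(noise)) xyz <- xyz + noise[group_of_atom, , f]
      coords[, , f] <- xyz
    }
    trajectories[[r]] <- new_trajectory(tmpl$atoms, coords,
                                        config$frame_interval_ps,
                                        run_id = sprintf("run%02d", r))
    truth$events[[r]] <- path$events
    truth$true_angle[[r]] <- path$angle
  }
  class(truth) <- "GroundTruth"
  list(trajectories = trajectories, truth = truth,
       open_ref = toy$open_ref, closed_ref = toy$closed_ref)
}

#' Canonical event-detection benchmark configuration
#'
#' The package's fixed validation world: 10 runs of 50 ns at 20-ps sampling,
#' starting closed with trans Pro16, with 4 scheduled opening events (runs 2,
#' 5, 7 and 9 at 25 ns). Event recall and false-call rate on this benchmark are
#' the package's substitute for by-eye event counts on undeposited MD data.
#'
#' @param seed RNG seed.
#' @return a `SyntheticConfig`.
#' @export
synthetic_benchmark_config <- function(seed = 42) {
  synthetic_config(
    n_runs = 10, run_length_ns = 50, frame_interval_ps = 20,
    start_state = "closed", omega16 = "trans", seed = seed,
    event_schedule = data.frame(run = c(2L, 5L, 7L, 9L),
                                time_ps = rep(25000, 4),
                                direction = rep("opening", 4),
                                stringsAsFactors = FALSE))
}

#' Canonical fixture suite: the eight starting conditions
#'
#' Emits the four starting conditions of the emulated simulation design
#' (open/empty, open/with-ligand-proxy, closed/with-ligand-proxy, closed/empty)
#' crossed with cis/trans Pro16. Trans fixtures carry one scheduled transition
#' per run (opening from closed, closure from open); cis fixtures carry none —
#' the cis/trans behavioral difference encoded as a fixture property. Scale is
#' reduced (2 runs x 10 ns each) so the suite stays end-to-end testable in
#' seconds.
#'
#' @param seed RNG seed; each fixture derives its own sub-seed.
#' @param n_runs,run_length_ns per-fixture scale.
#' @return named list of 8 fixtures, each a [generate_trajectory()] result plus
#'   `name` and `config`.
#' @export
benchmark_suite <- function(seed = 42, n_runs = 2, run_length_ns = 10) {
  grid <- expand.grid(start = c("open", "closed"), ligand = c(FALSE, TRUE),
                      omega = c("cis", "trans"), stringsAsFactors = FALSE)
  out <- list()
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    sched <- if (g$omega == "trans") {
      data.frame(run = seq_len(n_runs),
                 time_ps = rep(run_length_ns * 500, n_runs),
                 direction = rep(if (g$start == "closed") "opening" else "closing",
                                 n_runs),
                 stringsAsFactors = FALSE)
    } else NULL
    cfg <- synthetic_config(start_state = g$start, ligand = g$ligand,
                            omega16 = g$omega, n_runs = n_runs,
                            run_length_ns = run_length_ns,
                            event_schedule = sched, seed = seed + k)
    nm <- sprintf("%s_%s_%s", g$start, if (g$ligand) "holo" else "empty", g$omega)
    res <- generate_trajectory(cfg)
    res$name <- nm
    res$config <- cfg
    out[[nm]] <- res
  }
  out
}

#' Match detected crossovers against ground-truth events
#'
#' Greedy per-run matching of detected crossovers to true events within a frame
#' tolerance; the scoring used by the event-recovery benchmark.
#'
#' @param truth `GroundTruth` from [generate_trajectory()].
#' @param crossovers data.frame from [detect_crossovers()] (global frames over
#'   the concatenated bundle).
#' @param run_lengths per-run frame counts (to map global frames to runs).
#' @param tol_frames match tolerance in frames.
#' @return list with `recall`, `n_true`, `n_detected`, `n_matched`,
#'   `n_spurious`, `frame_errors`.
#' @export
evaluate_detection <- function(truth, crossovers, run_lengths, tol_frames = 25) {
  offsets <- c(0L, cumsum(run_lengths))
  n_true <- 0L; n_matched <- 0L; errs <- numeric()
  used <- rep(FALSE, nrow(crossovers))
  for (r in seq_along(truth$events)) {
    ev <- truth$events[[r]]
    n_true <- n_true + nrow(ev)
    if (nrow(ev) == 0L) next
    in_run <- which(crossovers$run == r & !used)
    for (k in seq_len(nrow(ev))) {
      gf <- ev$frame[k] + offsets[r]
      if (length(in_run) == 0L) next
      d <- abs(crossovers$frame[in_run] - gf)
      best <- which.min(d)
      if (d[best] <= tol_frames) {
        n_matched <- n_matched + 1L
        errs <- c(errs, d[best])
        used[in_run[best]] <- TRUE
        in_run <- in_run[-best]
      }
    }
  }
  list(recall = if (n_true > 0L) n_matched / n_true else NA_real_,
       n_true = n_true, n_detected = nrow(crossovers), n_matched = n_matched,
       n_spurious = nrow(crossovers) - n_matched, frame_errors = errs)
}
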