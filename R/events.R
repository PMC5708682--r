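# Endpoint-window summaries and crossover-based event detection on concatenated runs.

.GEOM_METRICS <- c("distance", "angle", "rmsd", "rg", "sas")
.ALL_METRICS <- c("distance", "angle", "dihedral", "rmsd", "rg", "sas",
                  "q_nc_open", "q_nc_closed", "q_sim_open", "q_sim_closed")

#' Bundle per-run metric tables into a concatenated MetricSeries
#'
#' Rows are frames in run order; `run_boundaries` records the first frame index
#' of each run after the first, so that no smoothing, sustain window or event
#' call ever spans a junction between independent runs.
#'
#' @param tables list of per-run data.frames sharing columns (one row per
#'   frame; must include `run_id` and `time_ps`).
#' @param frame_interval_ps common frame interval, ps.
#' @return a `MetricSeries`: list with `data` (row-bound data.frame),
#'   `run_boundaries` (0-length for a single run), `frame_interval_ps`,
#'   `run_lengths`.
#' @export
bundle_runs <- function(tables, frame_interval_ps) {
  stopifnot(length(tables) >= 1L)
  cols <- lapply(tables, names)
  if (!all(vapply(cols, identical, TRUE, y = cols[[1]]))) {
    stop("per-run tables have differing columns")
  }
  lens <- vapply(tables, nrow, 1L)
  boundaries <- if (length(tables) > 1L) cumsum(lens)[-length(lens)] + 1L else integer()
  structure(list(data = do.call(rbind, tables),
                 run_boundaries = as.integer(boundaries),
                 run_lengths = lens,
                 frame_interval_ps = frame_interval_ps),
            class = "MetricSeries")
}

#' @export
print.MetricSeries <- function(x, ...) {
  cat(sprintf("<MetricSeries> %d frames in %d run(s), dt = %g ps\n",
              nrow(x$data), length(x$run_lengths), x$frame_interval_ps))
  invisible(x)
}

# Frame index ranges per run of a MetricSeries.
.run_ranges <- function(bundle) {
  ends <- cumsum(bundle$run_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(function(s, e) s:e, starts, ends)
}

#' Endpoint-window quartile/whisker summaries
#'
#' Pools, across all runs, the samples from the first and last `window_ns` of
#' each run (one sample per `sample_every_ps`) and summarizes each pool with
#' linear-interpolation quartiles and min/max whiskers — the box-and-whisker
#' bookkeeping used to compare a simulation's start against its end. With ten
#' 50-ns runs sampled every 20 ps and a 5-ns window, each pool holds exactly
#' 2,500 values.
#'
#' @param bundle a [bundle_runs()] `MetricSeries`.
#' @param metric column name of the metric to summarize.
#' @param window_ns endpoint window length, ns (default 5).
#' @param sample_every_ps sampling stride, ps (default 20).
#' @return list with elements `initial` and `final`, each an `EndpointSummary`
#'   list: `window`, `quartiles` (Q1, median, Q3), `whiskers` (min, max),
#'   `n_values`.
#' @export
endpoint_summary <- function(bundle, metric, window_ns = 5, sample_every_ps = 20) {
  if (!metric %in% names(bundle$data)) stop("unknown metric column: ", metric)
  w_frames <- round(window_ns * 1000 / bundle$frame_interval_ps)
  stride <- max(1L, round(sample_every_ps / bundle$frame_interval_ps))
  if (any(bundle$run_lengths < 2L * w_frames)) {
    stop("a run is shorter than two endpoint windows")
  }
  v <- bundle$data[[metric]]
  pool <- function(which_end) {
    unlist(lapply(.run_ranges(bundle), function(rng) {
      win <- if (which_end == "initial") rng[seq_len(w_frames)]
             else rng[(length(rng) - w_frames + 1L):length(rng)]
      v[win[seq(1L, length(win), by = stride)]]
    }))
  }
  summarize <- function(x, window) {
    q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
    list(window = window,
         quartiles = c(Q1 = q[1], median = q[2], Q3 = q[3]),
         whiskers = c(min = min(x), max = max(x)),
         n_values = length(x))
  }
  list(initial = summarize(pool("initial"), "initial"),
       final = summarize(pool("final"), "final"))
}

# Centered moving average; width forced odd; series ends use shrinking windows.
smooth_series <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L || length(x) < 2L) return(x)
  half <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect similarity crossovers between open and closed references
#'
#' A crossover marks a frame span where similarity to the non-dominant
#' reference overtakes similarity to the dominant one — the signature of an
#' opening or closure transition. The difference `q_closed - q_open` is
#' smoothed with a centered moving average, and a sign change is reported only
#' when the new sign persists for at least `min_sustain_frames`. Runs are
#' processed independently: no crossover spans a run boundary.
#'
#' @param q_open,q_closed equal-length per-frame score vectors.
#' @param smooth_window_frames centered moving-average width (default 25 frames
#'   = 0.5 ns at 20 ps).
#' @param min_sustain_frames minimum persistence of the new dominant reference
#'   (default 50 frames = 1 ns at 20 ps).
#' @param run_boundaries first frame index of each run after the first
#'   (as in [bundle_runs()]).
#' @return data.frame with columns `frame` (global index of the first frame of
#'   the new regime), `new_dominant` (`"open"`/`"closed"`), `run`.
#' @export
detect_crossovers <- function(q_open, q_closed, smooth_window_frames = 25,
                              min_sustain_frames = 50, run_boundaries = integer()) {
  if (length(q_open) != length(q_closed)) stop("series length mismatch")
  n <- length(q_open)
  if (smooth_window_frames >= n) stop("smoothing window must be shorter than the series")
  starts <- c(1L, as.integer(run_boundaries))
  ends <- c(starts[-1L] - 1L, n)
  out <- list()
  for (r in seq_along(starts)) {
    rng <- starts[r]:ends[r]
    delta <- smooth_series(q_closed[rng] - q_open[rng], smooth_window_frames)
    sgn <- sign(delta)
    # carry forward the previous sign through exact zeros
    for (k in seq_along(sgn)) if (sgn[k] == 0 && k > 1L) sgn[k] <- sgn[k - 1L]
    runs <- rle(sgn)
    pos <- cumsum(c(1L, runs$lengths))
    state <- runs$values[1]
    for (k in seq_along(runs$values)[-1]) {
      if (runs$values[k] != state && runs$lengths[k] >= min_sustain_frames) {
        out[[length(out) + 1L]] <- data.frame(
          frame = rng[1] + pos[k] - 1L,
          new_dominant = if (runs$values[k] < 0) "open" else "closed",
          run = r, stringsAsFactors = FALSE)
        state <- runs$values[k]
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(frame = integer(), new_dominant = character(),
                      run = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Score multi-metric concurrency of a crossover
#'
#' Tests whether the geometric/descriptor metrics change concurrently with a
#' similarity crossover. For an opening event all five metrics (distance,
#' angle, RMSD, Rg, SAS) are expected to peak near the crossover; for a closure,
#' distance, angle, Rg and SAS show valleys while RMSD (measured from the
#' starting reference) still peaks. An extremum supports the call when its
#' prominence over the run's median exceeds `prominence_mads` times the run's
#' median absolute deviation. The dihedral is excluded: it has little
#' sensitivity to opening/closure.
#'
#' @param crossover one row of [detect_crossovers()] output (list or 1-row
#'   data.frame with `frame`, `new_dominant`, `run`).
#' @param bundle a `MetricSeries` whose data has the five metric columns.
#' @param window_frames half-width of the search window around the crossover
#'   (default 50 frames).
#' @param prominence_mads prominence threshold in run-MAD units (default 3).
#' @param min_metrics minimum supporting metrics for `sustained = TRUE`
#'   (default 3).
#' @param start_state conformation the run started in (`"closed"`/`"open"`);
#'   with the default `NULL`, the direction is taken from `new_dominant`
#'   (new dominant open = opening).
#' @return an `EventCall`: list with `direction`, `crossover_frame`, `run_id`,
#'   `supporting_metrics`, `sustained`.
#' @export
score_concurrency <- function(crossover, bundle, window_frames = 50,
                              prominence_mads = 3, min_metrics = 3,
                              start_state = NULL) {
  cf <- as.integer(crossover$frame)
  run <- as.integer(crossover$run)
  ranges <- .run_ranges(bundle)
  if (run < 1L || run > length(ranges)) stop("crossover run outside bundle")
  rng <- ranges[[run]]
  if (cf < rng[1] || cf > rng[length(rng)]) stop("crossover frame outside its run")
  direction <- if (identical(crossover$new_dominant, "open")) "opening" else "closing"
  win <- max(rng[1], cf - window_frames):min(rng[length(rng)], cf + window_frames)
  supporting <- character()
  for (m in .GEOM_METRICS) {
    if (!m %in% names(bundle$data)) next
    v <- bundle$data[[m]][rng]
    med <- stats::median(v)
    sigma <- stats::mad(v)
    if (!is.finite(sigma) || sigma == 0) next
    w <- bundle$data[[m]][win]
    expect_peak <- direction == "opening" || m == "rmsd"
    prominence <- if (expect_peak) max(w) - med else med - min(w)
    if (prominence > prominence_mads * sigma) supporting <- c(supporting, m)
  }
  structure(list(direction = direction, crossover_frame = cf,
                 run_id = as.character(run),
                 supporting_metrics = supporting,
                 sustained = length(supporting) >= min_metrics),
            class = "EventCall")
}

#' @export
print.EventCall <- function(x, ...) {
  cat(sprintf("<EventCall> %s at frame %d (run %s): %d supporting metric(s)%s\n",
              x$direction, x$crossover_frame, x$run_id,
              length(x$supporting_metrics),
              if (x$sustained) ", sustained" else ""))
  invisible(x)
}

#' Compute the ten per-frame metrics for one run
#'
#' Distance, angle and dihedral between domains; C-alpha RMSD to
#' `rmsd_reference`; heavy-atom Rg and Shrake-Rupley SASA; Q(NC) and
#' q(similarity) against both references. Frames are superposed on the
#' reference (heavy atoms by default) before RMSD; distance/angle/dihedral,
#' Rg, SASA, Q and q are superposition-invariant. Residues named in
#' `exclude_residue_names` (ligand proxies) are excluded from all metrics.
#'
#' @param trajectory a `Trajectory`.
#' @param open_ref,closed_ref reference `Structure`s.
#' @param partition a [domain_partition()].
#' @param rmsd_reference `"start"` (default: the run's starting reference,
#'   i.e. frame 1) or `"open"`/`"closed"`.
#' @param fit_atoms superposition atoms for RMSD (default `"heavy"`).
#' @param normalization score normalization (see [q_nc()]).
#' @param sasa_points sphere points per atom for the per-frame SASA
#'   (default 240; cheaper than the single-structure default, documented
#'   trade-off for long trajectories).
#' @param metrics subset of metric names to compute (default all ten).
#' @param exclude_residue_names residue names dropped before any metric.
#' @return data.frame with columns run_id, frame, time_ps and one column per
#'   requested metric.
#' @export
compute_metrics <- function(trajectory, open_ref, closed_ref,
                            partition = domain_partition(),
                            rmsd_reference = "start",
                            fit_atoms = "heavy",
                            normalization = "unit_identity",
                            sasa_points = 240,
                            metrics = .ALL_METRICS,
                            exclude_residue_names = "LIG") {
  metrics <- match.arg(metrics, .ALL_METRICS, several.ok = TRUE)
  keep <- !(trajectory$atoms$residue_name %in% exclude_residue_names)
  if (!all(keep)) {
    trajectory <- new_trajectory(trajectory$atoms[keep, , drop = FALSE],
                                 trajectory$coords[keep, , , drop = FALSE],
                                 trajectory$frame_interval_ps, trajectory$run_id)
  }
  strip <- function(s) {
    k <- !(s$atoms$residue_name %in% exclude_residue_names)
    if (all(k)) s else new_structure(s$atoms[k, , drop = FALSE],
                                     s$xyz[k, , drop = FALSE],
                                     s$label, s$model_number)
  }
  open_ref <- strip(open_ref); closed_ref <- strip(closed_ref)
  nf <- n_frames(trajectory)
  out <- data.frame(run_id = trajectory$run_id, frame = seq_len(nf),
                    time_ps = seq_len(nf) * trajectory$frame_interval_ps,
                    stringsAsFactors = FALSE)
  ref_for_rmsd <- switch(rmsd_reference,
                         start = get_frame(trajectory, 1L),
                         open = open_ref, closed = closed_ref,
                         stop("unknown rmsd_reference"))
  per_frame <- function(fun) vapply(seq_len(nf), function(k) fun(get_frame(trajectory, k)), numeric(1))
  for (m in metrics) {
    out[[m]] <- switch(
      m,
      distance = per_frame(function(s) interdomain_distance(s, partition)),
      angle = per_frame(function(s) interdomain_angle(s, partition)),
      dihedral = per_frame(function(s) interdomain_dihedral(s, partition)),
      rmsd = per_frame(function(s) rmsd(s, ref_for_rmsd, fit_atoms = fit_atoms,
                                        measure_atoms = "ca")),
      rg = per_frame(function(s) radius_of_gyration(s)),
      sas = per_frame(function(s) sasa(s, n_points = sasa_points)),
      q_nc_open = .series_engine(trajectory, open_ref, "Q_NC", normalization),
      q_nc_closed = .series_engine(trajectory, closed_ref, "Q_NC", normalization),
      q_sim_open = .series_engine(trajectory, open_ref, "q_similarity", normalization),
      q_sim_closed = .series_engine(trajectory, closed_ref, "q_similarity", normalization)
    )
  }
  out
}

#' Concatenate per-run metric tables for a set of trajectories
#'
#' Computes metrics run by run ([compute_metrics()]) and bundles them with run
#' boundaries recorded, so downstream smoothing and event detection never cross
#' a junction.
#'
#' @param trajectories list of `Trajectory` objects sharing roster and frame
#'   interval.
#' @param ... passed to [compute_metrics()].
#' @return a `MetricSeries` (see [bundle_runs()]).
#' @export
concatenate_runs <- function(trajectories, ...) {
  stopifnot(length(trajectories) >= 1L)
  ivals <- vapply(trajectories, function(t) t$frame_interval_ps, numeric(1))
  if (length(unique(ivals)) != 1L) stop("frame_interval_ps differs between runs")
  tables <- lapply(trajectories, compute_metrics, ...)
  bundle_runs(tables, ivals[1])
}

#' Detect and score conformational events on a concatenated bundle
#'
#' End-to-end: crossovers from the q(similarity) columns, each scored for
#' multi-metric concurrency.
#'
#' @param bundle a `MetricSeries` with `q_sim_open`/`q_sim_closed` columns.
#' @param smooth_window_frames,min_sustain_frames see [detect_crossovers()].
#' @param window_frames,prominence_mads,min_metrics see [score_concurrency()].
#' @return list of `EventCall`s.
#' @export
detect_events <- function(bundle, smooth_window_frames = 25,
                          min_sustain_frames = 50, window_frames = 50,
                          prominence_mads = 3, min_metrics = 3) {
  cx <- detect_crossovers(bundle$data$q_sim_open, bundle$data$q_sim_closed,
                          smooth_window_frames, min_sustain_frames,
                          bundle$run_boundaries)
  lapply(seq_len(nrow(cx)), function(k) {
    score_concurrency(cx[k, ], bundle, window_frames, prominence_mads, min_metrics)
  })
}
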