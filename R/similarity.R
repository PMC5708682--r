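# Native-contact sets and the Gaussian similarity scores Q(NC) and q(similarity).
#
# Both scores compare C-alpha inter-residue distances of a frame against a
# reference conformation with per-pair Gaussians of width sigma_ij = |i-j|^0.15
# (residue-index units). Q(NC) sums over the reference's native contacts
# (<= 8 A, |i-j| >= 2) with exponent denominator 2*sigma^2; q(similarity) sums
# over ALL pairs with |i-j| >= 2, no distance cutoff, denominator sigma^2.
#
# Normalization modes:
#   "unit_identity" (default): divide by the number of summed terms, so a frame
#     identical to the reference scores exactly 1 — consistent with reported
#     trajectory values of ~0.8-0.9.
#   "printed": the literal prefactors 1/((NC-1)(NC-2)) resp. 1/((n-1)(n-2)),
#     which do NOT give 1 at identity; kept selectable for comparability.

sigma_ij <- function(i, j) abs(i - j)^0.15

.all_pairs <- function(res, separation) {
  n <- length(res)
  i <- rep.int(seq_len(n), n)
  j <- rep(seq_len(n), each = n)
  keep <- j > i & (res[j] - res[i]) >= separation
  list(pi = i[keep], pj = j[keep])
}

#' Build the native-contact set of a reference structure
#'
#' All C-alpha pairs with sequence separation >= `separation` whose distance in
#' the reference is <= `cutoff` (boundary inclusive), with the native distances
#' stored.
#'
#' @param reference a `Structure` with one C-alpha per scored residue.
#' @param cutoff contact distance cutoff in Angstrom (default 8).
#' @param separation minimum residue-index separation j - i (default 2).
#' @param reference_label `"open"`, `"closed"` or free text.
#' @return a `ContactSet`: list with `pairs` (data.frame i, j),
#'   `native_distances`, `cutoff`, `separation`, `reference_label`,
#'   `residue_index` (the C-alpha roster it was built on).
#' @export
build_contacts <- function(reference, cutoff = 8.0, separation = 2,
                           reference_label = "") {
  ca <- ca_coords(reference)
  ap <- .all_pairs(ca$residue_index, separation)
  d <- cpp_pair_dists(ca$xyz, ap$pi - 1L, ap$pj - 1L)
  keep <- d <= cutoff
  if (!any(keep)) stop("no native contacts found at this cutoff")
  structure(list(
    pairs = data.frame(i = ca$residue_index[ap$pi[keep]],
                       j = ca$residue_index[ap$pj[keep]]),
    native_distances = d[keep],
    cutoff = cutoff, separation = as.integer(separation),
    reference_label = reference_label,
    residue_index = ca$residue_index), class = "ContactSet")
}

#' @export
print.ContactSet <- function(x, ...) {
  cat(sprintf("<ContactSet '%s'> %d contacts (cutoff %g A, separation >= %d)\n",
              x$reference_label, nrow(x$pairs), x$cutoff, x$separation))
  invisible(x)
}

#' Write a contact set as TSV
#' @param contacts a `ContactSet`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_contacts <- function(contacts, path) {
  df <- cbind(contacts$pairs, native_distance = contacts$native_distances)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Map a contact/pair list onto a frame's Calpha roster; returns 0-based indices.
.match_pairs_to_ca <- function(ca, i, j) {
  ai <- match(i, ca$residue_index)
  aj <- match(j, ca$residue_index)
  if (anyNA(ai) || anyNA(aj)) {
    missing <- c(i[is.na(ai)], j[is.na(aj)])[1]
    stop("frame lacks a C-alpha for residue ", missing)
  }
  list(ai = ai - 1L, aj = aj - 1L)
}

.normalize_score <- function(total, n_terms, normalization) {
  switch(normalization,
         unit_identity = total / n_terms,
         printed = total / ((n_terms - 1) * (n_terms - 2)),
         stop("unknown normalization: ", normalization))
}

#' Gaussian native-contact score Q(NC) of a frame
#'
#' Sum over the reference's native contacts of
#' exp\[-(r_nat - r_frame)^2 / (2 sigma_ij^2)\], sigma_ij = |i-j|^0.15.
#'
#' @param frame a `Structure` supplying a C-alpha for every contact residue.
#' @param contacts a [build_contacts()] result.
#' @param normalization `"unit_identity"` (default; 1.0 at identity) or
#'   `"printed"` (literal 1/((NC-1)(NC-2)) prefactor).
#' @return Q(NC) score.
#' @export
q_nc <- function(frame, contacts, normalization = c("unit_identity", "printed")) {
  normalization <- match.arg(normalization)
  ca <- ca_coords(frame)
  mp <- .match_pairs_to_ca(ca, contacts$pairs$i, contacts$pairs$j)
  d <- cpp_pair_dists(ca$xyz, mp$ai, mp$aj)
  sg <- sigma_ij(contacts$pairs$i, contacts$pairs$j)
  total <- sum(exp(-(contacts$native_distances - d)^2 / (2 * sg^2)))
  .normalize_score(total, nrow(contacts$pairs), normalization)
}

#' All-pair Gaussian similarity q(similarity) between two conformations
#'
#' Sum over all C-alpha pairs with sequence separation >= 2 (no distance
#' cutoff) of exp\[-(r_ref - r_frame)^2 / sigma_ij^2\]. Symmetric in its two
#' arguments; sensitive to domain motion where Q(NC) saturates.
#'
#' @param frame,reference `Structure`s sharing the C-alpha roster.
#' @param normalization as in [q_nc()].
#' @param separation minimum residue separation (default 2).
#' @return q(similarity) score.
#' @export
q_similarity <- function(frame, reference,
                         normalization = c("unit_identity", "printed"),
                         separation = 2) {
  normalization <- match.arg(normalization)
  car <- ca_coords(reference)
  caf <- ca_coords(frame)
  if (!identical(car$residue_index, caf$residue_index)) {
    stop("frame and reference C-alpha rosters differ")
  }
  ap <- .all_pairs(car$residue_index, separation)
  dr <- cpp_pair_dists(car$xyz, ap$pi - 1L, ap$pj - 1L)
  df <- cpp_pair_dists(caf$xyz, ap$pi - 1L, ap$pj - 1L)
  sg <- sigma_ij(car$residue_index[ap$pi], car$residue_index[ap$pj])
  total <- sum(exp(-(dr - df)^2 / sg^2))
  if (normalization == "unit_identity") total / length(ap$pi)
  else total / ((length(car$residue_index) - 1) * (length(car$residue_index) - 2))
}

# Per-frame series engine shared by similarity_series / compute_metrics.
# Returns the raw per-frame sums from the C++ kernel, already normalized.
.series_engine <- function(trajectory, ref_structure, metric_kind, normalization,
                           cutoff = 8.0, separation = 2, reference_label = "") {
  ca_ref <- ca_coords(ref_structure)
  ca_idx <- select_atoms(get_frame(trajectory, 1L), NULL, "ca")
  res_traj <- trajectory$atoms$residue_index[ca_idx]
  ord <- order(res_traj)
  ca_idx <- ca_idx[ord]; res_traj <- res_traj[ord]
  if (metric_kind == "Q_NC") {
    cs <- build_contacts(ref_structure, cutoff, separation, reference_label)
    ai <- match(cs$pairs$i, res_traj); aj <- match(cs$pairs$j, res_traj)
    if (anyNA(ai) || anyNA(aj)) stop("trajectory lacks a C-alpha for a contact residue")
    refd <- cs$native_distances
    sg <- sigma_ij(cs$pairs$i, cs$pairs$j)
    denom <- 2 * sg^2
    n_terms <- nrow(cs$pairs)
    norm_n <- n_terms
  } else {
    if (!identical(ca_ref$residue_index, res_traj)) {
      first_bad <- which(!(res_traj %in% ca_ref$residue_index) |
                           seq_along(res_traj) > length(ca_ref$residue_index))[1]
      stop("trajectory/reference C-alpha rosters differ",
           if (!is.na(first_bad)) paste0(" (first at residue ", res_traj[first_bad], ")"))
    }
    ap <- .all_pairs(ca_ref$residue_index, separation)
    ai <- ap$pi; aj <- ap$pj
    refd <- cpp_pair_dists(ca_ref$xyz, ai - 1L, aj - 1L)
    sg <- sigma_ij(ca_ref$residue_index[ai], ca_ref$residue_index[aj])
    denom <- sg^2
    n_terms <- length(ai)
    norm_n <- length(ca_ref$residue_index)
  }
  sub <- trajectory$coords[ca_idx, , , drop = FALSE]
  raw <- cpp_gauss_score_series(sub, ca_idx_map(ai), ca_idx_map(aj), refd, denom)
  if (normalization == "unit_identity") raw / n_terms
  else raw / ((norm_n - 1) * (norm_n - 2))
}

ca_idx_map <- function(i) as.integer(i - 1L)

#' Per-frame similarity series against open and closed references
#'
#' Scores every frame of a trajectory against both reference conformations with
#' either Q(NC) or q(similarity).
#'
#' @param trajectory a `Trajectory`.
#' @param open_ref,closed_ref reference `Structure`s.
#' @param metric_kind `"q_similarity"` (default) or `"Q_NC"`.
#' @param normalization as in [q_nc()].
#' @param cutoff,separation contact parameters (Q(NC) only uses `cutoff`).
#' @return a `SimilaritySeries`: list with per-frame `q_open`, `q_closed`,
#'   `metric_kind`, `normalization`, `frame_interval_ps`.
#' @export
similarity_series <- function(trajectory, open_ref, closed_ref,
                              metric_kind = c("q_similarity", "Q_NC"),
                              normalization = c("unit_identity", "printed"),
                              cutoff = 8.0, separation = 2) {
  metric_kind <- match.arg(metric_kind)
  normalization <- match.arg(normalization)
  if (n_frames(trajectory) == 0L) stop("empty trajectory")
  qo <- .series_engine(trajectory, open_ref, metric_kind, normalization,
                       cutoff, separation, "open")
  qc <- .series_engine(trajectory, closed_ref, metric_kind, normalization,
                       cutoff, separation, "closed")
  structure(list(q_open = qo, q_closed = qc, metric_kind = metric_kind,
                 normalization = normalization,
                 frame_interval_ps = trajectory$frame_interval_ps),
            class = "SimilaritySeries")
}

#' 2-D density map of paired score series
#'
#' Bins (x, y) score pairs on a square grid (default 100 x 100 over
#' \[0.4, 1\]^2) and reports log10(1 + count) per cell, the representation used
#' for Q(NC)_open vs Q(NC)_closed denaturation checks. Out-of-range points are
#' dropped and counted.
#'
#' @param series_x,series_y equal-length numeric vectors.
#' @param bins number of bins per axis.
#' @param range numeric length-2 inclusive range applied to both axes.
#' @return list with `counts` (bins x bins integer matrix, x rows), `log10`
#'   (log10(1+count)), `breaks`, `n_dropped`.
#' @export
density_map <- function(series_x, series_y, bins = 100, range = c(0.4, 1.0)) {
  if (length(series_x) != length(series_y)) stop("series length mismatch")
  ok <- series_x >= range[1] & series_x <= range[2] &
    series_y >= range[1] & series_y <= range[2] &
    is.finite(series_x) & is.finite(series_y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(sprintf("density_map: dropped %d out-of-range point(s)", n_dropped))
  }
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  bx <- pmin(pmax(findInterval(series_x[ok], breaks, rightmost.closed = TRUE), 1L), bins)
  by <- pmin(pmax(findInterval(series_y[ok], breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  if (any(ok)) {
    tab <- table(factor(bx, levels = seq_len(bins)), factor(by, levels = seq_len(bins)))
    counts <- matrix(as.integer(tab), bins, bins)
  }
  list(counts = counts, log10 = log10(1 + counts), breaks = breaks,
       n_dropped = n_dropped)
}

#' Write a density map matrix as TSV
#' @param map a [density_map()] result.
#' @param path output path.
#' @param layer `"log10"` or `"counts"`.
#' @return invisibly, `path`.
#' @export
write_density_map <- function(map, path, layer = c("log10", "counts")) {
  layer <- match.arg(layer)
  utils::write.table(map[[layer]], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
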