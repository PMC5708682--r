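# Radius of gyration, solvent-accessible surface area, omega-angle classification.

# van der Waals radii (Angstrom) used for SASA; overridable per call.
.DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                  SE = 1.90, H = 1.20)

#' Mass-weighted radius of gyration
#'
#' @param structure a `Structure`.
#' @param atom_filter `"heavy"` (default) or `"ca"`.
#' @param residue_set optional residue restriction.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(structure, atom_filter = c("heavy", "ca"),
                               residue_set = NULL) {
  atom_filter <- match.arg(atom_filter)
  idx <- select_atoms(structure, residue_set, atom_filter)
  if (length(idx) == 0L) stop("empty atom selection for Rg")
  m <- structure$atoms$mass[idx]
  xyz <- structure$xyz[idx, , drop = FALSE]
  com <- drop(crossprod(xyz, m)) / sum(m)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

# Deterministic golden-spiral unit-sphere point set.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the heavy atoms using a deterministic golden-spiral
#' point set, so results are bitwise reproducible for a given `n_points`.
#'
#' @param structure a `Structure`.
#' @param probe_radius probe radius in Angstrom (water: 1.4).
#' @param n_points sphere test points per atom; more points, finer area estimate.
#' @param radii named vector of van der Waals radii by element symbol; defaults
#'   to C 1.7, N 1.55, O 1.52, S 1.8 (P 1.8, Se 1.9, H 1.2).
#' @param per_atom return the per-atom area vector instead of the total.
#' @return total SASA in Angstrom^2 (or per-atom vector).
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                 radii = .DEFAULT_VDW, per_atom = FALSE) {
  idx <- select_atoms(structure, NULL, "heavy")
  if (length(idx) == 0L) stop("no heavy atoms for SASA")
  el <- structure$atoms$element[idx]
  r <- unname(radii[el])
  if (anyNA(r)) {
    stop("unknown element(s) for SASA radii: ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  }
  pts <- golden_spiral_points(n_points)
  a <- cpp_sasa(structure$xyz[idx, , drop = FALSE], r, probe_radius, pts)
  if (per_atom) a else sum(a)
}

#' Peptide-bond omega angles with cis/trans classification
#'
#' For each consecutive residue pair (i-1, i) with backbone atoms CA(i-1),
#' C(i-1), N(i), CA(i) present, computes the omega torsion and classifies it:
#' |omega| <= `cis_max` is "cis", |omega| >= `trans_min` is "trans", anything
#' between is "twisted". Bonds with missing backbone atoms are skipped (one
#' consolidated warning), not an error.
#'
#' @param structure a `Structure`.
#' @param cis_max,trans_min classification thresholds in degrees (defaults 30
#'   and 150, the conventional bands).
#' @return data.frame with columns `residue_index` (the C-terminal residue of
#'   the bond), `residue_name`, `omega_deg`, `isomer`.
#' @export
omega_angles <- function(structure, cis_max = 30, trans_min = 150) {
  a <- structure$atoms
  res <- sort(unique(a$residue_index))
  pick <- function(ri, nm) {
    i <- which(a$residue_index == ri & a$atom_name == nm)
    if (length(i) == 1L) structure$xyz[i, ] else NULL
  }
  out <- list(); skipped <- 0L
  for (k in seq_along(res)[-1]) {
    rp <- res[k - 1L]; ri <- res[k]
    if (ri != rp + 1L) next  # chain break
    ca0 <- pick(rp, "CA"); c0 <- pick(rp, "C")
    n1 <- pick(ri, "N"); ca1 <- pick(ri, "CA")
    if (is.null(ca0) || is.null(c0) || is.null(n1) || is.null(ca1)) {
      skipped <- skipped + 1L
      next
    }
    om <- torsion_angle(ca0, c0, n1, ca1)
    out[[length(out) + 1L]] <- data.frame(
      residue_index = ri,
      residue_name = a$residue_name[match(ri, a$residue_index)],
      omega_deg = om,
      isomer = classify_omega(om, cis_max, trans_min),
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L) {
    warning(sprintf("%d peptide bond(s) skipped: incomplete backbone", skipped))
  }
  if (length(out) == 0L) {
    return(data.frame(residue_index = integer(), residue_name = character(),
                      omega_deg = numeric(), isomer = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify an omega angle as cis, trans or twisted
#' @param omega_deg omega torsion in degrees.
#' @param cis_max,trans_min thresholds in degrees.
#' @return character vector of `"cis"`, `"trans"`, `"twisted"`.
#' @export
classify_omega <- function(omega_deg, cis_max = 30, trans_min = 150) {
  ifelse(abs(omega_deg) <= cis_max, "cis",
         ifelse(abs(omega_deg) >= trans_min, "trans", "twisted"))
}

#' Per-frame isomer state of one proline (or any residue)
#'
#' Tracks the omega angle of the peptide bond preceding `residue_index` across a
#' trajectory — the check that no spontaneous cis/trans isomerization occurred
#' during a run.
#'
#' @param trajectory a `Trajectory` whose roster includes backbone atoms
#'   CA(i-1), C(i-1), N(i), CA(i) for the tracked bond.
#' @param residue_index residue supplying N and CA (default 16, the conserved
#'   PBP binding-site proline).
#' @param cis_max,trans_min thresholds, degrees.
#' @return list with `isomer` (per-frame character), `omega_deg` (per-frame
#'   numeric), `stable` (TRUE when all frames agree) and, when unstable,
#'   `flip_frames` (frames whose label differs from frame 1's).
#' @export
check_proline_isomer <- function(trajectory, residue_index = 16,
                                 cis_max = 30, trans_min = 150) {
  nf <- n_frames(trajectory)
  if (nf == 0L) stop("empty trajectory")
  a <- trajectory$atoms
  need <- rbind(c(residue_index - 1L, "CA"), c(residue_index - 1L, "C"),
                c(residue_index, "N"), c(residue_index, "CA"))
  idx <- apply(need, 1, function(r) {
    i <- which(a$residue_index == as.integer(r[1]) & a$atom_name == r[2])
    if (length(i) != 1L) NA_integer_ else i
  })
  if (anyNA(idx)) {
    stop(sprintf("backbone atoms for omega(%d) absent from roster", residue_index))
  }
  om <- vapply(seq_len(nf), function(f) {
    x <- trajectory$coords[, , f]
    torsion_angle(x[idx[1], ], x[idx[2], ], x[idx[3], ], x[idx[4], ])
  }, numeric(1))
  iso <- classify_omega(om, cis_max, trans_min)
  stable <- length(unique(iso)) == 1L
  out <- list(isomer = iso, omega_deg = om, stable = stable)
  if (!stable) out$flip_frames <- which(iso != iso[1])
  out
}
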