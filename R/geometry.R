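# Superposition and inter-domain geometry metrics.

#' Mass-weighted center of mass of a residue selection
#'
#' @param structure a `Structure`.
#' @param residue_set integer residue indices; `NULL` selects all residues.
#' @param atom_filter `"heavy"` (default) or `"ca"`.
#' @return numeric length-3 position, Angstrom.
#' @export
center_of_mass <- function(structure, residue_set = NULL,
                           atom_filter = c("heavy", "ca")) {
  atom_filter <- match.arg(atom_filter)
  idx <- select_atoms(structure, residue_set, atom_filter)
  if (length(idx) == 0L) stop("empty atom selection for center of mass")
  m <- structure$atoms$mass[idx]
  drop(crossprod(structure$xyz[idx, , drop = FALSE], m)) / sum(m)
}

# Pair fit atoms of two structures 1:1 by (residue_index, atom_name).
.pair_fit_atoms <- function(mobile, reference, fit_atoms) {
  im <- select_atoms(mobile, NULL, fit_atoms)
  ir <- select_atoms(reference, NULL, fit_atoms)
  key <- function(s, idx) paste(s$atoms$residue_index[idx], s$atoms$atom_name[idx])
  km <- key(mobile, im); kr <- key(reference, ir)
  if (anyDuplicated(km) || anyDuplicated(kr)) {
    stop("duplicate (residue_index, atom_name) keys; cannot pair rosters")
  }
  common <- intersect(km, kr)
  if (length(common) < 3L) stop("fewer than 3 paired fit atoms")
  list(mobile = im[match(common, km)], reference = ir[match(common, kr)])
}

# Kabsch: optimal proper rotation via SVD of the covariance, reflection corrected.
.kabsch <- function(P, Q) {
  # P, Q: n x 3, already centered. Returns rotation R with min ||P %*% R - Q||.
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  s$u %*% D %*% t(s$v)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the mobile
#' structure's fit atoms onto the reference's, pairing atoms by
#' (residue_index, atom_name). Reflections are excluded.
#'
#' @param mobile,reference `Structure` objects sharing residue numbering.
#' @param fit_atoms `"heavy"` or `"ca"`.
#' @return a `SuperpositionResult`: list with `rotation` (3x3, det +1),
#'   `translation` (length 3, Angstrom), `rmsd_fit_atoms`, `n_fit_atoms`.
#'   The transform maps a mobile coordinate row-vector x to `x %*% rotation +
#'   translation`.
#' @export
superpose <- function(mobile, reference, fit_atoms = c("heavy", "ca")) {
  fit_atoms <- match.arg(fit_atoms)
  pr <- .pair_fit_atoms(mobile, reference, fit_atoms)
  P <- mobile$xyz[pr$mobile, , drop = FALSE]
  Q <- reference$xyz[pr$reference, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  R <- .kabsch(Pc, Qc)
  fitted <- Pc %*% R
  rmsd_val <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = drop(cq - cp %*% R),
                 rmsd_fit_atoms = rmsd_val, n_fit_atoms = nrow(P)),
            class = "SuperpositionResult")
}

#' Apply a rigid transform to a structure
#' @param structure a `Structure`.
#' @param sp a `SuperpositionResult` from [superpose()].
#' @return the transformed `Structure`.
#' @export
apply_superposition <- function(structure, sp) {
  structure$xyz <- sweep(structure$xyz %*% sp$rotation, 2, -sp$translation)
  structure
}

#' RMSD after superposition
#'
#' Superposes `mobile` onto `reference` over `fit_atoms`, then measures the
#' root-mean-square deviation over `measure_atoms` (C-alpha by default, the
#' convention for reporting open-vs-closed differences).
#'
#' @inheritParams superpose
#' @param measure_atoms `"ca"` or `"heavy"`.
#' @param residue_set optional residue restriction applied to both fit and
#'   measure selections.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(mobile, reference, fit_atoms = c("ca", "heavy"),
                 measure_atoms = "ca", residue_set = NULL) {
  fit_atoms <- match.arg(fit_atoms)
  if (!is.null(residue_set)) {
    mobile <- subset_residues(mobile, residue_set)
    reference <- subset_residues(reference, residue_set)
  }
  sp <- superpose(mobile, reference, fit_atoms)
  moved <- apply_superposition(mobile, sp)
  pr <- .pair_fit_atoms(moved, reference, measure_atoms)
  P <- moved$xyz[pr$mobile, , drop = FALSE]
  Q <- reference$xyz[pr$reference, , drop = FALSE]
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Restrict a structure to a residue set
#' @param structure a `Structure`.
#' @param residue_set integer residue indices to keep.
#' @return the restricted `Structure`.
#' @export
subset_residues <- function(structure, residue_set) {
  keep <- structure$atoms$residue_index %in% residue_set
  if (!any(keep)) stop("residue set not present in structure")
  new_structure(structure$atoms[keep, , drop = FALSE],
                structure$xyz[keep, , drop = FALSE],
                label = structure$label, model_number = structure$model_number)
}

#' Distance between the two domains' centers of mass
#'
#' @param structure a `Structure`.
#' @param partition a [domain_partition()].
#' @return Euclidean distance (heavy-atom COMs), Angstrom.
#' @export
interdomain_distance <- function(structure, partition = domain_partition()) {
  c1 <- center_of_mass(structure, partition$domain1)
  c2 <- center_of_mass(structure, partition$domain2)
  sqrt(sum((c1 - c2)^2))
}

#' Hinge angle subtended by the two domains
#'
#' Angle at the center of mass of the whole hinge (both linkers) between the two
#' domain centers of mass; range (0, 180] degrees.
#'
#' @inheritParams interdomain_distance
#' @return angle in degrees.
#' @export
interdomain_angle <- function(structure, partition = domain_partition()) {
  ch <- center_of_mass(structure, c(partition$linker1, partition$linker2))
  v1 <- center_of_mass(structure, partition$domain1) - ch
  v2 <- center_of_mass(structure, partition$domain2) - ch
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("degenerate (collocated) centers for angle")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Signed torsion over four points, degrees in (-180, 180]; IUPAC sign convention
# (cis = 0).
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) stop("degenerate torsion geometry")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2) / nb2, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Inter-domain dihedral angle
#'
#' Torsion over the four centers of mass
#' domain1 - linker1 - linker2 - domain2, signed, degrees in (-180, 180].
#'
#' @inheritParams interdomain_distance
#' @return dihedral angle in degrees.
#' @export
interdomain_dihedral <- function(structure, partition = domain_partition()) {
  torsion_angle(center_of_mass(structure, partition$domain1),
                center_of_mass(structure, partition$linker1),
                center_of_mass(structure, partition$linker2),
                center_of_mass(structure, partition$domain2))
}
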