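# Builders for tiny fixtures, constructed in code at test time.

# A Calpha-only structure from an n x 3 coordinate matrix.
ca_structure <- function(xyz, residue_index = seq_len(nrow(xyz)),
                         element = "C", label = "test") {
  n <- nrow(xyz)
  new_structure(atom_table(residue_index, rep("GLY", n), rep("CA", n),
                           element = rep(element, length.out = n)),
                xyz, label = label)
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Apply a rigid motion (random by default) to a Structure.
rigid_move <- function(s, R = random_rotation(), t = rnorm(3, sd = 20)) {
  s$xyz <- sweep(s$xyz %*% t(R), 2, -t)
  s
}

# Four-single-residue partition for hand-built geometry cases.
tiny_partition <- function() domain_partition(1L, 2L, 3L, 4L)

# Structure with one atom per residue at the four given points
# (domain1, domain2, linker1, linker2 order).
four_point_structure <- function(p_d1, p_d2, p_l1, p_l2) {
  ca_structure(rbind(p_d1, p_d2, p_l1, p_l2), residue_index = 1:4)
}

# Handcrafted PDB text: one ATOM line per row.
pdb_text <- function(xyz, residue_index = seq_len(nrow(xyz)),
                     atom_name = "CA", residue_name = "GLY", element = "C") {
  n <- nrow(xyz)
  atom_name <- rep(atom_name, length.out = n)
  residue_name <- rep(residue_name, length.out = n)
  element <- rep(element, length.out = n)
  vapply(seq_len(n), function(i) {
    nm <- if (nchar(atom_name[i]) < 4L) paste0(" ", atom_name[i]) else atom_name[i]
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, nm, residue_name[i], residue_index[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3], element[i])
  }, character(1))
}

# Rotation-space oracle: best of n random rotations followed by an annealed
# local random search. Independent of the SVD path it checks.
oracle_min_rmsd <- function(P, Q, n_random = 10000, n_refine = 3000) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(R) sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  best_R <- diag(3); best <- obj(best_R)
  for (k in seq_len(n_random)) {
    R <- random_rotation()
    v <- obj(R)
    if (v < best) { best <- v; best_R <- R }
  }
  small_rotation <- function(scale) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- rnorm(1, sd = scale)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  scale <- 0.3
  for (k in seq_len(n_refine)) {
    R <- best_R %*% small_rotation(scale)
    v <- obj(R)
    if (v < best) { best <- v; best_R <- R } else scale <- max(1e-4, scale * 0.995)
  }
  best
}

# A small reference pair + trajectory world shared by several tests.
tiny_world <- function(seed = 11, n_runs = 1, run_length_ns = 2,
                       schedule = NULL, ...) {
  cfg <- synthetic_config(n_runs = n_runs, run_length_ns = run_length_ns,
                          event_schedule = schedule, seed = seed, ...)
  generate_trajectory(cfg)
}
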