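# Domain types and PDB readers/writers.
#
# A Structure is a list(atoms = data.frame, xyz = n x 3 matrix, label, model_number);
# `atoms` has columns residue_index, residue_name, atom_name, element, mass.
# A Trajectory shares one atom roster across frames and stores coordinates as an
# n_atoms x 3 x n_frames array, the layout the C++ kernels consume directly.

.STANDARD_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  "NA" = 22.990, CL = 35.45, K = 39.098, CA = 40.078
)

.WATER_NAMES <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD")

#' Construct an atom table
#'
#' Builds the atom roster data.frame used inside [Structure] objects. Masses are
#' filled from standard atomic masses when not supplied.
#'
#' @param residue_index integer vector, 1-based mature-chain residue numbers.
#' @param residue_name character vector of 3-letter residue codes.
#' @param atom_name character vector of PDB atom names (e.g. `"CA"`).
#' @param element character vector of element symbols; inferred from `atom_name`
#'   when `NULL`.
#' @param mass numeric vector of atomic masses (amu); looked up from `element`
#'   when `NULL`.
#' @return a data.frame with the five roster columns.
#' @export
atom_table <- function(residue_index, residue_name, atom_name,
                       element = NULL, mass = NULL) {
  n <- length(residue_index)
  if (is.null(element)) element <- guess_element(atom_name)
  element <- toupper(element)
  if (is.null(mass)) {
    mass <- unname(.STANDARD_MASSES[element])
    if (anyNA(mass)) {
      bad <- unique(element[is.na(mass)])
      stop("no standard mass for element(s): ", paste(bad, collapse = ", "))
    }
  }
  stopifnot(length(residue_name) == n, length(atom_name) == n,
            length(element) == n, length(mass) == n)
  if (any(residue_index < 1L)) stop("residue_index must be >= 1")
  if (any(mass <= 0)) stop("atom masses must be > 0")
  data.frame(residue_index = as.integer(residue_index),
             residue_name = as.character(residue_name),
             atom_name = as.character(atom_name),
             element = element, mass = as.numeric(mass),
             stringsAsFactors = FALSE)
}

# Element from a PDB atom name: strip digits/primes, handle the common two-letter
# cases that survive in protein heavy-atom rosters.
guess_element <- function(atom_name) {
  nm <- toupper(gsub("[0-9'\\*]", "", trimws(atom_name)))
  el <- substr(nm, 1L, 1L)
  two <- nm %in% c("SE", "FE", "ZN", "MG", "CL")
  el[two] <- nm[two]
  el
}

#' Construct a Structure
#'
#' One conformation: an atom roster plus an `n x 3` coordinate matrix in Angstrom.
#'
#' @param atoms atom roster from [atom_table()].
#' @param xyz numeric `n x 3` matrix of coordinates (Angstrom).
#' @param label free-text label (e.g. a PDB id).
#' @param model_number model number for multi-model (NMR) provenance.
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, xyz, label = "", model_number = 1L) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must be an n x 3 matrix")
  if (nrow(xyz) != nrow(atoms)) stop("atoms and xyz disagree on atom count")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.unsorted(atoms$residue_index)) {
    stop("residue indices must be non-decreasing along the atom list")
  }
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz, label = label,
                 model_number = as.integer(model_number)),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure '%s'> %d atoms, %d residues (model %d)\n",
              x$label, nrow(x$atoms), length(unique(x$atoms$residue_index)),
              x$model_number))
  invisible(x)
}

#' Construct a Trajectory
#'
#' An ordered set of frames sharing one atom roster, with a fixed frame interval.
#'
#' @param atoms shared atom roster ([atom_table()]).
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param frame_interval_ps time between frames in picoseconds (> 0).
#' @param run_id label of the production run this trajectory came from.
#' @return an object of class `Trajectory`.
#' @export
new_trajectory <- function(atoms, coords, frame_interval_ps, run_id = "run1") {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(atoms)) stop("roster and coords disagree on atom count")
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0) {
    stop("frame_interval_ps must be > 0")
  }
  structure(list(atoms = atoms, coords = coords,
                 frame_interval_ps = as.numeric(frame_interval_ps),
                 run_id = as.character(run_id)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory '%s'> %d frames x %d atoms, dt = %g ps\n",
              x$run_id, n_frames(x), nrow(x$atoms), x$frame_interval_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a [new_trajectory()] object.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame of a trajectory as a Structure
#' @param trajectory a Trajectory.
#' @param i frame index (1-based).
#' @return a `Structure`.
#' @export
get_frame <- function(trajectory, i) {
  if (i < 1L || i > n_frames(trajectory)) stop("frame index out of range")
  new_structure(trajectory$atoms, trajectory$coords[, , i],
                label = sprintf("%s[%d]", trajectory$run_id, i),
                model_number = i)
}

#' Domain partition of a two-domain hinge protein
#'
#' Residue-index sets for the two rigid domains and the two hinge linkers. The
#' default is the canonical PBP partition (HisJ numbering): domain 1 = residues
#' 1-86 and 197-238, domain 2 = 90-192, linkers 87-89 and 193-196.
#'
#' @param domain1,domain2,linker1,linker2 integer vectors of residue indices;
#'   must be pairwise disjoint and non-empty.
#' @return an object of class `DomainPartition`.
#' @export
domain_partition <- function(domain1 = c(1:86, 197:238),
                             domain2 = 90:192,
                             linker1 = 87:89,
                             linker2 = 193:196) {
  sets <- list(domain1 = as.integer(domain1), domain2 = as.integer(domain2),
               linker1 = as.integer(linker1), linker2 = as.integer(linker2))
  if (any(vapply(sets, length, 1L) == 0L)) stop("all partition sets must be non-empty")
  all_idx <- unlist(sets)
  if (anyDuplicated(all_idx)) stop("partition sets must be pairwise disjoint")
  structure(sets, class = "DomainPartition")
}

# ---- PDB parsing ----------------------------------------------------------

.parse_pdb_atom_lines <- function(lines) {
  list(
    record   = substr(lines, 1, 6),
    atom_name = trimws(substr(lines, 13, 16)),
    altloc   = substr(lines, 17, 17),
    residue_name = trimws(substr(lines, 18, 20)),
    chain    = substr(lines, 22, 22),
    residue_index = suppressWarnings(as.integer(substr(lines, 23, 26))),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    element  = trimws(substr(lines, 77, 78))
  )
}

# Split raw PDB lines into per-model blocks of ATOM/HETATM lines. A file without
# MODEL records is one block.
.pdb_model_blocks <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    return(list(lines[grepl("^(ATOM  |HETATM)", lines)]))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts)) {
    model_ends <- c(model_ends, length(lines))
  }
  lapply(seq_along(model_starts), function(k) {
    blk <- lines[model_starts[k]:model_ends[k]]
    blk[grepl("^(ATOM  |HETATM)", blk)]
  })
}

.block_to_structure <- function(block, label, model_number,
                                drop_het = TRUE, drop_hydrogens = TRUE,
                                drop_waters = TRUE) {
  if (length(block) == 0L) stop("model contains no atom records")
  f <- .parse_pdb_atom_lines(block)
  keep <- rep(TRUE, length(block))
  keep <- keep & f$altloc %in% c(" ", "A")
  if (drop_waters) keep <- keep & !(f$residue_name %in% .WATER_NAMES)
  if (drop_het) keep <- keep & f$record == "ATOM  "
  el <- ifelse(nzchar(f$element), toupper(f$element), guess_element(f$atom_name))
  if (drop_hydrogens) keep <- keep & !(el %in% c("H", "D"))
  if (!any(keep)) stop("zero protein atoms after filtering (waters/heteroatoms excluded)")
  atoms <- atom_table(f$residue_index[keep], f$residue_name[keep],
                      f$atom_name[keep], element = el[keep])
  xyz <- cbind(f$x[keep], f$y[keep], f$z[keep])
  new_structure(atoms, xyz, label = label, model_number = model_number)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of the requested model. Waters, heteroatoms (HETATM),
#' hydrogens and alternate locations other than "A"/blank are dropped by default,
#' so the roster is the deterministic heavy-atom protein content.
#'
#' @param path path to a PDB file.
#' @param model_selector integer model number, or `"first"` (default) for model 1
#'   of multi-model (NMR ensemble) files.
#' @param drop_het drop HETATM records (ligands, ions). Default `TRUE`.
#' @param drop_hydrogens drop H/D atoms. Default `TRUE`.
#' @return a `Structure`.
#' @export
read_pdb <- function(path, model_selector = "first",
                     drop_het = TRUE, drop_hydrogens = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- .pdb_model_blocks(lines)
  k <- if (identical(model_selector, "first")) 1L else as.integer(model_selector)
  if (k < 1L || k > length(blocks)) {
    stop(sprintf("model %d not found (%d model(s) in %s)", k, length(blocks), path))
  }
  .block_to_structure(blocks[[k]], label = basename(path), model_number = k,
                      drop_het = drop_het, drop_hydrogens = drop_hydrogens)
}

#' Read a trajectory from a multi-model PDB file
#'
#' Each MODEL/ENDMDL block is one frame; all frames must share an identical atom
#' roster (residue index, residue name, atom name, in order).
#'
#' @param path path to a multi-model PDB file.
#' @param frame_interval_ps time between consecutive frames, picoseconds.
#' @param run_id run label; defaults to the file name.
#' @inheritParams read_pdb
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, frame_interval_ps, run_id = basename(path),
                            drop_het = TRUE, drop_hydrogens = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- .pdb_model_blocks(lines)
  frames <- lapply(seq_along(blocks), function(k) {
    .block_to_structure(blocks[[k]], label = basename(path), model_number = k,
                        drop_het = drop_het, drop_hydrogens = drop_hydrogens)
  })
  roster <- frames[[1]]$atoms
  for (k in seq_along(frames)) {
    fa <- frames[[k]]$atoms
    if (nrow(fa) != nrow(roster) ||
        !identical(fa[c("residue_index", "atom_name")],
                   roster[c("residue_index", "atom_name")])) {
      stop(sprintf("atom roster of frame %d does not match frame 1", k))
    }
  }
  coords <- array(0, dim = c(nrow(roster), 3L, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]$xyz
  new_trajectory(roster, coords, frame_interval_ps, run_id = run_id)
}

.format_pdb_atom <- function(serial, atom_name, residue_name, residue_index,
                             x, y, z, element) {
  # PDB convention: 1-3 character atom names start in column 14.
  nm <- if (nchar(atom_name) < 4L) paste0(" ", atom_name) else atom_name
  sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, residue_name, residue_index, x, y, z,
          1.0, 0.0, element)
}

.structure_pdb_lines <- function(structure) {
  a <- structure$atoms
  xyz <- structure$xyz
  vapply(seq_len(nrow(a)), function(i) {
    .format_pdb_atom(i, a$atom_name[i], a$residue_name[i], a$residue_index[i],
                     xyz[i, 1], xyz[i, 2], xyz[i, 3], a$element[i])
  }, character(1))
}

#' Write a structure to a PDB file
#' @param structure a `Structure`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  writeLines(c(.structure_pdb_lines(structure), "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, coordinates in fixed-width PDB columns
#' (3 decimals). Reading the file back reproduces coordinates to PDB precision.
#'
#' @param trajectory a `Trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(trajectory, path) {
  nf <- n_frames(trajectory)
  if (nf == 0L) stop("trajectory has no frames")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nf)) {
    writeLines(sprintf("MODEL %8d", k), con)
    writeLines(.structure_pdb_lines(get_frame(trajectory, k)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Atom selection helpers used across modules.
select_atoms <- function(structure, residue_set = NULL,
                         atom_filter = c("heavy", "ca")) {
  atom_filter <- match.arg(atom_filter)
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(residue_set)) keep <- keep & a$residue_index %in% residue_set
  if (atom_filter == "ca") keep <- keep & a$atom_name == "CA"
  else keep <- keep & a$element != "H"
  which(keep)
}

# Calpha coordinates ordered by residue index; errors if a scored residue lacks one.
ca_coords <- function(structure, residues = NULL) {
  idx <- select_atoms(structure, residues, "ca")
  if (length(idx) == 0L) stop("no C-alpha atoms in selection")
  ord <- order(structure$atoms$residue_index[idx])
  idx <- idx[ord]
  list(residue_index = structure$atoms$residue_index[idx],
       xyz = structure$xyz[idx, , drop = FALSE])
}
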