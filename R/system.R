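#' Molecular system container
#'
#' A `molecular_system` bundles the static topology every analysis needs:
#' an atom table, the residue partition of the protein, and the buffer
#' molecules with their charge states. Coordinates live in [frame()] /
#' [trajectory()] objects, never here.
#'
#' Atom groups partition the system: every atom is exactly one of
#' `protein`, `buffer_neutral`, `buffer_charged`, `ion`, `solvent`.
#'
#' @param atoms data frame with columns `index` (1-based integer), `name`,
#'   `element`, `residue_index` (non-negative integer), `residue_name`
#'   (3-letter code), `chain_id`, `vdw_radius` (nm, positive), `group`.
#' @param buffer_molecules optional data frame with columns `molecule_id`,
#'   `charge_state` (0 or 1) and a list-column `atom_indices`; may be `NULL`
#'   when the system has no buffer.
#' @return An object of class `molecular_system` with components `atoms`,
#'   `residues` (one row per protein residue with the atom index range) and
#'   `buffer_molecules`.
#' @examples
#' sys <- make_toy_protein(c("ALA", "GLY", "ALA"), seed = 1)$system
#' sys
#' @export
molecular_system <- function(atoms, buffer_molecules = NULL) {
  required <- c("index", "name", "element", "residue_index", "residue_name",
                "chain_id", "vdw_radius", "group")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  groups <- c("protein", "buffer_neutral", "buffer_charged", "ion", "solvent")
  if (!all(atoms$group %in% groups))
    stop("atom group must be one of: ", paste(groups, collapse = ", "))
  if (any(atoms$vdw_radius <= 0)) stop("all vdw radii must be positive")
  if (any(atoms$residue_index < 0)) stop("residue_index must be non-negative")

  prot <- atoms[atoms$group == "protein", , drop = FALSE]
  residues <- if (nrow(prot)) {
    key <- paste(prot$chain_id, prot$residue_index, sep = "\r")
    split_idx <- split(prot$index, factor(key, levels = unique(key)))
    first <- !duplicated(key)
    data.frame(
      residue_index = prot$residue_index[first],
      residue_name  = prot$residue_name[first],
      chain_id      = prot$chain_id[first],
      first_atom    = vapply(split_idx, min, integer(1)),
      last_atom     = vapply(split_idx, max, integer(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(residue_index = integer(), residue_name = character(),
               chain_id = character(), first_atom = integer(), last_atom = integer())
  }

  if (!is.null(buffer_molecules)) {
    if (!all(c("molecule_id", "charge_state", "atom_indices") %in% names(buffer_molecules)))
      stop("buffer_molecules needs columns molecule_id, charge_state, atom_indices")
    if (!all(buffer_molecules$charge_state %in% c(0L, 1L)))
      stop("charge_state must be 0 (neutral) or 1 (charged)")
    all_idx <- unlist(buffer_molecules$atom_indices)
    if (anyDuplicated(all_idx))
      stop("buffer molecule atom sets must be disjoint")
  }

  structure(list(atoms = atoms, residues = residues,
                 buffer_molecules = buffer_molecules),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  nb <- if (is.null(x$buffer_molecules)) 0L else nrow(x$buffer_molecules)
  cat("<molecular_system> ", nrow(x$atoms), " atoms, ",
      nrow(x$residues), " protein residues, ", nb, " buffer molecules\n", sep = "")
  tab <- table(x$atoms$group)
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Select atom indices by group
#' @param system a [molecular_system()].
#' @param group one or more of `"protein"`, `"buffer_neutral"`,
#'   `"buffer_charged"`, `"ion"`, `"solvent"`.
#' @return integer vector of atom indices.
#' @export
select_group <- function(system, group) {
  stopifnot(inherits(system, "molecular_system"))
  system$atoms$index[system$atoms$group %in% group]
}

#' Atom indices of a protein residue (by row of `system$residues`)
#' @keywords internal
residue_atom_indices <- function(system, residue_row) {
  r <- system$residues[residue_row, ]
  idx <- seq.int(r$first_atom, r$last_atom)
  idx[system$atoms$group[idx] == "protein" &
        system$atoms$residue_index[idx] == r$residue_index &
        system$atoms$chain_id[idx] == r$chain_id]
}

#' Logical mask of side-chain atoms
#'
#' Side chain = everything except the backbone N, CA, C, O (and OXT) and
#' hydrogens attached to them; with `heavy_only` every hydrogen is dropped.
#' For glycine the heavy-atom side chain is empty.
#' @param system a [molecular_system()].
#' @param heavy_only drop all hydrogens (default `TRUE`).
#' @return logical vector over atoms.
#' @export
side_chain_mask <- function(system, heavy_only = TRUE) {
  a <- system$atoms
  backbone <- a$name %in% c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3",
                            "HA2", "HA3", "HN")
  sc <- a$group == "protein" & !backbone
  if (heavy_only) sc <- sc & a$element != "H"
  sc
}

#' Single coordinate frame
#'
#' @param coordinates numeric matrix (n_atoms x 3), nm.
#' @param box 3x3 box matrix in nm (rows are box vectors), or `NULL` for a
#'   non-periodic system.
#' @param time time stamp in ps.
#' @return object of class `frame`.
#' @export
frame <- function(coordinates, box = NULL, time = 0) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be an n x 3 matrix")
  if (!is.null(box)) {
    box <- as.matrix(box)
    if (!all(dim(box) == c(3L, 3L))) stop("box must be a 3 x 3 matrix")
    if (any(diag(box) <= 0)) stop("box diagonal must be strictly positive")
  }
  structure(list(coordinates = coordinates, box = box, time = as.numeric(time)),
            class = "frame")
}

#' Trajectory: ordered frames over one molecular system
#'
#' @param system a [molecular_system()].
#' @param frames list of [frame()] objects with strictly increasing times and
#'   coordinate counts matching the system atom count.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(system, frames) {
  stopifnot(inherits(system, "molecular_system"))
  n_atoms <- nrow(system$atoms)
  for (f in frames) {
    if (!inherits(f, "frame")) stop("frames must be a list of frame objects")
    if (nrow(f$coordinates) != n_atoms)
      stop("frame has ", nrow(f$coordinates), " coordinates but system has ",
           n_atoms, " atoms")
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(system = system, frames = frames), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  times <- trajectory_times(x)
  cat("<trajectory> ", length(x$frames), " frames, ",
      nrow(x$system$atoms), " atoms", sep = "")
  if (length(times)) cat(", t = ", times[1], " .. ", times[length(times)], " ps", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Frame time stamps of a trajectory (ps)
#' @param traj a [trajectory()].
#' @export
trajectory_times <- function(traj) {
  vapply(traj$frames, `[[`, numeric(1), "time")
}
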