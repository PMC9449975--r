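#' Deterministic quasi-uniform sphere points (Fibonacci lattice)
#'
#' Seedless and bit-reproducible: the same point set is reused for every
#' atom, scaled to its extended radius.
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface by test points on a
#' deterministic Fibonacci lattice. The area of each atom in `atoms` is the
#' fraction of its test points not buried inside any *other* atom of
#' `context`, times the full sphere area 4*pi*(r_i + r_probe)^2. Separating
#' `atoms` from `context` lets callers include, e.g., adsorbed buffer
#' molecules as occluders without reporting their areas.
#'
#' @param frm a [frame()].
#' @param system a [molecular_system()].
#' @param atoms integer atom indices whose areas are wanted.
#' @param context integer atom indices acting as occluders; must contain
#'   `atoms`. Defaults to `atoms`.
#' @param probe_radius probe radius in nm (water: 0.14).
#' @param n_points test points per atom (>= 32; default 960).
#' @return object of class `sasa_result`: list with `area` (named numeric,
#'   nm^2, names are atom indices), `probe_radius`, `n_points`.
#' @examples
#' toy <- make_toy_protein(c("ALA", "LEU", "ALA"), seed = 1)
#' s <- shrake_rupley(toy$frame, toy$system, select_group(toy$system, "protein"))
#' sum(s$area)
#' @export
shrake_rupley <- function(frm, system, atoms, context = atoms,
                          probe_radius = 0.14, n_points = 960L) {
  stopifnot(inherits(frm, "frame"), inherits(system, "molecular_system"))
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_points < 32L) stop("n_points must be at least 32")
  if (length(atoms) == 0L)
    return(structure(list(area = numeric(0), probe_radius = probe_radius,
                          n_points = as.integer(n_points)),
                     class = "sasa_result"))
  if (!all(atoms %in% context)) stop("atoms must be a subset of context")

  xyz <- frm$coordinates
  radii <- system$atoms$vdw_radius
  ext <- radii + probe_radius          # extended radii for all atoms
  pts <- fibonacci_sphere(as.integer(n_points))

  ctx_xyz <- xyz[context, , drop = FALSE]
  ctx_ext <- ext[context]
  area <- numeric(length(atoms))
  for (ii in seq_along(atoms)) {
    i <- atoms[ii]
    ri <- ext[i]
    ci <- xyz[i, ]
    # neighbours: context atoms whose extended sphere can intersect atom i's
    dd <- sweep(ctx_xyz, 2L, ci)
    d2 <- rowSums(dd^2)
    near <- which(d2 < (ri + ctx_ext)^2 & d2 > 1e-20)
    near <- near[context[near] != i]
    if (!length(near)) {
      area[ii] <- 4 * pi * ri^2
      next
    }
    surf <- pts * ri
    surf <- sweep(surf, 2L, ci, "+")
    exposed <- rep(TRUE, nrow(surf))
    for (j in near) {
      cj <- ctx_xyz[j, ]
      rj2 <- ctx_ext[j]^2
      keep <- which(exposed)
      if (!length(keep)) break
      dj2 <- (surf[keep, 1] - cj[1])^2 + (surf[keep, 2] - cj[2])^2 +
             (surf[keep, 3] - cj[3])^2
      exposed[keep[dj2 < rj2]] <- FALSE
    }
    area[ii] <- 4 * pi * ri^2 * sum(exposed) / nrow(surf)
  }
  names(area) <- as.character(atoms)
  structure(list(area = area, probe_radius = probe_radius,
                 n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<sasa_result> ", length(x$area), " atoms, total ",
      format(sum(x$area), digits = 5), " nm^2 (probe ", x$probe_radius,
      " nm, ", x$n_points, " points)\n", sep = "")
  invisible(x)
}

#' Per-residue solvent-accessible area
#'
#' Sums the per-atom areas of a [shrake_rupley()] result over each protein
#' residue, optionally restricted to side-chain atoms.
#'
#' @param sasa a `sasa_result`.
#' @param system the [molecular_system()] the areas were computed on.
#' @param side_chain_only sum only side-chain atoms (default `TRUE`).
#' @param heavy_only side-chain definition drops hydrogens (default `TRUE`).
#' @return named numeric vector, one entry per row of `system$residues`
#'   (names = residue row index), nm^2. Residues with no atoms after the
#'   side-chain filter (Gly, heavy-only) get 0 with a warning.
#' @export
residue_saa <- function(sasa, system, side_chain_only = TRUE, heavy_only = TRUE) {
  stopifnot(inherits(sasa, "sasa_result"))
  covered <- as.integer(names(sasa$area))
  sc <- side_chain_mask(system, heavy_only = heavy_only)
  out <- numeric(nrow(system$residues))
  empty <- character(0)
  for (r in seq_len(nrow(system$residues))) {
    idx <- residue_atom_indices(system, r)
    if (side_chain_only) idx <- idx[sc[idx]]
    if (!length(idx)) {
      empty <- c(empty, system$residues$residue_name[r])
      next
    }
    idx <- intersect(idx, covered)
    out[r] <- sum(sasa$area[as.character(idx)])
  }
  if (length(empty))
    warning("residue(s) with empty side chain after filtering: ",
            paste(unique(empty), collapse = ", "), "; area set to 0",
            call. = FALSE)
  names(out) <- as.character(seq_len(nrow(system$residues)))
  out
}
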