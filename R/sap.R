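#' Spatial Aggregation Propensity (SAP) and its buffer-aware extension (BSAP)
#'
#' For each protein atom j and frame, SAP sums over all residues with at
#' least one side-chain atom within `radius` of j the product
#' (SAA of those side-chain atoms / fully-exposed side-chain SAA) x
#' (shifted residue hydrophobicity), then time-averages over frames. A
#' positive SAP flags a solvent-exposed hydrophobic patch.
#'
#' BSAP modifies SAP in two ways: (i) buffer atoms are added as geometric
#' occluders in the accessible-area calculation, so an adsorbed buffer
#' molecule shields the protein surface; (ii) each buffer molecule with any
#' atom within `contact_cutoff` of atom j contributes its own hydrophilicity
#' term, (molecule SAA / free-excipient SAA) x R_h(excipient). With a
#' hydrophilic excipient (negative shifted hydrophobicity, e.g. histidine)
#' adsorption lowers the index.
#'
#' @param traj a [trajectory()].
#' @param mode `"SAP"` or `"BSAP"`.
#' @param atoms protein atom indices to evaluate (default: all).
#' @param radius neighborhood radius, nm (default 0.5).
#' @param contact_cutoff buffer contact cutoff for the BSAP hydrophilicity
#'   term, nm (default 0.4).
#' @param scale a [hydrophobicity_scale()] (default the glycine-shifted
#'   Black & Mould scale).
#' @param reference an [build_exposure_reference()] result (default the
#'   packaged reconstruction).
#' @param excipient_residue residue name whose scale value weights the
#'   buffer term (default `"HIS"`).
#' @param probe_radius,n_points Shrake-Rupley parameters.
#' @param heavy_only side-chain/SAA convention drops hydrogens (default).
#' @param include_self count atom j's own residue when its side chain falls
#'   within `radius` (default `TRUE`).
#' @param pbc minimum-image distances (default `TRUE`).
#' @return object of class `sap_result`: `per_atom` and `per_residue`
#'   named numeric vectors, `score` (sum of positive per-atom values),
#'   `mode`, `radius`.
#' @examples
#' toy <- make_toy_protein(rep(c("LEU", "GLY"), 3), seed = 1)
#' traj <- trajectory(toy$system, list(toy$frame))
#' res <- sap_index(traj, n_points = 240)
#' res$score
#' @export
sap_index <- function(traj, mode = c("SAP", "BSAP"), atoms = NULL,
                      radius = 0.5, contact_cutoff = 0.4,
                      scale = bm_scale(), reference = default_exposure_reference(),
                      excipient_residue = "HIS",
                      probe_radius = 0.14, n_points = 960L,
                      heavy_only = TRUE, include_self = TRUE, pbc = TRUE) {
  mode <- match.arg(mode)
  stopifnot(radius > 0)
  sys <- traj$system
  prot_idx <- select_group(sys, "protein")
  if (is.null(atoms)) atoms <- prot_idx
  if (!all(atoms %in% prot_idx))
    stop("atoms must be protein atoms; offending index(es): ",
         paste(utils::head(setdiff(atoms, prot_idx), 3), collapse = ", "))

  sc_mask <- side_chain_mask(sys, heavy_only = heavy_only)
  sc_idx <- which(sc_mask)
  n_res <- nrow(sys$residues)
  res_of_atom <- integer(nrow(sys$atoms))
  for (r in seq_len(n_res)) res_of_atom[residue_atom_indices(sys, r)] <- r
  res_names <- sys$residues$residue_name
  rh <- scale_value(scale, res_names)
  saa_exp <- reference_value(reference, res_names)
  rh_exc <- scale_value(scale, excipient_residue)

  buf <- sys$buffer_molecules
  has_buffer <- mode == "BSAP" && !is.null(buf) && nrow(buf) > 0
  buf_idx <- if (has_buffer) unlist(buf$atom_indices) else integer(0)

  acc <- numeric(length(atoms))
  for (f in traj$frames) {
    box <- if (pbc) f$box else NULL
    context <- if (has_buffer) c(prot_idx, buf_idx) else prot_idx
    want <- unique(c(sc_idx, buf_idx))
    sasa <- shrake_rupley(f, sys, want, context,
                          probe_radius = probe_radius, n_points = n_points)
    area <- numeric(nrow(sys$atoms))
    area[want] <- sasa$area[as.character(want)]

    buf_mol_area <- if (has_buffer)
      vapply(buf$atom_indices, function(ix) sum(area[ix]), numeric(1))
    else numeric(0)

    sc_xyz <- f$coordinates[sc_idx, , drop = FALSE]
    sc_res <- res_of_atom[sc_idx]
    for (ii in seq_along(atoms)) {
      j <- atoms[ii]
      disp <- sweep(sc_xyz, 2L, f$coordinates[j, ])
      within <- min_image_sq(disp, box) <= radius^2
      if (!include_self) within <- within & sc_res != res_of_atom[j]
      val <- 0
      if (any(within)) {
        contrib <- tapply(area[sc_idx[within]], sc_res[within], sum)
        rr <- as.integer(names(contrib))
        val <- sum(contrib / saa_exp[rr] * rh[rr])
      }
      if (has_buffer) {
        for (m in seq_len(nrow(buf))) {
          bx <- f$coordinates[buf$atom_indices[[m]], , drop = FALSE]
          dmin2 <- min(min_image_sq(sweep(bx, 2L, f$coordinates[j, ]), box))
          if (dmin2 <= contact_cutoff^2)
            val <- val + rh_exc * buf_mol_area[m] / reference$saa_exposed_excipient
        }
      }
      acc[ii] <- acc[ii] + val
    }
  }
  per_atom <- acc / length(traj$frames)
  names(per_atom) <- as.character(atoms)

  per_residue <- tapply(per_atom, res_of_atom[atoms], mean)
  pr <- rep(NA_real_, n_res)
  pr[as.integer(names(per_residue))] <- as.numeric(per_residue)
  names(pr) <- as.character(seq_len(n_res))

  structure(list(per_atom = per_atom, per_residue = pr,
                 score = sum(pmax(per_atom, 0)), mode = mode,
                 radius = radius),
            class = "sap_result")
}

#' @export
print.sap_result <- function(x, ...) {
  cat("<sap_result> ", x$mode, " over ", length(x$per_atom), " atoms ",
      "(radius ", x$radius, " nm): score ", format(x$score, digits = 5),
      "\n", sep = "")
  invisible(x)
}

#' SAP of a single atom
#'
#' Convenience wrapper over [sap_index()] for one atom index.
#' @inheritParams sap_index
#' @param j protein atom index.
#' @param ... passed to [sap_index()].
#' @return the time-averaged SAP value of atom `j`.
#' @export
atom_sap <- function(traj, j, ...) {
  unname(sap_index(traj, mode = "SAP", atoms = j, ...)$per_atom)
}

#' BSAP of a single atom
#' @inheritParams atom_sap
#' @export
atom_bsap <- function(traj, j, ...) {
  unname(sap_index(traj, mode = "BSAP", atoms = j, ...)$per_atom)
}

#' Aggregate SAP/BSAP score: the sum of positive per-atom values
#' @param result a `sap_result` (or a bare numeric vector of per-atom
#'   values).
#' @return a single nonnegative number.
#' @export
sap_score <- function(result) {
  v <- if (inherits(result, "sap_result")) result$per_atom else result
  sum(pmax(v, 0))
}
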