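#' Heavy-atom side-chain topology templates
#'
#' Bond graphs (parent links from CB) for the 20 standard residues; used to
#' build idealized side-chain geometries for the fully-exposed reference
#' calculation and for template-based fixtures. Hydrogens are not modelled.
#' @return for [sidechain_graph()], a data frame with columns `name`,
#'   `element`, `parent` ("CB"-rooted), or zero rows for GLY.
#' @keywords internal
sidechain_graph <- function(resname) {
  g <- function(names, parents) {
    data.frame(name = names, element = substr(names, 1L, 1L), parent = parents,
               stringsAsFactors = FALSE)
  }
  switch(toupper(resname),
    GLY = g(character(0), character(0)),
    ALA = g("CB", "CA"),
    SER = g(c("CB", "OG"), c("CA", "CB")),
    CYS = g(c("CB", "SG"), c("CA", "CB")),
    THR = g(c("CB", "OG1", "CG2"), c("CA", "CB", "CB")),
    VAL = g(c("CB", "CG1", "CG2"), c("CA", "CB", "CB")),
    LEU = g(c("CB", "CG", "CD1", "CD2"), c("CA", "CB", "CG", "CG")),
    ILE = g(c("CB", "CG1", "CG2", "CD1"), c("CA", "CB", "CB", "CG1")),
    PRO = g(c("CB", "CG", "CD"), c("CA", "CB", "CG")),
    MET = g(c("CB", "CG", "SD", "CE"), c("CA", "CB", "CG", "SD")),
    ASP = g(c("CB", "CG", "OD1", "OD2"), c("CA", "CB", "CG", "CG")),
    ASN = g(c("CB", "CG", "OD1", "ND2"), c("CA", "CB", "CG", "CG")),
    GLU = g(c("CB", "CG", "CD", "OE1", "OE2"), c("CA", "CB", "CG", "CD", "CD")),
    GLN = g(c("CB", "CG", "CD", "OE1", "NE2"), c("CA", "CB", "CG", "CD", "CD")),
    LYS = g(c("CB", "CG", "CD", "CE", "NZ"), c("CA", "CB", "CG", "CD", "CE")),
    ARG = g(c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
            c("CA", "CB", "CG", "CD", "NE", "CZ", "CZ")),
    HIS = g(c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
            c("CA", "CB", "CG", "CG", "ND1", "CD2")),
    PHE = g(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
            c("CA", "CB", "CG", "CG", "CD1", "CD2", "CE1")),
    TYR = g(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
            c("CA", "CB", "CG", "CG", "CD1", "CD2", "CE1", "CZ")),
    TRP = g(c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
            c("CA", "CB", "CG", "CG", "CD1", "CD2", "CD2", "CE2", "CE3", "CZ2")),
    stop("unknown residue '", resname, "'; templates exist for the 20 standard residues")
  )
}

#' Names of residues with a template
#' @keywords internal
template_residues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' Idealized side-chain coordinates relative to CA
#'
#' Places atoms by breadth-first traversal of the bond graph: each bond step
#' advances ~0.125 nm along the side-chain axis with a small alternating
#' lateral zig-zag; siblings branch symmetrically out of the chain plane.
#' The geometry is idealized (bond lengths ~0.15 nm), adequate for
#' reproducible accessible-area references, not for energetics.
#'
#' @param resname 3-letter code.
#' @param direction +1 or -1, side-chain axis along +/- y.
#' @param twist rotation (radians) of the side chain about the CA->CB axis,
#'   used to generate distinct conformers.
#' @return matrix (n_sidechain_atoms x 3) with rownames = atom names, nm,
#'   relative to CA at the origin.
#' @keywords internal
sidechain_coords <- function(resname, direction = 1, twist = 0) {
  graph <- sidechain_graph(resname)
  if (!nrow(graph)) return(matrix(numeric(0), 0L, 3L))
  pos <- matrix(NA_real_, nrow(graph), 3L, dimnames = list(graph$name, NULL))
  level <- integer(nrow(graph))
  # bond level from CA
  for (i in seq_len(nrow(graph))) {
    p <- graph$parent[i]
    level[i] <- if (p == "CA") 1L else level[match(p, graph$name)] + 1L
  }
  # sibling rank among atoms sharing a parent
  sib <- stats::ave(seq_len(nrow(graph)), graph$parent, FUN = seq_along)
  nsib <- stats::ave(seq_len(nrow(graph)), graph$parent, FUN = length)
  for (i in seq_len(nrow(graph))) {
    base <- if (graph$parent[i] == "CA") c(0, 0, 0) else pos[graph$parent[i], ]
    lateral <- 0.055 * (-1)^level[i]
    branch <- 0.11 * (sib[i] - (nsib[i] + 1) / 2)
    pos[i, ] <- base + c(lateral, 0.125, branch)
  }
  pos[, 2] <- pos[, 2] * direction
  if (twist != 0) {
    # rotate about the y axis (the CA->CB direction up to the zig-zag)
    ct <- cos(twist); st <- sin(twist)
    xz <- pos[, c(1, 3), drop = FALSE]
    pos[, 1] <- ct * xz[, 1] - st * xz[, 2]
    pos[, 3] <- st * xz[, 1] + ct * xz[, 2]
  }
  pos
}

#' Build an extended Ala-X-Ala trimer (or a free single residue)
#'
#' Extended backbone along x (CA-CA spacing 0.38 nm), side chains
#' alternating above/below the chain. Heavy atoms only.
#'
#' @param sequence character vector of 3-letter codes.
#' @param twist side-chain twist (radians) applied to every residue.
#' @param group atom group label.
#' @return list(system = [molecular_system()], frame = [frame()]).
#' @keywords internal
build_peptide_template <- function(sequence, twist = 0, group = "protein") {
  sequence <- toupper(sequence)
  rows <- list(); coords <- list()
  idx <- 0L
  for (t in seq_along(sequence)) {
    res <- sequence[t]
    x0 <- 0.38 * (t - 1L)
    bb_names <- c("N", "CA", "C", "O")
    bb_xyz <- rbind(c(x0 - 0.145, 0.045, 0),
                    c(x0, 0, 0),
                    c(x0 + 0.15, 0.05, 0),
                    c(x0 + 0.175, 0.17, 0.05))
    sc <- sidechain_coords(res, direction = (-1)^(t - 1L), twist = twist)
    nm <- c(bb_names, rownames(sc))
    xyz <- rbind(bb_xyz, if (nrow(sc)) sweep(sc, 2L, c(x0, 0, 0), "+"))
    el <- substr(nm, 1L, 1L)
    n <- length(nm)
    rows[[t]] <- data.frame(
      index = idx + seq_len(n), name = nm, element = el,
      residue_index = t, residue_name = res, chain_id = "A",
      vdw_radius = vdw_radius(el), group = group, stringsAsFactors = FALSE)
    coords[[t]] <- xyz
    idx <- idx + n
  }
  atoms <- do.call(rbind, rows)
  sys <- molecular_system(atoms)
  list(system = sys, frame = frame(do.call(rbind, coords), box = NULL, time = 0))
}

#' Fully-exposed reference areas (ExposureReference)
#'
#' For each residue X, builds extended Ala-X-Ala trimer conformers (the
#' side chain of X twisted by evenly spaced angles about the CA->CB axis),
#' computes the side-chain accessible area of the central X occluded by the
#' whole trimer, and averages over conformers. Also computes the accessible
#' area of the free excipient molecule (a lone amino acid, histidine by
#' default) in isolation. These references are deterministic reconstructions
#' from idealized geometry; supply your own table (same structure) to
#' override them with e.g. trajectory-averaged values.
#'
#' Glycine has no heavy side-chain atom; its reference falls back to the
#' accessible area of its CA in the trimer so downstream normalizations
#' never divide by zero (glycine's shifted hydrophobicity is 0, so its SAP
#' contribution vanishes regardless).
#'
#' @param residue_names residues to tabulate (default: all 20).
#' @param probe_radius probe radius, nm.
#' @param n_points Shrake-Rupley test points.
#' @param conformers number of side-chain twist conformers to average.
#' @param excipient residue name of the free excipient molecule.
#' @return object of class `exposure_reference`: list with `saa_exposed`
#'   (named numeric, nm^2) and `saa_exposed_excipient` (nm^2).
#' @examples
#' ref <- build_exposure_reference(c("ALA", "LEU", "ARG"))
#' ref$saa_exposed
#' @export
build_exposure_reference <- function(residue_names = template_residues(),
                                     probe_radius = 0.14, n_points = 960L,
                                     conformers = 3L, excipient = "HIS") {
  residue_names <- toupper(residue_names)
  unknown <- setdiff(residue_names, template_residues())
  if (length(unknown))
    stop("no template for residue(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(template_residues(), collapse = ", "))
  twists <- 2 * pi * (seq_len(conformers) - 1L) / conformers
  out <- numeric(length(residue_names))
  names(out) <- residue_names
  for (res in residue_names) {
    acc <- 0
    for (tw in twists) {
      tpl <- build_peptide_template(c("ALA", res, "ALA"), twist = tw)
      sc <- side_chain_mask(tpl$system)
      central <- residue_atom_indices(tpl$system, 2L)
      target <- central[sc[central]]
      all_atoms <- tpl$system$atoms$index
      if (!length(target)) {
        # GLY fallback: CA-based area, documented above
        ca <- central[tpl$system$atoms$name[central] == "CA"]
        s <- shrake_rupley(tpl$frame, tpl$system, ca, all_atoms,
                           probe_radius = probe_radius, n_points = n_points)
      } else {
        s <- shrake_rupley(tpl$frame, tpl$system, target, all_atoms,
                           probe_radius = probe_radius, n_points = n_points)
      }
      acc <- acc + sum(s$area)
    }
    out[res] <- acc / length(twists)
  }
  free <- build_peptide_template(excipient)
  s_free <- shrake_rupley(free$frame, free$system, free$system$atoms$index,
                          probe_radius = probe_radius, n_points = n_points)
  structure(list(saa_exposed = out,
                 saa_exposed_excipient = sum(s_free$area),
                 probe_radius = probe_radius, n_points = as.integer(n_points),
                 conformers = as.integer(conformers), excipient = excipient),
            class = "exposure_reference")
}

#' @export
print.exposure_reference <- function(x, ...) {
  cat("<exposure_reference> ", length(x$saa_exposed), " residues, excipient ",
      x$excipient, " = ", format(x$saa_exposed_excipient, digits = 4),
      " nm^2\n", sep = "")
  print(round(x$saa_exposed, 4))
  invisible(x)
}

.bsapkit_cache <- new.env(parent = emptyenv())

#' Packaged default exposure reference (computed once per session)
#' @param ... passed to [build_exposure_reference()] on first use.
#' @return an `exposure_reference`.
#' @export
default_exposure_reference <- function(...) {
  if (is.null(.bsapkit_cache$exposure_reference))
    .bsapkit_cache$exposure_reference <- build_exposure_reference(...)
  .bsapkit_cache$exposure_reference
}

#' Reference lookup with a clear error
#' @keywords internal
reference_value <- function(reference, resname) {
  stopifnot(inherits(reference, "exposure_reference"))
  v <- reference$saa_exposed[resname]
  if (anyNA(v))
    stop("residue(s) missing from exposure reference: ",
         paste(unique(resname[is.na(v)]), collapse = ", "))
  unname(v)
}
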