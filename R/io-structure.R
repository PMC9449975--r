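#' Assign atom groups from residue names and a buffer declaration
#'
#' Buffer molecules are declared explicitly by residue name -> charge state
#' (e.g. `c(HIS0 = 0, HISP = 1)`); no protonation inference is attempted.
#' Common water (HOH/SOL/WAT/TIP3) and monatomic-ion residue names are
#' recognized; everything else is protein.
#' @keywords internal
classify_groups <- function(residue_name, buffer_residues = NULL) {
  rn <- toupper(residue_name)
  water <- c("HOH", "SOL", "WAT", "TIP3", "TIP4", "SPC")
  ions <- c("NA", "CL", "K", "MG", "CA2", "ZN", "NA+", "CL-", "SOD", "CLA", "POT")
  out <- rep("protein", length(rn))
  out[rn %in% water] <- "solvent"
  out[rn %in% ions] <- "ion"
  if (!is.null(buffer_residues)) {
    bn <- toupper(names(buffer_residues))
    for (i in seq_along(bn)) {
      st <- buffer_residues[[i]]
      out[rn == bn[i]] <- if (st == 1) "buffer_charged" else "buffer_neutral"
    }
  }
  out
}

#' Group buffer atoms into molecules by residue instance
#' @keywords internal
collect_buffer_molecules <- function(atoms) {
  sel <- atoms$group %in% c("buffer_neutral", "buffer_charged")
  if (!any(sel)) return(NULL)
  b <- atoms[sel, , drop = FALSE]
  key <- paste(b$chain_id, b$residue_index, b$residue_name, sep = "\r")
  ids <- split(b$index, factor(key, levels = unique(key)))
  states <- vapply(split(b$group, factor(key, levels = unique(key))),
                   function(g) if (g[1] == "buffer_charged") 1L else 0L,
                   integer(1))
  data.frame(molecule_id = seq_along(ids),
             charge_state = unname(states),
             atom_indices = I(unname(ids)),
             stringsAsFactors = FALSE)
}

box_from_cryst1 <- function(line) {
  a <- as.numeric(substr(line, 7, 15)) / 10
  b <- as.numeric(substr(line, 16, 24)) / 10
  c_ <- as.numeric(substr(line, 25, 33)) / 10
  al <- as.numeric(substr(line, 34, 40)) * pi / 180
  be <- as.numeric(substr(line, 41, 47)) * pi / 180
  ga <- as.numeric(substr(line, 48, 54)) * pi / 180
  if (anyNA(c(a, b, c_, al, be, ga)) || a <= 0) return(NULL)
  # standard lattice-vector construction
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(ga), b * sin(ga), 0)
  cx <- c_ * cos(be)
  cy <- c_ * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(0, c_^2 - cx^2 - cy^2))
  rbind(v1, v2, c(cx, cy, cz))
}

#' Read a structure file (PDB or GRO)
#'
#' Parses atoms, assembles residues in file order, infers elements from
#' atom names where the file does not carry them, assigns van der Waals
#' radii from the packaged element table, and classifies groups using the
#' buffer declaration. PDB coordinates (Angstrom) are converted to nm.
#'
#' @param path file path.
#' @param format `"PDB"` or `"GRO"` (default: guessed from the extension).
#' @param buffer_residues named vector/list mapping buffer residue names to
#'   charge states (0 neutral, 1 charged), e.g. `c(HIS0 = 0, HISP = 1)`.
#' @return list with `system` ([molecular_system()]) and `frame` ([frame()]).
#' @export
read_structure <- function(path, format = c("auto", "PDB", "GRO"),
                           buffer_residues = NULL) {
  format <- match.arg(toupper(format[1]), c("AUTO", "PDB", "GRO"))
  if (format == "AUTO")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "GRO" else "PDB"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "PDB") read_structure_pdb(path, buffer_residues)
  else read_structure_gro(path, buffer_residues)
}

read_structure_pdb <- function(path, buffer_residues) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(is.na(el) | !nzchar(trimws(el))))
    el <- infer_element(at$elety)
  else {
    miss <- is.na(el) | !nzchar(trimws(el))
    el[miss] <- infer_element(at$elety[miss])
    el <- toupper(trimws(el))
  }
  chain <- at$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  atoms <- data.frame(
    index = seq_len(nrow(at)),
    name = trimws(at$elety),
    element = el,
    residue_index = at$resno,
    residue_name = toupper(trimws(at$resid)),
    chain_id = chain,
    vdw_radius = vdw_radius(el),
    group = "protein",
    stringsAsFactors = FALSE)
  atoms$group <- classify_groups(atoms$residue_name, buffer_residues)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE) / 10
  box <- NULL
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cl)) box <- box_from_cryst1(cl[1])
  sys <- molecular_system(atoms, collect_buffer_molecules(atoms))
  list(system = sys, frame = frame(xyz, box = box, time = 0))
}

read_structure_gro <- function(path, buffer_residues) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("GRO file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("GRO format error at line 2: expected atom count, got '",
                     lines[2], "'")
  if (length(lines) < 2L + n + 1L)
    stop("GRO file truncated: declared ", n, " atoms, file has ",
         length(lines) - 3L, " atom lines")
  al <- lines[3:(2 + n)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resnm <- toupper(trimws(substr(al, 6, 10)))
  atnm <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("GRO format error at line ", 2L + bad[1], ": '", al[bad[1]], "'")
  bv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  box <- NULL
  if (length(bv) >= 3 && !anyNA(bv[1:3]) && all(bv[1:3] > 0)) {
    box <- diag(bv[1:3])
    if (length(bv) >= 9) {
      # GRO order: xx yy zz xy xz yx yz zx zy
      box[1, 2] <- bv[4]; box[1, 3] <- bv[5]; box[2, 1] <- bv[6]
      box[2, 3] <- bv[7]; box[3, 1] <- bv[8]; box[3, 2] <- bv[9]
    }
  }
  el <- infer_element(atnm)
  atoms <- data.frame(
    index = seq_len(n), name = atnm, element = el,
    residue_index = resno, residue_name = resnm, chain_id = "A",
    vdw_radius = vdw_radius(el), group = "protein", stringsAsFactors = FALSE)
  atoms$group <- classify_groups(resnm, buffer_residues)
  sys <- molecular_system(atoms, collect_buffer_molecules(atoms))
  list(system = sys, frame = frame(cbind(x, y, z), box = box, time = 0))
}

#' Write a structure to PDB or GRO
#'
#' @param system a [molecular_system()].
#' @param frm a [frame()].
#' @param path output file path.
#' @param format `"PDB"` or `"GRO"` (default from extension).
#' @param b_factor optional numeric vector (one per atom) written to the
#'   PDB B-factor column, e.g. per-atom SAP values for surface coloring.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, frm, path, format = c("auto", "PDB", "GRO"),
                            b_factor = NULL) {
  format <- match.arg(toupper(format[1]), c("AUTO", "PDB", "GRO"))
  if (format == "AUTO")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "GRO" else "PDB"
  a <- system$atoms
  xyz <- frm$coordinates
  if (format == "PDB") {
    b <- if (is.null(b_factor)) rep(0, nrow(a)) else round(b_factor, 2)
    if (!is.null(frm$box)) {
      L <- frm$box
      a_len <- sqrt(sum(L[1, ]^2)); b_len <- sqrt(sum(L[2, ]^2)); c_len <- sqrt(sum(L[3, ]^2))
      cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       a_len * 10, b_len * 10, c_len * 10, 90, 90, 90)
      writeLines(cryst, path)
      bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)) * 10,
                       resno = a$residue_index, resid = a$residue_name,
                       eleno = a$index, elety = a$name, chain = a$chain_id,
                       b = b, append = TRUE)
    } else {
      bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)) * 10,
                       resno = a$residue_index, resid = a$residue_name,
                       eleno = a$index, elety = a$name, chain = a$chain_id,
                       b = b)
    }
  } else {
    n <- nrow(a)
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    a$residue_index %% 100000L, a$residue_name,
                    substr(a$name, 1, 5), a$index %% 100000L,
                    xyz[, 1], xyz[, 2], xyz[, 3])
    boxline <- if (is.null(frm$box)) "   0.000   0.000   0.000"
               else sprintf("%10.5f%10.5f%10.5f", frm$box[1, 1], frm$box[2, 2], frm$box[3, 3])
    writeLines(c("written by bsapkit", sprintf("%5d", n), body, boxline), path)
  }
  invisible(path)
}
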