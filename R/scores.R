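#' Load the packaged HIS0 interaction-energy / hydrophobicity table
#'
#' Per-residue interaction energies (kcal/mol) for the cation-pi, pi-pi
#' stacking and hydrogen-pi interaction types, and glycine-shifted
#' hydrophobicities for the hydrogen-bond type, together with the
#' fragment-averaged and fully-exposed accessible areas they were tabulated
#' with. Users may pass their own table of the same shape to generalize
#' beyond histidine.
#'
#' @param path TSV path (default: the packaged table).
#' @return object of class `interaction_energy_table` (a data frame with
#'   columns `interaction_type`, `residue_name`, `energy_kcal_mol`, `hp`,
#'   `saa_fc_avg_nm2`, `saa_fab_avg_nm2`, `saa_exposed_nm2`).
#' @export
load_interaction_table <- function(path = system.file("extdata", "his0_interaction_table.tsv",
                                                      package = "bsapkit")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("interaction_type", "residue_name")
  if (!all(needed %in% names(tab)))
    stop("interaction table needs columns ", paste(needed, collapse = ", "))
  class(tab) <- c("interaction_energy_table", "data.frame")
  tab
}

as_exposure_vector <- function(reference) {
  if (inherits(reference, "exposure_reference")) reference$saa_exposed
  else if (is.numeric(reference) && !is.null(names(reference))) reference
  else stop("reference must be an exposure_reference or a named numeric vector")
}

score_breakdown <- function(per_residue, interaction_type) {
  structure(list(per_residue = per_residue, total = sum(per_residue),
                 interaction_type = interaction_type),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, digits = 3, ...) {
  cat("<score_breakdown> ", x$interaction_type, ": total ",
      format(x$total, digits = digits + 1), "\n", sep = "")
  print(round(x$per_residue, digits))
  invisible(x)
}

#' Excipient-affinity score S_E for one interaction type
#'
#' Per residue type i: S_i = -E_i * SAA_avg(i) / SAA_exposed(i), summed
#' into the total. Attractive (negative) energies yield positive scores;
#' a larger total means more solvent-exposed interaction partners for the
#' excipient on that surface.
#'
#' @param interaction_type `"cation_pi"`, `"pi_pi"` or `"h_pi"` (the
#'   hydrogen-bond type has its own scoring, [hbond_score()]).
#' @param saa_avg named numeric vector: trajectory-averaged SAA per residue
#'   type, nm^2 (e.g. from [saa_avg_from_trajectory()]).
#' @param energies an [load_interaction_table()] result.
#' @param reference an exposure reference or named numeric vector of
#'   fully-exposed areas; defaults to the `saa_exposed_nm2` column of
#'   `energies` for the rows of this interaction type.
#' @return a `score_breakdown` (fields `per_residue`, `total`,
#'   `interaction_type`).
#' @examples
#' tab <- load_interaction_table()
#' fc <- setNames(tab$saa_fc_avg_nm2[tab$interaction_type == "cation_pi"],
#'                tab$residue_name[tab$interaction_type == "cation_pi"])
#' se_score("cation_pi", fc, tab)
#' @export
se_score <- function(interaction_type, saa_avg, energies = load_interaction_table(),
                     reference = NULL) {
  if (interaction_type == "h_bond")
    stop("use hbond_score() for the hydrogen-bond type")
  rows <- energies[energies$interaction_type == interaction_type, , drop = FALSE]
  if (!nrow(rows)) stop("no entries of interaction type '", interaction_type, "'")
  res <- names(saa_avg)
  missing_e <- setdiff(res, rows$residue_name)
  if (length(missing_e))
    stop("no ", interaction_type, " energy for residue(s): ",
         paste(missing_e, collapse = ", "))
  m <- match(res, rows$residue_name)
  E <- rows$energy_kcal_mol[m]
  exp_area <- if (is.null(reference)) rows$saa_exposed_nm2[m]
              else {
                v <- as_exposure_vector(reference)[res]
                if (anyNA(v)) stop("missing exposed SAA for residue(s): ",
                                   paste(res[is.na(v)], collapse = ", "))
                v
              }
  per <- -E * as.numeric(saa_avg) / exp_area
  names(per) <- res
  score_breakdown(per, interaction_type)
}

#' Hydrogen-bond score from shifted hydrophobicities
#'
#' Per residue type i: S_i = -hp(i) * SAA_avg(i) / SAA_exposed(i).
#' Hydrophilic residues (hp < 0) score positively; glycine (hp = 0 by the
#' shift) scores 0.
#'
#' @inheritParams se_score
#' @return a `score_breakdown`.
#' @export
hbond_score <- function(saa_avg, energies = load_interaction_table(),
                        reference = NULL) {
  rows <- energies[energies$interaction_type == "h_bond", , drop = FALSE]
  if (!nrow(rows)) stop("no h_bond entries in the interaction table")
  res <- names(saa_avg)
  missing_h <- setdiff(res, rows$residue_name)
  if (length(missing_h))
    stop("no hydrophobicity entry for residue(s): ",
         paste(missing_h, collapse = ", "))
  m <- match(res, rows$residue_name)
  hp <- rows$hp[m]
  exp_area <- if (is.null(reference)) rows$saa_exposed_nm2[m]
              else {
                v <- as_exposure_vector(reference)[res]
                if (anyNA(v)) stop("missing exposed SAA for residue(s): ",
                                   paste(res[is.na(v)], collapse = ", "))
                v
              }
  per <- -hp * as.numeric(saa_avg) / exp_area
  names(per) <- res
  score_breakdown(per, "h_bond")
}

#' Trajectory-averaged side-chain SAA per residue type
#'
#' For each residue type, the frame-averaged combined side-chain accessible
#' area over all residues of that type (protein-only occlusion context).
#'
#' @param traj a [trajectory()].
#' @param residue_names residue types to tabulate (default: all present).
#' @param probe_radius,n_points,heavy_only Shrake-Rupley settings.
#' @return named numeric vector, nm^2; types absent from the protein get 0
#'   with a warning.
#' @export
saa_avg_from_trajectory <- function(traj, residue_names = NULL,
                                    probe_radius = 0.14, n_points = 960L,
                                    heavy_only = TRUE) {
  sys <- traj$system
  present <- unique(sys$residues$residue_name)
  if (is.null(residue_names)) residue_names <- present
  residue_names <- toupper(residue_names)
  absent <- setdiff(residue_names, present)
  if (length(absent))
    warning("residue type(s) absent from protein: ",
            paste(absent, collapse = ", "), "; reported as 0", call. = FALSE)
  prot_idx <- select_group(sys, "protein")
  acc <- stats::setNames(numeric(length(residue_names)), residue_names)
  for (f in traj$frames) {
    sasa <- shrake_rupley(f, sys, prot_idx, prot_idx,
                          probe_radius = probe_radius, n_points = n_points)
    per_res <- suppressWarnings(
      residue_saa(sasa, sys, side_chain_only = TRUE, heavy_only = heavy_only))
    by_type <- tapply(per_res, sys$residues$residue_name, sum)
    hit <- intersect(residue_names, names(by_type))
    acc[hit] <- acc[hit] + by_type[hit]
  }
  acc / length(traj$frames)
}

#' Recompute the packaged fragment score table
#'
#' Runs [se_score()] / [hbond_score()] on the packaged printed inputs for
#' one fragment and returns the per-residue and total scores per
#' interaction type.
#'
#' @param fragment `"Fc"` or `"Fab"`.
#' @param energies an [load_interaction_table()] result.
#' @return named list of `score_breakdown`s (`cation_pi`, `pi_pi`, `h_pi`,
#'   `h_bond`).
#' @export
fragment_scores <- function(fragment = c("Fc", "Fab"),
                            energies = load_interaction_table()) {
  fragment <- match.arg(fragment)
  col <- if (fragment == "Fc") "saa_fc_avg_nm2" else "saa_fab_avg_nm2"
  out <- list()
  for (ty in c("cation_pi", "pi_pi", "h_pi", "h_bond")) {
    rows <- energies[energies$interaction_type == ty, , drop = FALSE]
    saa <- stats::setNames(rows[[col]], rows$residue_name)
    out[[ty]] <- if (ty == "h_bond") hbond_score(saa, energies)
                 else se_score(ty, saa, energies)
  }
  out
}
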