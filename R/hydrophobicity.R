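#' Residue hydrophobicity scale
#'
#' Constructs a `hydrophobicity_scale`: a named vector of dimensionless
#' per-residue hydrophobicities shifted so that the reference residue
#' (glycine by default) scores exactly 0. Negative values are hydrophilic.
#'
#' @param values named numeric vector, names are 3-letter residue codes.
#' @param shift_reference residue whose value is shifted to zero.
#' @return object of class `hydrophobicity_scale`.
#' @seealso [bm_scale()] for the packaged Black & Mould scale.
#' @export
hydrophobicity_scale <- function(values, shift_reference = "GLY") {
  if (is.null(names(values))) stop("values must be named by residue")
  if (!shift_reference %in% names(values))
    stop("shift_reference '", shift_reference, "' not in values")
  values <- values - values[[shift_reference]]
  structure(list(values = values, shift_reference = shift_reference),
            class = "hydrophobicity_scale")
}

#' The Black & Mould hydrophobicity scale, glycine-shifted
#'
#' Empirical side-chain hydrophobicities of Black & Mould (1991), shifted so
#' glycine is 0. On this shifted scale arginine (-0.50) is the most
#' hydrophilic residue and phenylalanine (+0.50) the most hydrophobic;
#' free histidine scores -0.34.
#'
#' @return a [hydrophobicity_scale()].
#' @examples
#' sc <- bm_scale()
#' sc$values[c("GLY", "ARG", "HIS", "PHE")]
#' @export
bm_scale <- function() {
  raw <- c(ALA = 0.616, ARG = 0.000, ASN = 0.236, ASP = 0.028, CYS = 0.680,
           GLN = 0.251, GLU = 0.043, GLY = 0.501, HIS = 0.165, ILE = 0.943,
           LEU = 0.943, LYS = 0.283, MET = 0.738, PHE = 1.000, PRO = 0.711,
           SER = 0.359, THR = 0.450, TRP = 0.878, TYR = 0.880, VAL = 0.825)
  hydrophobicity_scale(raw, "GLY")
}

#' Look up shifted hydrophobicities, erroring on unknown residues
#' @keywords internal
scale_value <- function(scale, resname) {
  stopifnot(inherits(scale, "hydrophobicity_scale"))
  v <- scale$values[resname]
  if (anyNA(v))
    stop("residue(s) missing from hydrophobicity scale: ",
         paste(unique(resname[is.na(v)]), collapse = ", "))
  unname(v)
}
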