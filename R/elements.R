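#' Element data used throughout the package
#'
#' Van der Waals radii (nm) follow the Bondi compilation, the de-facto
#' standard for accessible-surface-area work; masses are standard atomic
#' weights (g/mol). Elements absent from the table fall back to the carbon
#' radius with a warning, so exotic HETATM entries never silently vanish
#' from an occlusion calculation.
#'
#' @format A data frame with columns `element`, `vdw_radius` (nm), `mass`.
#' @keywords internal
element_table <- function() {
  data.frame(
    element    = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I", "NA", "K", "MG", "CA", "ZN", "FE"),
    vdw_radius = c(0.120, 0.170, 0.155, 0.152, 0.180, 0.180, 0.147, 0.175, 0.185, 0.198,
                   0.227, 0.275, 0.173, 0.231, 0.139, 0.140),
    mass       = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998, 35.45, 79.904, 126.904,
                   22.990, 39.098, 24.305, 40.078, 65.38, 55.845),
    stringsAsFactors = FALSE
  )
}

#' Look up van der Waals radii for a vector of element symbols
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in nm.
#' @keywords internal
vdw_radius <- function(element) {
  tab <- element_table()
  idx <- match(toupper(element), tab$element)
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using carbon radius 0.170 nm", call. = FALSE)
    idx[is.na(idx)] <- match("C", tab$element)
  }
  tab$vdw_radius[idx]
}

#' @rdname vdw_radius
#' @keywords internal
atomic_mass <- function(element) {
  tab <- element_table()
  idx <- match(toupper(element), tab$element)
  idx[is.na(idx)] <- match("C", tab$element)
  tab$mass[idx]
}

#' Infer the element symbol from a PDB/GRO-style atom name
#'
#' Follows the usual convention: strip digits and primes, try the first
#' two characters against the known two-letter elements (CL, NA, ...),
#' else take the first letter. Names beginning with a digit (e.g. "1HB")
#' are hydrogens.
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @keywords internal
infer_element <- function(name) {
  nm <- toupper(trimws(name))
  out <- character(length(nm))
  two_letter <- c("CL", "BR", "NA", "MG", "ZN", "FE", "CA")
  for (i in seq_along(nm)) {
    s <- gsub("[0-9']", "", nm[i])
    if (!nzchar(s)) stop("cannot infer element from atom name '", name[i], "'")
    first2 <- substr(s, 1L, 2L)
    # Two-letter matches only when unambiguous: "CA" in a protein residue is
    # an alpha carbon, handled by callers passing resolved elements instead.
    if (first2 %in% setdiff(two_letter, "CA") && nchar(s) >= 2L) {
      out[i] <- first2
    } else if (grepl("^[0-9]", nm[i])) {
      out[i] <- "H"
    } else {
      out[i] <- substr(s, 1L, 1L)
    }
  }
  out
}
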