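# Element data used for bond perception and steric descriptors.
#
# Covalent radii: Cordero et al. single-bond radii (C is sp3).
# van der Waals radii: Bondi; Rh is not in Bondi's table, the 2.00 A value
# follows the crystallographic-contact compilation of Alvarez.
# All radii in Angstrom.

.element_table <- data.frame(
  symbol = c("H", "He", "B", "C", "N", "O", "F",
             "Si", "P", "S", "Cl", "Br", "I", "Rh"),
  covalent_r = c(0.31, 0.28, 0.84, 0.76, 0.71, 0.66, 0.57,
                 1.11, 1.07, 1.05, 1.02, 1.20, 1.39, 1.42),
  vdw_r = c(1.20, 1.40, 1.92, 1.70, 1.55, 1.52, 1.47,
            2.10, 1.80, 1.80, 1.75, 1.85, 1.98, 2.00),
  stringsAsFactors = FALSE
)

#' Normalize an element symbol
#'
#' Element symbols are matched case-insensitively and returned with standard
#' capitalization ("RH", "rh" -> "Rh"). Unknown symbols raise an error.
#'
#' @param symbol Character vector of element symbols.
#' @return Character vector of normalized symbols.
#' @export
normalize_element <- function(symbol) {
  if (!is.character(symbol)) stop("element symbols must be character")
  key <- toupper(trimws(symbol))
  idx <- match(key, toupper(.element_table$symbol))
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  .element_table$symbol[idx]
}

#' Covalent radius lookup
#'
#' @param symbol Character vector of element symbols (any capitalization).
#' @return Numeric vector of covalent radii in Angstrom.
#' @export
covalent_radius <- function(symbol) {
  sym <- normalize_element(symbol)
  .element_table$covalent_r[match(sym, .element_table$symbol)]
}

#' van der Waals radius lookup
#'
#' @param symbol Character vector of element symbols (any capitalization).
#' @return Numeric vector of van der Waals radii in Angstrom.
#' @export
vdw_radius <- function(symbol) {
  sym <- normalize_element(symbol)
  .element_table$vdw_r[match(sym, .element_table$symbol)]
}

#' Hartree to kcal/mol conversion factor
#'
#' Single pinned constant used for every derived reaction and probe energy:
#' 1 a.u. (hartree) = 627.5094740631 kcal/mol.
#'
#' @return The conversion factor as a numeric scalar.
#' @export
hartree_to_kcal <- function() 627.5094740631
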