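# Element data: atomic number, atomic mass, Cordero single-bond covalent
# radius (Angstrom). Subset covering organic/organometallic small molecules.

element_table <- data.frame(
  symbol = c("H", "D", "B", "C", "N", "O", "F", "Na", "Mg", "Si",
             "P", "S", "Cl", "K", "Ca", "Br", "I"),
  z      = c(1, 1, 5, 6, 7, 8, 9, 11, 12, 14, 15, 16, 17, 19, 20, 35, 53),
  mass   = c(1.008, 2.014, 10.811, 12.011, 14.007, 15.999, 18.998, 22.990,
             24.305, 28.086, 30.974, 32.065, 35.453, 39.098, 40.078,
             79.904, 126.904),
  r_cov  = c(0.31, 0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.66, 1.41, 1.11,
             1.07, 1.05, 1.02, 2.03, 1.76, 1.20, 1.39),
  stringsAsFactors = FALSE
)

normalize_element <- function(element) {
  e <- paste0(toupper(substr(element, 1, 1)), tolower(substring(element, 2)))
  sub("[^A-Za-z].*$", "", e)
}

element_lookup <- function(element, field) {
  e <- normalize_element(element)
  i <- match(e, element_table$symbol)
  if (anyNA(i))
    stop(sprintf("unknown element symbol(s): %s",
                 paste(unique(element[is.na(i)]), collapse = ", ")))
  element_table[[field]][i]
}

#' Covalent radii (Cordero-style single-bond radii, Angstrom)
#' @param element Chemical symbols.
#' @export
covalent_radius <- function(element) element_lookup(element, "r_cov")

#' Atomic masses (u)
#' @param element Chemical symbols.
#' @export
atomic_mass <- function(element) element_lookup(element, "mass")

#' Atomic numbers
#' @param element Chemical symbols.
#' @export
atomic_number <- function(element) element_lookup(element, "z")
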