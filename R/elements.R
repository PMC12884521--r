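# Element metadata used throughout the package. Masses in amu, radii in
# Angstrom (van der Waals: Bondi; covalent: Cordero).

.element_table <- tibble::tribble(
  ~element, ~number, ~mass,   ~vdw, ~covalent,
  "H",       1L,      1.008,  1.20, 0.31,
  "He",      2L,      4.0026, 1.40, 0.28,
  "Li",      3L,      6.94,   1.82, 1.28,
  "Be",      4L,      9.0122, 1.53, 0.96,
  "B",       5L,     10.81,   1.92, 0.84,
  "C",       6L,     12.011,  1.70, 0.76,
  "N",       7L,     14.007,  1.55, 0.71,
  "O",       8L,     15.999,  1.52, 0.66,
  "F",       9L,     18.998,  1.47, 0.57,
  "Ne",     10L,     20.180,  1.54, 0.58,
  "Na",     11L,     22.990,  2.27, 1.66,
  "Mg",     12L,     24.305,  1.73, 1.41,
  "Al",     13L,     26.982,  1.84, 1.21,
  "Si",     14L,     28.085,  2.10, 1.11,
  "P",      15L,     30.974,  1.80, 1.07,
  "S",      16L,     32.06,   1.80, 1.05,
  "Cl",     17L,     35.45,   1.75, 1.02,
  "Ar",     18L,     39.948,  1.88, 1.06
)

#' Element metadata table
#'
#' Atomic number, mass (amu), van der Waals radius and covalent radius
#' (both in Angstrom) for the elements the package parameterises (H through
#' Ar). Unknown element symbols are always rejected by the lookup helpers,
#' never silently defaulted.
#'
#' @return A tibble with columns `element`, `number`, `mass`, `vdw`,
#'   `covalent`.
#' @export
#' @examples
#' element_data()
element_data <- function() .element_table

.element_lookup <- function(symbols, column) {
  idx <- match(symbols, .element_table$element)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  .element_table[[column]][idx]
}

#' Look up element properties
#'
#' Vectorised lookups into [element_data()]. All of them error on an
#' unrecognised symbol.
#'
#' @param symbols Character vector of element symbols (e.g. `"C"`, `"Cl"`).
#' @return Numeric (or integer) vector aligned with `symbols`.
#' @export
element_mass <- function(symbols) .element_lookup(symbols, "mass")

#' @rdname element_mass
#' @export
element_vdw <- function(symbols) .element_lookup(symbols, "vdw")

#' @rdname element_mass
#' @export
element_covalent <- function(symbols) .element_lookup(symbols, "covalent")

#' @rdname element_mass
#' @export
element_number <- function(symbols) .element_lookup(symbols, "number")

# Angstrom -> bohr
.ang2bohr <- 1.8897259886
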