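# Molecular structures are plain tibbles with one row per atom, so they
# compose with dplyr verbs. Coordinates are Angstrom everywhere inside the
# package; bohr appears only at the cube-file and NCI-grid boundaries.

.structure_cols <- c("element", "name", "x", "y", "z",
                     "residue_name", "residue_seq", "chain",
                     "fragment", "charge")

#' Build a molecular structure tibble
#'
#' A structure is a tibble with one row per atom and columns `element`,
#' `name`, `x`, `y`, `z` (Angstrom), `residue_name`, `residue_seq`, `chain`,
#' `fragment` (one of `"ligand"`, `"site"`, `"cap"`) and `charge`
#' (elementary charge units). Every function in the package that takes a
#' structure accepts any data frame with these columns, so structures chain
#' through dplyr pipelines.
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Numeric coordinates in Angstrom.
#' @param name Atom labels; defaults to the element symbol.
#' @param residue_name Three-letter residue code or ligand code.
#' @param residue_seq Integer residue number.
#' @param chain Single-character chain identifier.
#' @param fragment `"ligand"`, `"site"` or `"cap"`.
#' @param charge Partial charge in elementary charge units.
#' @param title Free-text title stored as an attribute.
#' @return A validated structure tibble.
#' @export
#' @examples
#' mol_structure(c("O", "H"), x = c(0, 0.96), y = 0, z = 0)
mol_structure <- function(element, x, y, z, name = element,
                          residue_name = "UNL", residue_seq = 1L,
                          chain = "A", fragment = "ligand", charge = 0,
                          title = "") {
  df <- tibble::tibble(
    element = as.character(element),
    name = as.character(name),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    residue_name = as.character(residue_name),
    residue_seq = as.integer(residue_seq),
    chain = as.character(chain),
    fragment = as.character(fragment),
    charge = as.numeric(charge)
  )
  attr(df, "title") <- title
  validate_structure(df)
}

#' Validate a structure tibble
#'
#' Checks the column contract, that the structure is non-empty, that every
#' element symbol is parameterised (see [element_data()]) and that all
#' coordinates are finite.
#'
#' @param structure A structure tibble (see [mol_structure()]).
#' @return The structure, invisibly unchanged, for piping.
#' @export
validate_structure <- function(structure) {
  missing <- setdiff(.structure_cols, names(structure))
  if (length(missing) > 0) {
    stop("structure is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(structure) == 0) {
    stop("structure must contain at least one atom", call. = FALSE)
  }
  element_mass(structure$element) # errors on unknown symbols
  cm <- as.matrix(structure[, c("x", "y", "z")])
  if (!all(is.finite(cm))) {
    stop("structure contains non-finite coordinates", call. = FALSE)
  }
  bad <- !structure$fragment %in% c("ligand", "site", "cap")
  if (any(bad)) {
    stop("fragment must be one of 'ligand', 'site', 'cap'", call. = FALSE)
  }
  structure
}

#' Extract or replace the coordinate matrix of a structure
#'
#' @param structure A structure tibble.
#' @param coords An n x 3 numeric matrix of Angstrom coordinates.
#' @return `coords_matrix()` returns an n x 3 matrix; `set_coords()` the
#'   structure with replaced coordinates.
#' @export
coords_matrix <- function(structure) {
  m <- as.matrix(structure[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' @rdname coords_matrix
#' @export
set_coords <- function(structure, coords) {
  stopifnot(nrow(coords) == nrow(structure), ncol(coords) == 3)
  structure$x <- coords[, 1]
  structure$y <- coords[, 2]
  structure$z <- coords[, 3]
  structure
}

#' Mass-weighted centre of mass
#'
#' @param structure A structure tibble with recognised elements.
#' @return Named numeric vector `c(x, y, z)` in Angstrom.
#' @export
#' @examples
#' center_of_mass(mol_structure(c("O", "H"), x = c(0, 0.96), y = 0, z = 0))
center_of_mass <- function(structure) {
  validate_structure(structure)
  m <- element_mass(structure$element)
  total <- sum(m)
  if (total <= 0) stop("zero total mass", call. = FALSE)
  com <- colSums(coords_matrix(structure) * m) / total
  stats::setNames(as.numeric(com), c("x", "y", "z"))
}

# rows of `structure` belonging to the ligand fragment
.ligand_rows <- function(structure) which(structure$fragment == "ligand")
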