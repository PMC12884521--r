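# PDB reading is delegated to bio3d; this layer applies the package's
# policies (altLoc resolution, element inference, fragment tagging) and
# converts to the tibble structure contract.

#' Read a PDB file into a structure tibble
#'
#' Parses ATOM and HETATM records. HETATM atoms whose residue code matches
#' `ligand_code` are tagged `fragment = "ligand"`; everything else is tagged
#' `"site"`. Alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties: first listed). ANISOU/CONECT records
#' are ignored. Elements missing from the element column are inferred from
#' the atom name; symbols that remain unrecognised raise an error rather
#' than being defaulted.
#'
#' @param path Path to a PDB file.
#' @param ligand_code HETATM residue code identifying the ligand. Defaults
#'   to `"VDX"`, the calcitriol code used in the 1DB1 crystal structure of
#'   the vitamin D receptor.
#' @return A structure tibble (see [mol_structure()]) with waters retained;
#'   [select_site()] excludes waters by default.
#' @export
read_pdb <- function(path, ligand_code = "VDX") {
  if (!file.exists(path)) {
    stop("cannot read PDB file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  }
  # fail early, naming the offending line, on unparsable coordinates
  for (i in which(rec)) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields)))) {
      stop("unparsable coordinates on line ", i, " of ", path, call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)

  # altLoc policy: keep the highest-occupancy alternative, ties first-listed
  at$occ <- ifelse(is.na(at$o), 1, at$o)
  at <- at |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid, .data$elety) |>
    dplyr::slice_max(.data$occ, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)

  elem <- at$elesy
  elem[is.na(elem) | trimws(elem) == ""] <- NA_character_
  elem <- ifelse(is.na(elem),
                 infer_element(at$elety, hetatm = at$type == "HETATM"),
                 .normalise_symbol(elem))

  df <- tibble::tibble(
    element = elem,
    name = at$elety,
    x = at$x, y = at$y, z = at$z,
    residue_name = at$resid,
    residue_seq = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    fragment = ifelse(at$type == "HETATM" & at$resid == ligand_code,
                      "ligand", "site"),
    charge = 0
  )
  attr(df, "title") <- basename(path)
  validate_structure(df)
}

.normalise_symbol <- function(sym) {
  sym <- trimws(sym)
  paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym))))
}

#' Infer element symbols from PDB atom names
#'
#' Used when the element column of a PDB record is blank. Digits and
#' primes are stripped; for protein (ATOM) records the first alphabetic
#' character is used, while for HETATM records a leading two-letter symbol
#' is tried first so that halide and metal codes parse.
#'
#' @param names Atom-name strings (PDB columns 13-16).
#' @param hetatm Logical vector: is the record a HETATM?
#' @return Character vector of element symbols.
#' @export
infer_element <- function(names, hetatm = FALSE) {
  hetatm <- rep_len(hetatm, length(names))
  vapply(seq_along(names), function(i) {
    nm <- gsub("[^A-Za-z]", "", names[i])
    if (nchar(nm) == 0) stop("cannot infer element from atom name '",
                             names[i], "'", call. = FALSE)
    two <- .normalise_symbol(substr(nm, 1, 2))
    one <- .normalise_symbol(substr(nm, 1, 1))
    if (hetatm[i] && nchar(nm) >= 2 && two %in% .element_table$element) {
      two
    } else {
      one
    }
  }, character(1))
}

#' Write a structure tibble to a PDB file
#'
#' Ligand and cap atoms are written as HETATM records, site atoms as ATOM
#' records, via [bio3d::write.pdb()].
#'
#' @param structure A structure tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  validate_structure(structure)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords_matrix(structure))),
    type = ifelse(structure$fragment == "site", "ATOM", "HETATM"),
    resno = structure$residue_seq,
    resid = structure$residue_name,
    eleno = seq_len(nrow(structure)),
    elety = structure$name,
    chain = structure$chain,
    elesy = structure$element
  )
  invisible(path)
}
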