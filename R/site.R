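# Active-site definition: residue-level distance selection around the
# ligand, rule-based protonation at physiological pH, and hydrogen capping
# of excised peptide termini.

#' Select the active site around a ligand
#'
#' Residue-level selection: a residue enters the site whole if it satisfies
#' the distance rule. Two readings of "within a radius of the ligand" are
#' implemented: `mode = "com_sphere"` includes a residue when any of its
#' atoms lies within `radius` of the ligand centre of mass; `mode =
#' "any_atom"` (the default) includes it when the minimum distance from any
#' residue atom to any ligand atom is within `radius`. The literal
#' centre-of-mass sphere is geometrically much smaller, so the any-atom
#' reading is the default; both are kept so either convention can be
#' reproduced.
#'
#' @param structure A structure tibble containing ligand and receptor atoms
#'   (e.g. from [read_pdb()]).
#' @param radius Selection radius in Angstrom (default 6.0).
#' @param mode `"any_atom"` or `"com_sphere"`.
#' @param include_waters Keep water residues? Default `FALSE`: pocket-rim
#'   waters do not mediate ligand contacts and are excluded.
#' @param water_codes Residue codes treated as water.
#' @return An `active_site` tibble of site atoms (fragment `"site"`), with
#'   attributes `radius`, `center` (ligand centre of mass), `mode` and
#'   `source_residues` (tibble of chain, residue_seq, residue_name).
#' @export
select_site <- function(structure, radius = 6.0,
                        mode = c("any_atom", "com_sphere"),
                        include_waters = FALSE,
                        water_codes = c("HOH", "WAT", "H2O")) {
  mode <- match.arg(mode)
  validate_structure(structure)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  lig <- dplyr::filter(structure, .data$fragment == "ligand")
  if (nrow(lig) == 0) stop("structure contains no ligand atoms", call. = FALSE)
  rest <- dplyr::filter(structure, .data$fragment != "ligand")
  if (!include_waters) {
    rest <- dplyr::filter(rest, !.data$residue_name %in% water_codes)
  }
  if (nrow(rest) == 0) stop("structure contains no non-ligand residues",
                            call. = FALSE)
  com <- center_of_mass(lig)
  rest_xyz <- coords_matrix(rest)
  if (mode == "com_sphere") {
    d <- sqrt(rowSums(sweep(rest_xyz, 2, com)^2))
  } else {
    lig_xyz <- coords_matrix(lig)
    # min distance from each site atom to any ligand atom
    d2 <- outer(rowSums(rest_xyz^2), rowSums(lig_xyz^2), "+") -
      2 * rest_xyz %*% t(lig_xyz)
    d <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  key <- paste(rest$chain, rest$residue_seq, rest$residue_name)
  hit_keys <- unique(key[d <= radius])
  site <- rest[key %in% hit_keys, , drop = FALSE]
  site$fragment <- "site"
  res <- dplyr::distinct(site, .data$chain, .data$residue_seq,
                         .data$residue_name)
  attr(site, "radius") <- radius
  attr(site, "center") <- com
  attr(site, "mode") <- mode
  attr(site, "source_residues") <- res
  class(site) <- c("active_site", class(tibble::tibble()))
  site
}

# protonation rules at pH 7.4: heavy-atom name -> (number of H, bond length)
# Asp/Glu carboxylates deprotonated, Lys/Arg protonated, His neutral
# N-epsilon tautomer, hydroxyls/thiols neutral. Backbone amide N carries one
# hydrogen except proline.
.protonation_rules <- function(ph = 7.4) {
  r <- list(
    "*"   = list(N = c(1, 1.01)),
    PRO   = list(N = c(0, 1.01)),
    LYS   = list(NZ = c(3, 1.01)),
    ARG   = list(NE = c(1, 1.01), NH1 = c(2, 1.01), NH2 = c(2, 1.01)),
    HIS   = list(NE2 = c(1, 1.01), ND1 = c(0, 1.01)),
    SER   = list(OG = c(1, 0.96)),
    THR   = list(OG1 = c(1, 0.96)),
    TYR   = list(OH = c(1, 0.96)),
    CYS   = list(SG = c(1, 1.34)),
    TRP   = list(NE1 = c(1, 1.01)),
    ASN   = list(ND2 = c(2, 1.01)),
    GLN   = list(NE2 = c(2, 1.01)),
    ASP   = list(OD1 = c(0, 0.96), OD2 = c(0, 0.96)),
    GLU   = list(OE1 = c(0, 0.96), OE2 = c(0, 0.96)),
    HOH   = list(O = c(2, 0.96))
  )
  if (ph < 4) { # acidic regime: carboxylates and His delta protonated
    r$ASP$OD2 <- c(1, 0.96); r$GLU$OE2 <- c(1, 0.96); r$HIS$ND1 <- c(1, 1.01)
  }
  if (ph > 10.5) r$LYS$NZ <- c(2, 1.01) # neutral amine
  r
}

.known_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                     "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                     "THR", "TRP", "TYR", "VAL", "HOH", "WAT")

#' Protonate a site by residue rules
#'
#' Template protonation for the standard states at the requested pH
#' (default 7.4): Asp/Glu side chains deprotonated, Lys/Arg protonated,
#' His as the neutral N-epsilon tautomer, Ser/Thr/Tyr/Cys neutral, plus one
#' backbone amide hydrogen per non-proline residue. Only polar and charged
#' positions receive hydrogens (the polar-hydrogen representation used by
#' classic biomolecular force fields); aliphatic CH hydrogens are not
#' built. Hydrogens already present are counted, so the operation is
#' idempotent: only the deficit is added. Unknown residue names trigger a
#' warning and pass through unmodified.
#'
#' @param site A structure tibble (typically from [select_site()]).
#' @param ph Target pH; rule sets switch at extreme values.
#' @return The site with added hydrogens appended after their residue's
#'   atoms, inheriting the heavy atom's fragment tag.
#' @export
protonate <- function(site, ph = 7.4) {
  validate_structure(site)
  rules <- .protonation_rules(ph)
  unknown <- setdiff(unique(site$residue_name),
                     c(.known_residues, names(rules)))
  unknown <- setdiff(unknown, unique(site$residue_name[site$fragment == "ligand"]))
  if (length(unknown) > 0) {
    warning("unknown residue name(s) passed through unprotonated: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  xyz <- coords_matrix(site)
  key <- paste(site$chain, site$residue_seq, site$residue_name)
  new_rows <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    resname <- site$residue_name[idx[1]]
    if (!resname %in% c(.known_residues, names(rules))) next
    res_rules <- rules[[resname]] %||% list()
    if (!resname %in% c("HOH", "WAT") && !"N" %in% names(res_rules) &&
        is.null(rules[[resname]]$N)) {
      res_rules$N <- rules[["*"]]$N
    }
    if (resname == "PRO") res_rules$N <- c(0, 1.01)
    for (atom_name in names(res_rules)) {
      n_target <- res_rules[[atom_name]][1]
      blen <- res_rules[[atom_name]][2]
      ai <- idx[site$name[idx] == atom_name]
      if (length(ai) == 0 || n_target == 0) next
      ai <- ai[1]
      nbr <- .bonded_neighbours(site, xyz, ai)
      n_have <- sum(site$element[nbr] == "H")
      n_add <- n_target - n_have
      if (n_add <= 0) next
      hpos <- .place_hydrogens(xyz, ai, nbr, n_add, blen)
      for (j in seq_len(n_add)) {
        new_rows[[length(new_rows) + 1]] <- tibble::tibble(
          element = "H",
          name = paste0("H", atom_name, if (n_target > 1) j else ""),
          x = hpos[j, 1], y = hpos[j, 2], z = hpos[j, 3],
          residue_name = resname,
          residue_seq = site$residue_seq[ai],
          chain = site$chain[ai],
          fragment = site$fragment[ai],
          charge = 0
        )
      }
    }
  }
  out <- dplyr::bind_rows(site, !!!new_rows)
  # restore residue grouping order: original order, added H after their residue
  ord <- order(match(paste(out$chain, out$residue_seq, out$residue_name),
                     unique(key)))
  out <- out[ord, , drop = FALSE]
  .copy_site_attrs(out, site)
}

# indices of atoms covalently bonded to atom ai (covalent-radius cutoff)
.bonded_neighbours <- function(structure, xyz, ai, slack = 1.3) {
  d <- sqrt(colSums((t(xyz) - xyz[ai, ])^2))
  cutoff <- slack * (element_covalent(structure$element) +
                       element_covalent(structure$element[ai]))
  setdiff(which(d > 1e-8 & d <= cutoff), ai)
}

# place n_add hydrogens around heavy atom ai at bond length blen, completing
# an idealised tetrahedral arrangement opposite the existing neighbours
.place_hydrogens <- function(xyz, ai, nbr, n_add, blen) {
  centre <- xyz[ai, ]
  if (length(nbr) > 0) {
    u <- t(apply(xyz[nbr, , drop = FALSE], 1, function(p) {
      v <- p - centre; v / sqrt(sum(v^2))
    }))
    base <- -colSums(u)
    if (sqrt(sum(base^2)) < 1e-6) base <- c(0, 0, 1)
  } else {
    base <- c(0, 0, 1)
  }
  base <- base / sqrt(sum(base^2))
  # orthonormal frame around base
  ref <- if (abs(base[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * base) * base
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(base[2] * e1[3] - base[3] * e1[2],
          base[3] * e1[1] - base[1] * e1[3],
          base[1] * e1[2] - base[2] * e1[1])
  out <- matrix(0, n_add, 3)
  if (n_add == 1) {
    out[1, ] <- centre + blen * base
  } else {
    # spread on a cone at the tetrahedral half-angle about `base`
    half <- 70.53 * pi / 180
    for (j in seq_len(n_add)) {
      phi <- 2 * pi * (j - 1) / n_add
      dirn <- cos(half) * base +
        sin(half) * (cos(phi) * e1 + sin(phi) * e2)
      out[j, ] <- centre + blen * dirn
    }
  }
  out
}

.copy_site_attrs <- function(new, old) {
  for (a in c("radius", "center", "mode", "source_residues")) {
    attr(new, a) <- attr(old, a)
  }
  if (inherits(old, "active_site")) {
    class(new) <- c("active_site", class(tibble::tibble()))
  }
  new
}

#' Cap excised peptide termini with hydrogens
#'
#' A residue range cut out of a chain exposes a backbone amide nitrogen
#' whose preceding carbonyl carbon is missing, and a carbonyl carbon whose
#' following nitrogen is missing. Each such atom receives one hydrogen to
#' satisfy valence: along the former N-to-C direction at 1.01 Angstrom for
#' nitrogens, and along the former C-to-N direction at 1.09 Angstrom for
#' carbons. When `reference` (the uncut parent structure) is supplied the
#' true direction to the removed atom is used; otherwise an idealised
#' direction opposite the existing bonded neighbours is constructed. Cap
#' atoms are tagged `fragment = "cap"`.
#'
#' @param site A structure tibble built from excised residue ranges.
#' @param reference Optional full parent structure providing the removed
#'   neighbour positions.
#' @return The site with cap hydrogens appended.
#' @export
cap_termini <- function(site, reference = NULL) {
  validate_structure(site)
  xyz <- coords_matrix(site)
  have <- paste(site$chain, site$residue_seq, site$name)
  caps <- list()
  add_cap <- function(ai, direction, blen) {
    p <- xyz[ai, ] + blen * direction / sqrt(sum(direction^2))
    tibble::tibble(element = "H",
                   name = if (site$name[ai] == "N") "HCAP" else "HCAPC",
                   x = p[1], y = p[2], z = p[3],
                   residue_name = site$residue_name[ai],
                   residue_seq = site$residue_seq[ai],
                   chain = site$chain[ai], fragment = "cap", charge = 0)
  }
  find_ref_atom <- function(chain, seq, name) {
    if (is.null(reference)) return(NULL)
    hit <- which(reference$chain == chain & reference$residue_seq == seq &
                   reference$name == name)
    if (length(hit) == 0) NULL else as.numeric(
      coords_matrix(reference)[hit[1], ])
  }
  idealised_direction <- function(ai) {
    nbr <- .bonded_neighbours(site, xyz, ai)
    nbr <- nbr[site$element[nbr] != "H" | TRUE]
    if (length(nbr) == 0) {
      stop("cannot orient cap: residue ", site$residue_name[ai], " ",
           site$residue_seq[ai], " has no bonded neighbours for atom ",
           site$name[ai], call. = FALSE)
    }
    u <- t(apply(xyz[nbr, , drop = FALSE], 1, function(p) {
      v <- p - xyz[ai, ]; v / sqrt(sum(v^2))
    }))
    d <- -colSums(u)
    if (sqrt(sum(d^2)) < 1e-6) {
      stop("degenerate cap geometry at residue ", site$residue_seq[ai],
           call. = FALSE)
    }
    d
  }
  for (ai in which(site$name == "N" & site$fragment == "site")) {
    prev_key <- paste(site$chain[ai], site$residue_seq[ai] - 1, "C")
    if (prev_key %in% have) next # preceding carbonyl present: peptide intact
    if (!"CA" %in% site$name[site$chain == site$chain[ai] &
                               site$residue_seq == site$residue_seq[ai]]) {
      stop("missing backbone CA needed to cap residue ",
           site$residue_name[ai], " ", site$residue_seq[ai], call. = FALSE)
    }
    ref <- find_ref_atom(site$chain[ai], site$residue_seq[ai] - 1, "C")
    # with a reference, a neighbour absent from the parent too marks a
    # true chain terminus, not an excision cut: leave it uncapped
    if (!is.null(reference) && is.null(ref)) next
    dirn <- if (!is.null(ref)) ref - xyz[ai, ] else idealised_direction(ai)
    caps[[length(caps) + 1]] <- add_cap(ai, dirn, 1.01)
  }
  for (ai in which(site$name == "C" & site$fragment == "site")) {
    next_key <- paste(site$chain[ai], site$residue_seq[ai] + 1, "N")
    if (next_key %in% have) next
    res_atoms <- site$name[site$chain == site$chain[ai] &
                             site$residue_seq == site$residue_seq[ai]]
    if (!all(c("CA", "O") %in% res_atoms)) {
      stop("missing backbone CA/O needed to cap residue ",
           site$residue_name[ai], " ", site$residue_seq[ai], call. = FALSE)
    }
    ref <- find_ref_atom(site$chain[ai], site$residue_seq[ai] + 1, "N")
    if (!is.null(reference) && is.null(ref)) next
    dirn <- if (!is.null(ref)) ref - xyz[ai, ] else idealised_direction(ai)
    caps[[length(caps) + 1]] <- add_cap(ai, dirn, 1.09)
  }
  out <- dplyr::bind_rows(site, !!!caps)
  .copy_site_attrs(out, site)
}
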