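# Shared fixtures, all built in code.

# fixed-width minimal PDB writer for parser tests
write_min_pdb <- function(path, atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$record, i, a$name, a$alt %||% "", a$resname, a$chain, a$resseq,
            a$x, a$y, a$z, a$occ %||% 1, 0, a$element %||% "")
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pdb_atom_row <- function(record = "ATOM", name = "N", resname = "ALA",
                         chain = "A", resseq = 1L, x = 0, y = 0, z = 0,
                         element = "N", alt = "", occ = 1) {
  tibble::tibble(record = record, name = name, resname = resname,
                 chain = chain, resseq = as.integer(resseq),
                 x = x, y = y, z = z, element = element, alt = alt,
                 occ = occ)
}

# two-atom Lennard-Jones dimer along x
lj_dimer <- function(r, element = "C") {
  mol_structure(c(element, element), x = c(0, r), y = 0, z = 0)
}

# independent dihedral-rotation oracle: geometric decomposition about the
# axis (not the implementation's matrix form)
rotate_point_oracle <- function(p, axis_a, axis_b, angle_deg) {
  u <- (axis_b - axis_a) / sqrt(sum((axis_b - axis_a)^2))
  v <- p - axis_b
  v_par <- sum(v * u) * u
  v_perp <- v - v_par
  w <- c(u[2] * v_perp[3] - u[3] * v_perp[2],
         u[3] * v_perp[1] - u[1] * v_perp[3],
         u[1] * v_perp[2] - u[2] * v_perp[1])
  th <- angle_deg * pi / 180
  axis_b + v_par + cos(th) * v_perp + sin(th) * w
}

ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# minimal backbone coordinates for a two-residue peptide fragment
two_residue_fragment <- function(resseq = c(10L, 11L)) {
  mol_structure(
    element = c("N", "C", "C", "O", "N", "C", "C", "O"),
    name = c("N", "CA", "C", "O", "N", "CA", "C", "O"),
    x = c(0.0, 1.46, 2.00, 1.45, 3.30, 4.20, 5.70, 6.30),
    y = c(0.0, 0.00, 1.35, 2.40, 1.40, 2.60, 2.45, 1.40),
    z = 0,
    residue_name = "ALA",
    residue_seq = rep(resseq, each = 4),
    chain = "A", fragment = "site"
  )
}
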