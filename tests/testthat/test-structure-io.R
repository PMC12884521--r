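test_that("minimal PDB records parse with elements, residues and fragments", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_min_pdb(path, dplyr::bind_rows(
    pdb_atom_row(),
    pdb_atom_row(record = "HETATM", name = "C1", resname = "VDX",
                 resseq = 2L, x = 3, element = "C")
  ))
  s <- read_pdb(path)
  expect_equal(nrow(s), 2)
  expect_equal(s$element, c("N", "C"))
  expect_equal(s$residue_name, c("ALA", "VDX"))
  expect_equal(s$residue_seq, c(1L, 2L))
  expect_setequal(s$fragment, c("site", "ligand"))
})

test_that("elements are inferred from atom names when the column is blank", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_min_pdb(path, dplyr::bind_rows(
    pdb_atom_row(name = "CA", element = ""),
    pdb_atom_row(record = "HETATM", name = "CL1", resname = "LIG",
                 resseq = 2L, x = 5, element = "")
  ))
  s <- read_pdb(path, ligand_code = "LIG")
  expect_equal(s$element, c("C", "Cl")) # protein CA is carbon, het CL chlorine
})

test_that("alternate locations keep the highest occupancy, ties first", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_min_pdb(path, dplyr::bind_rows(
    pdb_atom_row(alt = "A", occ = 0.4, x = 0),
    pdb_atom_row(alt = "B", occ = 0.6, x = 9),
    pdb_atom_row(name = "CA", element = "C", alt = "A", occ = 0.5, x = 1),
    pdb_atom_row(name = "CA", element = "C", alt = "B", occ = 0.5, x = 7)
  ))
  s <- read_pdb(path)
  expect_equal(nrow(s), 2)
  expect_equal(s$x[s$name == "N"], 9)  # occupancy 0.6 wins
  expect_equal(s$x[s$name == "CA"], 1) # tie: first listed
})

test_that("unparsable coordinates raise an error naming the line", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(write_min_pdb(withr::local_tempfile(), dplyr::bind_rows(
    pdb_atom_row(), pdb_atom_row(name = "CA", element = "C", resseq = 1L)
  )))
  substr(lines[2], 31, 38) <- "  xx.yyy"
  writeLines(lines, path)
  expect_error(read_pdb(path), "line 2")
  expect_error(read_pdb(tempfile()), "cannot read")
})

test_that("XYZ round trip preserves elements and coordinates", {
  s <- mol_structure(c("C", "N", "O"),
                     x = c(0, 1.234567891, -2.5),
                     y = c(0.1, -0.987654321, 3),
                     z = c(5, 0, -0.000001))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(s, path)
  back <- read_xyz(path)
  expect_equal(back$element, s$element)
  expect_lt(max(abs(coords_matrix(back) - coords_matrix(s))), 1e-6)
  expect_error(write_xyz(s[0, ], path))
})

test_that("multi-frame XYZ files recover all frames in order", {
  frames <- lapply(1:26, function(i) {
    mol_structure(c("C", "O"), x = c(0, i), y = 0, z = 0,
                  title = paste("conformer", i))
  })
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(frames, path)
  back <- read_xyz_frames(path)
  expect_length(back, 26)
  expect_equal(vapply(back, function(fr) fr$x[2], numeric(1)),
               as.numeric(1:26))
  expect_error(read_xyz(path), "26 frames")
  # truncated file: header count exceeds remaining lines
  writeLines(c("3", "broken", "C 0 0 0"), path)
  expect_error(read_xyz_frames(path), "mismatch")
})

test_that("cube export writes bohr coordinates and z-fastest values", {
  g <- grid_field(origin = c(0, 0, 0), axes = diag(0.5, 3),
                  dims = c(2, 2, 2), values = rep(0, 8))
  s <- mol_structure("O", x = 1, y = 2, z = 3)
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(g, s, path)
  lines <- readLines(path)
  atom <- as.numeric(strsplit(trimws(lines[7]), "\\s+")[[1]])
  expect_equal(atom[1], 8) # atomic number of oxygen
  expect_equal(atom[3:5], c(1, 2, 3) * 1.8897259886, tolerance = 1e-6)
  expect_length(unlist(strsplit(trimws(lines[-(1:7)]), "\\s+")), 8)
})

test_that("cube write -> read -> write is byte-stable", {
  set.seed(42)
  g <- grid_field(origin = c(-1, 0, 2), axes = diag(0.3, 3),
                  dims = c(3, 4, 2), values = rnorm(24))
  s <- mol_structure(c("C", "H"), x = c(0, 1), y = 0, z = 0)
  p1 <- withr::local_tempfile(fileext = ".cube")
  p2 <- withr::local_tempfile(fileext = ".cube")
  write_cube(g, s, p1)
  back <- read_cube(p1)
  write_cube(back$grid, back$structure, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("inconsistent grids and unknown elements are rejected", {
  expect_error(grid_field(c(0, 0, 0), diag(3), c(3, 3, 3), rep(0, 26)),
               "26")
  expect_error(grid_field(c(0, 0, 0), matrix(1, 3, 3), c(2, 2, 2),
                          rep(0, 8)), "independent")
  expect_error(mol_structure("Xx", x = 0, y = 0, z = 0), "unknown element")
  expect_error(element_vdw("Zz"), "unknown element")
})
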