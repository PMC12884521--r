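test_that("centre of mass is mass-weighted and translation-equivariant", {
  two <- mol_structure(c("C", "C"), x = c(0, 2), y = 0, z = 0)
  expect_equal(unname(center_of_mass(two)), c(1, 0, 0))
  oh <- mol_structure(c("O", "H"), x = c(0, 0.96), y = 0, z = 0)
  expect_equal(unname(center_of_mass(oh))[1], 0.056899, tolerance = 1e-5)
  shifted <- oh
  shifted$x <- shifted$x + 3.2; shifted$y <- shifted$y - 1.1
  expect_equal(unname(center_of_mass(shifted)),
               unname(center_of_mass(oh)) + c(3.2, -1.1, 0))
  expect_error(center_of_mass(oh[0, ]))
})

make_site_system <- function(dists) {
  lig <- mol_structure("C", x = 0, y = 0, z = 0, residue_name = "LIG")
  res <- dplyr::bind_rows(lapply(seq_along(dists), function(i) {
    mol_structure("C", x = dists[i], y = 0, z = 0, name = "CA",
                  residue_name = "ALA", residue_seq = i + 1L,
                  fragment = "site")
  }))
  dplyr::bind_rows(lig, res)
}

test_that("site selection is residue-level with an inclusive boundary", {
  s <- make_site_system(c(5.99, 6.01))
  site <- select_site(s, radius = 6.0, mode = "any_atom")
  expect_equal(unique(site$residue_seq), 2L) # 5.99 in, 6.01 out
  expect_equal(nrow(attr(site, "source_residues")), 1)
  # whole residues enter: one near atom drags in a far atom of the same one
  split_res <- dplyr::bind_rows(
    mol_structure("C", x = 0, y = 0, z = 0, residue_name = "LIG"),
    mol_structure(c("C", "C"), name = c("CA", "CB"),
                  x = c(5.0, 9.0), y = 0, z = 0, residue_name = "ALA",
                  residue_seq = 2L, fragment = "site")
  )
  expect_equal(nrow(select_site(split_res, 6)), 2)
})

test_that("site selection limits behave: infinite radius takes all, tiny none", {
  s <- make_site_system(c(3, 30, 300))
  expect_equal(nrow(select_site(s, radius = Inf)), 3)
  expect_equal(nrow(select_site(s, radius = 1e-9, mode = "com_sphere")), 0)
  expect_error(select_site(s, radius = 0), "positive")
  expect_error(select_site(dplyr::mutate(s, fragment = "site")), "no ligand")
})

test_that("waters are excluded from selection by default", {
  s <- dplyr::bind_rows(
    mol_structure("C", x = 0, y = 0, z = 0, residue_name = "LIG"),
    mol_structure("O", name = "O", x = 3, y = 0, z = 0,
                  residue_name = "HOH", residue_seq = 2L,
                  fragment = "site"),
    mol_structure("C", name = "CA", x = 4, y = 0, z = 0,
                  residue_name = "ALA", residue_seq = 3L, fragment = "site")
  )
  expect_equal(unique(select_site(s, 6)$residue_name), "ALA")
  expect_setequal(unique(select_site(s, 6, include_waters = TRUE)$residue_name),
                  c("HOH", "ALA"))
})

test_that("protonation applies pH 7.4 residue rules", {
  lys <- mol_structure(
    c("N", "C", "C", "O", "N"),
    name = c("N", "CA", "C", "O", "NZ"),
    x = c(0, 1.46, 2.0, 1.45, 8.0), y = c(0, 0, 1.35, 2.4, 0), z = 0,
    residue_name = "LYS", fragment = "site"
  )
  p <- protonate(lys)
  xyz <- coords_matrix(p)
  nz <- which(p$name == "NZ")
  h_near_nz <- sum(p$element == "H" &
                     sqrt(rowSums(sweep(xyz, 2, xyz[nz, ])^2)) < 1.3)
  expect_equal(h_near_nz, 3) # protonated side-chain amine
  asp <- mol_structure(
    c("N", "C", "C", "O", "O", "O"),
    name = c("N", "CA", "C", "O", "OD1", "OD2"),
    x = c(0, 1.46, 2.0, 1.45, 8.0, 9.1), y = c(0, 0, 1.35, 2.4, 0, 0.5),
    z = 0, residue_name = "ASP", fragment = "site"
  )
  pa <- protonate(asp)
  xyz <- coords_matrix(pa)
  for (nm in c("OD1", "OD2")) {
    oi <- which(pa$name == nm)
    expect_equal(sum(pa$element == "H" &
                       sqrt(rowSums(sweep(xyz, 2, xyz[oi, ])^2)) < 1.2),
                 0) # carboxylate stays deprotonated
  }
})

test_that("protonation is idempotent and warns on unknown residues", {
  gly <- mol_structure(
    c("N", "C", "C", "O"),
    name = c("N", "CA", "C", "O"),
    x = c(0, 1.46, 2.0, 1.45), y = c(0, 0, 1.35, 2.4), z = 0,
    residue_name = "GLY", fragment = "site"
  )
  once <- protonate(gly)
  expect_gt(nrow(once), nrow(gly)) # backbone amide H added
  expect_equal(nrow(protonate(once)), nrow(once))
  odd <- dplyr::mutate(gly, residue_name = "XXX")
  expect_warning(out <- protonate(odd), "XXX")
  expect_equal(nrow(out), nrow(odd))
})

test_that("capping adds one hydrogen per excised peptide cut", {
  frag <- two_residue_fragment()
  capped <- cap_termini(frag)
  expect_equal(sum(capped$fragment == "cap"), 2) # one cut on each side
  expect_equal(unique(capped$element[capped$fragment == "cap"]), "H")
  nb <- capped[capped$fragment != "cap", ]
  expect_equal(nb$name, frag$name)
  expect_equal(coords_matrix(nb), coords_matrix(frag))
})

test_that("capping respects intact peptide bonds and true termini", {
  frag <- two_residue_fragment()
  # residue 11's N follows residue 10's C: that junction is never capped
  capped <- cap_termini(frag)
  cap_xyz <- coords_matrix(capped[capped$fragment == "cap", ])
  n11 <- coords_matrix(frag)[frag$name == "N" & frag$residue_seq == 11, ]
  expect_gt(min(sqrt(rowSums(sweep(cap_xyz, 2, n11)^2))), 1.2)
  # with the parent as reference, true chain termini are left alone
  expect_equal(sum(cap_termini(frag, reference = frag)$fragment == "cap"), 0)
  # but a residue cut out of a longer parent is capped towards the removed
  # neighbour's actual position
  parent <- dplyr::bind_rows(
    two_residue_fragment(c(9L, 10L))[1:4, ], two_residue_fragment()
  )
  site <- parent[parent$residue_seq >= 10, ]
  capped_ref <- cap_termini(site, reference = parent)
  expect_equal(sum(capped_ref$fragment == "cap"), 1) # only the 9|10 cut
})
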