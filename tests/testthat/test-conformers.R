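test_that("pose enumeration counts follow the closed-form product", {
  toy <- make_toy_complex(toy_complex_spec(seed = 2))
  rec <- enumerate_poses(toy$ligand, toy$dihedrals, angle_step = 90)
  expect_equal(nrow(rec), 16) # 4^2 dihedral combinations
  expect_equal(enumerate_poses(toy$ligand, toy$dihedrals[1],
                               angle_step = 90,
                               translations = translation_grid(),
                               count_only = TRUE), 108) # 4 * 27
  specs8 <- rep(toy$dihedrals[1], 8)
  expect_equal(enumerate_poses(toy$ligand, specs8, angle_step = 90,
                               count_only = TRUE), 65536) # 4^8
  expect_error(enumerate_poses(toy$ligand, specs8, angle_step = 90,
                               cap = 1e4), "65536")
  expect_error(enumerate_poses(toy$ligand, toy$dihedrals, angle_step = 77),
               "divide")
})

test_that("enumeration order is deterministic and lexicographic", {
  toy <- make_toy_complex(toy_complex_spec(seed = 2))
  rec <- enumerate_poses(toy$ligand, toy$dihedrals, angle_step = 90)
  d <- do.call(rbind, rec$dihedrals)
  expect_equal(d[, 1], rep(c(0, 90, 180, 270), each = 4))
  expect_equal(d[, 2], rep(c(0, 90, 180, 270), times = 4))
  rec2 <- enumerate_poses(toy$ligand, toy$dihedrals, angle_step = 90)
  expect_identical(rec$pose, rec2$pose)
})

test_that("clash filtering removes overlapping poses and only those", {
  toy <- make_toy_complex(toy_complex_spec(planted_clash = c(180, 90),
                                           seed = 7))
  rec <- enumerate_poses(toy$ligand, toy$dihedrals, angle_step = 90)
  surv <- clash_filter(rec, toy$site)
  expect_equal(nrow(surv), 15)
  removed <- rec$dihedrals[setdiff(rec$id, surv$id)]
  expect_equal(removed[[1]], c(d1 = 180, d2 = 90))
  # vacuous filter: empty site keeps everything
  expect_equal(nrow(clash_filter(rec, toy$site[0, ])), 16)
  # coincident atoms always clash
  onsite <- mol_structure("C", x = toy$ligand$x[1], y = toy$ligand$y[1],
                          z = toy$ligand$z[1], fragment = "site")
  expect_equal(nrow(clash_filter(rec[1, ], onsite)), 0)
})

test_that("local minimisation finds the Lennard-Jones dimer minimum", {
  r_min <- 3.8983 # Dreiding carbon R0
  dimer <- lj_dimer(1.2 * r_min)
  backend <- ff_backend()
  res <- local_minimize(dimer[2, ], dimer[1, ] |>
                          dplyr::mutate(fragment = "site"), backend,
                        free_atoms = 1)
  expect_true(res$converged)
  expect_equal(unname(res$pose$x[1]), r_min, tolerance = 1e-4 / r_min)
  expect_equal(res$energy, -ff_params()$lj$epsilon[
    ff_params()$lj$element == "C"], tolerance = 1e-6)
})

test_that("minimisation is a fixed point at a minimum and freezes the site", {
  r_min <- 3.8983
  dimer <- lj_dimer(r_min)
  site1 <- dplyr::mutate(dimer[1, ], fragment = "site")
  res <- local_minimize(dimer[2, ], site1, ff_backend(), free_atoms = 1)
  expect_lt(abs(res$energy - (-0.0951)), 1e-8) # already at the minimum
  expect_lt(abs(res$pose$x[1] - r_min), 1e-6)
  toy <- make_toy_complex(toy_complex_spec(seed = 4))
  backend <- ff_backend(toy$params, bonds = cbind(1:5, 2:6),
                        hbonds = toy$wells, valence = TRUE,
                        valence_ref = toy$ligand)
  m1 <- local_minimize(toy$ligand, toy$site, backend)
  expect_identical(coords_matrix(m1$site), coords_matrix(toy$site))
})

test_that("minimum verification accepts minima and flags saddles", {
  r_min <- 3.8983
  dimer <- lj_dimer(r_min)
  site1 <- dplyr::mutate(dimer[1, ], fragment = "site")
  backend <- ff_backend()
  expect_true(verify_minimum(dimer[2, ], site1, backend, free_atoms = 1))
  # midpoint between two repulsive walls: stationary but unstable sideways
  walls <- mol_structure(c("C", "C"), x = c(-3.6, 3.6), y = 0, z = 0,
                         fragment = "site")
  centre <- mol_structure("C", x = 0, y = 0, z = 0)
  expect_false(verify_minimum(centre, walls, backend, free_atoms = 1))
  # off-stationary points are not judged
  expect_warning(v <- verify_minimum(lj_dimer(3.0)[2, ], site1, backend,
                                     free_atoms = 1), "not stationary")
  expect_true(is.na(v))
})

test_that("deduplication merges near-identical poses and keeps energy order", {
  toy <- make_toy_complex(toy_complex_spec(seed = 3))
  base <- toy$ligand
  twisted <- rotate_dihedral(base, toy$dihedrals[[1]], 25)
  r_twist <- kabsch_rmsd(base, twisted)
  translated <- base
  translated$x <- translated$x + 5 # pure translation: zero after fit
  rec <- tibble::tibble(
    id = 1:3,
    dihedrals = list(c(0, 0), c(25, 0), c(0, 0)),
    tx = 0, ty = 0, tz = 0,
    pose = list(base, twisted, translated),
    energy = c(2, 1, 3), is_minimum = NA
  )
  kept_tight <- deduplicate(rec, rmsd_threshold = r_twist + 0.01)
  expect_equal(nrow(kept_tight), 1)
  expect_equal(kept_tight$energy, 1) # lowest-energy member survives
  kept_loose <- deduplicate(rec, rmsd_threshold = r_twist - 0.01)
  expect_equal(nrow(kept_loose), 2)
  expect_true(all(diff(kept_loose$energy) >= 0))
  expect_identical(deduplicate(kept_loose, r_twist - 0.01), kept_loose)
  bad <- rec
  bad$pose[[2]] <- base[1:3, ]
  expect_error(deduplicate(bad), "mismatched")
})

test_that("scan, filter, minimise and deduplicate recover the planted fold", {
  for (s in c(2, 9)) {
    toy <- make_toy_complex(toy_complex_spec(seed = s))
    backend <- ff_backend(toy$params, bonds = cbind(1:5, 2:6),
                          hbonds = toy$wells, valence = TRUE,
                        valence_ref = toy$ligand)
    rec <- enumerate_poses(toy$ligand, toy$dihedrals, angle_step = 90)
    rec <- clash_filter(rec, toy$site)
    rec <- minimize_conformers(rec, toy$site, backend)
    rec <- deduplicate(rec)
    planted <- toy$ligand
    for (k in seq_along(toy$dihedrals)) {
      planted <- rotate_dihedral(planted, toy$dihedrals[[k]],
                                 toy$spec$planted_minimum[k])
    }
    got <- vapply(seq_along(toy$dihedrals), function(k) {
      measure_dihedral(rec$pose[[1]], toy$dihedrals[[k]])
    }, numeric(1))
    want <- vapply(seq_along(toy$dihedrals), function(k) {
      measure_dihedral(planted, toy$dihedrals[[k]])
    }, numeric(1))
    expect_true(all(ang_diff(got, want) < 45))
    expect_true(verify_minimum(rec$pose[[1]], toy$site, backend))
  }
})
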