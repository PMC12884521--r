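test_that("Lennard-Jones term hits -epsilon at the minimum and vanishes far", {
  sigma_c <- 3.8983 / 2^(1 / 6)
  eps_c <- 0.0951
  expect_equal(ff_energy(lj_dimer(2^(1 / 6) * sigma_c)), -eps_c,
               tolerance = 1e-12)
  expect_lt(abs(ff_energy(lj_dimer(1e6))), 1e-20)
  expect_error(ff_energy(mol_structure(c("Na", "Ar", "Mg"),
                                       x = c(0, 3, 6), y = 0, z = 0)),
               "Mg")
})

test_that("Coulomb term reproduces the hand-checked value", {
  pair <- mol_structure(c("C", "C"), x = c(0, 3.320637), y = 0, z = 0,
                        charge = c(1, -1))
  lj_off <- ff_params(lj = tibble::tibble(element = "C", sigma = 1,
                                          epsilon = 0))
  expect_equal(ff_energy(pair, lj_off), -100.0, tolerance = 1e-12)
  pair$charge <- c(1, 1)
  expect_equal(ff_energy(pair, lj_off), 100.0, tolerance = 1e-12)
})

test_that("analytic gradients match central differences on random clusters", {
  set.seed(101)
  for (rep in 1:3) {
    n <- 6
    s <- mol_structure(sample(c("C", "N", "O", "H"), n, replace = TRUE),
                       x = 4 * runif(n), y = 4 * runif(n), z = 4 * runif(n),
                       charge = round(runif(n, -0.5, 0.5), 2))
    bonds <- cbind(1:2, 2:3)
    # the compiled evaluator freezes valence equilibria at the reference
    # geometry, so a displaced probe exercises every term
    ev <- ff_backend(bonds = bonds, valence = TRUE)$compile(s)
    xyz <- coords_matrix(s) + matrix(runif(3 * n, -0.2, 0.2), ncol = 3)
    g <- ev(xyz, gradient = TRUE)$gradient
    h <- 1e-5
    num <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      for (d in 1:3) {
        xp <- xyz; xp[i, d] <- xp[i, d] + h
        xm <- xyz; xm[i, d] <- xm[i, d] - h
        num[i, d] <- (ev(xp)$energy - ev(xm)$energy) / (2 * h)
      }
    }
    expect_lt(max(abs(g - num)) / max(abs(num)), 1e-4)
  }
})

test_that("bonded exclusions and pair scopes restrict the sum correctly", {
  tri <- mol_structure(c("C", "C", "C"), x = c(0, 1.5, 3.0), y = 0, z = 0)
  bonds <- cbind(c(1, 2), c(2, 3))
  # 1-2 and 1-3 excluded: nothing remains in a three-atom chain
  expect_equal(ff_energy(tri, bonds = bonds), 0)
  mixed <- dplyr::bind_rows(
    mol_structure("C", x = 0, y = 0, z = 0),
    mol_structure(c("C", "C"), x = c(0.5, 4), y = 0, z = 0,
                  fragment = "site")
  )
  e_inter <- ff_energy(mixed, pair_scope = "inter_fragment")
  e_all <- ff_energy(mixed)
  site_only <- ff_energy(mixed[2:3, ])
  expect_equal(e_all - site_only, e_inter, tolerance = 1e-10)
})

test_that("the 12-10 well applies to declared pairs with per-pair parameters", {
  pair <- mol_structure(c("O", "O"), x = c(0, 3.1), y = 0, z = 0)
  wells <- tibble::tibble(h_idx = 1, acceptor_idx = 2, depth = 12, r0 = 3.1)
  expect_equal(ff_energy(pair, hbonds = wells), -12, tolerance = 1e-12)
  # default global well parameters apply when no override columns exist
  d <- ff_params()$hb_depth
  at_r0 <- mol_structure(c("O", "O"), x = c(0, ff_params()$hb_r0),
                         y = 0, z = 0)
  expect_equal(ff_energy(at_r0, hbonds = tibble::tibble(h_idx = 1,
                                                        acceptor_idx = 2)),
               -d, tolerance = 1e-12)
})

test_that("two-layer combination satisfies its identity and collapse cases", {
  o <- oniom2_combine(10, 5, 3)
  expect_equal(o$e_oniom2, 12)
  expect_equal(o$e_oniom2, o$e_high_model + o$e_low_real - o$e_low_model)
  expect_equal(oniom2_combine(4.2, 9.9, 4.2)$e_oniom2, 9.9) # high == low
  expect_equal(oniom2_combine(7.7, 5.5, 5.5)$e_oniom2, 7.7) # model == real
  expect_error(oniom2_combine(1, Inf, 2), "finite")
  expect_equal(tidy(o)$energy, c(10, 5, 3, 12))
})

test_that("two-layer scoring matches hand-combined independent calls", {
  toy <- make_toy_complex(toy_complex_spec(seed = 6))
  complex <- dplyr::bind_rows(toy$ligand, toy$site)
  bonds <- cbind(1:5, 2:6)
  high <- ff_backend(toy$params, bonds = bonds)
  low <- ff_backend(ff_params(dielectric = "distance_dependent"),
                    bonds = bonds)
  o <- oniom2_score(complex, high, low)
  expect_equal(o$e_high_model, high$energy(toy$ligand))
  expect_equal(o$e_low_real, low$energy(complex))
  expect_equal(o$e_low_model, low$energy(toy$ligand))
  expect_equal(o$e_oniom2,
               high$energy(toy$ligand) + low$energy(complex) -
                 low$energy(toy$ligand))
  # identical backends collapse to the low level on the full system
  same <- oniom2_score(complex, high, high)
  expect_equal(same$e_oniom2, high$energy(complex), tolerance = 1e-10)
  # no site at all: the high-level model energy is the answer
  lig_only <- oniom2_score(toy$ligand, high, low)
  expect_equal(lig_only$e_oniom2, high$energy(toy$ligand))
  # a ligand covalently fused to the site needs link atoms: refused
  fused <- complex
  fused$x[7] <- fused$x[1] + 1.0
  fused$y[7] <- fused$y[1]; fused$z[7] <- fused$z[1]
  expect_error(oniom2_score(fused, high, low), "link-atom")
})

test_that("Boltzmann populations match the closed-form two-state value", {
  b <- boltzmann_populations(c(0, 0.665), 298.15)
  expect_equal(b$population, c(0.754432, 0.245568), tolerance = 1e-6)
  expect_equal(sum(b$population), 1, tolerance = 1e-12)
  expect_equal(boltzmann_populations(5.5)$population, 1)
  expect_equal(boltzmann_populations(rep(1.23, 7))$population,
               rep(1 / 7, 7), tolerance = 1e-12)
  expect_error(boltzmann_populations(numeric(0)), "empty")
  expect_error(boltzmann_populations(c(0, 1), temperature = 0), "positive")
})

test_that("Boltzmann populations obey shift invariance and T limits", {
  dg <- c(0, 0.3, 1.1, 2.7)
  a <- boltzmann_populations(dg)
  b <- boltzmann_populations(dg + 123.456)
  expect_equal(a$population, b$population, tolerance = 1e-12)
  expect_true(all(diff(a$population) <= 0)) # lower energy, higher weight
  hot <- boltzmann_populations(dg, temperature = 1e9)
  expect_equal(hot$population, rep(0.25, 4), tolerance = 1e-6)
  cold <- boltzmann_populations(dg, temperature = 1e-3)
  expect_equal(cold$population[1], 1, tolerance = 1e-12)
  # overflow safety at large gaps
  expect_equal(sum(boltzmann_populations(c(0, 5000))$population), 1)
  g <- glance(a)
  expect_equal(g$n_conformers, 4)
  expect_equal(g$temperature, 298.15)
})

test_that("binding energy decomposition is exact arithmetic", {
  b <- binding_energy(-100, -60, -30)
  expect_equal(b$binding_energy, -10)
  expect_equal(b$binding_energy,
               b$e_complex - (b$e_active_site + b$e_ligand))
  expect_equal(tidy(b)$energy[4], -10)
  expect_error(binding_energy(NaN, 0, 0), "finite")
})

test_that("non-interacting fragments bind with zero energy", {
  far <- dplyr::bind_rows(
    mol_structure(c("C", "O"), x = c(0, 1.5), y = 0, z = 0),
    mol_structure(c("C", "N"), x = c(1e6, 1e6 + 1.5), y = 0, z = 0,
                  fragment = "site")
  )
  backend <- ff_backend(pair_scope = "inter_fragment")
  b <- binding_energy(backend$energy(far),
                      ff_energy(far[3:4, ], pair_scope = "inter_fragment"),
                      ff_energy(far[1:2, ], pair_scope = "inter_fragment"))
  expect_lt(abs(b$binding_energy), 1e-10)
})

test_that("dissociation constants convert to binding free energies", {
  expect_equal(delta_g_from_kd(1), 0)
  expect_equal(delta_g_from_kd(0.37e-9, 298.15), -12.8673,
               tolerance = 1e-4)
  dd <- delta_g_from_kd(1e-6) - delta_g_from_kd(1e-7)
  expect_equal(dd, 1.3642, tolerance = 1e-4) # RT ln 10
  expect_error(delta_g_from_kd(0), "positive")
  expect_error(delta_g_from_kd(1e-9, temperature = -5), "positive")
})
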