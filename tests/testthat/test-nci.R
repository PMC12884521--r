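test_that("promolecular density matches its shell parameters at the nucleus", {
  h <- mol_structure("H", x = 0, y = 0, z = 0)
  model <- promolecular_model()
  d <- promolecular_density(h, matrix(0, 1, 3), hessian = FALSE)
  expect_equal(d$rho, sum(model$c[model$element == "H"]), tolerance = 1e-12)
  # additivity of fragments, and decay to zero far away
  dimer <- dplyr::bind_rows(
    mol_structure("O", x = 0, y = 0, z = 0),
    mol_structure("H", x = 2, y = 0, z = 0, fragment = "site")
  )
  pts <- matrix(c(0.7, 0.3, -0.2, 5, 1, 0), 2, 3, byrow = TRUE)
  tot <- promolecular_density(dimer, pts, hessian = FALSE)
  pa <- promolecular_density(dimer[1, ], pts, hessian = FALSE)
  pb <- promolecular_density(dimer[2, ], pts, hessian = FALSE)
  expect_equal(tot$rho, pa$rho + pb$rho, tolerance = 1e-12)
  far <- promolecular_density(h, matrix(c(200, 0, 0), 1, 3))
  expect_lt(far$rho, 1e-12)
  expect_lt(max(abs(far$grad)), 1e-12)
  expect_error(promolecular_density(
    mol_structure("Na", x = 0, y = 0, z = 0), pts,
    model = model[model$element == "H", ]), "Na")
})

test_that("analytic derivatives agree with finite differences", {
  set.seed(31)
  s <- mol_structure(c("C", "O", "H"), x = c(0, 1.2, -0.8),
                     y = c(0, 0.4, 1.0), z = c(0, -0.3, 0.2))
  pts <- matrix(runif(15, -3, 3), 5, 3)
  d <- promolecular_density(s, pts)
  h <- 1e-5
  for (p in 1:5) {
    for (dim in 1:3) {
      pp <- pts[p, , drop = FALSE]; pp[dim] <- pp[dim] + h
      pm <- pts[p, , drop = FALSE]; pm[dim] <- pm[dim] - h
      num_g <- as.numeric(
        promolecular_density(s, pp, hessian = FALSE)$rho -
          promolecular_density(s, pm, hessian = FALSE)$rho) / (2 * h)
      expect_equal(d$grad[p, dim], num_g, tolerance = 1e-6)
      num_h <- (promolecular_density(s, pp)$grad[1, ] -
                  promolecular_density(s, pm)$grad[1, ]) / (2 * h)
      expect_equal(d$hessian[p, , dim], num_h, tolerance = 1e-5)
    }
  }
})

test_that("reduced density gradient matches the single-shell closed form", {
  h <- mol_structure("H", x = 0, y = 0, z = 0)
  model <- promolecular_model()
  cc <- model$c[model$element == "H"]
  zeta <- model$zeta[model$element == "H"]
  r <- c(0.5, 1, 2, 3.5, 5)
  pts <- cbind(r, 0, 0)
  d <- promolecular_density(h, pts, hessian = FALSE)
  s_grid <- reduced_density_gradient(d$rho, d$grad)
  s_closed <- exp(r / (3 * zeta)) /
    (2 * (3 * pi^2)^(1 / 3) * zeta * cc^(1 / 3))
  expect_equal(s_grid, s_closed, tolerance = 1e-10)
  # homogeneity: scaling the density by lambda scales s by lambda^(-1/3)
  lam <- 7
  expect_equal(reduced_density_gradient(lam * d$rho, lam * d$grad),
               lam^(-1 / 3) * s_grid, tolerance = 1e-12)
  expect_equal(reduced_density_gradient(c(1, 2), matrix(0, 2, 3)),
               c(0, 0))
  expect_error(reduced_density_gradient(c(1, -1), matrix(0, 2, 3)),
               "positive")
})

test_that("signed density takes the middle Hessian eigenvalue's sign", {
  h <- mol_structure("H", x = 0, y = 0, z = 0)
  pts <- matrix(c(1.1, 0.4, -0.3), 1, 3)
  d <- promolecular_density(h, pts)
  # spherical decaying density: tangential curvature negative off-nucleus
  expect_equal(signed_density(d$rho, d$hessian), -d$rho)
  ref <- sort(eigen(d$hessian[1, , ], symmetric = TRUE)$values)[2]
  expect_lt(ref, 0)
  # midpoint of a close dimer: attractive-like signature
  dimer <- dplyr::bind_rows(
    mol_structure("O", x = 0, y = 0, z = 0),
    mol_structure("O", x = 2.0, y = 0, z = 0, fragment = "site")
  )
  mid <- promolecular_density(dimer, matrix(c(1 * 1.8897259886, 0, 0),
                                            1, 3))
  expect_lt(signed_density(mid$rho, mid$hessian), 0)
  bad <- d$hessian
  bad[1, 1, 2] <- bad[1, 1, 2] + 1e-6
  expect_error(signed_density(d$rho, bad), "symmetric")
})

test_that("the vectorised middle eigenvalue matches base eigen()", {
  set.seed(17)
  hs <- array(0, dim = c(20, 3, 3))
  for (i in 1:20) {
    a <- matrix(rnorm(9), 3, 3)
    hs[i, , ] <- (a + t(a)) / 2
  }
  mine <- pocketconf:::.lambda2(hs)
  ref <- vapply(1:20, function(i) {
    sort(eigen(hs[i, , ], symmetric = TRUE, only.values = TRUE)$values)[2]
  }, numeric(1))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("interaction classification partitions every point once", {
  v <- c(-0.03, -0.011, -0.01, 0, 0.01, 0.011, 0.03)
  cls <- classify_points(v, delta = 0.01)
  expect_equal(as.character(cls),
               c("attractive", "attractive", "van_der_waals",
                 "van_der_waals", "van_der_waals", "repulsive",
                 "repulsive"))
  expect_false(anyNA(cls))
  expect_error(classify_points(v, delta = -1))
})

test_that("RDG fields are invariant under rigid motion of the system", {
  dimer <- make_hbond_dimer(1.8, 170)
  pts <- matrix(runif(12, -1, 4), 4, 3)
  d0 <- promolecular_density(dimer, pts, hessian = FALSE)
  s0 <- reduced_density_gradient(d0$rho, d0$grad)
  th <- 0.9
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3)
  shift <- c(1.5, -2, 0.7)
  moved <- set_coords(dimer,
                      sweep(coords_matrix(dimer) %*% rot, 2, shift, "+"))
  pts_moved <- sweep(pts %*% rot, 2, shift * 1.8897259886, "+") # bohr
  d1 <- promolecular_density(moved, pts_moved, hessian = FALSE)
  expect_equal(reduced_density_gradient(d1$rho, d1$grad), s0,
               tolerance = 1e-9)
})

test_that("identical atoms give mirror-symmetric fields", {
  pair <- mol_structure(c("N", "N"), x = c(-1, 1), y = 0, z = 0)
  pts_a <- cbind(-2.5, c(0.3, 1), c(-0.4, 0.6))
  pts_b <- cbind(2.5, c(0.3, 1), c(-0.4, 0.6)) # mirror through x = 0
  da <- promolecular_density(pair, pts_a)
  db <- promolecular_density(pair, pts_b)
  expect_equal(da$rho, db$rho, tolerance = 1e-12)
  expect_equal(signed_density(da$rho, da$hessian),
               signed_density(db$rho, db$hessian), tolerance = 1e-12)
})

test_that("grid evaluation masks dense points and single fragments", {
  lone <- mol_structure("O", x = 0, y = 0, z = 0)
  g1 <- nci_grid(lone, spacing = 0.5, padding = 1.0,
                 intermolecular_only = TRUE)
  expect_equal(sum(g1$mask), 0) # one fragment: nothing intermolecular
  dimer <- make_hbond_dimer(1.8, 170)
  g2 <- nci_grid(dimer, spacing = 0.3, padding = 1.2,
                 intermolecular_only = TRUE)
  expect_gt(sum(g2$mask), 0)
  expect_true(all(g2$rho > 0))
  expect_true(all(g2$rdg >= 0))
  expect_lte(max(g2$rho[g2$mask]), g2$rho_cutoff)
  # the shared region carries an attractive (negative lambda2) signal
  expect_lt(min(g2$signed_rho[g2$mask]), 0)
  # low-s trough present between the fragments
  expect_lt(min(g2$rdg[g2$mask & g2$signed_rho < 0]), 0.6)
})

test_that("scatter export writes the masked two-column table", {
  dimer <- make_hbond_dimer(1.8, 170)
  g <- nci_grid(dimer, spacing = 0.4, padding = 1.0,
                intermolecular_only = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  scatter_export(g, path)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  expect_named(df, c("signed_rho", "s"))
  expect_equal(nrow(df), sum(g$mask))
  expect_equal(nrow(tidy(g)), sum(g$mask))
  cubes <- withr::local_tempfile()
  nci_export_cubes(g, dimer, cubes)
  expect_true(file.exists(paste0(cubes, "-dens.cube")))
  back <- read_cube(paste0(cubes, "-dens.cube"))
  expect_lt(max(abs(back$grid$values - g$rho)), 1e-5 * max(g$rho))
})

test_that("hydrogen bonds are detected by distance and angle rules", {
  hit <- hbond_table(make_hbond_dimer(1.8, 170))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$role, "ligand->protein")
  expect_equal(hit$distance, 1.8, tolerance = 1e-9)
  expect_equal(hit$angle, 170, tolerance = 1e-6)
  expect_equal(nrow(hbond_table(make_hbond_dimer(3.5, 170))), 0)
  expect_equal(nrow(hbond_table(make_hbond_dimer(1.8, 90))), 0)
  # reversed fragments flip the role
  flipped <- make_hbond_dimer(1.8, 170)
  flipped$fragment <- c("site", "site", "ligand")
  expect_equal(hbond_table(flipped)$role, "protein->ligand")
  expect_warning(out <- hbond_table(
    mol_structure(c("O", "O"), x = c(0, 2), y = 0, z = 0)), "no hydrogens")
  expect_equal(nrow(out), 0)
})
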