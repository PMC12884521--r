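# Conformer enumeration inside a fixed pocket: systematic dihedral x
# translation scanning, steric feasibility filtering, constrained local
# minimisation against an energy backend, minimum verification by a
# numerical Hessian, and RMSD-based deduplication. Everything here is
# deterministic; there is no randomness in this module.

#' Enumerate ligand poses over a dihedral and translation grid
#'
#' Builds the full Cartesian product of dihedral combinations (each spec
#' scanned from 0 to 360 minus the step, in `angle_step` degree increments;
#' the input pose's dihedral defines the 0-degree reference) with the rigid
#' translation grid. Output order is deterministic and lexicographic: the
#' first spec varies slowest, translations fastest.
#'
#' @param pose Ligand structure tibble.
#' @param specs List of [dihedral_spec()] objects.
#' @param angle_step Scan increment in degrees; must divide 360.
#' @param translations Tibble with columns `tx`, `ty`, `tz` (Angstrom).
#'   `NULL` means the identity translation only. See [translation_grid()].
#' @param cap Refuse (with the count) to build more records than this.
#' @param count_only Return just the closed-form record count.
#' @return A conformer record tibble with columns `id`, `dihedrals`
#'   (list-column of named degree vectors), `tx`, `ty`, `tz`, `pose`
#'   (list-column of structures), `energy`, `is_minimum`.
#' @export
enumerate_poses <- function(pose, specs, angle_step = 90,
                            translations = NULL, cap = 1e5,
                            count_only = FALSE) {
  validate_structure(pose)
  if (360 %% angle_step != 0) {
    stop("angle_step must divide 360", call. = FALSE)
  }
  if (is.null(translations)) {
    translations <- tibble::tibble(tx = 0, ty = 0, tz = 0)
  }
  nspec <- length(specs)
  nang <- 360 %/% angle_step
  total <- nang^nspec * nrow(translations)
  if (count_only) return(total)
  if (total > cap) {
    stop("pose enumeration would produce ", total,
         " records, exceeding the cap of ", cap, call. = FALSE)
  }
  angles <- seq(0, 360 - angle_step, by = angle_step)
  combos <- if (nspec > 0) {
    as.matrix(expand.grid(rep(list(angles), nspec)))[, nspec:1, drop = FALSE]
  } else {
    matrix(numeric(0), nrow = 1, ncol = 0)
  }
  rows <- vector("list", total)
  id <- 0L
  for (ci in seq_len(nrow(combos))) {
    p <- pose
    for (s in seq_len(nspec)) {
      if (combos[ci, s] != 0) {
        p <- rotate_dihedral(p, specs[[s]], combos[ci, s])
      }
    }
    base_xyz <- coords_matrix(p)
    for (ti in seq_len(nrow(translations))) {
      id <- id + 1L
      shifted <- set_coords(p, sweep(base_xyz, 2,
        c(translations$tx[ti], translations$ty[ti], translations$tz[ti]),
        "+"))
      rows[[id]] <- tibble::tibble(
        id = id,
        dihedrals = list(stats::setNames(as.numeric(combos[ci, ]),
                                         paste0("d", seq_len(nspec)))),
        tx = translations$tx[ti], ty = translations$ty[ti],
        tz = translations$tz[ti],
        pose = list(shifted),
        energy = NA_real_, is_minimum = NA
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Regular translation grid
#'
#' @param extent Half-width per axis in Angstrom (default 1.0).
#' @param n Points per axis (default 3, i.e. -extent, 0, +extent).
#' @return Tibble of `tx`, `ty`, `tz` offsets, lexicographic order.
#' @export
translation_grid <- function(extent = 1.0, n = 3) {
  v <- seq(-extent, extent, length.out = n)
  g <- expand.grid(tz = v, ty = v, tx = v)
  tibble::as_tibble(g[, c("tx", "ty", "tz")])
}

#' Remove sterically infeasible poses
#'
#' Keeps records whose every ligand-to-site interatomic distance is at
#' least `scale` times the sum of the two van der Waals radii.
#'
#' @param records Conformer record tibble from [enumerate_poses()].
#' @param site Site structure tibble (may be empty for a vacuous filter).
#' @param scale Overlap tolerance in (0, 1]; default 0.7.
#' @return The surviving records.
#' @export
clash_filter <- function(records, site, scale = 0.7) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]", call. = FALSE)
  if (nrow(records) == 0 || is.null(site) || nrow(site) == 0) return(records)
  site_xyz <- coords_matrix(site)
  site_vdw <- element_vdw(site$element)
  keep <- vapply(records$pose, function(p) {
    lx <- coords_matrix(p)
    lv <- element_vdw(p$element)
    d2 <- outer(rowSums(lx^2), rowSums(site_xyz^2), "+") -
      2 * lx %*% t(site_xyz)
    lim <- outer(lv, site_vdw, "+") * scale
    all(d2 >= lim^2 - 1e-12)
  }, logical(1))
  records[keep, , drop = FALSE]
}

# default free-atom selection in a ligand+site complex: all ligand atoms
# plus site hydrogens (heavy site atoms stay frozen)
.default_free <- function(complex) {
  which(complex$fragment == "ligand" |
          (complex$fragment != "ligand" & complex$element == "H"))
}

# fast evaluator for a backend on a fixed topology
.backend_evaluator <- function(backend, complex) {
  if (!is.null(backend$compile)) {
    backend$compile(complex)
  } else {
    function(xyz, gradient = FALSE) {
      s <- set_coords(complex, xyz)
      if (gradient) {
        list(energy = backend$energy(s), gradient = backend$gradient(s))
      } else {
        list(energy = backend$energy(s))
      }
    }
  }
}

#' Locally minimise a ligand pose inside a frozen site
#'
#' Quasi-Newton (L-BFGS-B) minimisation of the backend energy over the free
#' atoms only; by default all ligand atoms plus site hydrogens are free and
#' site heavy atoms stay frozen. Convergence is declared when the largest
#' gradient component drops below `gtol` (1e-4 kcal/mol/Angstrom) or after
#' `maxit` steps.
#'
#' @param pose Ligand structure tibble.
#' @param site Site structure tibble (`NULL` for an isolated ligand).
#' @param backend An energy backend (see [ff_backend()]).
#' @param free_atoms Integer indices into the combined ligand-then-site
#'   complex; default: ligand atoms and site hydrogens.
#' @param gtol Gradient convergence threshold, kcal/mol/Angstrom.
#' @param maxit Maximum number of minimisation steps.
#' @return List with `pose` (relaxed ligand), `site` (site with relaxed
#'   hydrogens), `energy` (kcal/mol, full complex), `converged`,
#'   `max_gradient`.
#' @export
local_minimize <- function(pose, site = NULL, backend = ff_backend(),
                           free_atoms = NULL, gtol = 1e-4, maxit = 2000) {
  complex <- if (is.null(site) || nrow(site) == 0) pose else
    dplyr::bind_rows(pose, site)
  n_lig <- nrow(pose)
  if (is.null(free_atoms)) free_atoms <- .default_free(complex)
  ev <- .backend_evaluator(backend, complex)
  xyz <- coords_matrix(complex)
  x0 <- as.vector(xyz[free_atoms, , drop = FALSE])
  fn <- function(x) {
    xyz[free_atoms, ] <- matrix(x, ncol = 3)
    ev(xyz)$energy
  }
  gr <- function(x) {
    xyz[free_atoms, ] <- matrix(x, ncol = 3)
    as.vector(ev(xyz, gradient = TRUE)$gradient[free_atoms, , drop = FALSE])
  }
  res <- tryCatch(
    stats::optim(x0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, pgtol = gtol, factr = 10)),
    error = function(e) stop("backend failure during minimisation: ",
                             conditionMessage(e), call. = FALSE)
  )
  xyz[free_atoms, ] <- matrix(res$par, ncol = 3)
  maxg <- max(abs(ev(xyz, gradient = TRUE)$gradient[free_atoms, ]))
  out_pose <- set_coords(pose, xyz[seq_len(n_lig), , drop = FALSE])
  out_site <- if (is.null(site) || nrow(site) == 0) site else
    set_coords(site, xyz[-seq_len(n_lig), , drop = FALSE])
  list(pose = out_pose, site = out_site, energy = res$value,
       converged = maxg < gtol, max_gradient = maxg)
}

#' Score or minimise a whole record set
#'
#' `score_conformers()` fills the `energy` column with the backend energy
#' of each pose-in-site complex (no relaxation). `minimize_conformers()`
#' relaxes each pose with [local_minimize()] and stores the relaxed pose
#' and final energy.
#'
#' @inheritParams local_minimize
#' @param records Conformer record tibble.
#' @return The records with updated `pose` (for minimisation) and `energy`.
#' @export
score_conformers <- function(records, site, backend = ff_backend()) {
  if (nrow(records) == 0) return(records)
  complex0 <- if (is.null(site) || nrow(site) == 0) records$pose[[1]] else
    dplyr::bind_rows(records$pose[[1]], site)
  ev <- .backend_evaluator(backend, complex0)
  site_xyz <- if (is.null(site) || nrow(site) == 0) NULL else
    coords_matrix(site)
  records$energy <- vapply(records$pose, function(p) {
    ev(rbind(coords_matrix(p), site_xyz))$energy
  }, numeric(1))
  records
}

#' @rdname score_conformers
#' @export
minimize_conformers <- function(records, site, backend = ff_backend(),
                                free_atoms = NULL, gtol = 1e-4,
                                maxit = 2000) {
  if (nrow(records) == 0) return(records)
  for (r in seq_len(nrow(records))) {
    m <- local_minimize(records$pose[[r]], site, backend,
                        free_atoms = free_atoms, gtol = gtol, maxit = maxit)
    records$pose[[r]] <- m$pose
    records$energy[r] <- m$energy
  }
  records
}

#' Verify that a relaxed pose sits at a local minimum
#'
#' Force-field analogue of a frequency check: a numerical Hessian (central
#' differences of the analytic gradient, step 1e-3 Angstrom) over the free
#' coordinates must have no eigenvalue below `-tol`. The tolerance absorbs
#' rigid-body zero modes when the free set is unconstrained. The check only
#' applies at stationary points: if the gradient is not (near) zero the
#' function returns `NA` with a warning.
#'
#' @inheritParams local_minimize
#' @param step Finite-difference displacement, Angstrom.
#' @param tol Eigenvalue tolerance (default 1e-6).
#' @return `TRUE`, `FALSE`, or `NA` when the pose is not stationary.
#' @export
verify_minimum <- function(pose, site = NULL, backend = ff_backend(),
                           free_atoms = NULL, step = 1e-3, tol = 1e-6) {
  complex <- if (is.null(site) || nrow(site) == 0) pose else
    dplyr::bind_rows(pose, site)
  if (is.null(free_atoms)) free_atoms <- .default_free(complex)
  ev <- .backend_evaluator(backend, complex)
  xyz <- coords_matrix(complex)
  g0 <- ev(xyz, gradient = TRUE)$gradient[free_atoms, , drop = FALSE]
  if (max(abs(g0)) > 1e-3) {
    warning("pose is not stationary (max gradient ",
            format(max(abs(g0)), digits = 3),
            " kcal/mol/A); minimum check not applicable", call. = FALSE)
    return(NA)
  }
  nf <- length(free_atoms)
  h <- matrix(0, 3 * nf, 3 * nf)
  col <- 0
  for (a in seq_len(nf)) {
    for (d in 1:3) {
      col <- col + 1
      xp <- xyz; xp[free_atoms[a], d] <- xp[free_atoms[a], d] + step
      xm <- xyz; xm[free_atoms[a], d] <- xm[free_atoms[a], d] - step
      gp <- ev(xp, gradient = TRUE)$gradient[free_atoms, , drop = FALSE]
      gm <- ev(xm, gradient = TRUE)$gradient[free_atoms, , drop = FALSE]
      h[, col] <- as.vector(t(gp - gm)) / (2 * step)
    }
  }
  if (!all(is.finite(h))) stop("non-finite Hessian entries", call. = FALSE)
  h <- (h + t(h)) / 2
  ev_min <- min(eigen(h, symmetric = TRUE, only.values = TRUE)$values)
  ev_min >= -tol
}

#' Deduplicate conformer records by superposed RMSD
#'
#' Greedy clustering in ascending-energy order: a record is distinct if its
#' best-superposition RMSD to every already-kept record exceeds the
#' threshold; otherwise it merges into that cluster and the lower-energy
#' member is kept. Output energies are non-decreasing, and the operation is
#' idempotent.
#'
#' @param records Conformer record tibble with energies filled in.
#' @param rmsd_threshold Distinctness threshold in Angstrom (default 0.5).
#' @return The distinct records, lowest energy first.
#' @export
deduplicate <- function(records, rmsd_threshold = 0.5) {
  if (nrow(records) <= 1) return(records)
  counts <- vapply(records$pose, nrow, 0L)
  if (length(unique(counts)) != 1) {
    stop("records have mismatched atom counts", call. = FALSE)
  }
  if (anyNA(records$energy)) {
    stop("records must be scored before deduplication", call. = FALSE)
  }
  records <- records[order(records$energy), , drop = FALSE]
  kept <- integer(0)
  for (r in seq_len(nrow(records))) {
    distinct <- TRUE
    for (k in kept) {
      if (kabsch_rmsd(records$pose[[k]], records$pose[[r]]) <=
          rmsd_threshold) {
        distinct <- FALSE
        break
      }
    }
    if (distinct) kept <- c(kept, r)
  }
  records[kept, , drop = FALSE]
}
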