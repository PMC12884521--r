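# Seeded synthetic fixtures: a toy pocket-ligand complex with a planted
# scan-grid energy minimum, energy sets with prescribed gaps, an exact-
# geometry hydrogen-bond dimer, and schematic transition tables. Every
# generator is a pure function of its spec and seed; the global RNG state
# is saved and restored.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a toy pocket-ligand complex
#'
#' @param n_pocket_atoms Cage atoms on the pocket sphere (default 40).
#' @param pocket_radius Cage radius in Angstrom (default 8).
#' @param n_ligand_atoms Heavy atoms in the ligand chain (default 6); must
#'   be at least `n_rotatable + 3`.
#' @param n_rotatable Number of scanned dihedrals (default 2).
#' @param planted_minimum Dihedral tuple (degrees, multiples of
#'   `angle_step`) at which the force-field scan-grid minimum is planted.
#' @param angle_step Scan step the planted minimum lives on (default 90).
#' @param planted_clash Optional dihedral tuple; a small blocker atom is
#'   placed so that exactly this scan combination fails the clash filter.
#' @param seed Seed fixing all randomness.
#' @return A `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(n_pocket_atoms = 40, pocket_radius = 8,
                             n_ligand_atoms = 6, n_rotatable = 2,
                             planted_minimum = c(90, 270), angle_step = 90,
                             planted_clash = NULL, seed = 1) {
  if (n_rotatable > n_ligand_atoms - 3) {
    stop("infeasible spec: n_rotatable exceeds chain length - 3",
         call. = FALSE)
  }
  if (length(planted_minimum) != n_rotatable) {
    stop("planted_minimum must have one angle per rotatable dihedral",
         call. = FALSE)
  }
  if (any(planted_minimum %% angle_step != 0)) {
    stop("planted_minimum angles must be multiples of the scan step",
         call. = FALSE)
  }
  structure(list(n_pocket_atoms = n_pocket_atoms,
                 pocket_radius = pocket_radius,
                 n_ligand_atoms = n_ligand_atoms,
                 n_rotatable = n_rotatable,
                 planted_minimum = planted_minimum,
                 angle_step = angle_step,
                 planted_clash = planted_clash,
                 seed = seed),
            class = "toy_complex_spec")
}

# all-trans zig-zag heavy-atom chain in the xy plane
.toy_chain <- function(n, bond = 1.7, bond_angle = 109.47) {
  half <- (180 - bond_angle) / 2 * pi / 180
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    s <- if (i %% 2 == 0) 1 else -1
    xyz[i, ] <- xyz[i - 1, ] + bond * c(cos(half), s * sin(half), 0)
  }
  xyz
}

#' Generate a toy pocket-ligand complex
#'
#' The ligand is a flexible heavy-atom chain with `n_rotatable` scanned
#' dihedrals; the pocket is a rigid spherical cage of inert atoms plus one
#' attractor atom per moving chain atom, tethered by a pair-specific
#' short-range well centred on the planted pose so that the force-field
#' energy over the scan grid -- and after local relaxation -- is lowest at
#' `planted_minimum`. Deterministic for a fixed seed.
#'
#' @param spec A [toy_complex_spec()].
#' @return List with `site` (site structure), `ligand` (base pose, all
#'   scan angles zero), `dihedrals` (list of [dihedral_spec()]), `params`
#'   (an [ff_params()] set), `wells` (the pair-specific 12-10 tether
#'   table, in combined ligand-then-site indexing, for the `hbonds`
#'   argument of [ff_backend()]) and `spec`.
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  n <- spec$n_ligand_atoms
  .with_seed(spec$seed, {
    chain <- .toy_chain(n)
    anchors <- rep(seq_len(n), each = 2) # two tethers per chain atom
    elements <- c("C", sample(c("C", "N", "O"), n - 2, replace = TRUE), "C")
    charges <- rep(0, n)
    ligand <- mol_structure(elements,
                            x = chain[, 1], y = chain[, 2], z = chain[, 3],
                            name = paste0(elements, seq_len(n)),
                            residue_name = "LIG", fragment = "ligand",
                            charge = charges, title = "toy ligand")
    dihedrals <- lapply(seq_len(spec$n_rotatable), function(k) {
      dihedral_spec(c(k, k + 1, k + 2, k + 3), (k + 3):n)
    })
    apply_angles <- function(angles) {
      p <- ligand
      for (k in seq_len(spec$n_rotatable)) {
        if (angles[k] != 0) p <- rotate_dihedral(p, dihedrals[[k]], angles[k])
      }
      p
    }
    planted <- apply_angles(spec$planted_minimum)
    pxyz <- coords_matrix(planted)
    # every ligand atom position reachable on the scan grid (identity
    # translation): used to keep pocket atoms clear of all poses
    grid_rec <- enumerate_poses(ligand, dihedrals,
                                angle_step = spec$angle_step)
    all_pose_xyz <- do.call(rbind, lapply(grid_rec$pose, coords_matrix))
    # Every chain atom is tethered to two attractor atoms through
    # pair-specific narrow 12-10 wells centred on the planted geometry.
    # Two distance tethers per atom plus chain rigidity pin the planted
    # configuration uniquely (a single tether would leave a mirror
    # ambiguity on each dihedral circle); the wells reward only their
    # designated atom, so registry-shifted or reflected folds collect
    # nothing, and their short range leaves other scan poses untouched.
    # Attractor positions are chosen deterministically as the sterically
    # safest directions on a small radius ladder; a final brute-force scan
    # verifies that the planted combination is the grid minimum.
    par0 <- ff_params()
    lj_o <- .atom_lj("O", par0)
    lj_l <- .atom_lj(ligand$element, par0)
    sig_mix <- (lj_l$sigma + lj_o$sigma) / 2
    pose_xyz <- lapply(grid_rec$pose, coords_matrix)
    well_depth <- 15 # kcal/mol per planted contact
    # sequential placement; thresholds: 2.35 A steric clearance from every
    # scan-pose atom (keeps all poses clash-feasible), one LJ diameter from
    # the other planted atoms (no strain on the planted pose), and an O-O
    # LJ optimum between attractors (no site-site blow-ups)
    placements <- list()
    placed <- NULL
    all_pose_mat <- do.call(rbind, pose_xyz)
    dirs <- .candidate_directions()
    row_min_d <- function(cand, pts) {
      d2 <- outer(rowSums(cand^2), rowSums(pts^2), "+") -
        2 * cand %*% t(pts)
      sqrt(pmax(apply(d2, 1, min), 0))
    }
    for (k in seq_along(anchors)) {
      m <- anchors[k]
      best <- NULL
      for (rr in sig_mix[m] + seq(0.2, 3.0, by = 0.25)) {
        cand <- sweep(dirs * rr, 2, pxyz[m, ], "+")
        pose_clear <- row_min_d(cand, all_pose_mat)
        planted_clear <- row_min_d(cand, pxyz[-m, , drop = FALSE])
        att_clear <- if (is.null(placed)) Inf else row_min_d(cand, placed)
        slack <- pmin(pose_clear - 2.35, planted_clear - 3.65,
                      att_clear - 3.4)
        i <- which.max(slack)
        if (is.null(best) || slack[i] > best$slack) {
          best <- list(pos = cand[i, ], r0 = rr, slack = slack[i])
        }
        if (best$slack >= 0.5) break # prefer the shortest adequate contact
      }
      if (best$slack < 0) {
        stop("infeasible spec: no sterically safe attractor position for ",
             "anchor atom ", m, call. = FALSE)
      }
      placed <- rbind(placed, best$pos)
      placements[[k]] <- best
    }
    attract <- do.call(rbind, lapply(placements, `[[`, "pos"))
    com <- center_of_mass(ligand)
    cage <- matrix(0, spec$n_pocket_atoms, 3)
    placed <- 0
    while (placed < spec$n_pocket_atoms) {
      u <- stats::rnorm(3)
      pos <- com + spec$pocket_radius * u / sqrt(sum(u^2))
      clear_lig <- min(sqrt(rowSums(sweep(all_pose_xyz, 2, pos)^2)))
      clear_att <- min(sqrt(rowSums(sweep(attract, 2, pos)^2)))
      if (clear_lig >= 4.0 && clear_att >= 4.0 &&
          (placed == 0 ||
             min(sqrt(rowSums(sweep(cage[seq_len(placed), , drop = FALSE],
                                    2, pos)^2))) >= 1.5)) {
        placed <- placed + 1
        cage[placed, ] <- pos
      }
    }
    site_xyz <- rbind(cage, attract)
    site_el <- c(rep("He", spec$n_pocket_atoms),
                 rep("O", length(anchors)))
    site_q <- rep(0, spec$n_pocket_atoms + length(anchors))
    site_nm <- c(paste0("CAGE", seq_len(spec$n_pocket_atoms)),
                 paste0("ATTR", seq_along(anchors)))
    if (!is.null(spec$planted_clash)) {
      cxyz <- coords_matrix(apply_angles(spec$planted_clash))
      target_key <- vapply(grid_rec$dihedrals, function(d) {
        all(d == spec$planted_clash)
      }, logical(1))
      other_xyz <- do.call(rbind,
                           lapply(grid_rec$pose[!target_key], coords_matrix))
      best <- NULL
      for (d in asplit(.candidate_directions(), 1)) {
        cand <- cxyz[n, ] + 1.2 * d
        clearance <- min(sqrt(rowSums(sweep(other_xyz, 2, cand)^2)))
        if (is.null(best) || clearance > best$clearance) {
          best <- list(pos = cand, clearance = clearance)
        }
      }
      if (best$clearance < 2.1) {
        stop("infeasible spec: clash blocker cannot single out the ",
             "requested combination", call. = FALSE)
      }
      site_xyz <- rbind(site_xyz, best$pos)
      site_el <- c(site_el, "H")
      site_q <- c(site_q, 0)
      site_nm <- c(site_nm, "BLCK")
    }
    site <- mol_structure(site_el,
                          x = site_xyz[, 1], y = site_xyz[, 2],
                          z = site_xyz[, 3],
                          name = site_nm, residue_name = "POC",
                          residue_seq = seq_along(site_el),
                          fragment = "site", charge = site_q,
                          title = "toy pocket")
    wells <- tibble::tibble(
      h_idx = anchors,
      acceptor_idx = n + spec$n_pocket_atoms + seq_along(anchors),
      depth = well_depth,
      r0 = vapply(placements, `[[`, 0, "r0")
    )
    toy <- list(site = site, ligand = ligand, dihedrals = dihedrals,
                params = ff_params(), wells = wells, spec = spec)
    found <- recover_planted_minimum(toy)
    if (!all(found == spec$planted_minimum)) {
      stop("internal generator check failed: scan-grid minimum (",
           paste(found, collapse = ","), ") is not the planted one",
           call. = FALSE)
    }
    toy
  })
}

# deterministic quasi-uniform unit directions (Fibonacci sphere)
.candidate_directions <- function(n = 200) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Recover the scan-grid minimum of a toy complex
#'
#' Brute-force scan over the dihedral grid (identity translation), scored
#' with the toy parameters; returns the dihedral tuple of the lowest-energy
#' pose. On a generated toy complex this recovers the planted minimum.
#'
#' @param toy Output of [make_toy_complex()].
#' @return Named numeric dihedral tuple (degrees).
#' @export
recover_planted_minimum <- function(toy) {
  backend <- ff_backend(toy$params, bonds = .complex_bonds(toy),
                        hbonds = toy$wells)
  records <- enumerate_poses(toy$ligand, toy$dihedrals,
                             angle_step = toy$spec$angle_step)
  records <- score_conformers(records, toy$site, backend)
  records$dihedrals[[which.min(records$energy)]]
}

# bond list for the ligand chain within a ligand+site complex (ligand rows
# first); used to exclude 1-2/1-3 intra-chain pairs
.complex_bonds <- function(toy) {
  n <- nrow(toy$ligand)
  cbind(seq_len(n - 1), 2:n)
}

#' Energy set with prescribed gaps
#'
#' Builds conformer energies from consecutive gaps, optionally with seeded
#' Gaussian jitter, so ground-truth Boltzmann populations are computable in
#' closed form from the returned values.
#'
#' @param n Number of conformers.
#' @param gaps Consecutive energy gaps in kcal/mol (recycled to length
#'   `n - 1`). All zero gives uniform populations.
#' @param jitter Standard deviation of additive noise (default 0).
#' @param seed Seed used when `jitter > 0`.
#' @return Numeric vector of energies, kcal/mol (first entry 0).
#' @export
make_energy_set <- function(n, gaps = 0, jitter = 0, seed = 1) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  gaps <- rep_len(gaps, max(n - 1, 0))
  dg <- cumsum(c(0, gaps))
  if (jitter > 0) {
    dg <- dg + .with_seed(seed, stats::rnorm(n, 0, jitter))
  }
  dg
}

#' Hydrogen-bond dimer at exact geometry
#'
#' An O-H donor (fragment `ligand`) and an O acceptor (fragment `site`)
#' with the requested H-to-acceptor distance and donor-H-acceptor angle,
#' in the xy plane.
#'
#' @param distance H...acceptor distance in Angstrom.
#' @param angle D-H...A angle in degrees.
#' @return A structure tibble with both fragments tagged.
#' @export
make_hbond_dimer <- function(distance = 1.8, angle = 170) {
  a <- angle * pi / 180
  h <- c(0.96, 0, 0)
  acceptor <- h + distance * c(-cos(a), sin(a), 0)
  mol_structure(
    c("O", "H", "O"),
    x = c(0, h[1], acceptor[1]),
    y = c(0, h[2], acceptor[2]),
    z = c(0, h[3], acceptor[3]),
    name = c("OD", "HD", "OA"),
    residue_name = c("DON", "DON", "ACC"),
    residue_seq = c(1L, 1L, 2L),
    fragment = c("ligand", "ligand", "site"),
    title = sprintf("O-H...O dimer d=%.2f A angle=%.0f deg", distance, angle)
  )
}

#' Schematic electronic transition table
#'
#' Seeded wavelengths, oscillator strengths and transition dipoles with
#' one row flagged predominant (the highest oscillator strength).
#'
#' @param n_states Number of excited states.
#' @param seed Seed fixing all randomness.
#' @return A transition tibble (see [transition_table()]).
#' @export
make_transition_table <- function(n_states = 10, seed = 1) {
  .with_seed(seed, {
    lambda <- sort(stats::runif(n_states, 170, 320), decreasing = TRUE)
    f <- stats::runif(n_states, 0.01, 0.6)
    tt <- transition_table(
      state = paste0("S", seq_len(n_states)),
      lambda_nm = lambda, f = f,
      mu_tr_D = sqrt(f) * stats::runif(n_states, 3, 6),
      assignment = "H -> L", character = "LE",
      percent = round(100 * f / sum(f)),
      predominant = seq_len(n_states) == which.max(f)
    )
    tt
  })
}
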