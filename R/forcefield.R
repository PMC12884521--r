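# Dreiding-style nonbonded surrogate force field: Lennard-Jones 12-6 with
# Lorentz-Berthelot combination, an optional 12-10 hydrogen-bond well on
# donor-H...acceptor pairs, and Coulomb electrostatics with a constant or
# distance-dependent dielectric. Nonbonded terms only by default --
# fragments are rigid during scanning -- with optional harmonic valence
# restraints (bond + 1-3 distances) for relaxation of flexible chains.

# Dreiding van der Waals parameters: R0 (Angstrom, potential minimum) and
# D0 (kcal/mol well depth); sigma = R0 / 2^(1/6).
.dreiding_vdw <- tibble::tribble(
  ~element, ~r0,     ~d0,
  "H",      3.195,  0.0152,
  "C",      3.8983, 0.0951,
  "N",      3.6621, 0.0774,
  "O",      3.4046, 0.0957,
  "F",      3.4720, 0.0725,
  "P",      4.15,   0.32,
  "S",      4.03,   0.344,
  "Cl",     3.9503, 0.2833,
  "Na",     3.144,  0.5,
  "He",     2.9,    0.021,
  "Ar",     3.868,  0.185
)

#' Force-field parameter set
#'
#' Per-element Lennard-Jones well depths and diameters (Dreiding van der
#' Waals values by default), the 12-10 hydrogen-bond well, the dielectric
#' model and the Coulomb constant 332.0637 kcal A / (mol e^2).
#'
#' @param lj Tibble with columns `element`, `sigma` (Angstrom), `epsilon`
#'   (kcal/mol). Defaults to the Dreiding van der Waals set.
#' @param hb_depth Hydrogen-bond well depth D_hb, kcal/mol (default 9.5).
#' @param hb_r0 Hydrogen-bond optimum distance R_hb, Angstrom
#'   (default 2.75, measured donor-to-acceptor).
#' @param bond_k,angle_k Harmonic force constants for the optional valence
#'   terms (kcal/mol/A^2): bond stretches and 1-3 (Urey-Bradley style)
#'   distance restraints. Used only when a backend enables `valence`.
#' @param dielectric `"constant"` or `"distance_dependent"`.
#' @param dielectric_constant Relative permittivity for the constant model.
#' @return An object of class `ff_params`.
#' @export
ff_params <- function(lj = NULL, hb_depth = 9.5, hb_r0 = 2.75,
                      dielectric = c("constant", "distance_dependent"),
                      dielectric_constant = 1,
                      bond_k = 700, angle_k = 150) {
  dielectric <- match.arg(dielectric)
  if (is.null(lj)) {
    lj <- tibble::tibble(element = .dreiding_vdw$element,
                         sigma = .dreiding_vdw$r0 / 2^(1 / 6),
                         epsilon = .dreiding_vdw$d0)
  }
  stopifnot(all(c("element", "sigma", "epsilon") %in% names(lj)))
  if (any(lj$epsilon < 0) || any(lj$sigma <= 0) || hb_depth < 0 || hb_r0 <= 0) {
    stop("epsilon and hb_depth must be >= 0; sigma and hb_r0 > 0",
         call. = FALSE)
  }
  structure(list(lj = lj, hb_depth = hb_depth, hb_r0 = hb_r0,
                 dielectric = dielectric,
                 dielectric_constant = dielectric_constant,
                 coulomb_k = 332.0637,
                 bond_k = bond_k, angle_k = angle_k),
            class = "ff_params")
}

# resolve per-atom LJ parameters, erroring on unparameterised elements
.atom_lj <- function(elements, params) {
  idx <- match(elements, params$lj$element)
  if (anyNA(idx)) {
    stop("no force-field parameters for element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  list(sigma = params$lj$sigma[idx], epsilon = params$lj$epsilon[idx])
}

# Precompute the pair list for a fixed topology. bonds: 2-column matrix of
# atom indices; when given, 1-2 and 1-3 pairs are excluded from all
# nonbonded terms. hbonds: tibble with columns h_idx, acceptor_idx; those
# pairs swap their LJ term for the 12-10 hydrogen-bond well.
.ff_compile <- function(structure, params,
                        pair_scope = c("all", "inter_fragment"),
                        bonds = NULL, hbonds = NULL, valence = FALSE,
                        valence_ref = NULL) {
  pair_scope <- match.arg(pair_scope)
  n <- nrow(structure)
  lj <- .atom_lj(structure$element, params)
  q <- structure$charge %||% rep(0, n)
  pi_ <- rep(seq_len(n - 1), times = (n - 1):1)
  pj_ <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  if (pair_scope == "inter_fragment") {
    lig <- structure$fragment == "ligand"
    keep <- lig[pi_] != lig[pj_]
    pi_ <- pi_[keep]; pj_ <- pj_[keep]
  }
  if (!is.null(bonds) && nrow(bonds) > 0) {
    adj <- vector("list", n)
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    excl <- new.env(hash = TRUE)
    key <- function(i, j) paste0(min(i, j), "_", max(i, j))
    for (i in seq_len(n)) {
      for (j in adj[[i]]) {
        assign(key(i, j), TRUE, excl)           # 1-2
        for (k in adj[[j]]) if (k != i) assign(key(i, k), TRUE, excl) # 1-3
      }
    }
    keep <- !vapply(seq_along(pi_), function(m) {
      exists(key(pi_[m], pj_[m]), excl, inherits = FALSE)
    }, logical(1))
    pi_ <- pi_[keep]; pj_ <- pj_[keep]
  }
  is_hb <- rep(FALSE, length(pi_))
  hb_depth <- hb_r0 <- numeric(length(pi_))
  if (!is.null(hbonds) && nrow(hbonds) > 0) {
    hk <- paste0(pmin(hbonds$h_idx, hbonds$acceptor_idx), "_",
                 pmax(hbonds$h_idx, hbonds$acceptor_idx))
    pk <- paste0(pi_, "_", pj_)
    hit <- match(pk, hk)
    is_hb <- !is.na(hit)
    # per-pair well parameters, defaulting to the global ones
    dep <- if ("depth" %in% names(hbonds)) hbonds$depth else
      rep(params$hb_depth, nrow(hbonds))
    rr0 <- if ("r0" %in% names(hbonds)) hbonds$r0 else
      rep(params$hb_r0, nrow(hbonds))
    hb_depth[is_hb] <- dep[hit[is_hb]]
    hb_r0[is_hb] <- rr0[hit[is_hb]]
  }
  sig <- (lj$sigma[pi_] + lj$sigma[pj_]) / 2
  eps <- sqrt(lj$epsilon[pi_] * lj$epsilon[pj_])
  qq <- params$coulomb_k * q[pi_] * q[pj_]
  val <- NULL
  if (valence) {
    if (is.null(bonds) || nrow(bonds) == 0) {
      stop("valence terms require a bond list", call. = FALSE)
    }
    # equilibrium distances come from the reference geometry so repeated
    # compilations judge against the same restraints
    xyz <- coords_matrix(valence_ref %||% structure)
    adj <- vector("list", n)
    for (b in seq_len(nrow(bonds))) {
      adj[[bonds[b, 1]]] <- c(adj[[bonds[b, 1]]], bonds[b, 2])
      adj[[bonds[b, 2]]] <- c(adj[[bonds[b, 2]]], bonds[b, 1])
    }
    vi <- bonds[, 1]; vj <- bonds[, 2]
    vk <- rep(params$bond_k, nrow(bonds))
    for (j0 in seq_len(n)) { # 1-3 (Urey-Bradley style) distance restraints
      nb <- adj[[j0]]
      if (length(nb) > 1) {
        cmb <- utils::combn(sort(nb), 2)
        vi <- c(vi, cmb[1, ]); vj <- c(vj, cmb[2, ])
        vk <- c(vk, rep(params$angle_k, ncol(cmb)))
      }
    }
    r0 <- sqrt(rowSums((xyz[vi, , drop = FALSE] -
                          xyz[vj, , drop = FALSE])^2))
    val <- list(i = vi, j = vj, k = vk, r0 = r0)
  }
  list(n = n, i = pi_, j = pj_, sigma = sig, eps = eps, qq = qq,
       is_hb = is_hb, hb_depth = hb_depth, hb_r0 = hb_r0,
       params = params, val = val)
}

# Evaluate energy (and optionally the full gradient) on coordinates.
.ff_eval <- function(xyz, sys, gradient = FALSE) {
  dx <- xyz[sys$i, 1] - xyz[sys$j, 1]
  dy <- xyz[sys$i, 2] - xyz[sys$j, 2]
  dz <- xyz[sys$i, 3] - xyz[sys$j, 3]
  r2 <- dx * dx + dy * dy + dz * dz
  r <- sqrt(r2)
  p <- sys$params
  e <- numeric(length(r))
  dEdr <- if (gradient) numeric(length(r)) else NULL
  lj_mask <- !sys$is_hb
  if (any(lj_mask)) {
    sr6 <- (sys$sigma[lj_mask] / r[lj_mask])^6
    epsm <- sys$eps[lj_mask]
    e[lj_mask] <- 4 * epsm * (sr6 * sr6 - sr6)
    if (gradient) {
      dEdr[lj_mask] <- 4 * epsm * (-12 * sr6 * sr6 + 6 * sr6) / r[lj_mask]
    }
  }
  if (any(sys$is_hb)) {
    xr <- sys$hb_r0[sys$is_hb] / r[sys$is_hb]
    x10 <- xr^10; x12 <- x10 * xr * xr
    dep <- sys$hb_depth[sys$is_hb]
    e[sys$is_hb] <- dep * (5 * x12 - 6 * x10)
    if (gradient) {
      dEdr[sys$is_hb] <- dep * 60 * (x10 - x12) / r[sys$is_hb]
    }
  }
  nonzero_q <- sys$qq != 0
  if (any(nonzero_q)) {
    if (p$dielectric == "constant") {
      ec <- sys$qq[nonzero_q] / (p$dielectric_constant * r[nonzero_q])
      e[nonzero_q] <- e[nonzero_q] + ec
      if (gradient) dEdr[nonzero_q] <- dEdr[nonzero_q] - ec / r[nonzero_q]
    } else { # epsilon(r) = r  =>  E = qq / r^2
      ec <- sys$qq[nonzero_q] / r2[nonzero_q]
      e[nonzero_q] <- e[nonzero_q] + ec
      if (gradient) dEdr[nonzero_q] <- dEdr[nonzero_q] - 2 * ec / r[nonzero_q]
    }
  }
  energy <- sum(e)
  vdx <- vdy <- vdz <- vr <- vdEdr <- NULL
  if (!is.null(sys$val)) {
    vdx <- xyz[sys$val$i, 1] - xyz[sys$val$j, 1]
    vdy <- xyz[sys$val$i, 2] - xyz[sys$val$j, 2]
    vdz <- xyz[sys$val$i, 3] - xyz[sys$val$j, 3]
    vr <- sqrt(vdx^2 + vdy^2 + vdz^2)
    energy <- energy + sum(0.5 * sys$val$k * (vr - sys$val$r0)^2)
    if (gradient) vdEdr <- sys$val$k * (vr - sys$val$r0)
  }
  if (!gradient) return(list(energy = energy))
  g <- matrix(0, sys$n, 3)
  acc <- function(g, idx_i, idx_j, fx, fy, fz) {
    gi <- rowsum(cbind(fx, fy, fz), idx_i, reorder = FALSE)
    g[as.integer(rownames(gi)), ] <- g[as.integer(rownames(gi)), ] + gi
    gj <- rowsum(cbind(fx, fy, fz), idx_j, reorder = FALSE)
    g[as.integer(rownames(gj)), ] <- g[as.integer(rownames(gj)), ] - gj
    g
  }
  g <- acc(g, sys$i, sys$j, dEdr * dx / r, dEdr * dy / r, dEdr * dz / r)
  if (!is.null(sys$val)) {
    g <- acc(g, sys$val$i, sys$val$j, vdEdr * vdx / vr,
             vdEdr * vdy / vr, vdEdr * vdz / vr)
  }
  list(energy = energy, gradient = g)
}

#' Nonbonded force-field energy
#'
#' Sums, over atom pairs in scope, the Lennard-Jones 12-6 term with
#' Lorentz-Berthelot combination, a 12-10 hydrogen-bond well for declared
#' donor-H...acceptor pairs, and Coulomb electrostatics. 1-2 and 1-3 pairs
#' are excluded when a bond list is provided.
#'
#' @param structure A structure tibble; the `charge` column feeds the
#'   Coulomb term.
#' @param params An [ff_params()] set.
#' @param pair_scope `"all"` (every pair) or `"inter_fragment"` (only
#'   ligand-to-site pairs).
#' @param bonds Optional 2-column integer matrix of bonded atom pairs.
#' @param hbonds Optional tibble with columns `h_idx`, `acceptor_idx`
#'   identifying hydrogen-bond(-like) pairs (e.g. from [hbond_table()]);
#'   these pairs use the 12-10 well instead of Lennard-Jones. Optional
#'   `depth` and `r0` columns override the global well parameters per
#'   pair.
#' @return Energy in kcal/mol.
#' @export
ff_energy <- function(structure, params = ff_params(),
                      pair_scope = c("all", "inter_fragment"),
                      bonds = NULL, hbonds = NULL, valence = FALSE,
                      valence_ref = NULL) {
  validate_structure(structure)
  sys <- .ff_compile(structure, params, match.arg(pair_scope), bonds,
                     hbonds, valence, valence_ref)
  .ff_eval(coords_matrix(structure), sys)$energy
}

#' @rdname ff_energy
#' @return `ff_gradient()` returns an n x 3 matrix of energy derivatives in
#'   kcal/mol/Angstrom.
#' @export
ff_gradient <- function(structure, params = ff_params(),
                        pair_scope = c("all", "inter_fragment"),
                        bonds = NULL, hbonds = NULL, valence = FALSE,
                        valence_ref = NULL) {
  validate_structure(structure)
  sys <- .ff_compile(structure, params, match.arg(pair_scope), bonds,
                     hbonds, valence, valence_ref)
  .ff_eval(coords_matrix(structure), sys, gradient = TRUE)$gradient
}

#' Construct an energy backend
#'
#' An energy backend is the contract the conformer machinery minimises
#' against: a `name`, an `energy(structure)` function returning kcal/mol,
#' and a `gradient(structure)` function returning an n x 3 matrix in
#' kcal/mol/Angstrom. [ff_backend()] wraps the package's nonbonded force
#' field; any user-supplied list with the same fields works in its place.
#'
#' @inheritParams ff_energy
#' @param valence Include harmonic bond and 1-3 distance terms for the
#'   bonded atoms? Default `FALSE` (rigid-fragment use).
#' @param valence_ref Reference structure supplying the valence
#'   equilibrium distances; defaults to the structure being evaluated.
#'   Supply the unperturbed ligand so every evaluation restrains towards
#'   the same geometry.
#' @param name Backend label carried into records and manifests.
#' @return A list with elements `name`, `energy`, `gradient` and `compile`
#'   (a topology pre-compiler used internally for speed).
#' @export
ff_backend <- function(params = ff_params(),
                       pair_scope = c("all", "inter_fragment"),
                       bonds = NULL, hbonds = NULL, valence = FALSE,
                       valence_ref = NULL, name = "dreiding") {
  pair_scope <- match.arg(pair_scope)
  force(params); force(bonds); force(hbonds); force(valence)
  force(valence_ref)
  list(
    name = name,
    energy = function(structure) {
      ff_energy(structure, params, pair_scope, bonds, hbonds, valence,
                valence_ref)
    },
    gradient = function(structure) {
      ff_gradient(structure, params, pair_scope, bonds, hbonds, valence,
                  valence_ref)
    },
    compile = function(structure) {
      sys <- .ff_compile(structure, params, pair_scope, bonds, hbonds,
                         valence, valence_ref)
      function(xyz, gradient = FALSE) .ff_eval(xyz, sys, gradient)
    }
  )
}
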