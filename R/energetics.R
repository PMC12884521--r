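# Two-layer energy combination, Boltzmann conformer populations, binding
# energy decomposition and the dissociation-constant bridge. All energies
# are kcal/mol; the gas constant is kcal/(mol K).

#' Gas constant in kcal/(mol K)
#' @export
gas_constant_kcal <- 1.98720425864e-3

#' Combine two-layer energies
#'
#' The two-layer extrapolation approximates the high-level energy of the
#' full (real) system as
#' `E = E_high,model + E_low,real - E_low,model`:
#' the model region at the high level, plus the full system at the low
#' level, minus the model region at the low level. Pure arithmetic; all
#' three inputs must be finite and in the same units.
#'
#' @param e_high_model High-level energy of the model region, kcal/mol.
#' @param e_low_real Low-level energy of the full system, kcal/mol.
#' @param e_low_model Low-level energy of the model region, kcal/mol.
#' @return An `oniom2` object holding the three components and the
#'   extrapolated total `e_oniom2`.
#' @export
#' @examples
#' oniom2_combine(10, 5, 3) # extrapolated total 12
oniom2_combine <- function(e_high_model, e_low_real, e_low_model) {
  vals <- c(e_high_model, e_low_real, e_low_model)
  if (length(vals) != 3 || !all(is.finite(vals))) {
    stop("all three energies must be finite scalars", call. = FALSE)
  }
  structure(
    list(e_high_model = e_high_model, e_low_real = e_low_real,
         e_low_model = e_low_model,
         e_oniom2 = e_high_model + e_low_real - e_low_model),
    class = "oniom2"
  )
}

#' @export
print.oniom2 <- function(x, ...) {
  cat("Two-layer energy combination (kcal/mol)\n")
  cat(sprintf("  E(high, model): %12.4f\n", x$e_high_model))
  cat(sprintf("  E(low,  real):  %12.4f\n", x$e_low_real))
  cat(sprintf("  E(low,  model): %12.4f\n", x$e_low_model))
  cat(sprintf("  E(extrapolated):%12.4f\n", x$e_oniom2))
  invisible(x)
}

#' Score a complex with a two-layer scheme
#'
#' The model layer is the whole ligand (no covalent boundary, hence no link
#' atoms): the high backend evaluates the isolated ligand, the low backend
#' the full complex and the isolated ligand, and the three energies are
#' combined with [oniom2_combine()]. A ligand covalently bonded to the site
#' is an unsupported boundary and raises an error.
#'
#' @param complex Structure tibble containing ligand and site atoms.
#' @param high_backend,low_backend Energy backends (see [ff_backend()]).
#' @return An `oniom2` object.
#' @export
oniom2_score <- function(complex, high_backend, low_backend) {
  validate_structure(complex)
  lig_idx <- .ligand_rows(complex)
  if (length(lig_idx) == 0) stop("complex contains no ligand atoms",
                                 call. = FALSE)
  ligand <- complex[lig_idx, , drop = FALSE]
  rest <- complex[-lig_idx, , drop = FALSE]
  if (nrow(rest) > 0) {
    # covalent ligand-site contact would need link atoms (unsupported)
    lx <- coords_matrix(ligand); rx <- coords_matrix(rest)
    d2 <- outer(rowSums(lx^2), rowSums(rx^2), "+") - 2 * lx %*% t(rx)
    lim <- outer(element_covalent(ligand$element),
                 element_covalent(rest$element), "+") * 1.3
    if (any(d2 < lim^2)) {
      stop("ligand selector crosses a covalent bond to the site; ",
           "link-atom boundaries are not supported", call. = FALSE)
    }
  }
  oniom2_combine(
    e_high_model = high_backend$energy(ligand),
    e_low_real = low_backend$energy(complex),
    e_low_model = low_backend$energy(ligand)
  )
}

#' Boltzmann conformer populations
#'
#' Population of conformer i at temperature T:
#' `P_i = exp(-dG_i / RT) / sum_j exp(-dG_j / RT)`,
#' computed with the max-shift (overflow-safe softmax) form. Populations
#' are invariant to adding a constant to every energy, sum to one, and are
#' monotone decreasing in energy.
#'
#' @param delta_g Numeric vector of conformer energies, kcal/mol.
#' @param temperature Temperature in kelvin (default 298.15).
#' @param ids Optional conformer labels.
#' @return A `boltzmann_pop` object: tibble with columns `id`, `delta_g`,
#'   `population`, `percent` (rounded to one decimal in the print method),
#'   plus `temperature` and `gas_constant` attributes.
#' @export
#' @examples
#' boltzmann_populations(c(0, 0.665), 298.15)
boltzmann_populations <- function(delta_g, temperature = 298.15, ids = NULL) {
  if (length(delta_g) == 0) stop("empty energy list", call. = FALSE)
  if (!all(is.finite(delta_g))) stop("non-finite energies", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  rt <- gas_constant_kcal * temperature
  w <- -(delta_g - min(delta_g)) / rt
  p <- exp(w) / sum(exp(w))
  out <- tibble::tibble(
    id = ids %||% seq_along(delta_g),
    delta_g = as.numeric(delta_g),
    population = p,
    percent = 100 * p
  )
  attr(out, "temperature") <- temperature
  attr(out, "gas_constant") <- gas_constant_kcal
  class(out) <- c("boltzmann_pop", class(tibble::tibble()))
  out
}

#' @export
print.boltzmann_pop <- function(x, ...) {
  cat("Boltzmann populations at", attr(x, "temperature"), "K\n")
  df <- tibble::as_tibble(x)
  df$percent <- round(df$percent, 1)
  print(df, ...)
  invisible(x)
}

#' Binding-energy decomposition
#'
#' `E_bind = E_complex - (E_active_site + E_ligand)`, with the three
#' energies computed independently on the same backend and in the same
#' units.
#'
#' @param e_complex,e_active_site,e_ligand Energies in kcal/mol.
#' @return A `binding_result` object.
#' @export
#' @examples
#' binding_energy(-100, -60, -30) # -10 kcal/mol
binding_energy <- function(e_complex, e_active_site, e_ligand) {
  vals <- c(e_complex, e_active_site, e_ligand)
  if (!all(is.finite(vals))) stop("non-finite energies", call. = FALSE)
  structure(
    list(e_complex = e_complex, e_active_site = e_active_site,
         e_ligand = e_ligand,
         binding_energy = e_complex - (e_active_site + e_ligand)),
    class = "binding_result"
  )
}

#' @export
print.binding_result <- function(x, ...) {
  cat("Binding energy decomposition (kcal/mol)\n")
  cat(sprintf("  E(complex):     %12.4f\n", x$e_complex))
  cat(sprintf("  E(active site): %12.4f\n", x$e_active_site))
  cat(sprintf("  E(ligand):      %12.4f\n", x$e_ligand))
  cat(sprintf("  E(binding):     %12.4f\n", x$binding_energy))
  invisible(x)
}

#' Binding energy from structures, with per-system relaxation
#'
#' Convenience driver for the decomposition: relaxes the bound complex and
#' an unbound state (the same system with the ligand displaced far enough
#' that every interaction vanishes) against the same backend -- so one
#' topology serves all terms -- and differences the energies. The isolated
#' ligand is additionally relaxed on its own to split the unbound energy
#' into the `e_active_site` and `e_ligand` components.
#'
#' @param complex Structure tibble with ligand and site fragments.
#' @param backend An energy backend.
#' @param minimize Relax each system first? Default `TRUE`.
#' @param separation Displacement (Angstrom) used for the unbound state.
#' @return A `binding_result` object.
#' @export
binding_energy_from_structures <- function(complex, backend = ff_backend(),
                                           minimize = TRUE,
                                           separation = 1e6) {
  validate_structure(complex)
  lig_idx <- .ligand_rows(complex)
  if (length(lig_idx) == 0 || length(lig_idx) == nrow(complex)) {
    stop("complex must contain both ligand and site atoms", call. = FALSE)
  }
  ligand <- complex[lig_idx, , drop = FALSE]
  site <- complex[-lig_idx, , drop = FALSE]
  far_ligand <- ligand
  far_ligand$x <- far_ligand$x + separation
  if (minimize) {
    e_complex <- local_minimize(ligand, site, backend)$energy
    e_unbound <- local_minimize(far_ligand, site, backend)$energy
    e_ligand <- local_minimize(ligand, NULL, backend)$energy
  } else {
    e_complex <- backend$energy(complex)
    e_unbound <- backend$energy(dplyr::bind_rows(far_ligand, site))
    e_ligand <- backend$energy(ligand)
  }
  binding_energy(e_complex, e_unbound - e_ligand, e_ligand)
}

#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(Kd / 1 M)`: a 1 M standard state gives zero, and
#' sub-nanomolar affinities give strongly negative free energies.
#'
#' @param kd Dissociation constant in mol/L; must be positive.
#' @param temperature Temperature in kelvin (default 298.15).
#' @return Binding free energy in kcal/mol.
#' @export
#' @examples
#' delta_g_from_kd(0.37e-9) # about -12.9 kcal/mol
delta_g_from_kd <- function(kd, temperature = 298.15) {
  if (any(kd <= 0)) stop("kd must be positive", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  gas_constant_kcal * temperature * log(kd)
}
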