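# Promolecular electron density: each atom contributes a sum of simple
# exponential shells rho(r) = sum_i c_i exp(-r / zeta_i) in atomic units
# (r in bohr). Gradients and Hessians are closed-form derivatives of the
# exponential sum -- no finite differences anywhere in this module.

# Exponential-shell coefficients per element, H-Ar. Fitted (log-linear per
# principal shell) to single-zeta Slater-model atomic densities with
# Clementi-Raimondi effective exponents, weighted towards the low-density
# region that noncovalent-interaction analysis probes. Versioned here so
# results are bit-reproducible.
.promolecular_shells <- tibble::tribble(
  ~element, ~c, ~zeta,
  "H", 0.31830989, 0.5,
  "He", 3.0592253, 0.2962963,
  "Li", 12.400167, 0.18583216,
  "Li", 0.026914302, 1.1775637,
  "Be", 31.850913, 0.13569257,
  "Be", 0.22711748, 0.74028431,
  "B", 65.234671, 0.10684902,
  "B", 0.87203785, 0.54677674,
  "C", 116.21162, 0.088141449,
  "C", 2.6001514, 0.42432449,
  "N", 188.49513, 0.075017629,
  "N", 6.7125792, 0.34279033,
  "O", 285.89673, 0.065292051,
  "O", 20.460807, 0.27989278,
  "F", 412.04392, 0.0578028,
  "F", 44.229312, 0.23955357,
  "Ne", 570.68311, 0.051855924,
  "Ne", 84.144633, 0.20951281,
  "Na", 763.79585, 0.047054838,
  "Na", 153.95572, 0.17594095,
  "Na", 0.026667636, 1.1996339,
  "Mg", 995.98623, 0.043070403,
  "Mg", 242.61376, 0.15424245,
  "Mg", 0.17094878, 0.83273265,
  "Al", 1270.752, 0.039710905,
  "Al", 360.16653, 0.13601341,
  "Al", 0.5918544, 0.64230706,
  "Si", 1592.3981, 0.036833769,
  "Si", 493.89974, 0.12297293,
  "Si", 1.0609551, 0.57668199,
  "P", 1964.1171, 0.034345849,
  "P", 659.49588, 0.11208631,
  "P", 2.0366097, 0.50299645,
  "S", 2389.5087, 0.032173169,
  "S", 844.38333, 0.10312708,
  "S", 3.6042985, 0.44519057,
  "Cl", 2872.2206, 0.0302592,
  "Cl", 1058.6642, 0.0955395,
  "Cl", 6.1469239, 0.39606334,
  "Ar", 3416.2727, 0.028559189,
  "Ar", 1290.1776, 0.089101816,
  "Ar", 8.8757022, 0.3545091
)

#' Promolecular atomic-density model
#'
#' The per-element exponential-shell table used to build promolecular
#' densities: coefficients `c` (atomic units) and decay lengths `zeta`
#' (bohr) per shell, for H through Ar. All coefficients are positive, so
#' each atomic density is strictly decreasing in distance.
#'
#' @return A tibble with columns `element`, `c`, `zeta`.
#' @export
promolecular_model <- function() .promolecular_shells

#' Promolecular density, gradient and Hessian at arbitrary points
#'
#' The promolecular density is the sum of non-interacting spherical atomic
#' densities, `rho(p) = sum_atoms sum_shells c_i exp(-|p - R| / zeta_i)`.
#' First and second derivatives are evaluated from the closed forms of the
#' exponential sum.
#'
#' @param structure A structure tibble (coordinates in Angstrom; converted
#'   to bohr internally).
#' @param points An m x 3 matrix of evaluation points in bohr.
#' @param model Shell table, defaulting to [promolecular_model()].
#' @param hessian Also return per-point Hessians? Default `TRUE`.
#' @return A list with `rho` (length m, atomic units), `grad` (m x 3) and,
#'   if requested, `hessian` (m x 3 x 3 array).
#' @export
promolecular_density <- function(structure, points,
                                 model = promolecular_model(),
                                 hessian = TRUE) {
  validate_structure(structure)
  points <- matrix(as.numeric(points), ncol = 3)
  if (!all(is.finite(points))) stop("non-finite points", call. = FALSE)
  missing_el <- setdiff(unique(structure$element), unique(model$element))
  if (length(missing_el) > 0) {
    stop("no promolecular parameters for element(s): ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  m <- nrow(points)
  rho <- numeric(m)
  grad <- matrix(0, m, 3)
  hess <- if (hessian) array(0, dim = c(m, 3, 3)) else NULL
  centres <- coords_matrix(structure) * .ang2bohr
  for (a in seq_len(nrow(structure))) {
    shells <- model[model$element == structure$element[a], , drop = FALSE]
    dx <- points[, 1] - centres[a, 1]
    dy <- points[, 2] - centres[a, 2]
    dz <- points[, 3] - centres[a, 3]
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    r_safe <- pmax(r, 1e-10)
    for (s in seq_len(nrow(shells))) {
      e <- shells$c[s] * exp(-r / shells$zeta[s])
      rho <- rho + e
      d1 <- -e / shells$zeta[s]            # d rho / d r
      f <- d1 / r_safe
      grad[, 1] <- grad[, 1] + f * dx
      grad[, 2] <- grad[, 2] + f * dy
      grad[, 3] <- grad[, 3] + f * dz
      if (hessian) {
        d2 <- e / shells$zeta[s]^2          # d2 rho / d r2
        g2 <- (d2 - f) / r_safe^2           # (rho'' - rho'/r) / r^2
        hess[, 1, 1] <- hess[, 1, 1] + g2 * dx * dx + f
        hess[, 2, 2] <- hess[, 2, 2] + g2 * dy * dy + f
        hess[, 3, 3] <- hess[, 3, 3] + g2 * dz * dz + f
        hess[, 1, 2] <- hess[, 1, 2] + g2 * dx * dy
        hess[, 1, 3] <- hess[, 1, 3] + g2 * dx * dz
        hess[, 2, 3] <- hess[, 2, 3] + g2 * dy * dz
      }
    }
  }
  if (hessian) {
    hess[, 2, 1] <- hess[, 1, 2]
    hess[, 3, 1] <- hess[, 1, 3]
    hess[, 3, 2] <- hess[, 2, 3]
  }
  out <- list(rho = unname(rho), grad = unname(grad))
  if (hessian) out$hessian <- hess
  out
}
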