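# Noncovalent-interaction analysis on promolecular densities: the reduced
# density gradient s, the density signed by the middle Hessian eigenvalue,
# classification into attractive / van der Waals / repulsive regimes, grid
# evaluation with intermolecular masking, 2D scatter export, and a
# geometric hydrogen-bond table.

#' Reduced density gradient
#'
#' `s = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3))`, dimensionless. Low s at
#' low density marks noncovalent interaction regions.
#'
#' @param rho Positive density values, atomic units.
#' @param grad m x 3 matrix of density gradients, atomic units.
#' @return Vector of s values.
#' @export
reduced_density_gradient <- function(rho, grad) {
  if (any(rho <= 0)) stop("rho must be strictly positive", call. = FALSE)
  gn <- sqrt(rowSums(matrix(grad, ncol = 3)^2))
  gn / (2 * (3 * pi^2)^(1 / 3) * rho^(4 / 3))
}

# middle eigenvalue of symmetric 3x3 matrices, vectorised (trigonometric
# closed form, deterministic ordering)
.lambda2 <- function(h) {
  a11 <- h[, 1, 1]; a22 <- h[, 2, 2]; a33 <- h[, 3, 3]
  a12 <- h[, 1, 2]; a13 <- h[, 1, 3]; a23 <- h[, 2, 3]
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  out <- numeric(length(q))
  deg <- p < 1e-30
  out[deg] <- q[deg]
  if (any(!deg)) {
    i <- !deg
    b11 <- (a11[i] - q[i]) / p[i]; b22 <- (a22[i] - q[i]) / p[i]
    b33 <- (a33[i] - q[i]) / p[i]
    b12 <- a12[i] / p[i]; b13 <- a13[i] / p[i]; b23 <- a23[i] / p[i]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[i] + 2 * p[i] * cos(phi)
    e3 <- q[i] + 2 * p[i] * cos(phi + 2 * pi / 3)
    out[i] <- 3 * q[i] - e1 - e3
  }
  out
}

#' Density signed by the middle Hessian eigenvalue
#'
#' Computes `sign(lambda2) * rho`, where lambda2 is the middle eigenvalue
#' (ascending order) of the density Hessian at each point. Negative values
#' mark attractive (hydrogen-bond-like) interactions, values near zero van
#' der Waals contacts, positive values steric repulsion.
#'
#' @param rho Density values, atomic units.
#' @param hessian m x 3 x 3 array of symmetric density Hessians.
#' @return Vector of sign(lambda2) * rho values.
#' @export
signed_density <- function(rho, hessian) {
  if (length(dim(hessian)) != 3 || any(dim(hessian)[2:3] != 3)) {
    stop("hessian must be an m x 3 x 3 array", call. = FALSE)
  }
  asym <- max(abs(hessian[, 1, 2] - hessian[, 2, 1]),
              abs(hessian[, 1, 3] - hessian[, 3, 1]),
              abs(hessian[, 2, 3] - hessian[, 3, 2]))
  if (asym > 1e-10) {
    stop("Hessians are not symmetric (max asymmetry ",
         format(asym, digits = 3), ")", call. = FALSE)
  }
  sign(.lambda2(hessian)) * rho
}

#' Classify interaction points
#'
#' Partitions each signed-density value into exactly one class:
#' `attractive` below `-delta`, `van_der_waals` within `[-delta, delta]`,
#' `repulsive` above `delta`.
#'
#' @param signed_rho Vector of sign(lambda2) * rho values, atomic units.
#' @param delta Half-width of the van der Waals band (default 0.01 au).
#' @return Factor with levels attractive, van_der_waals, repulsive.
#' @export
classify_points <- function(signed_rho, delta = 0.01) {
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  cls <- ifelse(signed_rho < -delta, "attractive",
                ifelse(signed_rho > delta, "repulsive", "van_der_waals"))
  factor(cls, levels = c("attractive", "van_der_waals", "repulsive"))
}

#' Evaluate NCI fields on a regular grid
#'
#' Builds an axis-aligned grid over the complex bounding box (plus
#' padding), evaluates the promolecular density, its gradient and Hessian,
#' the reduced density gradient and sign(lambda2) * rho, and masks points
#' for scatter export: points denser than `rho_cutoff` are dropped, and
#' with `intermolecular_only` a point is kept only where every fragment
#' contributes at least `min_fragment_share` of the total density.
#'
#' @param complex Structure tibble; the `fragment` column (ligand vs
#'   site/cap) defines the two promolecular fragments.
#' @param spacing Grid spacing in bohr (default 0.2).
#' @param padding Box padding in Angstrom (default 2.0).
#' @param rho_cutoff Scatter-export density cutoff in au (default 0.05).
#' @param intermolecular_only Keep only points shared between fragments?
#' @param min_fragment_share Minimum per-fragment density share when
#'   masking intermolecular points (default 0.05).
#' @param region Optional structure subset whose bounding box (plus
#'   padding) defines the grid extent; defaults to the whole complex.
#' @param model Promolecular shell table.
#' @return An `nci_grid` object: list with the grid geometry (`origin`,
#'   `spacing`, `dims`, bohr), arrays `rho`, `rdg`, `signed_rho`, logical
#'   array `mask` (points eligible for scatter export), the recommended
#'   surface `isovalue` (0.3 au) and per-fragment density arrays.
#' @export
nci_grid <- function(complex, spacing = 0.2, padding = 2.0,
                     rho_cutoff = 0.05, intermolecular_only = FALSE,
                     min_fragment_share = 0.05, region = NULL,
                     model = promolecular_model()) {
  validate_structure(complex)
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  box_src <- if (is.null(region)) complex else region
  bb <- coords_matrix(box_src) * .ang2bohr
  pad <- padding * .ang2bohr
  lo <- apply(bb, 2, min) - pad
  hi <- apply(bb, 2, max) + pad
  dims <- pmax(as.integer(ceiling((hi - lo) / spacing)) + 1L, 2L)
  if (prod(dims) == 0) stop("empty grid", call. = FALSE)
  ax <- lapply(1:3, function(d) lo[d] + spacing * (seq_len(dims[d]) - 1))
  pts <- as.matrix(expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]]))
  pts <- pts[, c("x", "y", "z")] # z fastest, matching cube ordering
  lig <- complex[complex$fragment == "ligand", , drop = FALSE]
  rest <- complex[complex$fragment != "ligand", , drop = FALSE]
  total <- promolecular_density(complex, pts, model = model)
  rho <- total$rho
  rdg <- reduced_density_gradient(rho, total$grad)
  srho <- signed_density(rho, total$hessian)
  frag_rho <- list()
  if (nrow(lig) > 0 && nrow(rest) > 0) {
    lig_d <- promolecular_density(lig, pts, model = model, hessian = FALSE)
    frag_rho <- list(ligand = lig_d$rho, site = rho - lig_d$rho)
  }
  mask <- rho <= rho_cutoff
  if (intermolecular_only) {
    if (length(frag_rho) < 2) {
      mask <- rep(FALSE, length(rho)) # single fragment: nothing is shared
    } else {
      share_lig <- frag_rho$ligand / rho
      mask <- mask & share_lig >= min_fragment_share &
        (1 - share_lig) >= min_fragment_share
    }
  }
  to_arr <- function(v) aperm(array(v, dim = rev(dims)), c(3, 2, 1))
  structure(
    list(origin = lo, spacing = spacing, dims = dims,
         rho = to_arr(rho), rdg = to_arr(rdg), signed_rho = to_arr(srho),
         mask = to_arr(mask), isovalue = 0.3,
         fragment_rho = lapply(frag_rho, to_arr),
         rho_cutoff = rho_cutoff,
         intermolecular_only = intermolecular_only),
    class = "nci_grid"
  )
}

#' @export
print.nci_grid <- function(x, ...) {
  cat("NCI grid:", paste(x$dims, collapse = " x "), "points at",
      x$spacing, "bohr spacing\n")
  cat(sprintf("  rho range: %.4g .. %.4g au\n", min(x$rho), max(x$rho)))
  cat(sprintf("  sign(lambda2)rho range: %.4g .. %.4g au\n",
              min(x$signed_rho), max(x$signed_rho)))
  cat("  points in scatter mask:", sum(x$mask), "/", length(x$mask), "\n")
  invisible(x)
}

#' Export the RDG scatter data
#'
#' Writes the two-column text file (sign(lambda2) rho, s) that 2D NCI
#' plots are drawn from, omitting masked-out points.
#'
#' @param result An [nci_grid()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
scatter_export <- function(result, path) {
  stopifnot(inherits(result, "nci_grid"))
  df <- tibble::tibble(
    signed_rho = as.vector(result$signed_rho)[as.vector(result$mask)],
    s = as.vector(result$rdg)[as.vector(result$mask)]
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Cube-file exports of the NCI fields
#'
#' Writes the density and RDG fields of an [nci_grid()] result as Gaussian
#' cube files (`<prefix>-dens.cube`, `<prefix>-grad.cube`).
#'
#' @param result An [nci_grid()] result.
#' @param complex The structure the grid was evaluated on.
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
nci_export_cubes <- function(result, complex, prefix) {
  stopifnot(inherits(result, "nci_grid"))
  g <- function(vals) grid_field(result$origin, diag(result$spacing, 3),
                                 result$dims, vals)
  paths <- c(paste0(prefix, "-dens.cube"), paste0(prefix, "-grad.cube"))
  write_cube(g(result$rho), complex, paths[1],
             comment = c("promolecular density (au)",
                         sprintf("NCI isovalue %.2f au", result$isovalue)))
  write_cube(g(result$rdg), complex, paths[2],
             comment = c("reduced density gradient s",
                         sprintf("NCI isovalue %.2f au", result$isovalue)))
  invisible(paths)
}

#' Geometric hydrogen-bond table
#'
#' Detects donor-H...acceptor contacts: the hydrogen must sit within a
#' covalent-radius cutoff of an electronegative donor (O, N or S), the
#' H...acceptor distance must not exceed `dist_max`, and the D-H...A angle
#' must be at least `angle_min`. The role is assigned from the donor's
#' fragment (`ligand->protein` or `protein->ligand`).
#'
#' @param complex Structure tibble with hydrogens present.
#' @param dist_max Maximum H...acceptor distance, Angstrom (default 2.5).
#' @param angle_min Minimum D-H...A angle, degrees (default 120).
#' @param inter_only Report only contacts between different fragments?
#'   Default `TRUE`.
#' @return Tibble with one row per contact: indices and identities of
#'   donor, hydrogen and acceptor, the H...A distance, the D-H...A angle
#'   and the role.
#' @export
hbond_table <- function(complex, dist_max = 2.5, angle_min = 120,
                        inter_only = TRUE) {
  validate_structure(complex)
  empty <- tibble::tibble(
    donor_idx = integer(0), h_idx = integer(0), acceptor_idx = integer(0),
    donor_name = character(0), donor_residue = character(0),
    acceptor_name = character(0), acceptor_residue = character(0),
    distance = numeric(0), angle = numeric(0), role = character(0)
  )
  h_idx <- which(complex$element == "H")
  if (length(h_idx) == 0) {
    warning("no hydrogens present; returning empty hydrogen-bond table",
            call. = FALSE)
    return(empty)
  }
  xyz <- coords_matrix(complex)
  en_idx <- which(complex$element %in% c("O", "N", "S"))
  rows <- list()
  for (h in h_idx) {
    dvec <- sqrt(colSums((t(xyz[en_idx, , drop = FALSE]) - xyz[h, ])^2))
    cutoff <- 1.3 * (element_covalent("H") +
                       element_covalent(complex$element[en_idx]))
    donors <- en_idx[dvec > 1e-8 & dvec <= cutoff]
    if (length(donors) == 0) next
    donor <- donors[which.min(dvec[match(donors, en_idx)])]
    acceptors <- setdiff(en_idx, donor)
    for (a in acceptors) {
      ha <- xyz[a, ] - xyz[h, ]
      dist <- sqrt(sum(ha^2))
      if (dist < 1e-8 || dist > dist_max) next
      hd <- xyz[donor, ] - xyz[h, ]
      cosang <- sum(ha * hd) / (dist * sqrt(sum(hd^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang < angle_min) next
      lig_d <- complex$fragment[donor] == "ligand"
      lig_a <- complex$fragment[a] == "ligand"
      if (inter_only && lig_d == lig_a) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        donor_idx = donor, h_idx = h, acceptor_idx = a,
        donor_name = complex$name[donor],
        donor_residue = paste0(complex$residue_name[donor],
                               complex$residue_seq[donor]),
        acceptor_name = complex$name[a],
        acceptor_residue = paste0(complex$residue_name[a],
                                  complex$residue_seq[a]),
        distance = dist, angle = ang,
        role = if (lig_d) "ligand->protein" else "protein->ligand"
      )
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}
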