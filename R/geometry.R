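# Rigid-body geometry: dihedral rotations about bonds and Kabsch
# least-squares superposition.

#' Define a rotatable dihedral
#'
#' @param atom_indices Integer vector `c(i, j, k, l)` of four distinct
#'   ligand atom indices; the rotation axis is the j-k bond.
#' @param rotating_set Indices of atoms displaced by the rotation. Must
#'   contain `l` and exclude `i`, `j`, `k`.
#' @return A `dihedral_spec` object.
#' @export
dihedral_spec <- function(atom_indices, rotating_set) {
  atom_indices <- as.integer(atom_indices)
  rotating_set <- as.integer(rotating_set)
  if (length(atom_indices) != 4 || anyDuplicated(atom_indices)) {
    stop("atom_indices must be four distinct indices", call. = FALSE)
  }
  if (!atom_indices[4] %in% rotating_set) {
    stop("rotating_set must contain the fourth dihedral atom", call. = FALSE)
  }
  if (any(atom_indices[1:3] %in% rotating_set)) {
    stop("rotating_set must exclude the first three dihedral atoms",
         call. = FALSE)
  }
  structure(list(atom_indices = atom_indices, rotating_set = rotating_set),
            class = "dihedral_spec")
}

#' Measure a dihedral angle
#'
#' @param pose A structure tibble.
#' @param spec A [dihedral_spec()].
#' @return Angle in degrees in `[0, 360)`.
#' @export
measure_dihedral <- function(pose, spec) {
  p <- coords_matrix(pose)[spec$atom_indices, ]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  (ang + 360) %% 360
}

#' Rotate a dihedral by a given angle
#'
#' Rotates the atoms in `spec$rotating_set` about the j-to-k bond axis by
#' `angle` degrees (right-hand rule looking from j towards k). Being a
#' rigid rotation of the moving set, all internal distances within the
#' rotating set and within the static set are preserved exactly.
#'
#' @param pose A structure tibble (ligand).
#' @param spec A [dihedral_spec()].
#' @param angle Rotation angle in degrees.
#' @return The pose with rotated coordinates.
#' @export
rotate_dihedral <- function(pose, spec, angle) {
  stopifnot(inherits(spec, "dihedral_spec"), is.finite(angle))
  xyz <- coords_matrix(pose)
  j <- spec$atom_indices[2]; k <- spec$atom_indices[3]
  axis <- xyz[k, ] - xyz[j, ]
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-6) {
    stop("degenerate rotation axis: atoms ", j, " and ", k,
         " are closer than 1e-6 Angstrom", call. = FALSE)
  }
  u <- axis / nrm
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  rot <- ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
  idx <- spec$rotating_set
  moved <- sweep(xyz[idx, , drop = FALSE], 2, xyz[k, ]) %*% t(rot)
  xyz[idx, ] <- sweep(moved, 2, xyz[k, ], "+")
  set_coords(pose, xyz)
}

# optimal proper rotation (Kabsch, via SVD) mapping centred B onto centred
# A when applied as B %*% R: maximises tr(R' B' A) over rotations
.kabsch_rotation <- function(a_centred, b_centred) {
  h <- crossprod(b_centred, a_centred)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root-mean-square deviation with optional Kabsch superposition
#'
#' With `superpose = TRUE` the optimal translation and proper rotation
#' (determinant +1) minimising the RMSD are applied to `pose_b` before
#' measuring. Atom correspondence is by row order; atom counts must match.
#'
#' @param pose_a,pose_b Structure tibbles (or n x 3 coordinate matrices)
#'   with equal atom counts and corresponding order.
#' @param superpose Apply optimal superposition first? Default `TRUE`.
#'   Requires at least three non-collinear atoms.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(pose_a, pose_b, superpose = TRUE) {
  a <- if (is.matrix(pose_a)) pose_a else coords_matrix(pose_a)
  b <- if (is.matrix(pose_b)) pose_b else coords_matrix(pose_b)
  if (nrow(a) != nrow(b)) {
    stop("atom counts differ: ", nrow(a), " vs ", nrow(b), call. = FALSE)
  }
  if (superpose) {
    if (nrow(a) < 3 || qr(sweep(a, 2, colMeans(a)))$rank < 2) {
      stop("superposition requires at least 3 non-collinear atoms",
           call. = FALSE)
    }
    ac <- sweep(a, 2, colMeans(a))
    bc <- sweep(b, 2, colMeans(b))
    b <- bc %*% .kabsch_rotation(ac, bc)
    a <- ac
  }
  sqrt(mean(rowSums((a - b)^2)))
}
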