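# Gaussian cube volumetric files, the standard carrier for NCI density and
# RDG fields. Grids are in atomic units (bohr); structures convert from
# Angstrom at this boundary only.

#' Construct a volumetric grid field
#'
#' @param origin Numeric length-3 grid origin, bohr.
#' @param axes 3 x 3 matrix of step vectors (rows), bohr.
#' @param dims Integer length-3 number of points along each axis.
#' @param values Numeric array of dimension `dims` (or a vector of length
#'   `prod(dims)`, filled with the first axis slowest).
#' @return A `grid_field` object.
#' @export
grid_field <- function(origin, axes, dims, values) {
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, all(dim(axes) == c(3, 3)), length(dims) == 3)
  if (any(dims < 1)) stop("dims must be positive", call. = FALSE)
  if (abs(det(axes)) < 1e-12) {
    stop("grid axes are not linearly independent", call. = FALSE)
  }
  if (length(values) != prod(dims)) {
    stop("values length ", length(values), " does not match dims product ",
         prod(dims), call. = FALSE)
  }
  structure(
    list(origin = origin, axes = axes, dims = dims,
         values = array(as.numeric(values), dim = dims)),
    class = "grid_field"
  )
}

#' Write a grid field to a Gaussian cube file
#'
#' Header carries the atom count and origin in bohr; one line per atom
#' (atomic number, nuclear charge, bohr coordinates); values in z-fastest
#' order, six per line. Structure coordinates are converted from Angstrom
#' with the factor 1.8897259886.
#'
#' @param grid A [grid_field()].
#' @param structure A structure tibble.
#' @param path Output path.
#' @param comment Two free-text header lines.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, structure, path,
                       comment = c("pocketconf cube",
                                   "isovalue 0.3 au recommended for NCI")) {
  stopifnot(inherits(grid, "grid_field"))
  validate_structure(structure)
  comment <- rep_len(comment, 2)
  n <- nrow(structure)
  hdr <- c(
    comment,
    sprintf("%5d %11.6f %11.6f %11.6f", n,
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[1],
            grid$axes[1, 1], grid$axes[1, 2], grid$axes[1, 3]),
    sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[2],
            grid$axes[2, 1], grid$axes[2, 2], grid$axes[2, 3]),
    sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[3],
            grid$axes[3, 1], grid$axes[3, 2], grid$axes[3, 3])
  )
  z <- element_number(structure$element)
  cm <- coords_matrix(structure) * .ang2bohr
  atoms <- sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z, as.numeric(z),
                   cm[, 1], cm[, 2], cm[, 3])
  # z fastest, then y, then x
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))
  vlines <- vapply(
    split(vals, ceiling(seq_along(vals) / 6)),
    function(v) paste(sprintf("%13.5E", v), collapse = " "),
    character(1)
  )
  writeLines(c(hdr, atoms, vlines), path)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' Inverse of [write_cube()]; used mainly for round-trip checks and for
#' consuming externally produced grids.
#'
#' @param path Path to a cube file.
#' @return A list with `grid` (a [grid_field()]) and `structure` (a
#'   structure tibble with coordinates converted back to Angstrom).
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parse_row <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr3 <- parse_row(lines[3])
  natom <- as.integer(hdr3[1])
  origin <- hdr3[2:4]
  ax <- t(vapply(4:6, function(i) parse_row(lines[i]), numeric(4)))
  dims <- as.integer(ax[, 1])
  axes <- ax[, 2:4, drop = FALSE]
  at <- t(vapply(7:(6 + natom), function(i) parse_row(lines[i]), numeric(5)))
  sym <- .element_table$element[match(as.integer(at[, 1]),
                                      .element_table$number)]
  structure <- mol_structure(sym,
                             x = at[, 3] / .ang2bohr,
                             y = at[, 4] / .ang2bohr,
                             z = at[, 5] / .ang2bohr)
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + natom))]), "\\s+")))
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  list(grid = grid_field(origin, axes, dims, arr), structure = structure)
}
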