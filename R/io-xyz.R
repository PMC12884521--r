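# Plain XYZ is the conformer exchange format: element symbol plus Angstrom
# coordinates, with multi-frame files holding one conformer per frame.

#' Write structures to an XYZ file
#'
#' @param structure A structure tibble, or a list of structure tibbles for
#'   a multi-frame file.
#' @param path Output path.
#' @param digits Decimal places for coordinates (default 8, so round trips
#'   preserve coordinates well beyond the 1e-6 Angstrom contract).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, digits = 8) {
  frames <- if (is.data.frame(structure)) list(structure) else structure
  if (length(frames) == 0) stop("no structures to write", call. = FALSE)
  out <- character(0)
  for (fr in frames) {
    validate_structure(fr)
    title <- attr(fr, "title") %||% ""
    body <- sprintf(paste0("%-3s %.", digits, "f %.", digits, "f %.",
                           digits, "f"),
                    fr$element, fr$x, fr$y, fr$z)
    out <- c(out, as.character(nrow(fr)), title, body)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an XYZ file
#'
#' `read_xyz()` returns a single structure tibble and errors if the file
#' holds more than one frame; `read_xyz_frames()` returns a list of
#' structures, one per frame, in file order.
#'
#' @param path Path to an XYZ file.
#' @return A structure tibble, or a list of them.
#' @export
read_xyz <- function(path) {
  frames <- read_xyz_frames(path)
  if (length(frames) != 1) {
    stop(path, " contains ", length(frames),
         " frames; use read_xyz_frames()", call. = FALSE)
  }
  frames[[1]]
}

#' @rdname read_xyz
#' @export
read_xyz_frames <- function(path) {
  if (!file.exists(path)) stop("cannot read XYZ file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      stop("bad atom count on line ", i, " of ", path, call. = FALSE)
    }
    if (i + 1 + n > length(lines)) {
      stop("element count mismatch with header on line ", i, " of ", path,
           call. = FALSE)
    }
    title <- lines[i + 1]
    body <- lines[(i + 2):(i + 1 + n)]
    tok <- strsplit(trimws(body), "\\s+")
    if (any(vapply(tok, length, 0L) < 4)) {
      stop("malformed XYZ atom line in frame starting at line ", i,
           call. = FALSE)
    }
    fr <- mol_structure(
      element = vapply(tok, `[`, "", 1),
      x = as.numeric(vapply(tok, `[`, "", 2)),
      y = as.numeric(vapply(tok, `[`, "", 3)),
      z = as.numeric(vapply(tok, `[`, "", 4)),
      title = title
    )
    frames[[length(frames) + 1]] <- fr
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop("no frames in ", path, call. = FALSE)
  frames
}

`%||%` <- function(a, b) if (is.null(a)) b else a
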